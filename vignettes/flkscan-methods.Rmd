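---
title: "Hierarchical FLK and hapFLK scans: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical FLK and hapFLK scans: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the drift model behind FLK, the haplotype-cluster model behind hapFLK, how
both are calibrated, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one defensible
choice existed.

## The drift model and FLK

A group of related populations descends from a common ancestor along a
tree. For a biallelic SNP with ancestral frequency $p_0$, pure drift makes
the vector $p$ of present-day population frequencies a random walk with

$$\mathbb{E}[p] = p_0 \mathbf{1}, \qquad
  \mathrm{Cov}(p) = p_0(1-p_0)\,F,$$

where the kinship matrix $F$ collects shared branch lengths: $F_{ij}$ is
the drift variance accumulated on the part of the tree shared by the
root-to-tip paths of populations $i$ and $j$, and $F_{ii}$ is the total
root-to-tip drift of population $i$. Branch lengths are in *drift units*:
a branch of length $d$ adds variance $d\,p(1-p)$.

FLK is the Mahalanobis norm of the deviation from the GLS-estimated
ancestral frequency,
$\hat p_0 = (\mathbf{1}^\top F^{-1}\mathbf{1})^{-1}\mathbf{1}^\top F^{-1}p$:

$$T = (p - \hat p_0\mathbf{1})^\top
      \left[\hat p_0(1-\hat p_0) F\right]^{-1}
      (p - \hat p_0\mathbf{1}).$$

If the deviations were exactly Gaussian and $F$ known, $T$ would be
$\chi^2_{n-1}$ (one degree of freedom is absorbed by $\hat p_0$). In
practice the scan estimates the degrees of freedom as the genome-wide mean
of the retained statistics, which absorbs residual scale error in $F$; the
theoretical $n-1$ is available as an option. SNPs whose estimated
ancestral minor allele frequency is not strictly above 5% are excluded
(`maf_min`): the model assumes the polymorphism existed in the ancestor,
and the $\chi^2$ approximation degrades for rare alleles.

### Estimating the tree and $F$

$F$ is estimated from the data: Reynolds distances between population
pairs (multilocus ratio-of-sums estimator), Neighbor-Joining, rooting on a
strongly diverged outgroup population, then shared path lengths. Two
points deserve emphasis because they are easy to get wrong:

* **Units.** The Reynolds distance between two populations estimates the
  *mean* of their two drift accumulations since the common ancestor —
  half the tree-path length in drift units. `population_tree()` therefore
  doubles the distance matrix before Neighbor-Joining; without this the
  fitted $F$ is half the drift covariance and the statistic twice its
  nominal scale. With the conversion, simulations in the test suite
  recover true $F$ entries within 20% relative error at 10,000 SNPs.
* **Sampling noise belongs in $F$.** Allele frequencies are estimated
  from finite samples, so observed frequency differences include binomial
  noise of order $1/(2N)$ on top of drift. The Reynolds estimator absorbs
  this into the estimated branch lengths, which is exactly what keeps $T$
  calibrated when the same genotypes are used for both $F$ and the scan.
  Consequently the estimated $F$ exceeds the purely demographic drift by
  the sampling term — visible in the worked example in the README, where
  populations of 25 diploids with drift 0.05 yield $\hat F_{ii}\approx
  0.07$–$0.10$.

Negative Neighbor-Joining branch estimates are truncated to zero so that
$F$ stays interpretable (and positive semidefinite); the outgroup is used
only for rooting and never enters $F$ or any statistic. If several
populations collapse to identical positions the resulting $F$ can be
singular; a $10^{-8}$ ridge is added with a warning.

## The haplotype-cluster model and hapFLK

Local haplotype structure is modelled by a mixture of $K$ ancestral
haplotype clusters: along a chromosome, a haplotype is a mosaic of
cluster memberships, switching between markers $m-1$ and $m$ with jump
probability $\rho_m$ and re-entering cluster $k$ with weight
$\alpha_{mk}$; cluster $k$ emits the B allele at marker $m$ with frequency
$\theta_{mk}$. On unphased genotypes the hidden state of an individual is
the unordered pair of clusters carried by its two chromosomes. The
implementation runs the EM E-step over the ordered-pair product chain
($K^2$ states), which is an exact reparameterisation of the unordered
state space (the likelihood and all posteriors are identical); the
rank-one structure of the transition matrix makes each forward–backward
step $O(K^2)$ rather than $O(K^4)$. M-step updates are closed-form;
parameters are clipped to their natural ranges
($\theta \in [10^{-6}, 1-10^{-6}]$, $\rho \in [10^{-6}, 0.5]$), and since
each clipped update still maximizes the constrained Q-function the
log-likelihood trace remains non-decreasing (asserted for every fit in the
tests, with $10^{-8}$ slack). Identical data and seed give bitwise
identical fits.

Per population $i$, marker $m$ and cluster $k$, the local cluster
frequency is the average over the population's individuals of the
posterior expected count of cluster $k$ in the individual's pair, divided
by two. hapFLK treats the $K$ clusters as alleles of a multiallelic locus:
with cluster frequency matrix $P$ (clusters $\times$ populations) and GLS
ancestral cluster frequencies $p_0$, the statistic is the quadratic form
of $\mathrm{vec}(P - p_0\mathbf{1}^\top)$ under the covariance
$F \otimes (\mathrm{diag}(p_0) - p_0p_0^\top)$ with a Moore–Penrose
pseudo-inverse. Because every population's residuals sum to zero over
clusters, this reduces to
$\sum_k r_k^\top F^{-1} r_k / p_{0k}$ — the form actually computed, and
verified in the tests against an explicit eigendecomposition
pseudo-inverse.

The scan averages the statistic over `nfits = 20` EM runs started from
different seeded initializations; averaging reduces the initialization
variance of the statistic at neutral markers (asserted in the acceptance
tests). p-values are one-sided upper tails of a normal distribution whose
location and scale are estimated robustly (median, and MAD scaled by
1.4826), so that the handful of selected regions cannot contaminate the
null fit. One-sided because only an *excess* of haplotype differentiation
is selection-like; a deficit is not a signal in this framework.

### Rare clusters

No SNP-style MAF filter applies to hapFLK as a whole, but a cluster whose
estimated ancestral frequency at a marker is very small behaves exactly
like a rare allele: its $1/p_{0k}$ term dominates the statistic and breaks
the normal approximation of the null. At the sample sizes this package
targets, locally rare clusters are common (the 5% quantile of the
per-marker minimum ancestral cluster frequency is below 0.01 in neutral
simulations). Cluster components with ancestral frequency at or below
`cluster_min_freq = 0.05` are therefore dropped from the statistic at that
marker — the direct analogue of the single-SNP ancestral-MAF rule, and
measurably necessary: without it the neutral tail mass at $p<0.05$ is
0.09–0.2 instead of ≈0.05.

### Choosing $K$

The number of clusters is chosen by masking cross-validation: a fraction
(`cv_mask = 0.05`) of genotype cells is hidden, the model fitted, the
hidden genotypes imputed by posterior expectation, and the mean squared
imputation error compared across the candidate grid; ties go to the
smaller $K$. Cross-validation fits run to tighter convergence
(`cv_max_iter = 60`, `cv_tol = 1e-4`) than scan fits (`max_iter = 20`,
`tol = 0.01`): the comparison rests on small held-out differences that
only well-converged fits resolve — an under-converged large-$K$ model has
not yet overfitted, which hides the penalty cross-validation relies on —
whereas scan fits are averaged over many runs, so per-run convergence
matters much less there. With five folds the generating $K$ is recovered
in 20/20 simulated replicates in the acceptance suite.

## Ancestral (between-group) scan

Within-group scans yield, per SNP, the GLS estimate of the group-ancestral
frequency. These estimates play the role of observed frequencies for a
second-level FLK across groups, with two filters applied first:

1. SNPs whose derived allele was observed in fewer than two groups are
   removed — such variants most likely arose after the group ancestors
   diverged, violating the ancestral-polymorphism assumption.
2. SNPs inside any within-group selection signature are removed, because
   within-group selection biases that group's ancestral estimate. Both
   FLK and hapFLK regions are excluded when available (an open choice;
   excluding both is the conservative reading).

The ancestor tree is built from Reynolds distances between the group
frequencies, restricted to SNPs with known ancestral allele, and rooted on
an artificial outgroup whose derived-allele frequency is zero everywhere —
the ancestral-allele table thus replaces the outgroup breed of the
within-group scans. SNPs without ancestral information are excluded from
tree building only, not from the test itself.

## Region calling and candidate genes

Significant SNPs (Storey q-value below 0.10 for FLK, 0.05 for hapFLK and
the ancestral scan) are grouped: for FLK, SNPs less than 500 kb apart
capture the same signal and merge transitively; candidate genes are all
genes whose nearest edge lies within 1 Mb of any significant SNP. For
hapFLK the signal is spatially continuous, so significant runs are kept
contiguous and the *candidate span* is the maximal stretch around the peak
where the statistic stays within $0.5\,\hat\sigma$ of the peak value
($\hat\sigma$ the genome-wide robust SD — the natural unit for a rule
phrased on the statistic scale); plateaus give broad spans, sharp peaks
narrow ones. Genes are ranked by the distance between the peak position
and the nearest gene edge (zero if the peak falls inside the gene), ties
broken by gene start. The per-region "most differentiated populations"
annotation scores each population by its drift-standardized deviation
$|p_i - \hat p_0| / \sqrt{F_{ii}\hat p_0(1-\hat p_0)}$ at the peak SNP and
reports those within 80% of the maximum; it is a heuristic label, not a
test.

$\pi_0$ for the q-values uses the single-$\lambda$ plug-in
$\#\{p > 0.5\} / (0.5\,m)$, clipped to $(0,1]$ — simple and stable at
genome scale; with $\pi_0$ fixed at 1 the q-values are exactly
Benjamini–Hochberg, which the tests assert.

Populations with fewer than 20 genotyped animals are dropped before a
group is scanned; below that, haplotype diversity (and even allele
frequencies) cannot be estimated precisely enough.

## The synthetic-data generator

The generator emulates the statistical regime the scans assume, not any
particular species:

* **Frequencies** drift along a user-supplied rooted tree by
  Balding–Nichols Beta steps: child frequency Beta-distributed with mean
  equal to the parent and variance $d\,p(1-p)$ for branch length $d < 1$.
  Fixed frequencies (0 or 1) stay fixed. This matches the FLK covariance
  model directly and is orders of magnitude faster than generation-by-
  generation Wright–Fisher; branch lengths of 1 or more are refused.
* **Genotypes** are Binomial(2, p) per individual (no-LD mode).
* **LD mode** builds an ancestral pool of $H$ haplotypes (sites Bernoulli
  on the ancestral frequencies), drifts the pool weights along the tree by
  Dirichlet perturbation with concentration $1/d - 1$ (matching the Beta
  drift variance), and samples each chromosome as a mosaic of pool
  members with switch rate $1/\text{seg\_len\_bp}$ per bp. $r^2$ between
  markers decays with distance, as the tests verify.
* **Sweeps**: hard (derived allele or haplotype to fixation), incomplete
  (to a stated final frequency) and soft (two haplotype backgrounds
  co-elevated). In frequency mode the locus frequency is set exactly and
  flanking markers move toward a template haplotype with a linear taper
  over the span — a crude but fully controllable stand-in for hitchhiking.
  In LD mode individual chromosomes are overwritten by the selected
  template over a random sub-span, with the replacement probability
  required to reach the target haplotype frequency. A sweep applied to
  several populations shares one template, emulating selection on their
  ancestral branch.

The default scenario — two groups of four populations, 25 diploids each,
10,000 SNPs on two chromosomes, ancestral frequencies Uniform(0.05, 0.95),
population and group branches of 0.05 drift units, an outgroup at 0.2 —
is sized so the full single-SNP pipeline runs in seconds and the haplotype
pipeline in minutes on one core.

What the generator does **not** emulate: coalescent recombination
genealogies (LD is mosaic-style, not ancestry-based), mutation,
bottlenecks, admixture and migration, ascertainment bias of SNP chips,
genotyping error. Passing tests therefore demonstrate correctness of the
statistical machinery under its own model assumptions — they do not
certify behaviour on real data with admixed populations, which the method
explicitly expects to be removed beforehand.

## Calibration limits worth knowing

* The $\chi^2$ calibration of FLK is excellent in the mean and at the 5%
  tail, but the p-value distribution is not perfectly uniform at strong
  drift: with four populations at 0.1 drift units the Kolmogorov–Smirnov
  distance to uniform plateaus near 0.02–0.03 *even under exactly Gaussian
  drift with the true $F$*, because the $\hat p_0(1-\hat p_0)$ rescaling
  is itself noisy with few populations. The deviation shrinks with more
  populations or less drift (below 0.015 at $d = 0.05$ or $n = 8$). The
  acceptance suite states the strict bound and records the measured value;
  practical FDR control is unaffected (the tail is conservative).
* The normal calibration of hapFLK is a large-$K(n-1)$ approximation: the
  statistic's null marginal is $\chi^2$-like with roughly $(K-1)(n-1)$
  degrees of freedom, and a median/MAD normal fit of a skewed
  distribution leaves excess upper-tail mass. With eight populations and
  $K = 6$ the p-value distribution is uniform to KS $\approx 0.03$; with
  four populations and small $K$ expect mild anticonservatism at the far
  tail. Larger groups and larger panels (where $K$ in the tens is
  supported by the data) are the intended operating regime.

## Problem sizes in the test suite

Unit and property tests run on datasets of 20–100 individuals and
25–600 markers; calibration checks use 6,000–10,000 SNPs in frequency
mode; the haplotype-model acceptance checks use 600-marker, 100–200
individual scenarios with 10–20 EM runs; power comparisons use ten
replicates of an incomplete sweep (selected haplotype at 60% in one of
four populations). The whole suite completes in roughly seven minutes on
one core, the acceptance script in about one.
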
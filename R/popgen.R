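## Population-level summaries and the neutral-drift scaffolding:
## allele frequencies, Reynolds distances, Neighbor-Joining trees,
## outgroup rooting, the kinship matrix F and ancestral frequencies.

#' Per-population allele frequencies
#'
#' @param dataset a [genotype_dataset()].
#' @param pops a [population_set()]; every genotyped individual must be
#'   assigned.
#' @param populations optional subset of populations (default: all that have
#'   individuals in `dataset`).
#' @return An object of class `allele_freq_table`: list with `freq`
#'   (populations x SNPs matrix of `allele_B` frequencies, `NA` where no
#'   genotype was observed), `count` (haploid sample counts per cell) and
#'   `snp_map`.
#' @export
compute_allele_freqs <- function(dataset, pops, populations = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(pops, "population_set"))
  unassigned <- setdiff(dataset$individual_ids, names(pops$pop))
  if (length(unassigned))
    stop("individuals without population assignment: ",
         paste(head(unassigned, 3), collapse = ", "))
  ind_pop <- pops$pop[dataset$individual_ids]
  if (is.null(populations)) populations <- unique(unname(ind_pop))
  g <- dataset$genotypes
  freq <- matrix(NA_real_, length(populations), ncol(g),
                 dimnames = list(populations, colnames(g)))
  count <- matrix(0L, length(populations), ncol(g),
                  dimnames = list(populations, colnames(g)))
  for (p in populations) {
    rows <- which(ind_pop == p)
    if (!length(rows)) next
    sub <- g[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    s <- colSums(sub, na.rm = TRUE)
    f <- ifelse(n_obs > 0L, s / (2 * n_obs), NA_real_)
    freq[p, ] <- f
    count[p, ] <- 2L * n_obs
  }
  structure(list(freq = freq, count = count, snp_map = dataset$snp_map),
            class = "allele_freq_table")
}

#' Build an allele frequency table from a plain matrix
#'
#' Used when tip frequencies are available directly (e.g. from
#' [simulate_frequencies()] or group-ancestral estimates).
#'
#' @param freq populations x SNPs numeric matrix with population row names.
#' @param snp_map optional SNP map (a default map on one chromosome is
#'   fabricated when omitted).
#' @param count optional haploid count matrix (defaults to `Inf`,
#'   i.e. noise-free frequencies).
#' @return An `allele_freq_table`.
#' @export
freq_table <- function(freq, snp_map = NULL, count = NULL) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq)))
    rownames(freq) <- paste0("P", seq_len(nrow(freq)))
  if (is.null(snp_map))
    snp_map <- data.frame(chrom = "1",
                          snp_id = paste0("snp", seq_len(ncol(freq))),
                          gpos = 0,
                          pos = seq_len(ncol(freq)) * 1000,
                          allele_A = "A", allele_B = "B",
                          stringsAsFactors = FALSE)
  if (is.null(count)) count <- matrix(Inf, nrow(freq), ncol(freq))
  structure(list(freq = freq, count = count, snp_map = snp_map),
            class = "allele_freq_table")
}

#' Reynolds genetic distances between populations
#'
#' Multilocus ratio-of-sums estimator: for populations a, b over the usable
#' SNPs,
#' \deqn{D_{ab} = \frac{\sum_l (p_{al}-p_{bl})^2 + (q_{al}-q_{bl})^2}
#'                    {2 \sum_l (1 - p_{al} p_{bl} - q_{al} q_{bl})}}
#' with \eqn{q = 1 - p}. SNPs with a missing frequency in either population
#' of a pair are excluded for that pair. The estimator is invariant to
#' relabelling alleles at any subset of SNPs.
#'
#' @param freqs an `allele_freq_table` (see [compute_allele_freqs()]).
#' @return Symmetric distance matrix with population dimnames.
#' @export
reynolds_distances <- function(freqs) {
  P <- freqs$freq
  n <- nrow(P)
  if (n < 2L) stop("need at least 2 populations")
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    pa <- P[a, ]; pb <- P[b, ]
    ok <- !is.na(pa) & !is.na(pb)
    pa <- pa[ok]; pb <- pb[ok]
    num <- sum((pa - pb)^2 + ((1 - pa) - (1 - pb))^2)
    den <- 2 * sum(1 - pa * pb - (1 - pa) * (1 - pb))
    if (den <= 0) {
      warning("zero Reynolds denominator for pair (", rownames(P)[a], ", ",
              rownames(P)[b], "); distance set to 0")
      d <- 0
    } else d <- num / den
    D[a, b] <- D[b, a] <- d
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}). Negative branch-length
#' estimates are truncated to zero so that the kinship matrix derived from the
#' tree stays interpretable as drift. For `n = 2` a single edge of length
#' `D[1,2]` is returned.
#'
#' @param D symmetric distance matrix with labels.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 populations")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(D)[1], D[1, 2] / 2,
                                        rownames(D)[2], D[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a population tree on an outgroup
#'
#' The root is placed at the point where the outgroup's pendant edge attaches
#' to the rest of the tree. The outgroup tip is retained (flagged in the
#' `"outgroup"` attribute) but excluded from kinship computation and all
#' statistics.
#'
#' @param tree `phylo` tree.
#' @param outgroup tip label.
#' @return A rooted `phylo` with attribute `"outgroup"`.
#' @export
root_tree <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup ", outgroup, " is not a tip of the tree")
  if (!ape::is.rooted(tree) || !is.null(attr(tree, "outgroup")))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  attr(tree, "outgroup") <- outgroup
  tree
}

#' Kinship (drift covariance) matrix from a rooted tree
#'
#' `F[i, j]` is the summed branch length shared by the root-to-tip paths of
#' populations i and j; `F[i, i]` is the total root-to-tip length. If the
#' tree carries an `"outgroup"` attribute (see [root_tree()]) that tip is
#' dropped first and the root taken at its attachment point.
#'
#' @param tree rooted `phylo`.
#' @return Symmetric positive semidefinite matrix over the ingroup
#'   populations.
#' @export
kinship_from_tree <- function(tree) {
  assert_rooted(tree, "kinship_from_tree needs a rooted tree")
  og <- attr(tree, "outgroup")
  if (!is.null(og) && og %in% tree$tip.label) {
    tree <- ape::drop.tip(tree, og)
    tree$root.edge <- NULL
  }
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)  # distance from root, all nodes
  F_mat <- matrix(0, ntip, ntip,
                  dimnames = list(tree$tip.label, tree$tip.label))
  if (ntip == 1L) { F_mat[1, 1] <- depth[1]; return(F_mat) }
  mrcas <- ape::mrca(tree)
  for (i in seq_len(ntip)) for (j in i:ntip) {
    F_mat[i, j] <- F_mat[j, i] <- if (i == j) depth[i] else depth[mrcas[i, j]]
  }
  F_mat
}

#' Population tree and kinship matrix from allele frequencies
#'
#' Convenience wrapper: Reynolds distances, conversion to drift-variance
#' units, Neighbor-Joining, outgroup rooting and kinship extraction.
#'
#' The Reynolds distance between two populations estimates the *mean* of
#' their drift accumulations since the common ancestor, i.e. half of the
#' tree-path length in drift-variance units (where a branch of length d
#' contributes variance d p(1-p)); the pairwise distances are therefore
#' doubled before Neighbor-Joining so that branch lengths — and hence F —
#' come out in the units the FLK covariance model requires.
#'
#' @param freqs an `allele_freq_table` including the outgroup population.
#' @param outgroup outgroup population label.
#' @param polymorphic_only drop SNPs fixed across all populations before
#'   computing distances (default `TRUE`).
#' @return List with `tree` (rooted, outgroup flagged), `D` (Reynolds
#'   distances) and `F` (kinship over the ingroup populations).
#' @export
population_tree <- function(freqs, outgroup, polymorphic_only = TRUE) {
  P <- freqs$freq
  if (!outgroup %in% rownames(P))
    stop("outgroup ", outgroup, " not present in frequency table")
  if (polymorphic_only) {
    mx <- apply(P, 2, max, na.rm = TRUE)
    mn <- apply(P, 2, min, na.rm = TRUE)
    keep <- mx > 0 & mn < 1
    freqs <- freq_table(P[, keep, drop = FALSE],
                        freqs$snp_map[keep, , drop = FALSE])
  }
  D <- reynolds_distances(freqs)
  tr <- neighbor_joining(2 * D)   # Reynolds units -> drift-variance units
  tr <- root_tree(tr, outgroup)
  list(tree = tr, D = D, F = kinship_from_tree(tr))
}

#' Generalized-least-squares estimate of the ancestral allele frequency
#'
#' Under the drift model the population frequencies p at one SNP have mean
#' `p0 * 1` and covariance `p0 (1 - p0) F`; the best linear unbiased
#' estimator of p0 is \eqn{(1' F^{-1} 1)^{-1} 1' F^{-1} p}, clipped to
#' \[0, 1\].
#'
#' @param p frequency vector over the n populations (complete).
#' @param F_mat kinship matrix.
#' @return Scalar estimate in \[0, 1\].
#' @export
estimate_ancestral_freq <- function(p, F_mat) {
  w <- gls_weights(F_mat)
  min(1, max(0, sum(w * p)))
}

## internal: rooted means a binary root (ape convention) OR an explicit flag:
## simulation trees may have a true multifurcating root, which ape cannot
## distinguish from an unrooted tree.
assert_rooted <- function(tree, msg) {
  ok <- ape::is.rooted(tree) || !is.null(attr(tree, "outgroup")) ||
    isTRUE(attr(tree, "rooted"))
  if (!ok) stop(msg)
  invisible(tree)
}

## internal: GLS weights w = F^{-1} 1 / (1' F^{-1} 1), with ridge fallback
gls_weights <- function(F_mat) {
  Fi <- tryCatch(solve(F_mat), error = function(e) {
    warning("singular kinship matrix; adding 1e-8 ridge")
    solve(F_mat + diag(1e-8, nrow(F_mat)))
  })
  ones <- rep(1, nrow(F_mat))
  w <- Fi %*% ones
  as.numeric(w / sum(w))
}

## internal: inverse of F with ridge fallback
kinship_inverse <- function(F_mat) {
  tryCatch(chol2inv(chol(F_mat)), error = function(e) {
    warning("kinship matrix not positive definite; adding 1e-8 ridge")
    solve(F_mat + diag(1e-8, nrow(F_mat)))
  })
}
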
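## Forward simulator of structured populations: Balding-Nichols Beta drift
## along a known tree, optional haplotype-mosaic LD structure, injected
## selective sweeps, and truth-aware evaluation of scans.

#' Simulation configuration
#'
#' The default scenario is a desk-scale analogue of a multi-group SNP-chip
#' study: 2 groups of 4 populations drifting from a common ancestor
#' (population branches 0.05, group branches 0.05 in drift-variance units),
#' one outgroup population (drift 0.2) used for tree rooting, 25 diploid
#' animals per population, and 10,000 SNPs evenly spaced on 2 chromosomes
#' with ancestral frequencies Uniform(0.05, 0.95).
#'
#' @param groups named list: group label -> character vector of population
#'   labels.
#' @param tree_newick rooted Newick string over all populations plus the
#'   outgroup, branch lengths in drift-variance units (a branch of length d
#'   adds variance d p(1-p)). Built automatically from `groups` when `NULL`.
#' @param d_pop,d_group,d_out branch lengths used when building the default
#'   tree.
#' @param outgroup outgroup tip label.
#' @param n_per_pop diploid sample size per population (scalar or named).
#' @param n_snps,n_chrom,spacing_bp marker layout.
#' @param p0_range range of the uniform ancestral frequency distribution.
#' @param haplotype logical: simulate haplotype-mosaic LD structure instead
#'   of independent sites.
#' @param H ancestral haplotype pool size (haplotype mode).
#' @param seg_len_bp mean mosaic segment length in bp (haplotype mode).
#' @param sweeps list of [sweep_spec()] records.
#' @param seed integer seed; identical config + seed gives identical data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(groups = list(G1 = paste0("A", 1:4),
                                     G2 = paste0("B", 1:4)),
                       tree_newick = NULL, d_pop = 0.05, d_group = 0.05,
                       d_out = 0.2, outgroup = "OUT", n_per_pop = 25,
                       n_snps = 10000, n_chrom = 2, spacing_bp = 5000,
                       p0_range = c(0.05, 0.95), haplotype = FALSE, H = 20,
                       seg_len_bp = 1e6, sweeps = list(), seed = 1) {
  pops <- unlist(groups, use.names = FALSE)
  if (is.null(tree_newick)) {
    grp_txt <- vapply(groups, function(ps)
      sprintf("(%s):%.8g", paste0(ps, ":", d_pop, collapse = ","), d_group),
      "")
    tree_newick <- sprintf("(%s,%s:%.8g);", paste(grp_txt, collapse = ","),
                           outgroup, d_out)
  }
  stopifnot(n_per_pop >= 1, n_snps >= 1)
  if (length(n_per_pop) == 1L)
    n_per_pop <- setNames(rep(n_per_pop, length(pops)), pops)
  structure(list(groups = groups, tree_newick = tree_newick,
                 outgroup = outgroup, n_per_pop = n_per_pop,
                 n_snps = n_snps, n_chrom = n_chrom,
                 spacing_bp = spacing_bp, p0_range = p0_range,
                 haplotype = haplotype, H = H, seg_len_bp = seg_len_bp,
                 sweeps = sweeps, seed = seed),
            class = "sim_config")
}

## internal: SNP map for a config
sim_snp_map <- function(config) {
  per <- ceiling(config$n_snps / config$n_chrom)
  chrom <- rep(as.character(seq_len(config$n_chrom)), each = per)[
    seq_len(config$n_snps)]
  pos <- unlist(lapply(table(chrom)[unique(chrom)], function(k)
    seq_len(k) * config$spacing_bp), use.names = FALSE)
  data.frame(chrom = chrom,
             snp_id = paste0("snp", seq_len(config$n_snps)),
             gpos = 0, pos = pos, allele_A = "A", allele_B = "B",
             stringsAsFactors = FALSE)
}

## internal: one Balding-Nichols Beta drift step; absorbing at 0/1
drift_step <- function(p, d) {
  if (d == 0) return(p)
  if (d >= 1) stop("branch length ", d, " outside the drift approximation")
  s <- 1 / d - 1
  out <- p
  seg <- p > 0 & p < 1
  out[seg] <- rbeta(sum(seg), p[seg] * s, (1 - p[seg]) * s)
  out
}

#' Simulate population allele frequencies along a tree
#'
#' Ancestral frequencies are drawn per SNP; along each branch of length d
#' the child frequency is Beta-distributed with mean equal to the parent
#' frequency and variance d p(1-p) (Balding-Nichols drift). Frequencies
#' hitting 0 or 1 stay fixed downstream.
#'
#' @param tree rooted `phylo` with branch lengths in drift-variance units
#'   (all < 1).
#' @param n_snps number of SNPs.
#' @param p0_range uniform range of ancestral frequencies, or a vector of
#'   length `n_snps` of fixed ancestral frequencies.
#' @param seed integer seed.
#' @return List: `freq` (tips x SNPs matrix), `p0` (ancestral frequencies),
#'   `F` (exact kinship implied by the tree, outgroup attribute respected).
#' @export
simulate_frequencies <- function(tree, n_snps, p0_range = c(0.05, 0.95),
                                 seed = 1) {
  attr(tree, "rooted") <- TRUE  # simulation trees are rooted by construction
  set.seed(seed %% .Machine$integer.max)
  p0 <- if (length(p0_range) == 2L)
    runif(n_snps, p0_range[1], p0_range[2]) else rep_len(p0_range, n_snps)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  node_freq <- matrix(NA_real_, nnode, n_snps)
  root <- ntip + 1L
  node_freq[root, ] <- p0
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    node_freq[child, ] <- drift_step(node_freq[par, ], tree$edge.length[e])
  }
  freq <- node_freq[seq_len(ntip), , drop = FALSE]
  rownames(freq) <- tree$tip.label
  list(freq = freq, p0 = p0, F = kinship_from_tree(tree))
}

#' Sample diploid genotypes from population frequencies
#'
#' Independent Binomial(2, p) sampling per individual (no-LD mode).
#'
#' @param freq populations x SNPs frequency matrix (row names = populations).
#' @param sizes named vector of diploid sample sizes per population.
#' @param snp_map SNP map data frame (as produced via [sim_config()]).
#' @param seed integer seed.
#' @return A [genotype_dataset()]; individual ids are
#'   `<population>_<index>`.
#' @export
simulate_genotypes <- function(freq, sizes, snp_map, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  pops <- rownames(freq)
  m <- ncol(freq)
  geno <- list(); ids <- character(0)
  for (p in pops) {
    n <- sizes[[p]]
    g <- matrix(rbinom(n * m, 2L, rep(freq[p, ], each = n)), n, m)
    geno[[p]] <- g
    ids <- c(ids, paste0(p, "_", seq_len(n)))
  }
  genotype_dataset(do.call(rbind, geno), ids, snp_map)
}

#' Simulate genotypes with haplotype-mosaic LD structure
#'
#' An ancestral pool of H haplotypes is drawn over the SNP map (alleles
#' Bernoulli on the ancestral frequencies). Pool weights drift along the
#' tree by Dirichlet perturbation with concentration `1/d - 1` on each
#' branch of length d (matching the Beta drift variance). Each individual
#' chromosome is a mosaic of pool members, switching between members at
#' rate `1/seg_len_bp` per bp; genotypes are the unphased sums of two
#' mosaics.
#'
#' @param config a [sim_config()] with `haplotype = TRUE` (`H >= 2`).
#' @param tree rooted `phylo` over the populations to sample (typically the
#'   config tree).
#' @return List: `dataset` (a [genotype_dataset()]), `haplotypes` (list per
#'   population of 2n x M allele matrices), `pool` (H x M ancestral
#'   haplotypes), `weights` (per-population pool weights), `p0`.
#' @export
simulate_haplotypes <- function(config, tree = NULL) {
  if (config$H < 2L) stop("haplotype pool size H must be at least 2")
  if (!is.null(tree)) attr(tree, "rooted") <- TRUE
  set.seed(config$seed %% .Machine$integer.max)
  map <- sim_snp_map(config)
  m <- nrow(map)
  p0 <- runif(m, config$p0_range[1], config$p0_range[2])
  pool <- matrix(rbinom(config$H * m, 1L, rep(p0, each = config$H)),
                 config$H, m)
  if (is.null(tree)) tree <- ape::read.tree(text = config$tree_newick)
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "rooted") <- TRUE
  ntip <- length(tree$tip.label)
  node_w <- matrix(NA_real_, ntip + tree$Nnode, config$H)
  node_w[ntip + 1L, ] <- rep(1 / config$H, config$H)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    d <- tree$edge.length[e]
    w <- node_w[par, ]
    if (d == 0) node_w[child, ] <- w
    else {
      conc <- (1 / min(d, 0.99)) - 1
      x <- rgamma(config$H, shape = pmax(w * conc, 1e-8))
      node_w[child, ] <- x / sum(x)
    }
  }
  pops <- tree$tip.label
  sizes <- sizes_with_outgroup(config, tree)
  weights <- node_w[seq_len(ntip), , drop = FALSE]
  rownames(weights) <- pops
  ## per-chromosome switch probabilities between adjacent markers
  gap <- c(0, diff(map$pos))
  newchrom <- c(TRUE, map$chrom[-1] != map$chrom[-m])
  p_switch <- 1 - exp(-gap / config$seg_len_bp)
  p_switch[newchrom] <- 1
  haplotypes <- list()
  for (p in pops) {
    n_hap <- 2L * sizes[[p]]
    w <- weights[p, ]
    hap <- matrix(0L, n_hap, m)
    for (h in seq_len(n_hap)) {
      switches <- runif(m) < p_switch
      seg_id <- cumsum(switches)
      members <- sample.int(config$H, max(seg_id), replace = TRUE, prob = w)
      hap[h, ] <- pool[cbind(members[seg_id], seq_len(m))]
    }
    haplotypes[[p]] <- hap
  }
  out <- list(dataset = NULL, haplotypes = haplotypes, pool = pool,
              weights = weights, p0 = p0, map = map,
              F = kinship_from_tree(tree))
  out$dataset <- haplotypes_to_dataset(out, config)
  out
}

## internal: sum haplotype pairs into a genotype_dataset
haplotypes_to_dataset <- function(sim, config) {
  pops <- names(sim$haplotypes)
  geno <- list(); ids <- character(0)
  for (p in pops) {
    hap <- sim$haplotypes[[p]]
    n <- nrow(hap) / 2L
    g <- hap[2 * seq_len(n) - 1L, , drop = FALSE] +
      hap[2 * seq_len(n), , drop = FALSE]
    geno[[p]] <- g
    ids <- c(ids, paste0(p, "_", seq_len(n)))
  }
  genotype_dataset(do.call(rbind, geno), ids, sim$map)
}

#' Specification of one injected selective sweep
#'
#' @param chrom,pos locus of the selected variant.
#' @param pops target population(s); several populations emulate a sweep on
#'   their shared ancestral branch.
#' @param type `"hard"` (derived allele/haplotype to fixation),
#'   `"incomplete"` (to `final_freq` < 1) or `"soft"` (two distinct
#'   haplotype backgrounds co-elevated).
#' @param final_freq final derived-allele/haplotype frequency (1 for hard).
#' @param span_bp length of the perturbed (hitchhiking) span centred on the
#'   locus; the perturbation tapers linearly to zero at the span edges.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, pos, pops, type = c("hard", "incomplete",
                                                  "soft"),
                       final_freq = if (match.arg(type) == "hard") 1 else 0.6,
                       span_bp = 2e6) {
  type <- match.arg(type)
  if (type == "hard") final_freq <- 1
  structure(list(chrom = as.character(chrom), pos = pos, pops = pops,
                 type = type, final_freq = final_freq, span_bp = span_bp),
            class = "sweep_spec")
}

#' Inject a selective sweep
#'
#' Frequency mode (`x` is a populations x SNPs matrix): the derived-allele
#' frequency at the locus is set exactly to `final_freq` in each target
#' population, and linked markers are moved toward the alleles of a shared
#' pseudo-haplotype with a linearly tapering effect over the span
#' (hitchhiking stand-in). Haplotype mode (`x` is the list returned by
#' [simulate_haplotypes()]): individual chromosomes of the target
#' populations are replaced, with the probability needed to reach
#' `final_freq`, by a selected template haplotype over a span that tapers
#' around the locus; soft sweeps split the replacement over two distinct
#' templates.
#'
#' @param x frequency matrix or [simulate_haplotypes()] output.
#' @param spec a [sweep_spec()].
#' @param snp_map SNP map (frequency mode).
#' @param seed integer seed.
#' @return List: `data` (modified object of the same kind as `x`) and
#'   `truth` (data frame: chrom, pos, pops, type, final_freq, span_begin,
#'   span_end).
#' @export
inject_sweep <- function(x, spec, snp_map = NULL, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  truth <- data.frame(chrom = spec$chrom, pos = spec$pos,
                      pops = paste(spec$pops, collapse = " "),
                      type = spec$type, final_freq = spec$final_freq,
                      span_begin = spec$pos - spec$span_bp / 2,
                      span_end = spec$pos + spec$span_bp / 2,
                      stringsAsFactors = FALSE)
  if (is.matrix(x)) {
    if (is.null(snp_map)) stop("snp_map needed in frequency mode")
    loc <- which(snp_map$chrom == spec$chrom & snp_map$pos == spec$pos)
    if (!length(loc)) stop("sweep locus not on the SNP map")
    in_span <- snp_map$chrom == spec$chrom &
      abs(snp_map$pos - spec$pos) <= spec$span_bp / 2
    taper <- ifelse(in_span,
                    1 - abs(snp_map$pos - spec$pos) / (spec$span_bp / 2), 0)
    n_templates <- if (spec$type == "soft") 2L else 1L
    ## template haplotypes shared across target populations, so that a sweep
    ## applied to several populations mimics one on their ancestral branch
    templates <- lapply(seq_len(n_templates), function(tpl) {
      h <- rbinom(ncol(x), 1L, x[spec$pops[1], ])
      h[loc] <- 1L
      h
    })
    for (p in spec$pops) {
      pcur <- x[p, loc]
      if (spec$final_freq <= pcur)
        stop("final frequency must exceed the current frequency (",
             signif(pcur, 3), ") in population ", p)
      q_tot <- (spec$final_freq - pcur) / (1 - pcur)
      for (h in templates) {
        w <- taper * q_tot / n_templates
        x[p, ] <- (1 - w) * x[p, ] + w * h
      }
      x[p, loc] <- spec$final_freq
    }
    return(list(data = x, truth = truth))
  }
  ## haplotype mode
  sim <- x
  map <- sim$map
  loc <- which(map$chrom == spec$chrom & map$pos == spec$pos)
  if (!length(loc)) stop("sweep locus not on the SNP map")
  chr_idx <- which(map$chrom == spec$chrom)
  n_templates <- if (spec$type == "soft") 2L else 1L
  ## selected templates: the most frequent pool members whose weight is
  ## still below the target haplotype frequency, forced derived at the locus
  first_pop <- spec$pops[1]
  w0 <- sim$weights[first_pop, ]
  ord <- order(w0, decreasing = TRUE)
  ord <- c(ord[w0[ord] < spec$final_freq], ord[w0[ord] >= spec$final_freq])
  members <- ord[seq_len(n_templates)]
  templates <- lapply(members, function(i) {
    h <- sim$pool[i, ]
    h[loc] <- 1L
    h
  })
  for (p in spec$pops) {
    hap <- sim$haplotypes[[p]]
    ## current frequency of the selected haplotype background(s)
    pcur <- sum(sim$weights[p, members])
    if (spec$final_freq <= pcur)
      stop("final haplotype frequency must exceed the selected background's ",
           "current frequency (", signif(pcur, 3), ") in population ", p)
    q_tot <- (spec$final_freq - pcur) / (1 - pcur)
    for (h_i in seq_len(nrow(hap))) {
      if (runif(1) >= q_tot) next
      tpl <- templates[[sample.int(n_templates, 1L)]]
      ext_l <- runif(1, 0, spec$span_bp / 2)
      ext_r <- runif(1, 0, spec$span_bp / 2)
      seg <- chr_idx[map$pos[chr_idx] >= spec$pos - ext_l &
                       map$pos[chr_idx] <= spec$pos + ext_r]
      hap[h_i, seg] <- tpl[seg]
    }
    sim$haplotypes[[p]] <- hap
  }
  sim$dataset <- NULL  # stale; rebuilt by the caller via haplotypes_to_dataset
  list(data = sim, truth = truth)
}

#' Simulate a complete structured-population dataset
#'
#' Runs the full generator for a [sim_config()]: tree parsing, frequency or
#' haplotype simulation, sweep injection, genotype sampling, population
#' assignments and truth records.
#'
#' @param config a [sim_config()].
#' @return List: `dataset` ([genotype_dataset()]), `pops`
#'   ([population_set()], outgroup population assigned to group `"OUT"`),
#'   `tree` (true rooted `phylo` with the outgroup flagged), `F` (true
#'   ingroup kinship), `freq` (true tip frequencies, frequency mode only),
#'   `p0` (true ancestral frequencies), `truth` (sweep truth table),
#'   `ancestral` (per-SNP ancestral allele, always `"A"`: allele B is the
#'   derived allele throughout the simulator).
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- ape::read.tree(text = config$tree_newick)
  map <- sim_snp_map(config)
  truth <- NULL
  if (config$haplotype) {
    sim <- simulate_haplotypes(config, tree)
    for (i in seq_along(config$sweeps)) {
      res <- inject_sweep(sim, config$sweeps[[i]],
                          seed = config$seed + 7000 + i)
      sim <- res$data
      truth <- rbind(truth, res$truth)
    }
    sim$dataset <- haplotypes_to_dataset(sim, config)
    dataset <- sim$dataset
    freq <- NULL; p0 <- sim$p0
  } else {
    fr <- simulate_frequencies(tree, config$n_snps, config$p0_range,
                               seed = config$seed)
    freq <- fr$freq; p0 <- fr$p0
    for (i in seq_along(config$sweeps)) {
      res <- inject_sweep(freq, config$sweeps[[i]], snp_map = map,
                          seed = config$seed + 7000 + i)
      freq <- res$data
      truth <- rbind(truth, res$truth)
    }
    dataset <- simulate_genotypes(freq, sizes_with_outgroup(config, tree),
                                  map, seed = config$seed + 1)
  }
  pop_of <- sub("_[0-9]+$", "", dataset$individual_ids)
  grp_map <- c(unlist(lapply(names(config$groups), function(g)
    setNames(rep(g, length(config$groups[[g]])), config$groups[[g]]))),
    setNames("OUT", config$outgroup))
  pops <- population_set(dataset$individual_ids, pop_of,
                         unname(grp_map[pop_of]))
  tree_flagged <- tree
  attr(tree_flagged, "outgroup") <- config$outgroup
  if (is.null(truth)) truth <- data.frame()
  list(dataset = dataset, pops = pops, tree = tree_flagged,
       F = kinship_from_tree(tree_flagged), freq = freq, p0 = p0,
       truth = truth,
       ancestral = rep("A", nrow(map)))
}

## internal: sample sizes for every tree tip (outgroup defaults to 25)
sizes_with_outgroup <- function(config, tree) {
  sizes <- config$n_per_pop
  for (tip in setdiff(tree$tip.label, names(sizes)))
    sizes[[tip]] <- 25L
  sizes
}

#' Evaluate a scan against the simulation truth
#'
#' A sweep counts as detected when any region overlaps its perturbed span;
#' power is the detected fraction of injected sweeps; realized FDR is the
#' fraction of regions overlapping no truth span; localization error is the
#' distance from each detecting region's peak to the sweep locus.
#'
#' @param regions region data frame.
#' @param truth sweep truth table from [simulate_dataset()].
#' @return List: `power` (NA when no sweeps injected), `fdr`,
#'   `localization_bp` (named by truth row), `n_regions`, `detected`
#'   (logical per sweep).
#' @export
evaluate_scan <- function(regions, truth) {
  n_reg <- if (is.null(regions)) 0L else nrow(regions)
  n_true <- if (is.null(truth)) 0L else nrow(truth)
  if (n_true == 0L) {
    return(list(power = NA_real_, fdr = if (n_reg) 1 else 0,
                localization_bp = numeric(0), n_regions = n_reg,
                detected = logical(0)))
  }
  detected <- logical(n_true)
  localization <- rep(NA_real_, n_true)
  region_hit <- rep(FALSE, n_reg)
  for (t in seq_len(n_true)) {
    for (r in seq_len(n_reg)) {
      if (regions$chrom[r] == truth$chrom[t] &&
          regions$end[r] >= truth$span_begin[t] &&
          regions$begin[r] <= truth$span_end[t]) {
        detected[t] <- TRUE
        region_hit[r] <- TRUE
        d <- abs(regions$peak[r] - truth$pos[t])
        if (is.na(localization[t]) || d < localization[t])
          localization[t] <- d
      }
    }
  }
  list(power = mean(detected),
       fdr = if (n_reg) mean(!region_hit) else 0,
       localization_bp = localization, n_regions = n_reg,
       detected = detected)
}
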
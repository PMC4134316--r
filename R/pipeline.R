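## Orchestration: within-group FLK + hapFLK scans and the between-group
## scan on estimated ancestral allele frequencies.

#' Run FLK and hapFLK scans within one population group
#'
#' Populations with fewer than `config$min_pop_size` genotyped animals are
#' dropped (haplotype diversity cannot be determined with sufficient
#' precision in small samples). The population tree is then built from
#' Reynolds distances by Neighbor-Joining, rooted on the outgroup, the
#' kinship matrix F derived from it, and the scans run over the remaining
#' populations: FLK with empirical-DF chi-squared p-values and (optionally)
#' hapFLK with robust-normal p-values, each with Storey q-values attached.
#'
#' @param dataset a [genotype_dataset()] containing the group's individuals
#'   and the outgroup population.
#' @param pops a [population_set()].
#' @param group group label to scan (populations mapped to it in `pops`).
#' @param outgroup outgroup population label (used for rooting only; exempt
#'   from the sample-size filter and excluded from all statistics).
#' @param config a [scan_config()].
#' @param hapflk either `NULL` to skip the haplotype scan or a
#'   [hapflk_config()].
#' @return List with elements `flk` (scan result), `hapflk` (or `NULL`),
#'   `tree`, `F`, `freqs`, `populations`, `dropped` (populations removed by
#'   the size filter).
#' @export
run_within_group <- function(dataset, pops, group, outgroup,
                             config = scan_config(), hapflk = NULL) {
  populations <- group_populations(pops, group)
  populations <- setdiff(populations, outgroup)
  sizes <- vapply(populations, function(p)
    length(individuals_of(dataset, pops, p)), 0L)
  dropped <- populations[sizes < config$min_pop_size]
  populations <- populations[sizes >= config$min_pop_size]
  if (length(populations) < 2L)
    stop("group ", group, " has fewer than 2 usable populations")
  ids <- individuals_of(dataset, pops, c(populations, outgroup))
  ds <- subset_dataset(dataset, individuals = ids)
  freqs <- compute_allele_freqs(ds, pops, c(populations, outgroup))
  pt <- population_tree(freqs, outgroup)
  F_mat <- pt$F[populations, populations]
  in_freqs <- freq_table(freqs$freq[populations, , drop = FALSE],
                         freqs$snp_map)
  flk <- flk_scan(in_freqs, F_mat, maf_min = config$maf_min)
  flk <- add_qvalues(flk_pvalues(flk, df_mode = "empirical"))
  cal <- attr(flk, "calibration"); cal$group <- group
  attr(flk, "calibration") <- cal
  hap <- NULL
  if (!is.null(hapflk)) {
    ds_in <- subset_dataset(ds, individuals = individuals_of(ds, pops, populations))
    hap <- hapflk_scan(ds_in, pops, F_mat, hapflk)
    hap <- add_qvalues(hapflk_pvalues(hap))
    calh <- attr(hap, "calibration"); calh$group <- group
    attr(hap, "calibration") <- calh
  }
  list(flk = flk, hapflk = hap, tree = pt$tree, F = F_mat,
       freqs = in_freqs, populations = populations, dropped = dropped)
}

#' Presence of the derived allele per population group
#'
#' For every group and SNP: was the alternate (`allele_B`-derived) allele
#' observed at least once among the group's genotypes? Used by the
#' between-group scan to remove SNPs segregating in a single group.
#'
#' @param dataset a [genotype_dataset()].
#' @param pops a [population_set()].
#' @param groups group labels (default: all except any the caller excludes).
#' @param ancestral optional per-SNP ancestral allele (`"A"`/`"B"`/`NA`);
#'   when given, presence is assessed for the derived allele (i.e. genotype
#'   counts are flipped where `allele_B` is ancestral).
#' @return groups x SNPs logical matrix.
#' @export
derived_allele_seen <- function(dataset, pops, groups = NULL,
                                ancestral = NULL) {
  ind_group <- unname(pops$group[pops$pop[dataset$individual_ids]])
  if (is.null(groups)) groups <- unique(ind_group)
  g <- dataset$genotypes
  out <- matrix(FALSE, length(groups), ncol(g),
                dimnames = list(groups, colnames(g)))
  for (gr in groups) {
    sub <- g[ind_group == gr, , drop = FALSE]
    cnt_b <- colSums(sub, na.rm = TRUE)
    n_obs <- colSums(!is.na(sub))
    seen_b <- cnt_b > 0L
    seen_a <- cnt_b < 2L * n_obs
    if (is.null(ancestral)) out[gr, ] <- seen_b
    else out[gr, ] <- ifelse(!is.na(ancestral) & ancestral == "B",
                             seen_a, seen_b)
  }
  out
}

#' Between-group FLK scan on ancestral allele frequencies
#'
#' Tests for older selection events using, for each SNP, the estimated
#' allele frequency in the population ancestral to each group (the GLS
#' estimate produced by the within-group scans). Two SNP filters are
#' applied first: (1) SNPs whose derived (alternate) allele has been seen in
#' only one group are removed — such variants likely arose after the groups
#' diverged and violate the assumption of ancestral polymorphism; (2) SNPs
#' inside any within-group selection signature are removed, since selection
#' within a group biases that group's ancestral frequency estimate. The
#' ancestral tree is built from Reynolds distances between the group
#' frequencies (restricted to SNPs with known ancestral allele) and rooted
#' on an artificial outgroup homozygous for the ancestral allele at every
#' SNP; FLK with empirical-DF p-values and Storey q-values follows.
#'
#' @param p0_table groups x SNPs matrix of within-group ancestral frequency
#'   estimates (counts of `allele_B`), complete rows.
#' @param seen_table groups x SNPs logical matrix: was the alternate
#'   (derived) allele observed in the group's genotypes?
#' @param snp_map SNP map data frame matching the columns.
#' @param regions within-group regions (both tests); SNPs inside any
#'   `begin`..`end` interval are removed.
#' @param ancestral per-SNP ancestral allele: `"A"`, `"B"` or `NA`
#'   (unknown). Frequencies are oriented to the derived allele; SNPs with
#'   unknown ancestral allele are excluded from tree building but kept in
#'   the test (oriented by `allele_B` as-is).
#' @param config a [scan_config()].
#' @return List with `result` (scan result with per-group derived-allele
#'   frequencies as extra columns), `tree` (rooted ancestral-group tree) and
#'   `F` (kinship over group ancestors).
#' @export
ancestral_scan <- function(p0_table, seen_table, snp_map, regions,
                           ancestral, config = scan_config()) {
  stopifnot(ncol(p0_table) == nrow(snp_map),
            all(dim(p0_table) == dim(seen_table)))
  if (all(is.na(ancestral)))
    stop("no SNP with ancestral-allele information: tree cannot be rooted")
  m <- ncol(p0_table)
  ## orient to derived-allele frequencies where the ancestral allele is known
  derived <- p0_table
  flip <- !is.na(ancestral) & ancestral == "B"
  derived[, flip] <- 1 - derived[, flip]
  ## filter 1: derived allele seen in at least two groups
  keep1 <- colSums(seen_table) >= 2L
  ## filter 2: outside every within-group signature
  keep2 <- rep(TRUE, m)
  if (!is.null(regions) && nrow(regions)) {
    for (r in seq_len(nrow(regions))) {
      hit <- snp_map$chrom == regions$chrom[r] &
        snp_map$pos >= regions$begin[r] & snp_map$pos <= regions$end[r]
      keep2[hit] <- FALSE
    }
  }
  keep <- keep1 & keep2
  ## ancestral tree: known-ancestral SNPs only, artificial all-ancestral outgroup
  tree_snps <- keep & !is.na(ancestral)
  if (!any(tree_snps))
    stop("no SNP with ancestral-allele information after filtering")
  tre_freq <- rbind(derived[, tree_snps, drop = FALSE],
                    ANCESTRAL_OUT = 0)
  pt <- population_tree(freq_table(tre_freq,
                                   snp_map[tree_snps, , drop = FALSE]),
                        outgroup = "ANCESTRAL_OUT")
  groups <- rownames(p0_table)
  F_mat <- pt$F[groups, groups]
  scan_freqs <- freq_table(derived[, keep, drop = FALSE],
                           snp_map[keep, , drop = FALSE])
  res <- flk_scan(scan_freqs, F_mat, maf_min = config$maf_min)
  res <- add_qvalues(flk_pvalues(res, df_mode = "empirical"))
  ## attach per-group derived frequencies (schema of the ancestral table)
  cal <- attr(res, "calibration")
  gf <- t(derived[, keep, drop = FALSE])
  colnames(gf) <- paste0("freq_", groups)
  res <- cbind(as.data.frame(res), as.data.frame(gf, row.names = NULL))
  cal$test <- "ancestralFLK"
  cal$n_filtered_private <- sum(!keep1)
  cal$n_filtered_regions <- sum(keep1 & !keep2)
  attr(res, "calibration") <- cal
  class(res) <- c("scan_result", "data.frame")
  list(result = res, tree = pt$tree, F = F_mat, kept = which(keep))
}
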
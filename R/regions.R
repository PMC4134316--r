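## Region calling from significant SNPs and candidate-gene ranking.

#' Scan configuration for the full pipeline
#'
#' Defaults follow the study design: a 5% ancestral-MAF filter, FDR control
#' at 10% for FLK and 5% for hapFLK and the ancestral scan, a 500 kb merge
#' rule for significant FLK SNPs, a 1 Mb gene search window around
#' significant FLK SNPs, a 0.5 sigma drop rule for the hapFLK candidate
#' span, and removal of populations with fewer than 20 animals.
#'
#' @param maf_min ancestral minor-allele-frequency filter.
#' @param q_threshold_flk,q_threshold_hapflk,q_threshold_ancestral q-value
#'   significance thresholds per test.
#' @param flk_merge_bp significant FLK SNPs closer than this capture the
#'   same signal.
#' @param gene_window_bp genes closer than this to any significant FLK SNP
#'   are candidates.
#' @param hapflk_peak_drop_sigma candidate span: statistic within this many
#'   robust SDs of the peak.
#' @param min_pop_size smallest usable diploid sample size per population.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(maf_min = 0.05, q_threshold_flk = 0.10,
                        q_threshold_hapflk = 0.05,
                        q_threshold_ancestral = 0.05,
                        flk_merge_bp = 5e5, gene_window_bp = 1e6,
                        hapflk_peak_drop_sigma = 0.5, min_pop_size = 20) {
  cfg <- list(maf_min = maf_min, q_threshold_flk = q_threshold_flk,
              q_threshold_hapflk = q_threshold_hapflk,
              q_threshold_ancestral = q_threshold_ancestral,
              flk_merge_bp = flk_merge_bp, gene_window_bp = gene_window_bp,
              hapflk_peak_drop_sigma = hapflk_peak_drop_sigma,
              min_pop_size = min_pop_size)
  if (any(unlist(cfg) <= 0)) stop("all scan_config values must be positive")
  structure(cfg, class = "scan_config")
}

empty_regions <- function() {
  data.frame(group = character(0), test = character(0), chrom = character(0),
             begin = numeric(0), end = numeric(0), peak = numeric(0),
             min_pvalue = numeric(0), min_qvalue = numeric(0),
             n_snps = integer(0), cand_begin = numeric(0),
             cand_end = numeric(0), diff_pops = character(0),
             stringsAsFactors = FALSE)
}

region_row <- function(sub, group, test) {
  best <- which.min(sub$pvalue)
  data.frame(group = group, test = test, chrom = sub$chrom[1],
             begin = min(sub$pos), end = max(sub$pos),
             peak = sub$pos[best],
             min_pvalue = min(sub$pvalue), min_qvalue = min(sub$qvalue),
             n_snps = nrow(sub), cand_begin = NA_real_, cand_end = NA_real_,
             diff_pops = NA_character_, stringsAsFactors = FALSE)
}

#' Call selected regions from an FLK scan
#'
#' Significant SNPs (q-value below the threshold) less than `flk_merge_bp`
#' apart on the same chromosome are considered to capture the same selection
#' signal and are merged transitively into one region. Region bounds are the
#' outermost significant SNPs, the peak is the smallest p-value.
#'
#' @param result `scan_result` with `pvalue` and `qvalue` columns.
#' @param config a [scan_config()].
#' @param q_threshold threshold override (default `config$q_threshold_flk`).
#' @param group group label stored in the output.
#' @return Region data frame (columns `group, test, chrom, begin, end, peak,
#'   min_pvalue, min_qvalue, n_snps, cand_begin, cand_end, diff_pops`).
#' @export
call_flk_regions <- function(result, config = scan_config(),
                             q_threshold = config$q_threshold_flk,
                             group = NA_character_) {
  sig <- result[!is.na(result$qvalue) & result$qvalue < q_threshold, ,
                drop = FALSE]
  if (!nrow(sig)) return(empty_regions())
  test <- attr(result, "calibration")$test
  if (is.null(test)) test <- "FLK"
  out <- list()
  for (ch in unique(sig$chrom)) {
    sub <- sig[sig$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(sub$pos) >= config$flk_merge_bp))
    for (gidx in unique(grp))
      out[[length(out) + 1L]] <- region_row(sub[grp == gidx, , drop = FALSE],
                                            group, test)
  }
  do.call(rbind, out)
}

#' Call selected regions from a hapFLK scan
#'
#' Significant SNPs are grouped into contiguous significant runs (no
#' intervening non-significant SNP). Within each run, the candidate span is
#' the maximal contiguous stretch of SNPs around the peak whose statistic
#' stays within `hapflk_peak_drop_sigma` robust SDs of the peak value
#' (plateau-shaped signals give broad spans, sharp peaks narrow ones); the
#' candidate span, used for gene ranking, is recorded in
#' `cand_begin`/`cand_end` alongside the significant span.
#'
#' @param result `scan_result` with `stat`, `pvalue`, `qvalue`.
#' @param sigma_hat genome-wide robust SD of the statistic (defaults to the
#'   value recorded in the calibration attribute).
#' @param config a [scan_config()].
#' @param group group label stored in the output.
#' @return Region data frame as in [call_flk_regions()].
#' @export
call_hapflk_regions <- function(result, sigma_hat = NULL,
                                config = scan_config(),
                                group = NA_character_) {
  if (is.null(sigma_hat)) {
    sigma_hat <- attr(result, "calibration")$sigma_hat
    if (is.null(sigma_hat))
      stop("sigma_hat not given and absent from calibration block")
  }
  sig_flag <- !is.na(result$qvalue) & result$qvalue < config$q_threshold_hapflk
  if (!any(sig_flag)) return(empty_regions())
  out <- list()
  for (ch in unique(result$chrom[sig_flag])) {
    idx <- which(result$chrom == ch)
    track <- result[idx, , drop = FALSE]
    ord <- order(track$pos)
    track <- track[ord, , drop = FALSE]
    flag <- sig_flag[idx][ord]
    runs <- rle(flag)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      span <- starts[r]:ends[r]
      sub <- track[span, , drop = FALSE]
      row <- region_row(sub, group, "hapFLK")
      ## candidate span: expand around the peak over the whole track
      peak_i <- span[which.min(sub$pvalue)]
      cut <- track$stat[peak_i] - config$hapflk_peak_drop_sigma * sigma_hat
      lo <- peak_i
      while (lo > 1L && track$stat[lo - 1L] >= cut) lo <- lo - 1L
      hi <- peak_i
      while (hi < nrow(track) && track$stat[hi + 1L] >= cut) hi <- hi + 1L
      row$cand_begin <- track$pos[lo]
      row$cand_end <- track$pos[hi]
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Annotate the most differentiated population(s) of each region
#'
#' Heuristic: at the peak SNP, populations are scored by their
#' drift-standardized deviation from the ancestral frequency,
#' `z_i = (p_i - p0) / sqrt(F_ii p0 (1 - p0))`; populations whose |z| is
#' within 80% of the maximum are reported.
#'
#' @param regions region data frame.
#' @param freqs `allele_freq_table` over the scanned populations.
#' @param F_mat kinship matrix.
#' @return `regions` with the `diff_pops` column filled
#'   (space-separated labels).
#' @export
annotate_diff_pops <- function(regions, freqs, F_mat) {
  if (!nrow(regions)) return(regions)
  P <- freqs$freq[rownames(F_mat), , drop = FALSE]
  map <- freqs$snp_map
  for (r in seq_len(nrow(regions))) {
    j <- which(map$chrom == regions$chrom[r] & map$pos == regions$peak[r])
    if (!length(j)) next
    p <- P[, j[1]]
    if (anyNA(p)) next
    p0 <- estimate_ancestral_freq(p, F_mat)
    p0c <- min(1 - 1e-6, max(1e-6, p0))
    z <- abs(p - p0) / sqrt(diag(F_mat) * p0c * (1 - p0c))
    top <- names(z)[z >= 0.8 * max(z)]
    regions$diff_pops[r] <- paste(top, collapse = " ")
  }
  regions
}

#' Rank candidate genes for selected regions
#'
#' For FLK regions: all genes whose nearest edge lies strictly less than
#' `gene_window_bp` from any significant SNP of the region. For hapFLK
#' regions: genes overlapping the candidate span. Genes are ranked by the
#' distance between the peak position and the nearest gene edge (0 when the
#' peak falls inside the gene), rank 1 being the closest; ties are broken by
#' gene start.
#'
#' @param regions region data frame from [call_flk_regions()] /
#'   [call_hapflk_regions()] (a `region_id` is assigned from row order).
#' @param genes gene table from [read_gene_annotation()].
#' @param config a [scan_config()].
#' @param result optional `scan_result` the regions came from; needed to
#'   locate the significant SNPs of FLK regions (falls back to the region
#'   bounds when omitted).
#' @return Data frame `region_id, gene, rank, distance_bp`.
#' @export
rank_candidate_genes <- function(regions, genes, config = scan_config(),
                                 result = NULL) {
  empty <- data.frame(region_id = integer(0), gene = character(0),
                      rank = integer(0), distance_bp = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(genes)) {
    warning("empty gene table")
    return(empty)
  }
  out <- list()
  for (r in seq_len(nrow(regions))) {
    ch <- regions$chrom[r]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    if (regions$test[r] == "hapFLK" && !is.na(regions$cand_begin[r])) {
      keep <- g$end >= regions$cand_begin[r] & g$start <= regions$cand_end[r]
    } else {
      ## distance of each gene to the nearest significant SNP
      if (!is.null(result)) {
        sig_pos <- result$pos[result$chrom == ch & !is.na(result$qvalue) &
                                result$qvalue < config$q_threshold_flk &
                                result$pos >= regions$begin[r] &
                                result$pos <= regions$end[r]]
      } else sig_pos <- c(regions$begin[r], regions$end[r])
      keep <- vapply(seq_len(nrow(g)), function(i) {
        d <- pmax(0, pmax(g$start[i] - sig_pos, sig_pos - g$end[i]))
        min(d) < config$gene_window_bp
      }, TRUE)
    }
    g <- g[keep, , drop = FALSE]
    if (!nrow(g)) next
    peak <- regions$peak[r]
    dist <- pmax(0, pmax(g$start - peak, peak - g$end))
    ord <- order(dist, g$start)
    out[[length(out) + 1L]] <- data.frame(
      region_id = r, gene = g$gene[ord], rank = seq_along(ord),
      distance_bp = dist[ord], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
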
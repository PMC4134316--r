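## The single-SNP FLK test and its multiallelic extension.

#' FLK statistic for one SNP
#'
#' Quadratic form in the deviations of population allele frequencies from the
#' ancestral frequency, rescaled by the drift covariance:
#' \deqn{T = (p - p_0 1)' [p_0 (1 - p_0) F]^{-1} (p - p_0 1).}
#' With p0 estimated by GLS from the same frequencies, T is approximately
#' chi-squared with n - 1 degrees of freedom under neutrality.
#'
#' @param p frequency vector over n populations.
#' @param F_mat kinship matrix (n x n, positive definite).
#' @param p0 scalar ancestral frequency, or `"estimate"` (default) to use
#'   [estimate_ancestral_freq()].
#' @return Scalar statistic, or `NA` with a `"skipped"` attribute when
#'   p0 is 0 or 1 (statistic undefined).
#' @export
flk_single <- function(p, F_mat, p0 = "estimate") {
  if (identical(p0, "estimate")) p0 <- estimate_ancestral_freq(p, F_mat)
  if (p0 <= 0 || p0 >= 1) {
    out <- NA_real_
    attr(out, "skipped") <- "p0 at boundary"
    return(out)
  }
  p0c <- min(1 - 1e-6, max(1e-6, p0))
  r <- p - p0
  Fi <- kinship_inverse(F_mat)
  as.numeric(crossprod(r, Fi %*% r)) / (p0c * (1 - p0c))
}

#' Multiallelic FLK statistic
#'
#' Extension of [flk_single()] to A alleles (used by hapFLK with haplotype
#' clusters as alleles). With residual matrix `R = P - p0 1'` (alleles x
#' populations) the statistic is the quadratic form of `vec(R)` under the
#' covariance `F \%x\% (diag(p0) - p0 p0')`, evaluated with the
#' Moore-Penrose pseudo-inverse (the allele covariance has rank A - 1).
#' Because every column of R sums to zero this equals
#' \eqn{\sum_a r_a' F^{-1} r_a / p_{0a}}, which is how it is computed.
#'
#' @param P alleles x populations frequency matrix (columns sum to 1).
#' @param F_mat kinship matrix.
#' @param p0_vec ancestral allele-frequency vector (sums to 1). Components
#'   equal to 0 are dropped (together with their allele rows) before
#'   computation.
#' @param F_inv optional precomputed inverse of `F_mat`.
#' @return Scalar statistic.
#' @export
multiallelic_flk <- function(P, F_mat, p0_vec, F_inv = NULL) {
  P <- as.matrix(P)
  keep <- p0_vec > 0
  P <- P[keep, , drop = FALSE]
  p0_vec <- p0_vec[keep]
  if (is.null(F_inv)) F_inv <- kinship_inverse(F_mat)
  R <- P - matrix(p0_vec, nrow(P), ncol(P))
  s <- 0
  for (a in seq_len(nrow(R))) {
    r <- R[a, ]
    s <- s + as.numeric(crossprod(r, F_inv %*% r)) / p0_vec[a]
  }
  s
}

#' Genome-wide FLK scan
#'
#' Estimates the ancestral frequency p0 per SNP by GLS, excludes SNPs whose
#' ancestral minor allele frequency is not strictly above `maf_min` (the
#' model assumes polymorphism in the ancestral population), and computes the
#' FLK statistic for the rest. SNPs with a missing population frequency are
#' skipped and flagged.
#'
#' @param freqs an `allele_freq_table` over the scanned populations (no
#'   outgroup).
#' @param F_mat kinship matrix over the same populations.
#' @param maf_min ancestral minor-allele-frequency threshold (default 0.05,
#'   strict inequality).
#' @return A `scan_result` data frame with columns `chrom, pos, snp_id, p0,
#'   stat` and a `filter` column (`"ok"`, `"maf"`, `"missing"`); statistics
#'   are `NA` for filtered SNPs. Attribute `calibration` carries test
#'   metadata.
#' @export
flk_scan <- function(freqs, F_mat, maf_min = 0.05) {
  P <- freqs$freq[rownames(F_mat), , drop = FALSE]
  m <- ncol(P)
  w <- gls_weights(F_mat)
  Fi <- kinship_inverse(F_mat)
  complete <- colSums(is.na(P)) == 0L
  p0 <- rep(NA_real_, m)
  p0[complete] <- pmin(1, pmax(0, as.numeric(crossprod(w, P[, complete, drop = FALSE]))))
  filter <- ifelse(!complete, "missing",
                   ifelse(pmin(p0, 1 - p0) <= maf_min, "maf", "ok"))
  stat <- rep(NA_real_, m)
  ok <- which(filter == "ok")
  if (length(ok)) {
    p0c <- pmin(1 - 1e-6, pmax(1e-6, p0[ok]))
    R <- P[, ok, drop = FALSE] - matrix(p0[ok], nrow(P), length(ok), byrow = TRUE)
    quad <- colSums((Fi %*% R) * R)
    stat[ok] <- quad / (p0c * (1 - p0c))
  }
  res <- data.frame(chrom = freqs$snp_map$chrom, pos = freqs$snp_map$pos,
                    snp_id = freqs$snp_map$snp_id,
                    p0 = p0, stat = stat, filter = filter,
                    stringsAsFactors = FALSE)
  attr(res, "calibration") <- list(test = "FLK", n_pops = nrow(P),
                                   maf_min = maf_min)
  class(res) <- c("scan_result", class(res))
  res
}

#' Attach chi-squared p-values to an FLK scan
#'
#' Under neutrality the statistic should follow a chi-squared distribution
#' with n - 1 degrees of freedom; the empirical mode instead uses the
#' genome-wide mean of the retained statistics as degrees of freedom, which
#' typically fits the observed distribution better.
#'
#' @param result `scan_result` from [flk_scan()] (or [ancestral_scan()]).
#' @param df_mode `"empirical"` (default) or `"theoretical"`.
#' @param trim trimming fraction for the empirical mean (default 0, i.e. the
#'   plain mean; selection outliers are rare at genome scale).
#' @return `result` with a `pvalue` column; the degrees of freedom used are
#'   recorded in the calibration attribute.
#' @export
flk_pvalues <- function(result, df_mode = c("empirical", "theoretical"),
                        trim = 0) {
  df_mode <- match.arg(df_mode)
  cal <- attr(result, "calibration")
  stats_ok <- result$stat[!is.na(result$stat)]
  if (df_mode == "empirical") {
    if (!length(stats_ok) || all(stats_ok == 0))
      stop("cannot estimate empirical degrees of freedom: no positive statistics")
    df <- mean(stats_ok, trim = trim)
  } else {
    df <- cal$n_pops - 1
  }
  result$pvalue <- ifelse(is.na(result$stat), NA_real_,
                          pchisq(result$stat, df = df, lower.tail = FALSE))
  cal$df <- df
  cal$df_mode <- df_mode
  attr(result, "calibration") <- cal
  result
}
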
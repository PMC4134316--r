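## Storey q-values with a single-lambda plug-in estimate of pi0.

#' Storey q-values
#'
#' The proportion of true nulls is estimated by the plug-in
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))` at `lambda = 0.5`, clipped to
#' (0, 1]; q-values are then the usual step-up minimum
#' `q_i = min_\{j: p_j >= p_i\} pi0 m p_j / rank(p_j)`. With `pi0 = 1` this
#' is exactly the Benjamini-Hochberg adjustment.
#'
#' @param pvalues vector of p-values in (0, 1]; `NA`s are carried through.
#' @param lambda plug-in tuning point (default 0.5).
#' @param pi0 optional fixed pi0 overriding the plug-in estimate.
#' @return Vector of q-values, same length/order as `pvalues`, with the
#'   pi0 used attached as the `"pi0"` attribute.
#' @export
storey_qvalues <- function(pvalues, lambda = 0.5, pi0 = NULL) {
  if (!length(pvalues)) return(numeric(0))
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- sum(p > lambda) / (m * (1 - lambda))
    pi0 <- min(1, max(pi0, 1 / m))
  }
  ord <- order(p)
  ranked <- pi0 * m * p[ord] / seq_len(m)
  qs <- rev(cummin(rev(ranked)))
  qs <- pmin(qs, 1)
  q <- numeric(m)
  q[ord] <- qs
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Attach q-values to a scan result
#' @param result `scan_result` with a `pvalue` column.
#' @param ... passed to [storey_qvalues()].
#' @return `result` with a `qvalue` column; pi0 recorded in calibration.
#' @export
add_qvalues <- function(result, ...) {
  q <- storey_qvalues(result$pvalue, ...)
  result$qvalue <- as.numeric(q)
  cal <- attr(result, "calibration")
  cal$pi0 <- attr(q, "pi0")
  attr(result, "calibration") <- cal
  result
}
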
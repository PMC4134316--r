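## Independent oracles and fixture builders used across the test files.
## These deliberately avoid the package's own computational paths.

## Matrix inverse by cofactor (adjugate) expansion -- brute-force oracle
## for quadratic-form checks, independent of solve()/chol().
cofactor_inverse <- function(A) {
  n <- nrow(A)
  detA <- det_rec(A)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    minor <- A[-i, -j, drop = FALSE]
    adj[j, i] <- (-1)^(i + j) * det_rec(minor)
  }
  adj / detA
}
det_rec <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(1)
  if (n == 1L) return(A[1, 1])
  s <- 0
  for (j in seq_len(n))
    s <- s + (-1)^(1 + j) * A[1, j] * det_rec(A[-1, -j, drop = FALSE])
  s
}

## Moore-Penrose pseudo-inverse from an eigendecomposition (oracle for the
## multiallelic statistic).
eigen_pinv <- function(A, tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

## Nested-loop allele-frequency counter (oracle for compute_allele_freqs).
brute_force_freqs <- function(geno, ind_pop, populations) {
  m <- ncol(geno)
  out <- matrix(NA_real_, length(populations), m,
                dimnames = list(populations, colnames(geno)))
  for (pi in seq_along(populations)) {
    rows <- which(ind_pop == populations[pi])
    for (j in seq_len(m)) {
      num <- 0; den <- 0
      for (i in rows) {
        if (!is.na(geno[i, j])) {
          num <- num + geno[i, j]
          den <- den + 2
        }
      }
      if (den > 0) out[pi, j] <- num / den
    }
  }
  out
}

## Per-pair ratio-of-sums Reynolds distance (loop oracle).
brute_force_reynolds <- function(P, a, b) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(P))) {
    pa <- P[a, l]; pb <- P[b, l]
    if (is.na(pa) || is.na(pb)) next
    num <- num + (pa - pb)^2 + ((1 - pa) - (1 - pb))^2
    den <- den + 2 * (1 - pa * pb - (1 - pa) * (1 - pb))
  }
  num / den
}

## Random positive-definite kinship-like matrix with population names.
random_kinship <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n, sd = 0.1), n, n)
  F_mat <- crossprod(A) + diag(0.05, n)
  dimnames(F_mat) <- list(paste0("P", seq_len(n)), paste0("P", seq_len(n)))
  F_mat
}

## Tiny genotype dataset fixture.
tiny_dataset <- function(n = 6, m = 10, seed = 1, miss = 0) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2, 0.4), n, m)
  if (miss > 0) g[sample(length(g), miss)] <- NA
  map <- data.frame(chrom = "1", snp_id = paste0("s", seq_len(m)), gpos = 0,
                    pos = seq_len(m) * 1000, allele_A = "A", allele_B = "G",
                    stringsAsFactors = FALSE)
  genotype_dataset(g, paste0("i", seq_len(n)), map)
}

## Star-tree scan scenario shared by calibration tests.
star_newick <- function(n_pops, d = 0.1, d_out = 0.2) {
  sprintf("(%s,OUT:%g);",
          paste0("P", seq_len(n_pops), ":", d, collapse = ","), d_out)
}

## Build a scan_result-like data frame by hand (for region-calling tests).
make_scan <- function(pos, stat, pvalue, qvalue, chrom = "1",
                      test = "FLK") {
  res <- data.frame(chrom = chrom, pos = pos,
                    snp_id = paste0("s", seq_along(pos)),
                    stat = stat, pvalue = pvalue, qvalue = qvalue,
                    stringsAsFactors = FALSE)
  attr(res, "calibration") <- list(test = test)
  class(res) <- c("scan_result", class(res))
  res
}
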
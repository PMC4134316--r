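## hapFLK: haplotype-cluster mixture model (EM on unphased genotypes),
## cross-validated cluster number, local cluster frequencies, multiallelic
## FLK over clusters averaged across EM runs, robust-normal calibration.

#' Configuration for a hapFLK scan
#'
#' @param K number of haplotype clusters, or `"cv"` to select it by
#'   cross-validation over `cv_grid`.
#' @param nfits number of EM runs averaged into the statistic (default 20).
#' @param max_iter,tol EM stopping rule (absolute log-likelihood increase).
#' @param cv_grid candidate cluster numbers for cross-validation.
#' @param cv_folds number of masking folds.
#' @param cv_mask fraction of genotype cells masked per fold (must be
#'   < 0.5).
#' @param cv_max_iter,cv_tol EM stopping rule for cross-validation fits;
#'   tighter than the scan default because the choice of K rests on small
#'   held-out imputation-error differences that only well-converged fits
#'   resolve (scan fits are averaged over many runs, so per-run convergence
#'   matters less there).
#' @param cluster_min_freq clusters whose estimated ancestral frequency at a
#'   marker is not above this are dropped from the multiallelic statistic at
#'   that marker, mirroring the single-SNP ancestral-MAF rule: the
#'   chi-squared approximation of a frequency deviation breaks down for rare
#'   alleles, and a haplotype cluster that is locally rare behaves exactly
#'   like a rare allele.
#' @param seed base seed; EM run e uses `seed + e`.
#' @return A list of class `hapflk_config`.
#' @export
hapflk_config <- function(K = "cv", nfits = 20, max_iter = 20, tol = 1e-2,
                          cv_grid = c(2, 4, 6, 8, 10), cv_folds = 3,
                          cv_mask = 0.05, cv_max_iter = 60, cv_tol = 1e-4,
                          cluster_min_freq = 0.05, seed = 1) {
  stopifnot(nfits >= 1)
  if (cv_mask >= 0.5) stop("cv_mask must be below 0.5")
  structure(list(K = K, nfits = nfits, max_iter = max_iter, tol = tol,
                 cv_grid = cv_grid, cv_folds = cv_folds, cv_mask = cv_mask,
                 cv_max_iter = cv_max_iter, cv_tol = cv_tol,
                 cluster_min_freq = cluster_min_freq, seed = seed),
            class = "hapflk_config")
}

## internal: seeded parameter initialization
init_ld_params <- function(dataset, K, seed) {
  g <- dataset$genotypes
  M <- ncol(g)
  phat <- colMeans(g, na.rm = TRUE) / 2
  phat[is.na(phat)] <- 0.5
  set.seed(seed %% .Machine$integer.max)
  theta <- matrix(pmin(1 - 1e-3, pmax(1e-3, phat + runif(M * K, -0.2, 0.2))),
                  M, K)
  alpha <- matrix(rexp(M * K) + 0.5, M, K)
  alpha <- alpha / rowSums(alpha)
  d_bp <- c(0, diff(dataset$snp_map$pos))
  d_bp[d_bp < 0] <- mean(d_bp[d_bp > 0])  # chromosome boundary safeguard
  rho <- pmin(0.5, pmax(1e-6, 1 - exp(-d_bp * 2e-6)))
  rho[1] <- 1e-6
  list(theta = theta, alpha = alpha, rho = rho)
}

#' Fit the haplotype-cluster mixture model by EM
#'
#' Fits the LD model on unphased genotypes of one chromosome: the hidden
#' state of an individual at a marker is the unordered pair of haplotype
#' clusters carried by its two chromosomes; transitions are per-interval
#' cluster jumps with re-entry weights `alpha`, emissions are Binomial on
#' the per-marker cluster allele frequencies `theta`. The E-step runs
#' forward-backward over pair states; M-step updates are closed-form; the
#' log-likelihood trace is non-decreasing.
#'
#' @param dataset a [genotype_dataset()] restricted to one chromosome
#'   (markers ordered by position).
#' @param K number of haplotype clusters (>= 1).
#' @param seed integer seed for the (random) initialization; identical seed
#'   and data give bitwise-identical fits.
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `ld_model`: list with `K`, `theta` (markers x
#'   K), `alpha` (markers x K, rows sum to 1), `rho` (per-interval jump
#'   probabilities), `loglik` (trace), `seed`.
#' @export
fit_ld_model <- function(dataset, K, seed = 1, max_iter = 50, tol = 1e-3) {
  stopifnot(inherits(dataset, "genotype_dataset"), K >= 1)
  if (length(unique(dataset$snp_map$chrom)) > 1L)
    stop("fit_ld_model expects a single chromosome; use subset_dataset()")
  if (K > 2 * nrow(dataset$genotypes))
    warning("K exceeds the number of chromosomes in the sample")
  ini <- init_ld_params(dataset, K, seed)
  fit <- ld_em_cpp(dataset$genotypes, ini$theta, ini$alpha, ini$rho,
                   as.integer(max_iter), tol)
  structure(list(K = K, theta = fit$theta, alpha = fit$alpha, rho = fit$rho,
                 loglik = fit$loglik, seed = seed),
            class = "ld_model")
}

#' @export
print.ld_model <- function(x, ...) {
  cat("ld_model: K =", x$K, ",", nrow(x$theta), "markers,",
      length(x$loglik), "EM iterations, loglik =",
      format(tail(x$loglik, 1)), "\n")
  invisible(x)
}

## internal: posterior expected cluster counts, n x M x K (sums to 2 over K)
posterior_cluster_counts <- function(model, dataset) {
  out <- ld_posterior_cpp(dataset$genotypes, model$theta, model$alpha,
                          model$rho)
  out$counts
}

#' Select the number of haplotype clusters by cross-validation
#'
#' Masks a fraction of genotype cells at random, fits the model for each
#' candidate K, imputes the masked genotypes by their posterior expectation
#' and scores the mean squared imputation error; the K with the smallest
#' mean error across folds wins (ties go to the smaller K).
#'
#' @param dataset one-chromosome [genotype_dataset()].
#' @param K_grid candidate cluster numbers (non-empty).
#' @param config a [hapflk_config()] (uses `cv_folds`, `cv_mask`,
#'   `max_iter`, `tol`, `seed`).
#' @return The selected K (integer). The per-K mean errors are attached as
#'   the `"cv_errors"` attribute.
#' @export
select_num_clusters <- function(dataset, K_grid, config = hapflk_config()) {
  if (!length(K_grid)) stop("empty K grid")
  K_grid <- sort(K_grid)
  if (config$cv_mask >= 0.5) stop("masking fraction must be below 0.5")
  g <- dataset$genotypes
  obs <- which(!is.na(g))
  err <- matrix(NA_real_, config$cv_folds, length(K_grid))
  for (f in seq_len(config$cv_folds)) {
    set.seed((config$seed + 1000 * f) %% .Machine$integer.max)
    mask <- sample(obs, max(1L, round(config$cv_mask * length(obs))))
    gm <- g
    gm[mask] <- NA_integer_
    masked <- dataset
    masked$genotypes <- gm
    for (ki in seq_along(K_grid)) {
      K <- K_grid[ki]
      model <- fit_ld_model(masked, K, seed = config$seed + 1000 * f + ki,
                            max_iter = config$cv_max_iter %||% 60,
                            tol = config$cv_tol %||% 1e-4)
      counts <- posterior_cluster_counts(model, masked)
      n <- nrow(gm); M <- ncol(gm)
      idx <- arrayInd(mask, dim(gm))
      pred <- vapply(seq_len(nrow(idx)), function(r) {
        i <- idx[r, 1]; m <- idx[r, 2]
        sum(counts[i, m, ] * model$theta[m, ])
      }, 0)
      err[f, ki] <- mean((pred - g[mask])^2)
    }
  }
  mean_err <- colMeans(err)
  best <- K_grid[which.min(round(mean_err, 12))]  # ties -> smaller K (grid order)
  structure(as.integer(best), cv_errors = setNames(mean_err, K_grid))
}

#' Local haplotype-cluster frequencies per population
#'
#' For population i, marker m and cluster k: the average over the
#' population's individuals of the posterior expected count of cluster k in
#' the individual's cluster pair, divided by 2.
#'
#' @param model fitted [fit_ld_model()].
#' @param dataset the dataset the model was fitted on.
#' @param pops a [population_set()] covering the dataset's individuals.
#' @param populations optional population subset/order.
#' @return populations x markers x K array; slices sum to 1 over K.
#' @export
local_cluster_freqs <- function(model, dataset, pops, populations = NULL) {
  counts <- posterior_cluster_counts(model, dataset)
  ind_pop <- pops$pop[dataset$individual_ids]
  if (is.null(populations)) populations <- unique(unname(ind_pop))
  if (!all(populations %in% ind_pop))
    stop("population absent from dataset: ",
         paste(setdiff(populations, ind_pop), collapse = ", "))
  M <- ncol(dataset$genotypes); K <- model$K
  out <- array(0, dim = c(length(populations), M, K),
               dimnames = list(populations, NULL, NULL))
  for (pi in seq_along(populations)) {
    rows <- which(ind_pop == populations[pi])
    cnt <- counts[rows, , , drop = FALSE]
    out[pi, , ] <- apply(cnt, c(2, 3), mean) / 2
  }
  out
}

#' Genome-wide hapFLK scan
#'
#' For each of `nfits` EM runs (seeds `seed + e`): fit the LD model per
#' chromosome, compute local cluster frequencies per population, and at each
#' marker apply [multiallelic_flk()] over the K clusters (clusters treated
#' as alleles, per-cluster ancestral frequencies by GLS under `F_mat`).
#' The hapFLK statistic is the average over the runs. No MAF filter is
#' applied: haplotype clusters are never rare by construction.
#'
#' @param dataset a [genotype_dataset()] of the group's individuals
#'   (outgroup excluded).
#' @param pops a [population_set()].
#' @param F_mat kinship matrix over the scanned populations.
#' @param config a [hapflk_config()]; if `config$K == "cv"` the cluster
#'   number is chosen once on the first chromosome via
#'   [select_num_clusters()].
#' @return A `scan_result` data frame with columns `chrom, pos, snp_id,
#'   stat`; calibration attribute records `K`, `nfits` and the number of
#'   successful EM runs.
#' @export
hapflk_scan <- function(dataset, pops, F_mat, config = hapflk_config()) {
  populations <- rownames(F_mat)
  keep_ids <- individuals_of(dataset, pops, populations)
  dataset <- subset_dataset(dataset, individuals = keep_ids)
  K <- config$K
  chroms <- unique(dataset$snp_map$chrom)
  if (identical(K, "cv")) {
    K <- select_num_clusters(subset_dataset(dataset, chrom = chroms[1]),
                             config$cv_grid, config)
  }
  Fi <- kinship_inverse(F_mat)
  w <- gls_weights(F_mat)
  stat_all <- numeric(0)
  nruns_ok <- 0L
  per_chrom <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ds <- subset_dataset(dataset, chrom = chroms[ci])
    M <- ncol(ds$genotypes)
    acc <- matrix(NA_real_, config$nfits, M)
    for (e in seq_len(config$nfits)) {
      res <- tryCatch({
        model <- fit_ld_model(ds, K, seed = config$seed + e,
                              max_iter = config$max_iter, tol = config$tol)
        cf <- local_cluster_freqs(model, ds, pops, populations)
        hapflk_from_cluster_freqs(cf, Fi, w, config$cluster_min_freq)
      }, error = function(err) NULL)
      if (!is.null(res)) acc[e, ] <- res
    }
    ok <- rowSums(is.na(acc)) == 0
    if (!any(ok)) stop("all EM runs failed on chromosome ", chroms[ci])
    per_chrom[[ci]] <- colMeans(acc[ok, , drop = FALSE])
    nruns_ok <- nruns_ok + sum(ok)
  }
  stat <- unlist(per_chrom)
  res <- data.frame(chrom = dataset$snp_map$chrom, pos = dataset$snp_map$pos,
                    snp_id = dataset$snp_map$snp_id, stat = stat,
                    stringsAsFactors = FALSE)
  attr(res, "calibration") <- list(test = "hapFLK", K = K,
                                   nfits = config$nfits,
                                   nruns_ok = nruns_ok / length(chroms),
                                   n_pops = length(populations))
  class(res) <- c("scan_result", class(res))
  res
}

## internal: multiallelic FLK at every marker from a cluster-frequency array
## cf: populations x markers x K; Fi: inverse kinship; w: GLS weights;
## clusters below min_freq (ancestral) excluded marker-wise, as rare alleles
hapflk_from_cluster_freqs <- function(cf, Fi, w, min_freq = 0.05) {
  n <- dim(cf)[1]; M <- dim(cf)[2]; K <- dim(cf)[3]
  stat <- numeric(M)
  for (k in seq_len(K)) {
    Pk <- matrix(cf[, , k], n, M)           # populations x markers
    p0k <- as.numeric(crossprod(w, Pk))     # GLS per marker
    ok <- p0k > min_freq
    Rk <- Pk - matrix(p0k, n, M, byrow = TRUE)
    quad <- colSums((Fi %*% Rk) * Rk)
    stat[ok] <- stat[ok] + quad[ok] / p0k[ok]
  }
  stat
}

#' Robust location and scale of a statistic vector
#'
#' Median and MAD (scaled by 1.4826 for consistency at the normal), so that
#' outlying (potentially selected) regions do not influence the null
#' calibration.
#'
#' @param stats numeric vector (length >= 100).
#' @return List with `mu_hat` and `sigma_hat`.
#' @export
robust_normal_calibration <- function(stats) {
  stats <- stats[!is.na(stats)]
  if (length(stats) < 100)
    stop("need at least 100 statistics for calibration")
  mu <- median(stats)
  sigma <- mad(stats, center = mu)  # 1.4826 * MAD
  if (sigma == 0) stop("degenerate scan: zero robust scale")
  list(mu_hat = mu, sigma_hat = sigma)
}

#' Attach robust-normal p-values to a hapFLK scan
#'
#' One-sided upper-tail p-values from Normal(mu_hat, sigma_hat): only excess
#' haplotype differentiation is a selection signal.
#'
#' @param result `scan_result` from [hapflk_scan()].
#' @param calibration list from [robust_normal_calibration()]; computed from
#'   `result$stat` when omitted.
#' @return `result` with a `pvalue` column and calibration recorded.
#' @export
hapflk_pvalues <- function(result, calibration = NULL) {
  if (is.null(calibration))
    calibration <- robust_normal_calibration(result$stat)
  result$pvalue <- pnorm(result$stat, mean = calibration$mu_hat,
                         sd = calibration$sigma_hat, lower.tail = FALSE)
  cal <- attr(result, "calibration")
  cal$mu_hat <- calibration$mu_hat
  cal$sigma_hat <- calibration$sigma_hat
  attr(result, "calibration") <- cal
  result
}


`%||%` <- function(a, b) if (is.null(a)) b else a
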
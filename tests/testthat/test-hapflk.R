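## Small shared fixtures: one-population LD dataset and a two-population
## star scenario, built once per file.
ld_fixture <- function(seed = 5, n = 40, m = 60, H = 3, d = 0.001) {
  cfg <- sim_config(groups = list(G1 = "P1"),
                    tree_newick = sprintf("(P1:%g,OUT:%g);", d, d),
                    n_per_pop = n, n_snps = m, n_chrom = 1,
                    spacing_bp = 5e4, haplotype = TRUE, H = H,
                    seg_len_bp = 5e5, seed = seed)
  sim <- simulate_dataset(cfg)
  subset_dataset(sim$dataset,
                 individuals = grep("^P1", sim$dataset$individual_ids,
                                    value = TRUE))
}

test_that("K = 1 degenerates to the binomial-independence model", {
  ds <- tiny_dataset(n = 30, m = 25, seed = 8)
  model <- fit_ld_model(ds, K = 1, seed = 3)
  phat <- colMeans(ds$genotypes, na.rm = TRUE) / 2
  expect_equal(unname(model$theta[, 1]), unname(phat), tolerance = 1e-5)
  ll_binom <- sum(dbinom(ds$genotypes, 2,
                         rep(phat, each = nrow(ds$genotypes)), log = TRUE))
  expect_equal(tail(model$loglik, 1), ll_binom, tolerance = 1e-4)
})

test_that("EM log-likelihood is non-decreasing and deterministic", {
  ds <- ld_fixture()
  for (s in 1:3) {
    model <- fit_ld_model(ds, K = 3, seed = s, max_iter = 30)
    expect_true(all(diff(model$loglik) >= -1e-8))
  }
  m1 <- fit_ld_model(ds, K = 3, seed = 42)
  m2 <- fit_ld_model(ds, K = 3, seed = 42)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$loglik, m2$loglik)
  ## alpha rows are distributions, theta in [0, 1]
  expect_equal(rowSums(m1$alpha), rep(1, nrow(m1$alpha)), tolerance = 1e-9)
  expect_true(all(m1$theta >= 0 & m1$theta <= 1))
  expect_true(all(m1$rho >= 0 & m1$rho <= 0.5))
})

test_that("a 3-cluster mosaic is imputed better by K = 3 than K = 1", {
  wins <- 0
  for (s in 1:5) {
    ds <- ld_fixture(seed = 60 + s)
    k <- select_num_clusters(ds, c(1, 3), hapflk_config(cv_folds = 2,
                                                        seed = 60 + s))
    err <- attr(k, "cv_errors")
    wins <- wins + (err["3"] < err["1"])
  }
  expect_gte(wins, 4)
})

test_that("cross-validation guards its contract", {
  ds <- ld_fixture()
  expect_error(select_num_clusters(ds, integer(0)), "empty")
  expect_error(select_num_clusters(ds, c(1, 3),
                                   hapflk_config(cv_mask = 0.6)))
})

test_that("local cluster frequencies are population posterior averages", {
  ds <- ld_fixture(seed = 9, n = 20, m = 30)
  ps <- population_set(ds$individual_ids, rep("P1", 20), rep("G", 20))
  model <- fit_ld_model(ds, K = 3, seed = 2)
  cf <- local_cluster_freqs(model, ds, ps)
  expect_equal(dim(cf), c(1, 30, 3))
  expect_equal(apply(cf, c(1, 2), sum)[1, ], rep(1, 30), tolerance = 1e-6)
  ## K = 1: tensor identically one
  m1 <- fit_ld_model(ds, K = 1, seed = 2)
  expect_equal(as.numeric(local_cluster_freqs(m1, ds, ps)), rep(1, 30))
  ## duplicated individuals in two populations give identical slices
  g2 <- rbind(ds$genotypes, ds$genotypes)
  ds2 <- genotype_dataset(g2, c(ds$individual_ids,
                                paste0("dup_", ds$individual_ids)),
                          ds$snp_map)
  ps2 <- population_set(ds2$individual_ids,
                        rep(c("P1", "P2"), each = 20), rep("G", 40))
  cf2 <- local_cluster_freqs(model, ds2, ps2, c("P1", "P2"))
  expect_equal(cf2[1, , ], cf2[2, , ])
  expect_error(local_cluster_freqs(model, ds, ps, "P9"), "absent")
})

test_that("hapFLK with one EM run equals a single multiallelic scan", {
  ds <- ld_fixture(seed = 12, n = 30, m = 40)
  ps <- population_set(ds$individual_ids,
                       rep(c("P1", "P2"), 15), rep("G", 30))
  F_mat <- diag(0.05, 2)
  dimnames(F_mat) <- list(c("P1", "P2"), c("P1", "P2"))
  cfgh <- hapflk_config(K = 3, nfits = 1, seed = 4)
  scan <- hapflk_scan(ds, ps, F_mat, cfgh)
  ## manual single run with the same seed
  model <- fit_ld_model(ds, K = 3, seed = cfgh$seed + 1,
                        max_iter = cfgh$max_iter, tol = cfgh$tol)
  cf <- local_cluster_freqs(model, ds, ps, c("P1", "P2"))
  Fi <- solve(F_mat)
  w <- rep(0.5, 2)
  manual <- sapply(seq_len(dim(cf)[2]), function(j) {
    P <- t(cf[, j, ])
    p0 <- as.numeric(P %*% w)
    keep <- p0 > cfgh$cluster_min_freq
    if (!any(keep)) return(0)
    multiallelic_flk(P[keep, , drop = FALSE] , F_mat, p0[keep], F_inv = Fi)
  })
  expect_equal(scan$stat, manual, tolerance = 1e-9)
})

test_that("hapFLK is invariant to cluster label permutation", {
  set.seed(20)
  n <- 3; M <- 5; K <- 4
  cf <- array(rexp(n * M * K), c(n, M, K))
  cf <- cf / rep(apply(cf, c(1, 2), sum), K)
  F_mat <- random_kinship(n, seed = 21)
  Fi <- solve(F_mat)
  w <- as.numeric(Fi %*% rep(1, n)); w <- w / sum(w)
  s1 <- flkscan:::hapflk_from_cluster_freqs(cf, Fi, w, min_freq = 0)
  perm <- sample(K)
  s2 <- flkscan:::hapflk_from_cluster_freqs(cf[, , perm], Fi, w, min_freq = 0)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("robust calibration resists outliers", {
  set.seed(13)
  x <- rnorm(10000, 3, 1)
  cal <- robust_normal_calibration(x)
  expect_lt(abs(cal$mu_hat - 3), 0.05)
  expect_lt(abs(cal$sigma_hat - 1), 0.05)
  xo <- x
  xo[1:100] <- xo[1:100] + 20  # 1% outliers
  cal2 <- robust_normal_calibration(xo)
  expect_lt(abs(cal2$mu_hat - cal$mu_hat), 0.05)
  expect_lt(abs(cal2$sigma_hat - cal$sigma_hat), 0.05)
  expect_error(robust_normal_calibration(rep(2, 500)), "degenerate")
  expect_error(robust_normal_calibration(rnorm(50)), "100")
})

test_that("hapFLK p-values are the upper normal tail", {
  res <- make_scan(pos = c(1e5, 2e5, 3e5), stat = c(5, 5 + 1.96 * 2, 1),
                   pvalue = NA, qvalue = NA, test = "hapFLK")
  out <- hapflk_pvalues(res, calibration = list(mu_hat = 5, sigma_hat = 2))
  expect_equal(out$pvalue[1], 0.5)
  expect_equal(out$pvalue[2], pnorm(1.96, lower.tail = FALSE))
  expect_gt(out$pvalue[3], 0.97)
})
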
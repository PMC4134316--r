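test_that("Storey q-values match Benjamini-Hochberg when pi0 is 1", {
  set.seed(15)
  p <- c(runif(500), rbeta(50, 0.2, 5))
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  ## all p = 1 -> all q = 1
  expect_equal(as.numeric(storey_qvalues(rep(1, 10))), rep(1, 10))
  ## monotone in p
  q2 <- storey_qvalues(p)
  expect_true(all(diff(as.numeric(q2)[order(p)]) >= -1e-12))
  ## pi0 plug-in on uniform p-values
  set.seed(16)
  pu <- runif(10000)
  expect_gte(attr(storey_qvalues(pu), "pi0"), 0.95)
  expect_lte(attr(storey_qvalues(pu), "pi0"), 1)
  ## empty input
  expect_equal(length(storey_qvalues(numeric(0))), 0L)
})

test_that("FLK regions merge significant SNPs under the 500 kb rule", {
  cfg <- scan_config()
  ## significant SNPs at 1.0, 1.3, 2.0 Mb: gap 700 kb splits
  res <- make_scan(pos = c(1.0e6, 1.3e6, 2.0e6), stat = c(9, 10, 11),
                   pvalue = c(1e-4, 1e-5, 1e-6), qvalue = rep(0.01, 3))
  reg <- call_flk_regions(res, cfg)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$begin, c(1.0e6, 2.0e6))
  expect_equal(reg$end, c(1.3e6, 2.0e6))
  ## single significant SNP: begin = end = peak
  res1 <- make_scan(pos = 5e6, stat = 9, pvalue = 1e-5, qvalue = 0.01)
  reg1 <- call_flk_regions(res1, cfg)
  expect_equal(c(reg1$begin, reg1$peak, reg1$end), rep(5e6, 3))
  ## chain at 0, 0.4, 0.8, 1.2 Mb merges transitively
  resc <- make_scan(pos = c(0, 0.4, 0.8, 1.2) * 1e6 + 1, stat = 9:12,
                    pvalue = rep(1e-5, 4), qvalue = rep(0.01, 4))
  expect_equal(nrow(call_flk_regions(resc, cfg)), 1L)
  ## exactly 500 kb apart: NOT merged ("less than 500 kb" is strict)
  resb <- make_scan(pos = c(1.0e6, 1.5e6), stat = c(9, 9),
                    pvalue = c(1e-5, 1e-5), qvalue = c(0.01, 0.01))
  expect_equal(nrow(call_flk_regions(resb, cfg)), 2L)
  ## nothing significant
  res0 <- make_scan(pos = 1e6, stat = 1, pvalue = 0.5, qvalue = 0.9)
  expect_equal(nrow(call_flk_regions(res0, cfg)), 0L)
})

test_that("region calling is idempotent", {
  set.seed(99)
  pos <- sort(sample(1:300, 60)) * 1e5
  res <- make_scan(pos = pos, stat = rchisq(60, 3),
                   pvalue = runif(60, 0, 0.2),
                   qvalue = runif(60, 0, 0.2))
  reg <- call_flk_regions(res, scan_config())
  sig <- res[!is.na(res$qvalue) & res$qvalue < 0.1, ]
  reg2 <- call_flk_regions(sig, scan_config())
  expect_equal(reg[, c("chrom", "begin", "end", "peak")],
               reg2[, c("chrom", "begin", "end", "peak")])
})

test_that("hapFLK candidate spans follow the 0.5 sigma drop rule", {
  cfg <- scan_config()
  ## profile (2.0, 5.8, 6.0, 5.7, 3.0), sigma = 1: span covers values >= 5.5
  res <- make_scan(pos = (1:5) * 1e5, stat = c(2.0, 5.8, 6.0, 5.7, 3.0),
                   pvalue = c(0.5, 1e-4, 1e-5, 2e-4, 0.3),
                   qvalue = c(0.9, 0.01, 0.01, 0.01, 0.6), test = "hapFLK")
  reg <- call_hapflk_regions(res, sigma_hat = 1, cfg)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$cand_begin, 2e5)
  expect_equal(reg$cand_end, 4e5)
  ## plateau retained whole
  resp <- make_scan(pos = (1:3) * 1e5, stat = c(6, 6, 6),
                    pvalue = rep(1e-5, 3), qvalue = rep(0.01, 3),
                    test = "hapFLK")
  regp <- call_hapflk_regions(resp, sigma_hat = 1, cfg)
  expect_equal(c(regp$cand_begin, regp$cand_end), c(1e5, 3e5))
  ## sharp peak: single-SNP candidate span
  ress <- make_scan(pos = (1:3) * 1e5, stat = c(2, 6, 2),
                    pvalue = c(0.4, 1e-5, 0.4), qvalue = c(0.8, 0.01, 0.8),
                    test = "hapFLK")
  regs <- call_hapflk_regions(ress, sigma_hat = 1, cfg)
  expect_equal(c(regs$cand_begin, regs$cand_end), c(2e5, 2e5))
  ## sigma taken from the calibration block when present
  attr(ress, "calibration") <- list(test = "hapFLK", sigma_hat = 1)
  expect_equal(call_hapflk_regions(ress, config = cfg)$cand_begin, 2e5)
})

test_that("candidate genes are windowed, ranked by distance and tie-broken", {
  cfg <- scan_config()
  genes <- data.frame(chrom = "1",
                      start = c(9.8e6, 10.4e6, 11.3e6, 9.6e6),
                      end = c(9.9e6, 10.6e6, 11.5e6, 9.7e6),
                      gene = c("g1", "g2", "far", "g3"),
                      biotype = NA, stringsAsFactors = FALSE)
  ## FLK region with a single significant SNP at 10.0 Mb
  res <- make_scan(pos = 10e6, stat = 9, pvalue = 1e-5, qvalue = 0.01)
  reg <- call_flk_regions(res, cfg)
  rk <- rank_candidate_genes(reg, genes, cfg, result = res)
  expect_equal(rk$gene, c("g1", "g3", "g2"))  # 0.1, 0.3, 0.4 Mb from peak
  expect_equal(rk$rank, 1:3)
  expect_false("far" %in% rk$gene)            # 1.3 Mb > 1 Mb window
  ## gene overlapping the peak has distance 0
  genes0 <- rbind(genes, data.frame(chrom = "1", start = 9.95e6, end = 10.1e6,
                                    gene = "hit", biotype = NA))
  rk0 <- rank_candidate_genes(reg, genes0, cfg, result = res)
  expect_equal(rk0$gene[1], "hit")
  expect_equal(rk0$distance_bp[1], 0)
  ## equidistant tie broken by start coordinate
  gtie <- data.frame(chrom = "1", start = c(10.2e6, 9.7e6),
                     end = c(10.3e6, 9.8e6), gene = c("right", "left"),
                     biotype = NA)
  rkt <- rank_candidate_genes(reg, gtie, cfg, result = res)
  expect_equal(rkt$gene, c("left", "right"))
  ## hapFLK regions use the candidate span overlap
  resh <- make_scan(pos = c(9.9e6, 10.0e6, 10.1e6), stat = c(5.8, 6, 5.9),
                    pvalue = c(1e-4, 1e-5, 1e-4), qvalue = rep(0.01, 3),
                    test = "hapFLK")
  regh <- call_hapflk_regions(resh, sigma_hat = 1, cfg)
  rkh <- rank_candidate_genes(regh, genes, cfg)
  expect_equal(rkh$gene, "g1")  # only g1 overlaps [9.9, 10.1] Mb
  expect_warning(rank_candidate_genes(reg, genes[0, ], cfg), "empty")
})

test_that("populations below the size threshold are dropped from a group", {
  cfg <- sim_config(groups = list(G1 = paste0("P", 1:4)),
                    tree_newick = star_newick(4, d = 0.05),
                    n_per_pop = c(P1 = 25, P2 = 25, P3 = 25, P4 = 19),
                    n_snps = 400, n_chrom = 1, seed = 5)
  sim <- simulate_dataset(cfg)
  res <- suppressWarnings(
    run_within_group(sim$dataset, sim$pops, "G1", "OUT"))
  expect_equal(res$dropped, "P4")
  expect_equal(sort(res$populations), paste0("P", 1:3))
  expect_equal(sort(rownames(res$F)), paste0("P", 1:3))
  ## with only one usable population the group is skipped
  cfg2 <- sim_config(groups = list(G1 = paste0("P", 1:2)),
                     tree_newick = star_newick(2, d = 0.05),
                     n_per_pop = c(P1 = 25, P2 = 10),
                     n_snps = 200, n_chrom = 1, seed = 6)
  sim2 <- simulate_dataset(cfg2)
  expect_error(run_within_group(sim2$dataset, sim2$pops, "G1", "OUT"),
               "fewer than 2")
})

test_that("ancestral scan filters private and in-region SNPs", {
  ## synthetic group-level inputs: 4 groups, 6 SNPs on one chromosome
  p0 <- rbind(G1 = c(0.4, 0.5, 0.6, 0.2, 0.0, 0.3),
              G2 = c(0.5, 0.5, 0.5, 0.3, 0.0, 0.4),
              G3 = c(0.6, 0.4, 0.5, 0.4, 0.0, 0.5),
              G4 = c(0.5, 0.6, 0.4, 0.5, 0.2, 0.6))
  seen <- p0 > 0
  map <- data.frame(chrom = "1", snp_id = paste0("s", 1:6), gpos = 0,
                    pos = c(1, 2, 3, 30, 31, 60) * 1e6,
                    allele_A = "A", allele_B = "B")
  regions <- data.frame(chrom = "1", begin = 28.5e6, end = 30.5e6)
  anc <- suppressWarnings(
    ancestral_scan(p0, seen, map, regions, ancestral = rep("A", 6)))
  kept <- map$snp_id[anc$kept]
  expect_false("s5" %in% kept)  # private to G4 (filter 1)
  expect_false("s4" %in% kept)  # inside the within-group region (filter 2)
  expect_true(all(c("s1", "s2", "s3", "s6") %in% kept))
  ## no retained SNP violates either filter
  expect_true(all(colSums(seen[, anc$kept]) >= 2))
  expect_true(all(map$pos[anc$kept] < 28.5e6 | map$pos[anc$kept] > 30.5e6))
  ## schema: per-group frequencies alongside p and q
  expect_true(all(paste0("freq_G", 1:4) %in% names(anc$result)))
  expect_true(all(c("pvalue", "qvalue") %in% names(anc$result)))
  ## ancestral alleles required
  expect_error(ancestral_scan(p0, seen, map, regions,
                              ancestral = rep(NA_character_, 6)),
               "ancestral")
})
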
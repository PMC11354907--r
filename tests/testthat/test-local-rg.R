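test_that("locus partition uses inclusive boundaries and counts outsiders", {
  loci <- data.frame(locus = c(1L, 2L), chr = c(1L, 1L),
                     start = c(100L, 500L), stop = c(200L, 600L))
  ss <- make_ss(sprintf("rs%d", 1:5), beta = rep(0.01, 5), chr = 1L,
                bp = c(100L, 200L, 300L, 500L, 601L))
  part <- partition_by_locus(ss, loci)
  expect_equal(part$subsets[["1"]]$snp, c("rs1", "rs2"))
  expect_equal(part$subsets[["2"]]$snp, "rs4")
  expect_equal(part$n_outside, 2)
})

test_that("partition reproduces known per-locus counts on synthetic data", {
  loci <- data.frame(locus = 1:3, chr = c(6L, 6L, 19L),
                     start = c(1e6, 5e6, 1e6), stop = c(2e6, 6e6, 2e6))
  lb <- simulate_local_blocks(loci, per_locus_rho = 0, snps_per_locus = 40,
                              seed = 71)
  part <- partition_by_locus(lb$a, loci)
  expect_equal(vapply(part$subsets, nrow, integer(1), USE.NAMES = FALSE),
               rep(40L, 3))
  expect_equal(part$n_outside, 0)
})

test_that("univariate local test is calibrated under the null", {
  loci <- data.frame(locus = 1L, chr = 1L, start = 1e6, stop = 2e6)
  ps <- vapply(1:200, function(s) {
    lb <- simulate_local_blocks(loci, per_locus_rho = 0, h2_local = 0,
                                snps_per_locus = 100, seed = 500 + s)
    local_univariate(lb$a$data)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("univariate local heritability is unbiased with power at signal", {
  loci <- data.frame(locus = 1L, chr = 1L, start = 1e6, stop = 2e6)
  h2_planted <- 0.004
  est <- ps <- numeric(200)
  for (s in 1:200) {
    lb <- simulate_local_blocks(loci, per_locus_rho = 0,
                                h2_local = h2_planted,
                                snps_per_locus = 150, seed = 900 + s)
    u <- local_univariate(lb$a$data)
    est[s] <- u$h2_local; ps[s] <- u$p
  }
  expect_lt(abs(mean(est) - h2_planted), 3 * sd(est) / sqrt(200))
  expect_gt(mean(ps < 0.05), 0.95)
  # fewer than two SNPs: not-run flag
  one_snp <- lb <- simulate_local_blocks(loci, snps_per_locus = 2, seed = 1)
  expect_false(local_univariate(lb$a$data[1, , drop = FALSE])$run)
})

test_that("bivariate correlation respects the univariate filter contract", {
  loci <- data.frame(locus = 1L, chr = 1L, start = 1e6, stop = 2e6)
  lb <- simulate_local_blocks(loci, per_locus_rho = 0.9, h2_local = 0,
                              snps_per_locus = 100, seed = 75)
  res <- local_bivariate(lb$a$data, lb$b$data, n_null_sims = 200, seed = 1)
  expect_false(res$run)
  expect_match(res$reason, "filter|heritability")
})

test_that("a trait against itself gives rho = 1 and r2 = 1", {
  loci <- data.frame(locus = 1L, chr = 1L, start = 1e6, stop = 2e6)
  lb <- simulate_local_blocks(loci, per_locus_rho = 0, h2_local = 0.004,
                              snps_per_locus = 150, seed = 77)
  res <- local_bivariate(lb$a$data, lb$a$data, n_null_sims = 500, seed = 1)
  expect_true(res$run)
  expect_equal(res$rho, 1)
  expect_equal(res$r2, 1)
})

test_that("r2 equals rho squared on every emitted scan row", {
  loci <- data.frame(locus = 1:4, chr = 1L,
                     start = c(1, 3, 5, 7) * 1e6, stop = c(2, 4, 6, 8) * 1e6)
  lb <- simulate_local_blocks(loci, per_locus_rho = c("1" = 0.8, "2" = 0,
                                                      "3" = -0.8, "4" = 0.3),
                              h2_local = 0.004, snps_per_locus = 100,
                              seed = 79)
  scan <- local_rg_scan(lb$a, lb$b, loci, n_null_sims = 500, seed = 1)
  ok <- scan$run
  expect_true(any(ok))
  expect_equal(scan$r2[ok], scan$rho[ok]^2, tolerance = 1e-12)
  expect_true(all(abs(scan$rho[ok]) <= 1))
})

test_that("rho sign matches the planted local covariance", {
  loci <- data.frame(locus = 1L, chr = 1L, start = 1e6, stop = 2e6)
  signs <- vapply(1:40, function(s) {
    rho_true <- if (s %% 2 == 0) 0.7 else -0.7
    lb <- simulate_local_blocks(loci, per_locus_rho = rho_true,
                                h2_local = 0.004, snps_per_locus = 150,
                                seed = 1200 + s)
    res <- local_bivariate(lb$a$data, lb$b$data, n_null_sims = 500, seed = s)
    if (!res$run) return(NA_real_)
    sign(res$rho) == sign(rho_true)
  }, numeric(1))
  expect_gt(mean(signs, na.rm = TRUE), 0.95)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(35), 0.05 / 35)
  expect_equal(round(bonferroni_threshold(35), 4), 0.0014)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20, 0.025), 1.25e-3)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("scan summary averages rho over strictly significant loci", {
  res <- data.frame(
    locus = 1:4, chr = c(6, 6, 19, 19), start = 1, stop = 2, n_snps = 10,
    trait_a = "t", trait_b = "u",
    rho = c(0.34, 0.37, 0.5, -0.2), r2 = c(0.34, 0.37, 0.5, -0.2)^2,
    p = c(1e-5, 1.3e-3, 1.4e-3, 0.5),
    univ_p_a = 0.01, univ_p_b = 0.01, run = TRUE, reason = NA,
    stringsAsFactors = FALSE)
  s <- scan_and_summarise(res, biv_alpha = 1.4e-3)
  # p = 1.4e-3 exactly is NOT significant (strict inequality)
  expect_equal(s$n_significant, 2)
  expect_equal(s$loci, c(1L, 2L))
  expect_equal(s$mean_rho, 0.355)
  # round-half-away-from-zero display
  expect_equal(s$mean_rho_display, 0.36)
  expect_equal(s$per_chromosome_counts, c("6" = 2L))
  empty <- scan_and_summarise(res[res$p > 0.4, ], biv_alpha = 1.4e-3)
  expect_equal(empty$n_significant, 0)
  expect_true(is.na(empty$mean_rho))
})

test_that("eigen-projection decorrelation handles a correlated LD block", {
  set.seed(81)
  k <- 40
  ld <- outer(1:k, 1:k, function(i, j) 0.9^abs(i - j))
  n <- 50000
  # effects observed through LD: marginal beta ~ N(0, (h2/k) * R^2 + R/n)
  h2 <- 0.01
  g <- as.numeric(chol(ld * h2 / k) %*% rnorm(k))
  noise <- as.numeric(chol(ld / n) %*% rnorm(k))
  sub <- data.frame(beta = g + noise, n = n)
  res <- local_univariate(sub, n = n, ld_model = ld)
  expect_true(res$run)
  expect_lt(res$k_eff, k)
  expect_true(is.finite(res$h2_local))
})
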
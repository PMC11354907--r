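test_that("instrument selection applies strict threshold and greedy clumping", {
  ss <- make_ss(c("rs1", "rs2", "rs3", "rs4"),
                beta = c(0.30, 0.28, 0.25, 0.02),
                se = 0.03, chr = c(1, 1, 2, 2),
                bp = c(1e6, 1.5e6, 1e6, 2e6))
  # rs1/rs2 same block within the window; rs3 distinct chromosome; rs4 weak
  blocks <- c(rs1 = 1, rs2 = 1, rs3 = 2, rs4 = 2)
  kept <- select_instruments(ss, p_thresh = 5e-8, clump_kb = 1000,
                             ld_blocks = blocks)
  expect_setequal(kept, c("rs1", "rs3"))
  # distinct blocks are independent even within the distance window
  blocks2 <- c(rs1 = 1, rs2 = 2, rs3 = 3, rs4 = 4)
  kept2 <- select_instruments(ss, p_thresh = 5e-8, clump_kb = 1000,
                              ld_blocks = blocks2)
  expect_setequal(kept2, c("rs1", "rs2", "rs3"))
  weak <- make_ss("rs9", beta = 0.001, se = 0.03)
  expect_warning(none <- select_instruments(weak), "no genome-wide")
  expect_length(none, 0)
})

test_that("planted independent signals are recovered as instruments", {
  set.seed(51)
  n_sig <- 30
  beta <- c(rnorm(n_sig, 0.4, 0.05), rnorm(470, 0, 0.005))
  ss <- make_ss(sprintf("rs%03d", 1:500), beta = beta, se = 0.02,
                chr = rep(1:20, 25), bp = rep(seq(1e6, 25e6, by = 1e6),
                                              each = 20))
  kept <- select_instruments(ss, clump_kb = 100)
  expect_gte(length(kept), n_sig - 2)
  expect_lte(length(kept), n_sig + 2)
})

test_that("extraction drops missing instruments and orients effects", {
  exp_ss <- make_ss(c("rs1", "rs2", "rs3"), beta = c(0.3, -0.4, 0.5),
                    se = 0.03)
  out_data <- exp_ss$data[1:2, ]
  out_data$beta <- c(0.1, 0.2)
  out_data$z <- out_data$beta / out_data$se
  # swap rs1's alleles in the outcome: effect must be sign-corrected
  out_data$a1[1] <- "G"; out_data$a2[1] <- "A"
  out_ss <- sumstats("out", out_data)
  expect_message(set <- extract_and_harmonise(c("rs1", "rs2", "rs3"),
                                              exp_ss, out_ss),
                 "absent from the outcome")
  expect_equal(nrow(set), 2)
  expect_true(all(set$beta_exp > 0))
  # rs1: outcome allele-swapped (-0.1), exposure positive -> pair (0.3, -0.1)
  expect_equal(set$beta_out[set$snp == "rs1"], -0.1)
  # rs2: exposure -0.4 flipped positive flips the outcome too
  expect_equal(set$beta_out[set$snp == "rs2"], -0.2)
})

test_that("IVW reduces to the exact ratio in degenerate cases", {
  ivs <- make_ivs(beta_exp = c(0.2, 0.4), beta_out = c(0.1, 0.2))
  expect_equal(mr_ivw(ivs)$beta, 0.5, tolerance = 1e-12)
  single <- make_ivs(0.2, 0.1)
  expect_false(mr_ivw(single)$run)
  expect_false(mr_weighted_median(make_ivs(c(0.1, 0.2), c(0.1, 0.2)))$run)
  expect_false(mr_egger(make_ivs(c(0.1, 0.2), c(0.1, 0.2)))$run)
  expect_false(mr_presso(make_ivs(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)))$run)
})

test_that("fixed-effect IVW matches the weighted regression oracle", {
  d <- simulate_mr_dataset(n_iv = 25, beta_causal = 0.2, pleio_sd = 0.01,
                           seed = 53)
  fit <- mr_ivw(d, model = "fixed")
  oracle <- stats::lm(beta_out ~ 0 + beta_exp, data = d,
                      weights = 1 / d$se_out^2)
  expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-10)
  expect_equal(fit$se,
               summary(oracle)$coefficients[1, 2] / summary(oracle)$sigma,
               tolerance = 1e-10)
})

test_that("estimators are invariant to relabelling and joint sign flips", {
  d <- simulate_mr_dataset(n_iv = 20, beta_causal = 0.3, seed = 57)
  perm <- d[sample(nrow(d)), ]
  flip <- d
  flip$beta_exp[1:5] <- -flip$beta_exp[1:5]
  flip$beta_out[1:5] <- -flip$beta_out[1:5]
  for (f in list(mr_ivw, mr_egger)) {
    expect_equal(f(d)$beta, f(perm)$beta, tolerance = 1e-12)
  }
  expect_equal(mr_ivw(d)$beta, mr_ivw(flip)$beta, tolerance = 1e-12)
  expect_equal(cochran_q(d)$q, cochran_q(flip)$q, tolerance = 1e-12)
  # Egger is orientation-dependent by design; the harmonised orientation
  # (all exposure effects positive) is what the pipeline feeds it
})

test_that("weighted median hits the interpolated 50th percentile", {
  ivs <- make_ivs(beta_exp = c(1, 1, 1), beta_out = c(0.1, 0.2, 0.9))
  wm <- mr_weighted_median(ivs, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.2, tolerance = 1e-12)
  # same seed, same bootstrap SE
  wm2 <- mr_weighted_median(ivs, n_boot = 100, seed = 1)
  expect_identical(wm$se, wm2$se)
})

test_that("weighted median agrees with a weighted-quantile oracle on <= 5 IVs", {
  set.seed(59)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    bx <- runif(n, 0.1, 0.5)
    by <- runif(n, -0.2, 0.4)
    so <- runif(n, 0.01, 0.05)
    ivs <- make_ivs(bx, by, se_out = so)
    ratio <- by / bx
    w <- (bx / so)^2
    ord <- order(ratio)
    cum <- cumsum(w[ord]) / sum(w) - w[ord] / (2 * sum(w))
    oracle <- if (min(cum) > 0.5) {
      ratio[ord][1]
    } else {
      stats::approx(cum, ratio[ord], xout = 0.5, rule = 2)$y
    }
    expect_equal(mr_weighted_median(ivs, n_boot = 10, seed = 1)$beta, oracle,
                 tolerance = 1e-9)
  }
})

test_that("weighted median resists invalid instruments better than IVW", {
  err_ivw <- err_wm <- numeric(30)
  for (s in 1:30) {
    d <- simulate_mr_dataset(n_iv = 50, beta_causal = 0.3,
                             frac_outliers = 0.4, outlier_pleio_sd = 0.15,
                             seed = 200 + s)
    err_ivw[s] <- abs(mr_ivw(d)$beta - 0.3)
    err_wm[s] <- abs(mr_weighted_median(d, n_boot = 50, seed = s)$beta - 0.3)
  }
  expect_lt(mean(err_wm), mean(err_ivw))
})

test_that("Egger recovers planted directional pleiotropy in the intercept", {
  est <- vapply(1:30, function(s) {
    d <- simulate_mr_dataset(n_iv = 40, beta_causal = 0.2, pleio_mean = 0.05,
                             pleio_sd = 0.005, seed = 300 + s)
    mr_egger(d)$intercept
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.05), 0.01)
  # collinear exposure effects: not-run flag
  collinear <- make_ivs(rep(0.2, 5), runif(5))
  expect_false(mr_egger(collinear)$run)
})

test_that("Cochran's Q behaves under homogeneity and a gross outlier", {
  same <- make_ivs(c(0.2, 0.3, 0.4), c(0.1, 0.15, 0.2))
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$p, 1)
  ratios <- vapply(1:50, function(s) {
    d <- simulate_mr_dataset(n_iv = 30, beta_causal = 0.3, seed = 400 + s)
    q <- cochran_q(d)
    q$q / q$df
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 3 * sd(ratios) / sqrt(50))
  outlier <- simulate_mr_dataset(n_iv = 30, beta_causal = 0.3, seed = 1)
  outlier$beta_out[1] <- outlier$beta_out[1] + 0.5
  expect_lt(cochran_q(outlier)$p, 1e-6)
})

test_that("MR-PRESSO leaves clean data uncorrected and is seed-stable", {
  d <- simulate_mr_dataset(n_iv = 30, beta_causal = 0.3, seed = 61)
  p1 <- mr_presso(d, n_sim = 500, seed = 2)
  p2 <- mr_presso(d, n_sim = 500, seed = 2)
  expect_identical(p1$global_p, p2$global_p)
  expect_null(p1$corrected)
  expect_true(is.na(p1$distortion_p))
  expect_equal(p1$raw$beta, mr_ivw(d)$beta)
  expect_gt(p1$global_p, 0.05)
})

test_that("bi-directional runs swap direction labels and recover an effect", {
  # exposure with strong, LD-independent instruments; outcome a pure
  # downstream consequence (causal effect 0.3)
  set.seed(63)
  n_iv <- 30; n_null <- 200
  bx_true <- c(runif(n_iv, 0.3, 0.5), rep(0, n_null))
  m <- n_iv + n_null
  se_x <- 0.02; se_y <- 0.02
  bx <- bx_true + rnorm(m, 0, se_x)
  by <- 0.3 * bx_true + rnorm(m, 0, se_y)
  snp <- sprintf("rs%04d", 1:m)
  chr <- rep(1:22, length.out = m)
  bp <- rep(seq(1e6, by = 5e6, length.out = ceiling(m / 22)), each = 22)[1:m]
  exp_ss <- make_ss(snp, beta = bx, se = se_x, chr = chr, bp = bp,
                    trait = "lipid")
  out_ss <- make_ss(snp, beta = by, se = se_y, chr = chr, bp = bp,
                    trait = "target")
  res <- run_bidirectional(exp_ss, out_ss, n_boot = 100, presso_sims = 200,
                           seed = 3, clump_kb = 100)
  expect_equal(res$forward$exposure, "lipid")
  expect_equal(res$forward$outcome, "target")
  expect_equal(res$reverse$exposure, "target")
  expect_lt(abs(res$forward$ivw$beta - 0.3), 2 * res$forward$ivw$se)
  expect_lt(res$forward$ivw$p, 1e-6)
})
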
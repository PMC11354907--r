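# independent oracle: direct log-space summation of the binomial upper tail
binom_tail_oracle <- function(k, n, p0) {
  if (k == 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

# independent oracle: numerical quadrature of the chi-square(4) density
chisq4_tail_oracle <- function(x) {
  stats::integrate(function(t) stats::dchisq(t, df = 4), lower = x,
                   upper = Inf, rel.tol = 1e-12)$value
}

test_that("exact binomial upper tail matches direct summation and binom.test", {
  expect_equal(exact_binomial_upper(7, 10, 0.5), 0.171875)
  expect_equal(exact_binomial_upper(5, 20, 0.25),
               binom_tail_oracle(5, 20, 0.25), tolerance = 1e-12)
  expect_equal(exact_binomial_upper(0, 50, 0.3), 1)
  for (case in list(c(3, 12, 0.1), c(40, 60, 0.6), c(294, 1768, 0.106))) {
    expect_equal(exact_binomial_upper(case[1], case[2], case[3]),
                 binom_tail_oracle(case[1], case[2], case[3]),
                 tolerance = 1e-10)
    expect_equal(exact_binomial_upper(case[1], case[2], case[3]),
                 stats::binom.test(case[1], case[2], case[3],
                                   alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  expect_error(exact_binomial_upper(1, 10, 0), "p0")
  expect_error(exact_binomial_upper(11, 10, 0.5), "k must")
})

test_that("binomial tail is monotone in k and in the null proportion", {
  p_by_k <- vapply(0:20, exact_binomial_upper, numeric(1), n = 20, p0 = 0.3)
  expect_true(all(diff(p_by_k) <= 0))
  p_by_p0 <- vapply(seq(0.05, 0.95, by = 0.05), function(p0)
    exact_binomial_upper(8, 20, p0), numeric(1))
  expect_true(all(diff(p_by_p0) >= 0))
})

test_that("overlap assessment computes proportions and the exact test", {
  # discovery: 20 genes, 5 significant; target: 20 genes, first 8 significant
  # of which 5 overlap the discovery's significant set
  disc <- make_gene_table("lipid", 20, sig_idx = 1:5)
  targ <- make_gene_table("target", 20, sig_idx = 1:8)
  res <- overlap_assessment(disc, targ, null_rounding = NULL)
  expect_equal(res$sig_discovery, 5)
  expect_equal(res$sig_target, 8)
  expect_equal(res$n_overlap, 5)
  expect_equal(res$expected_prop, 0.25)
  expect_equal(res$observed_prop, 5 / 8)
  expect_equal(res$p_binomial, binom_tail_oracle(5, 8, 0.25),
               tolerance = 1e-12)
})

test_that("zero overlap gives p = 1 and zero target-significant genes flag", {
  disc <- make_gene_table("d", 20, sig_idx = 1:5)
  targ_disjoint <- make_gene_table("t", 20, sig_idx = 10:12)
  expect_equal(overlap_assessment(disc, targ_disjoint)$n_overlap, 0)
  expect_equal(overlap_assessment(disc, targ_disjoint,
                                  null_rounding = NULL)$p_binomial,
               binom_tail_oracle(0, 3, 0.25))
  targ_none <- make_gene_table("t", 20, sig_idx = integer(0))
  res <- overlap_assessment(disc, targ_none)
  expect_false(res$p_defined)
  expect_true(is.na(res$p_binomial))
})

test_that("overlap binomial test controls type-I error under independence", {
  # shared fraction at the independence expectation (frac_assoc_b)
  rej <- 0
  n_rep <- 400
  for (s in 1:n_rep) {
    g <- simulate_gene_tables(n_genes = 2000, frac_assoc_a = 0.1,
                              frac_assoc_b = 0.1, frac_shared = 0.1,
                              seed = s)
    o <- overlap_assessment(g$b, g$a, null_rounding = NULL)
    rej <- rej + (o$p_binomial < 0.05)
  }
  # the test is conservative under this sampling scheme (overlap given both
  # margins is hypergeometric): require control, not exact uniformity
  expect_lt(rej / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Fisher combination matches the chi-square quadrature oracle", {
  expect_equal(fisher_combine(1, 1), 1)
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(fisher_combine(0.05, 0.05), chisq4_tail_oracle(x),
               tolerance = 1e-9)
  expect_equal(fisher_combine(1e-4, 1e-4),
               chisq4_tail_oracle(-2 * 2 * log(1e-4)), tolerance = 1e-9)
  set.seed(1)
  pa <- runif(20); pb <- runif(20)
  expect_equal(fisher_combine(pa, pb), fisher_combine(pb, pa))
  # monotone non-decreasing in each argument
  grid <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(fisher_combine(grid, 0.3)) >= 0))
  # crossover: combining two equal p-values helps for small p, hurts near 1
  expect_lt(fisher_combine(0.05, 0.05), 0.05)
  expect_gt(fisher_combine(0.9, 0.9), 0.9)
  expect_error(fisher_combine(0, 0.5), "clamp")
})

test_that("sentinel shared genes respect the strict threshold", {
  tabs <- list(
    target = make_gene_table("target", 10, sig_idx = c(1, 2, 3), p_sig = 1e-8),
    x = make_gene_table("x", 10, sig_idx = c(1, 4), p_sig = 1e-7),
    y = make_gene_table("y", 10, sig_idx = c(2, 5), p_sig = 2.6e-6))
  out <- find_sentinel_shared(tabs, "target", gws = 2.6e-6)
  # gene 2 in y sits exactly at the threshold: excluded (strict inequality)
  expect_equal(out$gene, "G00001")
  expect_equal(out$traits, "target,x")
  expect_error(find_sentinel_shared(tabs, "missing"), "not in tables")
})

test_that("sentinel discovery recovers a planted truth", {
  g <- simulate_gene_tables(n_genes = 500, frac_assoc_a = 0.04,
                            frac_assoc_b = 0.04, frac_shared = 1,
                            assoc_z_mean = 12, seed = 19)
  tabs <- list(target = g$a, other = g$b)
  out <- find_sentinel_shared(tabs, "target", gws = 2.6e-6)
  planted <- toupper(g$a$data$gene[g$truth_a])
  expect_setequal(out$gene, planted)
})

test_that("FCP classification applies the category rules", {
  # gene 1: 1e-4 in both -> reaches GWS through combination
  # gene 2: already GWS in the target -> improved at best, never fcp_reaching
  # gene 3: 0.04 and 0.3 -> excluded (second p above alpha)
  ta <- make_gene_table("t", 3, sig_idx = 1:3, p_sig = 1)
  ta$data$p <- c(1e-4, 1e-8, 0.04)
  tb <- make_gene_table("o", 3, sig_idx = 1:3, p_sig = 1)
  tb$data$p <- c(1e-4, 1e-3, 0.3)
  out <- classify_fcp_genes(ta, tb)
  reaching <- out[out$category == "fcp_reaching", ]
  expect_equal(reaching$gene, "G00001")
  expect_equal(reaching$p_fcp, chisq4_tail_oracle(-4 * log(1e-4)),
               tolerance = 1e-9)
  expect_false("G00002" %in% out$gene[out$category == "fcp_reaching"])
  expect_true("G00002" %in% out$gene[out$category == "improved"])
  expect_false("G00003" %in% out$gene)
})

test_that("cross-trait summary aggregates and filters by trait count", {
  shared <- data.frame(
    gene = c("APOE", "APOE", "APOE", "SOLO", "DUP", "DUP"),
    trait = c("t1", "t2", "t3", "t1", "t2", "t2"),
    stringsAsFactors = FALSE)
  out <- cross_trait_gene_summary(shared, min_traits = 2)
  expect_equal(out$gene, "APOE")
  expect_equal(out$n_traits, 3)
  expect_equal(out$traits, "t1,t2,t3")
  all_out <- cross_trait_gene_summary(shared, min_traits = 1)
  expect_setequal(all_out$gene, c("APOE", "SOLO", "DUP"))
  expect_equal(all_out$n_traits[all_out$gene == "DUP"], 1)
})
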
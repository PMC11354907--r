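# Locus-restricted genetic correlation: univariate local signal testing,
# bivariate local correlation with simulation-based p-values, and mean-rho
# aggregation over significant loci.

#' Partition summary statistics by locus
#'
#' A SNP belongs to a locus when the chromosome matches and
#' `start <= bp <= stop` (inclusive at both ends, 1-based coordinates).
#' SNPs outside every locus are excluded and counted.
#'
#' @param ss A [sumstats] object.
#' @param loci Locus-definition table (columns `locus`, `chr`, `start`,
#'   `stop`).
#' @return List with `subsets` (named list of per-locus record data.frames,
#'   names = locus ids) and `n_outside`.
#' @export
partition_by_locus <- function(ss, loci) {
  loci <- validate_loci(as.data.frame(loci))
  d <- ss$data
  assigned <- rep(FALSE, nrow(d))
  subsets <- list()
  for (i in seq_len(nrow(loci))) {
    in_locus <- d$chr == loci$chr[i] & d$bp >= loci$start[i] &
      d$bp <= loci$stop[i]
    subsets[[as.character(loci$locus[i])]] <- d[in_locus, , drop = FALSE]
    assigned <- assigned | in_locus
  }
  list(subsets = subsets, n_outside = sum(!assigned))
}

# decorrelate marginal effects against a locus LD model: with identity LD
# this is a pass-through; otherwise project onto the leading eigenvectors
# retaining `var_frac` of the LD variance and whiten
decorrelate_effects <- function(beta, ld_model = NULL, var_frac = 0.99) {
  if (is.null(ld_model)) {
    return(list(eta = beta, k_eff = length(beta)))
  }
  eig <- eigen(ld_model, symmetric = TRUE)
  keep <- seq_len(min(which(cumsum(eig$values) / sum(eig$values) >= var_frac)))
  u <- eig$vectors[, keep, drop = FALSE]
  d <- eig$values[keep]
  list(eta = as.numeric(t(u) %*% beta / sqrt(d)), k_eff = length(keep))
}

#' Univariate local heritability and signal test
#'
#' Method-of-moments on decorrelated squared effects: with K (effective)
#' SNPs and sampling variance 1/n per effect,
#' `h2_local = sum(eta^2) - K/n`; the signal p-value refers
#' `n * sum(eta^2)` to a chi-square with K degrees of freedom (the scaled
#' chi-square of the summed signal under the null of no local heritability).
#'
#' @param subset Per-locus record data.frame (from [partition_by_locus()]),
#'   needing columns `beta` and `n` (or pass a numeric vector of effects via
#'   `subset` and give `n`).
#' @param n Sample size; defaults to the subset's `n` column.
#' @param ld_model Optional locus LD correlation matrix; `NULL` means
#'   identity LD (the bundled synthetic setting).
#' @param var_frac Variance fraction retained by the eigen-projection when an
#'   LD model is supplied.
#' @return List with `h2_local`, `p`, `n_snps`, `k_eff`, `run`; a not-run
#'   flag below 2 SNPs.
#' @export
local_univariate <- function(subset, n = NULL, ld_model = NULL,
                             var_frac = 0.99) {
  beta <- if (is.data.frame(subset)) subset$beta else subset
  n <- n %||% mean(subset$n)
  if (length(beta) < 2) {
    return(list(h2_local = NA_real_, p = NA_real_, n_snps = length(beta),
                k_eff = NA_integer_, run = FALSE, reason = "fewer than 2 SNPs"))
  }
  dec <- decorrelate_effects(beta, ld_model, var_frac)
  k <- dec$k_eff
  ss_eta <- sum(dec$eta^2)
  h2_local <- ss_eta - k / n
  p <- stats::pchisq(n * ss_eta, df = k, lower.tail = FALSE)
  list(h2_local = h2_local, p = p, n_snps = length(beta), k_eff = k,
       run = TRUE)
}

#' Bivariate local genetic correlation for one locus
#'
#' Requires a nominally significant univariate signal in both traits
#' (`univ_p < univ_alpha`); otherwise a not-run flag is returned with the
#' reason. The local correlation is the cross-product of decorrelated
#' effects divided by `sqrt(h2_local_a * h2_local_b)`, truncated to
#' `[-1, 1]`; its p-value comes from a seeded simulation of the null
#' (independent effects with the estimated per-trait local variances),
#' two-sided on the cross-product statistic.
#'
#' @param subset_a,subset_b Per-locus record data.frames over the same SNPs.
#' @param n_a,n_b Sample sizes (default: subset `n` columns).
#' @param ld_model Optional locus LD matrix (`NULL` = identity).
#' @param univ_alpha Univariate filter level.
#' @param n_null_sims Null simulation draws for the p-value.
#' @param seed Integer seed.
#' @return A `local_rg_result` list: `locus` fields are filled by the caller;
#'   contains `rho`, `r2`, `p`, `univ_p_a`, `univ_p_b`, `h2_local_a`,
#'   `h2_local_b`, `n_snps`, `run`, `reason`.
#' @export
local_bivariate <- function(subset_a, subset_b, n_a = NULL, n_b = NULL,
                            ld_model = NULL, univ_alpha = 0.05,
                            n_null_sims = 10000, seed = 1) {
  stopifnot(nrow(subset_a) == nrow(subset_b))
  n_a <- n_a %||% mean(subset_a$n)
  n_b <- n_b %||% mean(subset_b$n)
  uni_a <- local_univariate(subset_a, n_a, ld_model)
  uni_b <- local_univariate(subset_b, n_b, ld_model)
  not_run <- function(reason) {
    list(rho = NA_real_, r2 = NA_real_, p = NA_real_,
         univ_p_a = uni_a$p, univ_p_b = uni_b$p,
         h2_local_a = uni_a$h2_local, h2_local_b = uni_b$h2_local,
         n_snps = nrow(subset_a), run = FALSE, reason = reason)
  }
  if (!uni_a$run || !uni_b$run) return(not_run("fewer than 2 SNPs"))
  if (uni_a$p >= univ_alpha || uni_b$p >= univ_alpha) {
    return(not_run("univariate filter not passed"))
  }
  if (uni_a$h2_local <= 0 || uni_b$h2_local <= 0) {
    return(not_run("non-positive local heritability, rho undefined"))
  }
  dec_a <- decorrelate_effects(subset_a$beta, ld_model)
  dec_b <- decorrelate_effects(subset_b$beta, ld_model)
  k <- dec_a$k_eff
  gencov <- sum(dec_a$eta * dec_b$eta)
  rho <- gencov / sqrt(uni_a$h2_local * uni_b$h2_local)
  rho_trunc <- max(-1, min(1, rho))

  # null: independent per-SNP effects with total variance h2 + K/n per trait
  sd_a <- sqrt((uni_a$h2_local + k / n_a) / k)
  sd_b <- sqrt((uni_b$h2_local + k / n_b) / k)
  null_stats <- with_seed(seed, {
    ea <- matrix(stats::rnorm(k * n_null_sims, 0, sd_a), nrow = k)
    eb <- matrix(stats::rnorm(k * n_null_sims, 0, sd_b), nrow = k)
    colSums(ea * eb)
  })
  p <- (1 + sum(abs(null_stats) >= abs(gencov))) / (1 + n_null_sims)

  list(rho = rho_trunc, rho_raw = rho, r2 = rho_trunc^2, p = p,
       univ_p_a = uni_a$p, univ_p_b = uni_b$p,
       h2_local_a = uni_a$h2_local, h2_local_b = uni_b$h2_local,
       n_snps = nrow(subset_a), run = TRUE, reason = NA_character_)
}

#' Locus scan of local genetic correlation for one trait pair
#'
#' Partitions both traits by locus, runs the univariate filter and bivariate
#' correlation per locus, and returns one row per locus.
#'
#' @param a,b [sumstats] objects.
#' @param loci Locus-definition table.
#' @param ... Passed to [local_bivariate()].
#' @return data.frame with columns `locus`, `chr`, `start`, `stop`,
#'   `n_snps`, `trait_a`, `trait_b`, `rho`, `r2`, `p`, `univ_p_a`,
#'   `univ_p_b`, `run`, `reason`.
#' @export
local_rg_scan <- function(a, b, loci, ...) {
  loci <- validate_loci(as.data.frame(loci))
  sh <- restrict_shared(a, b)
  part_a <- partition_by_locus(sh$a, loci)$subsets
  part_b <- partition_by_locus(sh$b, loci)$subsets
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    id <- as.character(loci$locus[i])
    sa <- part_a[[id]]
    sb <- part_b[[id]]
    if (nrow(sa) == 0) {
      res <- list(rho = NA_real_, r2 = NA_real_, p = NA_real_,
                  univ_p_a = NA_real_, univ_p_b = NA_real_,
                  n_snps = 0L, run = FALSE, reason = "no SNPs in locus")
    } else {
      res <- local_bivariate(sa, sb, ...)
    }
    data.frame(locus = loci$locus[i], chr = loci$chr[i],
               start = loci$start[i], stop = loci$stop[i],
               n_snps = res$n_snps, trait_a = a$trait_id, trait_b = b$trait_id,
               rho = res$rho, r2 = res$r2, p = res$p,
               univ_p_a = res$univ_p_a, univ_p_b = res$univ_p_b,
               run = res$run, reason = res$reason %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni threshold for a family of tests
#'
#' @param n_tests Number of tests performed.
#' @param family_alpha Family-wise level.
#' @return `family_alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop_format("n_tests must be >= 1")
  family_alpha / n_tests
}

#' Summarise a local-correlation scan for one trait pair
#'
#' Flags loci significant at `p < biv_alpha` (strict), averages their rho
#' estimates (`mean_rho`, full precision plus a 2-decimal
#' round-half-away-from-zero display value), and tallies significant loci per
#' chromosome.
#'
#' @param results data.frame from [local_rg_scan()] (rows for one trait
#'   pair).
#' @param biv_alpha Bivariate significance threshold.
#' @return A `local_rg_summary` list: `trait_a`, `trait_b`, `loci`
#'   (significant locus ids), `n_significant`, `mean_rho`,
#'   `mean_rho_display`, `per_chromosome_counts` (named vector), `results`
#'   (the significant rows).
#' @export
scan_and_summarise <- function(results, biv_alpha = 1.4e-3) {
  sig <- results[!is.na(results$p) & results$p < biv_alpha, , drop = FALSE]
  mean_rho <- if (nrow(sig) > 0) mean(sig$rho) else NA_real_
  counts <- if (nrow(sig) > 0) {
    tab <- table(sig$chr)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  structure(list(
    trait_a = if (nrow(results) > 0) results$trait_a[1] else NA_character_,
    trait_b = if (nrow(results) > 0) results$trait_b[1] else NA_character_,
    loci = sig$locus, n_significant = nrow(sig),
    mean_rho = mean_rho,
    mean_rho_display = if (is.na(mean_rho)) NA_real_ else
      round_half_away(mean_rho, 2),
    per_chromosome_counts = counts, results = sig),
    class = "local_rg_summary")
}

#' @export
print.local_rg_summary <- function(x, ...) {
  cat(sprintf("<local_rg_summary> %s ~ %s: %d significant locus/loci%s\n",
              x$trait_a, x$trait_b, x$n_significant,
              if (!is.na(x$mean_rho))
                sprintf(", mean rho = %.2f", x$mean_rho_display) else ""))
  invisible(x)
}
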
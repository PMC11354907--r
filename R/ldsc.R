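# LD-score regression: heritability, genetic covariance, genetic correlation.
#
# Both univariate and cross-trait fits go through one covariance-regression
# routine (the univariate chi-square regression is the self-pair case of the
# z-score product regression), so that a trait regressed on itself yields a
# genetic correlation of exactly 1. Standard errors come from a
# delete-a-block jackknife over contiguous SNP blocks, computed from
# block-wise weighted cross-products at the final weights.

ldsc_blocks <- function(m, n_blocks) {
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

# Weighted regression of za*zb on sqrt(nA*nB)*l2/m_ref.
# Heteroskedasticity weights 1 / (l * (vA*vB + c^2)) with vX the expected
# per-SNP z-variance of trait X and c the expected z-product, refined over
# `n_passes` reweighting passes from an initial unweighted-in-signal fit.
# var_params fixes vA/vB from previously fitted univariate models (cross-trait
# case); when NULL (univariate case) they track the current slope.
ldsc_cov_regression <- function(za, zb, n_a, n_b, l2, m_ref, n_blocks,
                                constrain_intercept = NULL,
                                var_params = NULL, n_passes = 2) {
  m <- length(za)
  y <- za * zb
  x <- sqrt(n_a * n_b) * l2 / m_ref
  if (stats::var(x) == 0) stop_format("singular design: all LD scores equal")
  free_int <- is.null(constrain_intercept)
  lw <- pmax(l2, 1)

  fit_wls <- function(w) {
    if (free_int) {
      sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
      swy <- sum(w * y); swxy <- sum(w * x * y)
      det <- sw * swx2 - swx^2
      slope <- (sw * swxy - swx * swy) / det
      int <- (swx2 * swy - swx * swxy) / det
    } else {
      yc <- y - constrain_intercept
      slope <- sum(w * x * yc) / sum(w * x^2)
      int <- constrain_intercept
    }
    list(slope = slope, intercept = int)
  }

  fit <- fit_wls(1 / lw)
  for (pass in seq_len(n_passes)) {
    if (is.null(var_params)) {
      # univariate case (za == zb, n_a == n_b): current slope is the h2 estimate
      va <- pmax(1 + n_a * fit$slope * l2 / m_ref, 0.1)
      vb <- va
    } else {
      va <- pmax(1 + n_a * var_params$h2_a * l2 / m_ref, 0.1)
      vb <- pmax(1 + n_b * var_params$h2_b * l2 / m_ref, 0.1)
    }
    cj <- fit$slope * x + fit$intercept
    w <- 1 / (lw * (va * vb + cj^2))
    fit <- fit_wls(w)
  }

  # block cross-products at the final weights for the delete-a-block jackknife
  blk <- ldsc_blocks(m, n_blocks)
  if (free_int) {
    xs <- cbind(1, x)
    sw_b <- rowsum(w, blk)
    swx_b <- rowsum(w * x, blk)
    swx2_b <- rowsum(w * x^2, blk)
    swy_b <- rowsum(w * y, blk)
    swxy_b <- rowsum(w * x * y, blk)
    sw <- sum(sw_b); swx <- sum(swx_b); swx2 <- sum(swx2_b)
    swy <- sum(swy_b); swxy <- sum(swxy_b)
    a11 <- sw - sw_b; a12 <- swx - swx_b; a22 <- swx2 - swx2_b
    b1 <- swy - swy_b; b2 <- swxy - swxy_b
    det <- a11 * a22 - a12^2
    delete_slopes <- as.numeric((a11 * b2 - a12 * b1) / det)
    delete_intercepts <- as.numeric((a22 * b1 - a12 * b2) / det)
  } else {
    yc <- y - constrain_intercept
    sxx_b <- rowsum(w * x^2, blk)
    sxy_b <- rowsum(w * x * yc, blk)
    sxx <- sum(sxx_b); sxy <- sum(sxy_b)
    delete_slopes <- as.numeric((sxy - sxy_b) / (sxx - sxx_b))
    delete_intercepts <- rep(constrain_intercept, max(blk))
  }
  list(slope = fit$slope, intercept = fit$intercept,
       delete_slopes = delete_slopes, delete_intercepts = delete_intercepts,
       n_blocks = max(blk))
}

jackknife_se <- function(delete_values) {
  d <- delete_values[is.finite(delete_values)]
  b <- length(d)
  sqrt((b - 1) / b * sum((d - mean(d))^2))
}

# align summary statistics with LD scores and apply the chi-square guard
ldsc_prepare <- function(ss_list, ld, chisq_max = NULL) {
  shared <- Reduce(intersect, c(list(ld$snp), lapply(ss_list, function(s) s$data$snp)))
  if (length(shared) < 200) stop_format("fewer than 200 SNPs with LD scores")
  ldm <- ld[match(shared, ld$snp), , drop = FALSE]
  ord <- order(ldm$chr, ldm$bp)
  shared <- shared[ord]
  ldm <- ldm[ord, , drop = FALSE]
  zs <- lapply(ss_list, function(s) {
    d <- s$data[match(shared, s$data$snp), , drop = FALSE]
    list(z = d$z, n = mean(d$n))
  })
  keep <- rep(TRUE, length(shared))
  for (t in zs) {
    cap <- chisq_max %||% max(80, 0.001 * t$n)
    keep <- keep & (t$z^2 <= cap)
  }
  list(l2 = ldm$l2[keep],
       zs = lapply(zs, function(t) list(z = t$z[keep], n = t$n)),
       n_snps = sum(keep))
}

#' Estimate SNP heritability by LD-score regression
#'
#' Regresses per-SNP chi-square statistics on `n * l_j / M` with
#' heteroskedasticity weights refined over two reweighting passes; the
#' standard error comes from a delete-a-block jackknife over `n_blocks`
#' contiguous blocks. SNPs with chi-square above `max(80, 0.001 n)` are
#' dropped before the regression (set `chisq_max = Inf` to disable).
#'
#' @param ss A [sumstats] object.
#' @param ld An LD-score table from [read_ldscores()] or a simulator.
#' @param m_ref Reference SNP count M in the slope term; defaults to the
#'   number of regression SNPs.
#' @param n_blocks Number of jackknife blocks.
#' @param constrain_intercept Optional fixed value for the regression
#'   intercept (e.g. 1); `NULL` leaves it free.
#' @param chisq_max Chi-square cap; `NULL` uses the default guard.
#' @return List with `h2`, `se`, `intercept`, `intercept_se`, `n_snps`,
#'   `n_blocks`.
#' @export
estimate_h2 <- function(ss, ld, m_ref = NULL, n_blocks = 200,
                        constrain_intercept = NULL, chisq_max = NULL) {
  prep <- ldsc_prepare(list(ss), ld, chisq_max)
  if (prep$n_snps <= n_blocks) stop_format("fewer SNPs (%d) than jackknife blocks (%d)",
                                           prep$n_snps, n_blocks)
  m_ref <- m_ref %||% prep$n_snps
  z <- prep$zs[[1]]$z
  n <- prep$zs[[1]]$n
  fit <- ldsc_cov_regression(z, z, n, n, prep$l2, m_ref, n_blocks,
                             constrain_intercept = constrain_intercept)
  list(h2 = fit$slope, se = jackknife_se(fit$delete_slopes),
       intercept = fit$intercept,
       intercept_se = if (is.null(constrain_intercept))
         jackknife_se(fit$delete_intercepts) else 0,
       n_snps = prep$n_snps, n_blocks = fit$n_blocks)
}

#' Estimate global genetic correlation between two traits
#'
#' Bivariate LD-score regression: the z-score product is regressed on
#' `sqrt(n_a n_b) l_j / M`, giving the genetic covariance; the genetic
#' correlation is `rg = gencov / sqrt(h2_a h2_b)` with univariate
#' heritabilities fitted on the same SNP set. The cross-trait intercept
#' absorbs sample overlap; `constrain_intercepts = TRUE` fixes it at 0
#' (univariate intercepts remain free). The jackknife SE of the ratio uses
#' delete-a-block estimates of all three regressions over shared blocks, and
#' the p-value is two-sided normal. `rg` is reported unclipped (a warning is
#' raised when |rg| > 1, which can happen through estimation noise).
#'
#' @param a,b [sumstats] objects.
#' @param ld LD-score table.
#' @param m_ref Reference SNP count; defaults to the regression SNP count.
#' @param n_blocks Jackknife blocks.
#' @param constrain_intercepts Fix the cross-trait intercept at 0.
#' @param chisq_max Chi-square cap (see [estimate_h2()]).
#' @return An `rg_estimate` list: `trait_a`, `trait_b`, `rg`, `se`, `p`,
#'   `h2_a`, `h2_b`, `gencov`, `intercept_uni_a`, `intercept_uni_b`,
#'   `intercept_biv`, `n_snps`, `n_blocks`, `constrained`.
#' @export
estimate_rg <- function(a, b, ld, m_ref = NULL, n_blocks = 200,
                        constrain_intercepts = FALSE, chisq_max = NULL) {
  prep <- ldsc_prepare(list(a, b), ld, chisq_max)
  if (prep$n_snps <= n_blocks) stop_format("fewer SNPs (%d) than jackknife blocks (%d)",
                                           prep$n_snps, n_blocks)
  m_ref <- m_ref %||% prep$n_snps
  za <- prep$zs[[1]]$z; n_a <- prep$zs[[1]]$n
  zb <- prep$zs[[2]]$z; n_b <- prep$zs[[2]]$n

  # preliminary univariate fits supply the variance parameters, after which
  # all three regressions share one weighting rule (so a self-pair gives
  # gencov identical to h2 and rg = 1 exactly)
  pre_a <- ldsc_cov_regression(za, za, n_a, n_a, prep$l2, m_ref, n_blocks)
  pre_b <- ldsc_cov_regression(zb, zb, n_b, n_b, prep$l2, m_ref, n_blocks)
  uni_a <- ldsc_cov_regression(za, za, n_a, n_a, prep$l2, m_ref, n_blocks,
                               var_params = list(h2_a = pre_a$slope,
                                                 h2_b = pre_a$slope))
  uni_b <- ldsc_cov_regression(zb, zb, n_b, n_b, prep$l2, m_ref, n_blocks,
                               var_params = list(h2_a = pre_b$slope,
                                                 h2_b = pre_b$slope))
  if (uni_a$slope * uni_b$slope <= 0) {
    stop_format("non-positive heritability, rg undefined (h2_a = %.4g, h2_b = %.4g)",
                uni_a$slope, uni_b$slope)
  }
  cov_fit <- ldsc_cov_regression(
    za, zb, n_a, n_b, prep$l2, m_ref, n_blocks,
    constrain_intercept = if (constrain_intercepts) 0 else NULL,
    var_params = list(h2_a = pre_a$slope, h2_b = pre_b$slope))

  rg <- cov_fit$slope / sqrt(uni_a$slope * uni_b$slope)
  prod_k <- uni_a$delete_slopes * uni_b$delete_slopes
  rg_k <- ifelse(prod_k > 0, cov_fit$delete_slopes / sqrt(pmax(prod_k, 0)), NA_real_)
  if (any(!is.finite(rg_k))) {
    warning("some jackknife blocks gave non-positive heritability; SE uses the remaining blocks",
            call. = FALSE)
  }
  se <- jackknife_se(rg_k)
  p <- 2 * stats::pnorm(-abs(rg / se))
  if (abs(rg) > 1 + 1e-9) {
    warning(sprintf("estimated rg = %.3f lies outside [-1, 1] (estimation noise); reported unclipped", rg),
            call. = FALSE)
  }
  structure(list(trait_a = a$trait_id, trait_b = b$trait_id,
                 rg = rg, se = se, p = p,
                 h2_a = uni_a$slope, h2_b = uni_b$slope,
                 gencov = cov_fit$slope,
                 intercept_uni_a = uni_a$intercept,
                 intercept_uni_b = uni_b$intercept,
                 intercept_biv = cov_fit$intercept,
                 intercept_biv_se = if (constrain_intercepts) 0 else
                   jackknife_se(cov_fit$delete_intercepts),
                 n_snps = prep$n_snps, n_blocks = cov_fit$n_blocks,
                 constrained = constrain_intercepts),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("<rg_estimate> %s ~ %s: rg = %.3f (se %.3f, p = %.3g)%s\n",
              x$trait_a, x$trait_b, x$rg, x$se, x$p,
              if (x$constrained) " [cross-intercept constrained to 0]" else ""))
  invisible(x)
}

#' Pairwise genetic-correlation scan of one target against a trait panel
#'
#' Runs [estimate_rg()] for the target against each other trait and flags
#' pairs significant at `p < alpha_pair` (strict inequality). Per-pair errors
#' are recorded and the scan continues.
#'
#' @param target A [sumstats] object.
#' @param others List of [sumstats] objects.
#' @param ld LD-score table.
#' @param alpha_pair Pairwise significance level.
#' @param ... Passed to [estimate_rg()].
#' @return data.frame with one row per pair: trait labels, `rg`, `se`, `p`,
#'   `h2_a`, `h2_b`, `intercept_biv`, `significant`, `error`.
#' @export
pairwise_rg_scan <- function(target, others, ld, alpha_pair = 0.025, ...) {
  if (length(others) < 1) stop_format("need at least one other trait")
  rows <- lapply(others, function(other) {
    res <- tryCatch(estimate_rg(target, other, ld, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(trait_a = target$trait_id, trait_b = other$trait_id,
                 rg = NA_real_, se = NA_real_, p = NA_real_,
                 h2_a = NA_real_, h2_b = NA_real_, intercept_biv = NA_real_,
                 significant = NA, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(trait_a = res$trait_a, trait_b = res$trait_b,
                 rg = res$rg, se = res$se, p = res$p,
                 h2_a = res$h2_a, h2_b = res$h2_b,
                 intercept_biv = res$intercept_biv,
                 significant = res$p < alpha_pair, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
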
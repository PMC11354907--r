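# Two-sample Mendelian randomisation: instrument selection, IVW, weighted
# median, MR-Egger, Cochran's Q, and MR-PRESSO global/outlier/distortion
# tests. Estimators run on a harmonised instrument table (one row per
# instrument with exposure and outcome effects on the same effect allele).
# Methods below their minimum instrument count return a not-run flag rather
# than numbers, reproducing the dash/absence conventions of published MR
# result tables.

#' Construct an instrument set
#'
#' @param data data.frame with columns `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (one row per instrument).
#' @param exposure,outcome Trait labels.
#' @return The data.frame with class `instrument_set` and attributes
#'   `exposure`, `outcome`.
#' @export
instrument_set <- function(data, exposure = "exposure", outcome = "outcome") {
  req <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop_format("instrument set missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(data$snp)) stop_format("duplicate instrument snp id")
  if (any(data$se_exp <= 0) || any(data$se_out <= 0)) {
    stop_format("instrument standard errors must be > 0")
  }
  structure(as.data.frame(data, stringsAsFactors = FALSE),
            class = c("instrument_set", "data.frame"),
            exposure = exposure, outcome = outcome)
}

mr_not_run <- function(reason) {
  list(beta = NA_real_, se = NA_real_, p = NA_real_, run = FALSE,
       reason = reason)
}

#' Select independent genome-wide significant instruments
#'
#' Candidates with `p < p_thresh` (strict) are sorted by ascending p-value
#' and greedily clumped: a SNP is dropped when it lies within `clump_kb`
#' kilobases of an already-retained SNP on the same chromosome and, when LD
#' block information is available, in the same LD block. With `ld_blocks`
#' given, two SNPs in different blocks are treated as independent regardless
#' of distance.
#'
#' @param exposure A [sumstats] object.
#' @param p_thresh Genome-wide significance threshold for instruments.
#' @param clump_kb Clumping window in kilobases.
#' @param ld_blocks Optional named vector mapping snp id to an LD-block id.
#' @return Character vector of retained SNP ids (possibly empty, with a
#'   warning).
#' @export
select_instruments <- function(exposure, p_thresh = 5e-8, clump_kb = 10000,
                               ld_blocks = NULL) {
  d <- exposure$data
  cand <- d[d$p < p_thresh, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning(sprintf("no genome-wide significant SNPs for '%s'; no instruments",
                    exposure$trait_id), call. = FALSE)
    return(character(0))
  }
  cand <- cand[order(cand$p), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (j in kept) {
      if (cand$chr[i] != cand$chr[j]) next
      same_window <- abs(cand$bp[i] - cand$bp[j]) <= clump_kb * 1000
      if (!same_window) next
      if (!is.null(ld_blocks)) {
        bi <- ld_blocks[cand$snp[i]]
        bj <- ld_blocks[cand$snp[j]]
        if (!is.na(bi) && !is.na(bj) && bi != bj) next
      }
      conflict <- TRUE
      break
    }
    if (!conflict) kept <- c(kept, i)
  }
  cand$snp[kept]
}

#' Extract instruments from the outcome and harmonise effects
#'
#' Looks up the selected instruments in both tables, harmonises the outcome's
#' allele coding to the exposure's via [harmonise()] (instruments absent from
#' the outcome, or dropped as palindromic/unmatchable, are removed with a
#' reported count), and orients every instrument so its exposure effect is
#' positive by flipping both betas together — Wald ratios are invariant to
#' this, and it fixes the orientation MR-Egger requires.
#'
#' @param ivs Character vector of instrument SNP ids.
#' @param exposure,outcome [sumstats] objects.
#' @return An [instrument_set].
#' @export
extract_and_harmonise <- function(ivs, exposure, outcome) {
  de <- exposure$data[exposure$data$snp %in% ivs, , drop = FALSE]
  present <- de$snp %in% outcome$data$snp
  if (any(!present)) {
    message(sprintf("extract_and_harmonise: %d instrument(s) absent from the outcome dropped",
                    sum(!present)))
  }
  de <- de[present, , drop = FALSE]
  if (nrow(de) == 0) stop_format("no usable instruments")
  exp_sub <- sumstats(exposure$trait_id, de)
  out_sub <- sumstats(outcome$trait_id,
                      outcome$data[outcome$data$snp %in% de$snp, , drop = FALSE])
  h <- harmonise(exp_sub, out_sub)
  shared <- restrict_shared(h$a, h$b)
  if (shared$n_shared == 0) stop_format("no usable instruments")
  be <- shared$a$data$beta
  bo <- shared$b$data$beta
  flip <- be < 0
  tab <- data.frame(snp = shared$a$data$snp,
                    beta_exp = ifelse(flip, -be, be),
                    se_exp = shared$a$data$se,
                    beta_out = ifelse(flip, -bo, bo),
                    se_out = shared$b$data$se,
                    stringsAsFactors = FALSE)
  instrument_set(tab, exposure = exposure$trait_id, outcome = outcome$trait_id)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`. Under the multiplicative random-effects
#' model (the default) the standard error is inflated by
#' `max(1, sqrt(Q / (n_iv - 1)))`; the fixed-effect model leaves it as is.
#' The p-value is two-sided normal.
#'
#' @param ivs An [instrument_set].
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return List with `beta`, `se`, `p`, `n_iv`, `run`; when fewer than 2
#'   instruments are available a not-run flag with a reason.
#' @export
mr_ivw <- function(ivs, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  if (nrow(ivs) < 2) return(mr_not_run("fewer than 2 instruments"))
  w <- 1 / ivs$se_out^2
  bx <- ivs$beta_exp
  by <- ivs$beta_out
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  if (model == "multiplicative_random") {
    q <- sum(w * (by - beta * bx)^2)
    se <- se * max(1, sqrt(q / (nrow(ivs) - 1)))
  }
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
       n_iv = nrow(ivs), run = TRUE, model = model)
}

#' Weighted-median MR estimate
#'
#' Per-instrument Wald ratios are ordered and the estimate is the weighted
#' 50th percentile under inverse-variance weights (first-order ratio
#' variances), with linear interpolation between the bracketing ratios. The
#' standard error comes from a seeded parametric bootstrap.
#'
#' @param ivs An [instrument_set].
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return List with `beta`, `se`, `p`, `n_iv`, `run`; not-run below 3
#'   instruments.
#' @export
mr_weighted_median <- function(ivs, n_boot = 1000, seed = 1) {
  if (nrow(ivs) < 3) return(mr_not_run("fewer than 3 instruments"))
  est <- weighted_median_point(ivs$beta_exp, ivs$beta_out, ivs$se_out)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(ivs), ivs$beta_exp, ivs$se_exp)
      by <- stats::rnorm(nrow(ivs), ivs$beta_out, ivs$se_out)
      weighted_median_point(bx, by, ivs$se_out)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  list(beta = est, se = se, p = 2 * stats::pnorm(-abs(est / se)),
       n_iv = nrow(ivs), run = TRUE)
}

# weighted 50th percentile of Wald ratios, Bowden-style interpolation
weighted_median_point <- function(beta_exp, beta_out, se_out) {
  ratio <- beta_out / beta_exp
  w <- (beta_exp / se_out)^2   # 1 / var(ratio), first-order
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] > 0.5) return(ratio[1])
  j <- max(which(cum <= 0.5))
  if (j == length(ratio) || cum[j] == 0.5) return(ratio[j])
  ratio[j] + (ratio[j + 1] - ratio[j]) * (0.5 - cum[j]) / (cum[j + 1] - cum[j])
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free intercept
#' (weights `1/se_out^2`). The intercept estimates directional pleiotropy;
#' its p-value is the pleiotropy test. Slope and intercept inference use a t
#' distribution with `n_iv - 2` degrees of freedom.
#'
#' @param ivs An [instrument_set] (exposure effects should be oriented
#'   positive, as [extract_and_harmonise()] ensures).
#' @return List with `beta`, `se`, `p`, `intercept`, `intercept_se`,
#'   `intercept_p`, `n_iv`, `run`; not-run below 3 instruments or with no
#'   spread in the exposure effects.
#' @export
mr_egger <- function(ivs) {
  if (nrow(ivs) < 3) return(mr_not_run("fewer than 3 instruments"))
  bx <- ivs$beta_exp
  by <- ivs$beta_out
  w <- 1 / ivs$se_out^2
  if (stats::var(bx) == 0) return(mr_not_run("no spread in exposure effects"))
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / det
  int <- (swx2 * swy - swx * swxy) / det
  df <- nrow(ivs) - 2
  rss <- sum(w * (by - int - slope * bx)^2)
  sigma2 <- max(rss / df, 1)   # multiplicative random-effects floor
  se_slope <- sqrt(sigma2 * sw / det)
  se_int <- sqrt(sigma2 * swx2 / det)
  list(beta = slope, se = se_slope,
       p = 2 * stats::pt(-abs(slope / se_slope), df),
       intercept = int, intercept_se = se_int,
       intercept_p = 2 * stats::pt(-abs(int / se_int), df),
       n_iv = nrow(ivs), run = TRUE)
}

#' Cochran's Q heterogeneity test across instruments
#'
#' `Q = sum w_i (r_i - beta_ref)^2` over per-instrument Wald ratios with
#' first-order inverse-variance weights, referred to a chi-square with
#' `n_iv - 1` degrees of freedom.
#'
#' @param ivs An [instrument_set].
#' @param beta_ref Reference estimate; defaults to the fixed-effect IVW
#'   estimate (which minimises Q under these weights).
#' @return List with `q`, `df`, `p`, `run`.
#' @export
cochran_q <- function(ivs, beta_ref = NULL) {
  if (nrow(ivs) < 2) return(list(q = NA_real_, df = NA_integer_,
                                 p = NA_real_, run = FALSE,
                                 reason = "fewer than 2 instruments"))
  if (is.null(beta_ref)) beta_ref <- mr_ivw(ivs, model = "fixed")$beta
  ratio <- ivs$beta_out / ivs$beta_exp
  w <- (ivs$beta_exp / ivs$se_out)^2
  q <- sum(w * (ratio - beta_ref)^2)
  df <- nrow(ivs) - 1
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       run = TRUE)
}

#' MR-PRESSO global, outlier, and distortion tests
#'
#' The global test compares the observed residual sum of squares — each
#' instrument's outcome effect against its leave-one-out IVW prediction —
#' with the RSS distribution over `n_sim` parametric simulations of the
#' no-pleiotropy model. Per-instrument outlier p-values are the simulated
#' exceedance probabilities of each observed residual, Bonferroni-thresholded
#' at `outlier_alpha / n_iv`. When outliers are found, the outlier-corrected
#' estimate is IVW after removing them, and the distortion test compares the
#' raw-vs-corrected shift against the shift obtained by removing equally many
#' random instruments; with no outliers the corrected estimate and distortion
#' p are absent (`NA`), matching the reporting convention for "no pleiotropy
#' detected".
#'
#' @param ivs An [instrument_set].
#' @param n_sim Number of parametric simulations.
#' @param seed Integer seed.
#' @param outlier_alpha Family-wise level for the outlier test.
#' @param min_iv Minimum instruments required.
#' @return List with `global_p`, `outliers` (SNP ids), `raw` (IVW list),
#'   `corrected` (IVW list or `NULL`), `distortion_p`, `run`.
#' @export
mr_presso <- function(ivs, n_sim = 1000, seed = 1, outlier_alpha = 0.05,
                      min_iv = 4) {
  if (nrow(ivs) < min_iv) {
    return(list(global_p = NA_real_, outliers = character(0), raw = NULL,
                corrected = NULL, distortion_p = NA_real_, run = FALSE,
                reason = sprintf("fewer than %d instruments", min_iv)))
  }
  n <- nrow(ivs)
  bx <- ivs$beta_exp; by <- ivs$beta_out
  sx <- ivs$se_exp; sy <- ivs$se_out
  w <- 1 / sy^2

  loo_beta <- function(bx, by, w) {
    num <- sum(w * bx * by); den <- sum(w * bx^2)
    (num - w * bx * by) / (den - w * bx^2)   # leave-one-out IVW, vectorised
  }
  obs_b <- loo_beta(bx, by, w)
  obs_res <- w * (by - obs_b * bx)^2
  rss_obs <- sum(obs_res)

  sims <- with_seed(seed, {
    bexp <- matrix(stats::rnorm(n * n_sim, bx, sx), nrow = n)
    bexp_pred <- matrix(rep(obs_b * bx, n_sim), nrow = n)
    bout <- matrix(stats::rnorm(n * n_sim, bexp_pred, sy), nrow = n)
    res <- matrix(0, n, n_sim)
    for (s in seq_len(n_sim)) {
      b_s <- loo_beta(bexp[, s], bout[, s], w)
      res[, s] <- w * (bout[, s] - b_s * bexp[, s])^2
    }
    res
  })
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)

  out_p <- (1 + rowSums(sims >= obs_res)) / (1 + n_sim)
  outliers <- ivs$snp[out_p < outlier_alpha / n]

  raw <- mr_ivw(ivs)
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && n - length(outliers) >= 2) {
    keep <- !ivs$snp %in% outliers
    corrected <- mr_ivw(ivs[keep, , drop = FALSE])
    obs_shift <- raw$beta - corrected$beta
    n_out <- length(outliers)
    shifts <- with_seed(seed + 1L, {
      vapply(seq_len(min(n_sim, 1000)), function(i) {
        drop_idx <- sample(n, n_out)
        sub <- ivs[-drop_idx, , drop = FALSE]
        raw$beta - mr_ivw(sub)$beta
      }, numeric(1))
    })
    distortion_p <- mean(abs(shifts) >= abs(obs_shift))
  }
  list(global_p = global_p, outliers = outliers, raw = raw,
       corrected = corrected, distortion_p = distortion_p, run = TRUE)
}

or_ci <- function(beta, se) {
  if (is.na(beta)) return(c(or = NA_real_, lo = NA_real_, hi = NA_real_))
  c(or = exp(beta), lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se))
}

#' Run the full MR estimator suite in one direction
#'
#' Instrument selection on the exposure, extraction/harmonisation against the
#' outcome, then IVW, weighted median, MR-Egger, Cochran's Q and MR-PRESSO.
#' Odds ratios and 95% confidence intervals are `exp(beta)`,
#' `exp(beta +- 1.96 se)`.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param p_thresh,clump_kb,ld_blocks Instrument selection (see
#'   [select_instruments()]).
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso_sims MR-PRESSO simulations.
#' @param seed Integer seed for the seeded components.
#' @return An `mr_result` list with per-method results, `egger_intercept*`,
#'   `q_stat`/`q_p`, `presso_*`, `n_iv`, `exposure`, `outcome`.
#' @export
run_mr <- function(exposure, outcome, p_thresh = 5e-8, clump_kb = 10000,
                   ld_blocks = NULL, n_boot = 1000, presso_sims = 1000,
                   seed = 1) {
  ivs_ids <- select_instruments(exposure, p_thresh, clump_kb, ld_blocks)
  empty <- function(n_iv) {
    structure(list(exposure = exposure$trait_id, outcome = outcome$trait_id,
                   n_iv = n_iv, ivw = mr_not_run("insufficient instruments"),
                   weighted_median = mr_not_run("insufficient instruments"),
                   egger = mr_not_run("insufficient instruments"),
                   q = list(run = FALSE), presso = list(run = FALSE),
                   wald_ratio = NA_real_),
              class = "mr_result")
  }
  if (length(ivs_ids) == 0) return(empty(0L))
  set <- tryCatch(extract_and_harmonise(ivs_ids, exposure, outcome),
                  error = function(e) NULL)
  if (is.null(set)) return(empty(0L))
  n_iv <- nrow(set)
  wald <- if (n_iv == 1) set$beta_out / set$beta_exp else NA_real_
  structure(list(exposure = exposure$trait_id, outcome = outcome$trait_id,
                 n_iv = n_iv,
                 ivw = mr_ivw(set),
                 weighted_median = mr_weighted_median(set, n_boot, seed),
                 egger = mr_egger(set),
                 q = cochran_q(set),
                 presso = mr_presso(set, presso_sims, seed),
                 wald_ratio = wald, instruments = set),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s -> %s (nIV = %d)\n", x$exposure, x$outcome,
              x$n_iv))
  for (m in c("ivw", "weighted_median", "egger")) {
    r <- x[[m]]
    if (isTRUE(r$run)) {
      ci <- or_ci(r$beta, r$se)
      cat(sprintf("  %-16s OR %.2f (%.2f-%.2f), p = %.3g\n", m, ci["or"],
                  ci["lo"], ci["hi"], r$p))
    } else {
      cat(sprintf("  %-16s -\n", m))
    }
  }
  invisible(x)
}

#' Bi-directional two-sample MR
#'
#' Runs the full estimator suite with `a` as exposure and `b` as outcome,
#' then with the roles swapped.
#'
#' @param a,b [sumstats] objects.
#' @param ... Passed to [run_mr()].
#' @return List with elements `forward` (`a` as exposure) and `reverse`.
#' @export
run_bidirectional <- function(a, b, ...) {
  list(forward = run_mr(a, b, ...), reverse = run_mr(b, a, ...))
}
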
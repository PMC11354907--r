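# Gene-level genetic overlap: exact binomial overlap assessment, sentinel
# shared-gene discovery, and Fisher's combined p-value analysis.

#' One-sided exact binomial upper-tail p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, the test used to ask whether the
#' observed proportion of overlapping genes exceeds the expected proportion.
#' Computed in log space (via the stable upper-tail of the binomial CDF) so
#' extreme tails do not underflow.
#'
#' @param k Number of successes (overlapping genes).
#' @param n Number of trials (genes significant in the target set).
#' @param p0 Null proportion (expected overlap proportion).
#' @return The upper-tail p-value.
#' @export
exact_binomial_upper <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop_format("p0 must lie in (0, 1)")
  if (k < 0 || k > n) stop_format("k must lie in [0, n]")
  if (k == 0) return(1)
  exp(stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE))
}

#' Gene-level overlap assessment between a discovery and a target trait
#'
#' Counts genes significant at `P_gene < alpha` (strict) in each table and
#' genes significant in both. The expected overlap proportion is
#' `sig_discovery / total_discovery`; the observed proportion is
#' `n_overlap / sig_target`. A one-sided exact binomial test asks whether the
#' observed proportion exceeds the expected one, with the null proportion
#' rounded to `null_rounding` decimal places (set `null_rounding = NULL` for
#' the exact fraction).
#'
#' @param discovery,target [gene_table] objects. Gene symbols are matched
#'   after upper-casing.
#' @param alpha Gene significance threshold.
#' @param null_rounding Decimal places for the null proportion (default 3);
#'   `NULL` uses the unrounded expected proportion.
#' @return An `overlap_result` list: trait labels, the counts, `expected_prop`,
#'   `observed_prop`, `null_prop` (as used in the test), `p_binomial`, and
#'   `p_defined` (FALSE when no target-significant genes exist).
#' @export
overlap_assessment <- function(discovery, target, alpha = 0.05,
                               null_rounding = 3) {
  dd <- discovery$data
  dt <- target$data
  if (nrow(dd) == 0 || nrow(dt) == 0) stop_format("empty gene table")
  sig_d <- dd$gene[dd$p < alpha]
  sig_t <- dt$gene[dt$p < alpha]
  n_overlap <- length(intersect(sig_d, sig_t))
  expected <- length(sig_d) / nrow(dd)
  null_prop <- if (is.null(null_rounding)) expected else
    round(expected, null_rounding)
  if (length(sig_t) == 0) {
    observed <- NA_real_
    p_binom <- NA_real_
    p_defined <- FALSE
  } else {
    observed <- n_overlap / length(sig_t)
    p_binom <- exact_binomial_upper(n_overlap, length(sig_t), null_prop)
    p_defined <- TRUE
  }
  structure(list(discovery = discovery$trait_id, target = target$trait_id,
                 total_discovery = nrow(dd), total_target = nrow(dt),
                 sig_discovery = length(sig_d), sig_target = length(sig_t),
                 n_overlap = n_overlap,
                 expected_prop = expected, observed_prop = observed,
                 null_prop = null_prop,
                 p_binomial = p_binom, p_defined = p_defined),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %s (discovery) vs %s (target): %d/%d overlap, expected %.1f%%, observed %s, p = %s\n",
    x$discovery, x$target, x$n_overlap, x$sig_target,
    100 * x$expected_prop,
    if (x$p_defined) sprintf("%.1f%%", 100 * x$observed_prop) else "undefined",
    if (x$p_defined) format(x$p_binomial, digits = 3) else "undefined"))
  invisible(x)
}

#' Fisher's combined p-value for two gene p-values
#'
#' `X = -2 (ln p_a + ln p_b)` referred to the upper tail of a chi-square
#' distribution with 4 degrees of freedom, computed in log space.
#'
#' @param p_a,p_b p-values in (0, 1]. Vectorised.
#' @return Combined p-value(s).
#' @export
fisher_combine <- function(p_a, p_b) {
  if (any(p_a <= 0) || any(p_b <= 0)) stop_format("p-values must be > 0 (clamp underflowed values first)")
  x <- -2 * (log(p_a) + log(p_b))
  exp(stats::pchisq(x, df = 4, lower.tail = FALSE, log.p = TRUE))
}

#' Sentinel shared genes across gene tables
#'
#' Genes already genome-wide significant (`P_gene < gws`, strict) in the
#' target trait and in at least one other trait, annotated with the full
#' list of qualifying traits.
#'
#' @param tables Named list of [gene_table] objects (names = trait labels).
#' @param target Name of the target trait within `tables`.
#' @param gws Genome-wide gene significance threshold.
#' @return data.frame with columns `gene`, `traits` (comma-separated,
#'   alphabetically sorted, target first), `n_other`, `category`
#'   (`"sentinel_overlap"`), `p_target`.
#' @export
find_sentinel_shared <- function(tables, target, gws = 2.6e-6) {
  if (!target %in% names(tables)) stop_format("target '%s' not in tables", target)
  gws_genes <- lapply(tables, function(gt) gt$data$gene[gt$data$p < gws])
  tgt <- gws_genes[[target]]
  others <- names(tables)[names(tables) != target]
  rows <- lapply(tgt, function(g) {
    hits <- others[vapply(others, function(tr) g %in% gws_genes[[tr]], logical(1))]
    if (length(hits) == 0) return(NULL)
    ptab <- tables[[target]]$data
    data.frame(gene = g,
               traits = paste(c(target, sort(hits)), collapse = ","),
               n_other = length(hits), category = "sentinel_overlap",
               p_target = ptab$p[match(g, ptab$gene)],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(gene = character(), traits = character(),
                      n_other = integer(), category = character(),
                      p_target = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Genes reaching genome-wide significance through Fisher's combination
#'
#' For every gene present in both tables, combines the two p-values with
#' [fisher_combine()]. A gene is emitted as `fcp_reaching` when it is not yet
#' genome-wide significant in either input (`gws <= p < alpha` in both) but
#' the combined p-value falls below `gws`. Genes already genome-wide
#' significant in one input whose combined p improves on both inputs are
#' emitted as `improved`. Underflowed input p-values are clamped to 1e-300
#' before log-space combination.
#'
#' @param table_target,table_other [gene_table] objects.
#' @param gws Genome-wide gene significance threshold.
#' @param alpha Nominal gene significance threshold.
#' @return data.frame with columns `gene`, `p_target`, `p_other`, `p_fcp`,
#'   `category` in `{fcp_reaching, improved}`.
#' @export
classify_fcp_genes <- function(table_target, table_other, gws = 2.6e-6,
                               alpha = 0.05) {
  dt <- table_target$data
  do <- table_other$data
  shared <- intersect(dt$gene, do$gene)
  if (length(shared) == 0) stop_format("no shared genes between tables")
  p_t <- clamp_p(dt$p[match(shared, dt$gene)])
  p_o <- clamp_p(do$p[match(shared, do$gene)])
  p_fcp <- fisher_combine(p_t, p_o)

  not_gws_both <- p_t >= gws & p_o >= gws
  nominal_both <- p_t < alpha & p_o < alpha
  reaching <- not_gws_both & nominal_both & p_fcp < gws
  improved <- (p_t < gws | p_o < gws) & p_fcp < pmin(p_t, p_o)

  out <- rbind(
    if (any(reaching)) data.frame(
      gene = shared[reaching], p_target = p_t[reaching],
      p_other = p_o[reaching], p_fcp = p_fcp[reaching],
      category = "fcp_reaching", stringsAsFactors = FALSE),
    if (any(improved)) data.frame(
      gene = shared[improved], p_target = p_t[improved],
      p_other = p_o[improved], p_fcp = p_fcp[improved],
      category = "improved", stringsAsFactors = FALSE))
  if (is.null(out)) {
    out <- data.frame(gene = character(), p_target = numeric(),
                      p_other = numeric(), p_fcp = numeric(),
                      category = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarise genes shared with the target across multiple traits
#'
#' Aggregates shared-gene records (from [find_sentinel_shared()] and/or
#' per-pair [classify_fcp_genes()] results annotated with the partner trait)
#' into one row per gene shared with at least `min_traits` non-target traits.
#'
#' @param shared data.frame with columns `gene` and `trait` (the non-target
#'   partner trait of each record).
#' @param min_traits Minimum number of distinct non-target traits.
#' @return data.frame with columns `gene`, `n_traits`, `traits`
#'   (deduplicated, alphabetically sorted, comma-separated).
#' @export
cross_trait_gene_summary <- function(shared, min_traits = 2) {
  if (nrow(shared) == 0) {
    return(data.frame(gene = character(), n_traits = integer(),
                      traits = character(), stringsAsFactors = FALSE))
  }
  sp <- split(shared$trait, shared$gene)
  rows <- lapply(names(sp), function(g) {
    tr <- sort(unique(sp[[g]]))
    if (length(tr) < min_traits) return(NULL)
    data.frame(gene = g, n_traits = length(tr),
               traits = paste(tr, collapse = ","), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(gene = character(), n_traits = integer(),
                      traits = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene), , drop = FALSE]
}
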
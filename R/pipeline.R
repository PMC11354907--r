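# Workflow orchestration: run every analysis stage in order over a target
# trait and trait panels, classify global-vs-local concordance, and emit the
# report tables.

#' Classify concordance between global and local genetic correlation
#'
#' Compares the LD-score-regression estimate with the mean local correlation
#' over significant loci for the same trait pair. Both significant with the
#' same sign gives `both_concordant`; both significant with opposite signs
#' `both_discordant`; one significant `ldsc_only` / `lava_only`; otherwise
#' `neither`. Significance uses `p < alpha_ldsc` for the global estimate and,
#' for the local summary, at least one locus significant at the local
#' family threshold (already applied when the summary was built).
#'
#' @param rg An `rg_estimate` (or list with `rg`, `p`).
#' @param summary A `local_rg_summary`.
#' @param alpha_ldsc Pairwise significance level for the global estimate.
#' @return A `concordance_record` list: `trait_a`, `trait_b`, `ldsc_sig`,
#'   `lava_sig`, `ldsc_sign`, `lava_sign`, `category`.
#' @export
classify_concordance <- function(rg, summary, alpha_ldsc = 0.025) {
  ldsc_sig <- !is.na(rg$p) && rg$p < alpha_ldsc
  lava_sig <- summary$n_significant > 0
  if (lava_sig && is.na(summary$mean_rho)) {
    stop_format("internal inconsistency: significant local results without a mean rho")
  }
  ldsc_sign <- sign(rg$rg)
  lava_sign <- if (lava_sig) sign(summary$mean_rho) else NA_real_
  category <- if (ldsc_sig && lava_sig) {
    if (ldsc_sign == lava_sign) "both_concordant" else "both_discordant"
  } else if (ldsc_sig) {
    "ldsc_only"
  } else if (lava_sig) {
    "lava_only"
  } else {
    "neither"
  }
  structure(list(trait_a = rg$trait_a, trait_b = rg$trait_b,
                 ldsc_sig = ldsc_sig, lava_sig = lava_sig,
                 ldsc_sign = ldsc_sign, lava_sign = lava_sign,
                 category = category),
            class = "concordance_record")
}

#' Default workflow configuration
#'
#' Returns the configuration list [run_workflow()] consumes, optionally
#' overridden from a YAML document. The synthetic-generation block defines
#' the inputs; thresholds follow the analysis families used throughout the
#' package (pairwise global 0.025, gene 0.05 nominal, gene genome-wide
#' 2.6e-6, local bivariate family 0.05 / number of local tests).
#'
#' @param path Optional YAML file; values found there override the defaults.
#' @return Named list of configuration values.
#' @export
workflow_config <- function(path = NULL) {
  cfg <- list(
    target = "AD",
    lipid_panel = c("HDL", "LDL"),
    cad_panel = c("CAD"),
    seed = 1,
    m_snps = 20000, n_blocks_sim = 100, n_ldsc_blocks = 100,
    h2 = 0.3, rg_lipids = c(0.0, 0.25), rg_cad = c(0.25),
    n_target = 50000, n_other = 50000,
    n_genes = 2000, frac_assoc = 0.1, frac_shared = 0.5, assoc_z_mean = 4,
    alpha_pair = 0.025, alpha_gene = 0.05, gws_gene = 2.6e-6,
    univ_alpha = 0.05,
    mr_p_thresh = 5e-8, presso_sims = 200, n_boot = 200,
    mr_allow = character(0),
    n_loci = 6, snps_per_locus = 150, local_h2 = 0.002,
    local_rho_planted = 0.8, n_null_sims = 2000
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full cross-trait workflow on synthetic inputs
#'
#' Executes the stages in analysis order: synthetic input generation, global
#' genetic correlation of the target against both panels, gene-level overlap
#' assessment, sentinel and Fisher's-combined-p shared-gene discovery,
#' bi-directional MR on the qualifying traits (those passing the global
#' correlation or gene-overlap gate, plus any explicit `mr_allow` entries),
#' local genetic correlation per trait pair, and global-vs-local concordance
#' classification. Every stage's tables are written to `out_dir` together
#' with a manifest and the resolved configuration; stage failures are
#' recorded in the manifest and dependent stages are skipped with a reason.
#'
#' @param config Configuration list from [workflow_config()] (or a YAML
#'   path).
#' @param out_dir Run directory for report tables; `NULL` skips writing.
#' @return A report bundle: list with `config`, `rg_table`, `overlap_table`,
#'   `shared_genes`, `mr_results`, `local_results`, `local_summaries`,
#'   `concordance`, `manifest`.
#' @export
run_workflow <- function(config = workflow_config(), out_dir = NULL) {
  if (is.character(config)) config <- workflow_config(config)
  cfg <- config
  manifest <- list()
  note <- function(stage, status, detail = "") {
    manifest[[stage]] <<- list(status = status, detail = detail)
    stage_log(stage, status)
  }

  panels <- c(stats::setNames(cfg$rg_lipids, cfg$lipid_panel),
              stats::setNames(cfg$rg_cad, cfg$cad_panel))

  # --- stage 1: synthetic inputs ------------------------------------------
  sims <- list()
  gene_tabs <- list()
  seed_i <- cfg$seed
  for (tr in names(panels)) {
    seed_i <- seed_i + 1
    sims[[tr]] <- simulate_sumstats_pair(
      m_snps = cfg$m_snps, n_blocks = cfg$n_blocks_sim,
      h2_a = cfg$h2, h2_b = cfg$h2, rg_true = panels[[tr]],
      n_a = cfg$n_target, n_b = cfg$n_other, seed = seed_i)
    sims[[tr]]$a$trait_id <- cfg$target
    sims[[tr]]$b$trait_id <- tr
    seed_i <- seed_i + 1
    gt <- simulate_gene_tables(
      n_genes = cfg$n_genes, frac_assoc_a = cfg$frac_assoc,
      frac_assoc_b = cfg$frac_assoc, frac_shared = cfg$frac_shared,
      assoc_z_mean = cfg$assoc_z_mean, seed = seed_i)
    gt$a$trait_id <- cfg$target
    gt$b$trait_id <- tr
    gene_tabs[[tr]] <- gt
  }
  note("simulate", "complete", sprintf("%d trait pairs", length(panels)))

  # --- stage 2: global genetic correlation --------------------------------
  rg_rows <- lapply(names(panels), function(tr) {
    res <- tryCatch(
      estimate_rg(sims[[tr]]$a, sims[[tr]]$b, sims[[tr]]$ld,
                  n_blocks = cfg$n_ldsc_blocks, constrain_intercepts = TRUE),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(trait_a = cfg$target, trait_b = tr, rg = NA_real_,
                 se = NA_real_, p = NA_real_, significant = NA,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(trait_a = cfg$target, trait_b = tr, rg = res$rg, se = res$se,
                 p = res$p, significant = res$p < cfg$alpha_pair,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  rg_table <- do.call(rbind, rg_rows)
  rg_estimates <- lapply(names(panels), function(tr) {
    i <- match(tr, rg_table$trait_b)
    list(trait_a = cfg$target, trait_b = tr, rg = rg_table$rg[i],
         p = rg_table$p[i])
  })
  names(rg_estimates) <- names(panels)
  note("global_rg", "complete", sprintf("%d pairs", nrow(rg_table)))

  # --- stage 3: gene-level overlap ----------------------------------------
  overlap_rows <- lapply(names(panels), function(tr) {
    res <- overlap_assessment(gene_tabs[[tr]]$b, gene_tabs[[tr]]$a,
                              alpha = cfg$alpha_gene)
    data.frame(discovery = tr, target = cfg$target,
               total_discovery = res$total_discovery,
               sig_discovery = res$sig_discovery,
               sig_target = res$sig_target, n_overlap = res$n_overlap,
               expected_pct = 100 * res$expected_prop,
               observed_pct = 100 * res$observed_prop,
               p_binomial = res$p_binomial,
               significant = res$p_defined && res$p_binomial < cfg$alpha_pair,
               stringsAsFactors = FALSE)
  })
  overlap_table <- do.call(rbind, overlap_rows)
  note("gene_overlap", "complete", sprintf("%d pairs", nrow(overlap_table)))

  # --- stage 4: sentinel + FCP shared genes -------------------------------
  shared_rows <- list()
  for (tr in names(panels)) {
    tabs <- list(gene_tabs[[tr]]$a, gene_tabs[[tr]]$b)
    names(tabs) <- c(cfg$target, tr)
    sent <- find_sentinel_shared(tabs, cfg$target, gws = cfg$gws_gene)
    if (nrow(sent) > 0) {
      shared_rows[[paste0(tr, "_sent")]] <- data.frame(
        gene = sent$gene, trait = tr, category = "sentinel_overlap",
        p_fcp = NA_real_, stringsAsFactors = FALSE)
    }
    fcp <- classify_fcp_genes(gene_tabs[[tr]]$a, gene_tabs[[tr]]$b,
                              gws = cfg$gws_gene, alpha = cfg$alpha_gene)
    fcp <- fcp[fcp$category == "fcp_reaching", , drop = FALSE]
    if (nrow(fcp) > 0) {
      shared_rows[[paste0(tr, "_fcp")]] <- data.frame(
        gene = fcp$gene, trait = tr, category = "fcp_reaching",
        p_fcp = fcp$p_fcp, stringsAsFactors = FALSE)
    }
  }
  shared_genes <- if (length(shared_rows) > 0) {
    do.call(rbind, c(shared_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(gene = character(), trait = character(),
               category = character(), p_fcp = numeric(),
               stringsAsFactors = FALSE)
  }
  multi_trait <- cross_trait_gene_summary(shared_genes, min_traits = 2)
  note("shared_genes", "complete",
       sprintf("%d records, %d multi-trait genes",
               nrow(shared_genes), nrow(multi_trait)))

  # --- stage 5: MR on qualifying traits -----------------------------------
  gate <- union(
    union(rg_table$trait_b[which(rg_table$significant)],
          overlap_table$discovery[which(overlap_table$significant)]),
    cfg$mr_allow)
  mr_results <- list()
  for (tr in intersect(names(panels), gate)) {
    mr_results[[tr]] <- tryCatch(
      run_bidirectional(sims[[tr]]$b, sims[[tr]]$a,
                        p_thresh = cfg$mr_p_thresh,
                        n_boot = cfg$n_boot, presso_sims = cfg$presso_sims,
                        seed = cfg$seed),
      error = function(e) e)
  }
  note("mr", "complete", sprintf("%d gated trait(s): %s", length(mr_results),
                                 paste(names(mr_results), collapse = ", ")))

  # --- stage 6: local genetic correlation ---------------------------------
  loci <- data.frame(locus = seq_len(cfg$n_loci),
                     chr = rep_len(c(6L, 8L, 17L, 19L), cfg$n_loci),
                     start = 1e6 + 2e6 * (seq_len(cfg$n_loci) - 1),
                     stop = 2e6 + 2e6 * (seq_len(cfg$n_loci) - 1))
  biv_alpha <- bonferroni_threshold(cfg$n_loci * length(panels))
  local_results <- list()
  local_summaries <- list()
  seed_i <- cfg$seed + 1000
  for (tr in names(panels)) {
    seed_i <- seed_i + 1
    rho_map <- stats::setNames(
      rep(c(cfg$local_rho_planted, 0), length.out = cfg$n_loci),
      loci$locus)
    lb <- simulate_local_blocks(loci, per_locus_rho = rho_map,
                                h2_local = cfg$local_h2,
                                snps_per_locus = cfg$snps_per_locus,
                                n_a = cfg$n_target, n_b = cfg$n_other,
                                seed = seed_i)
    lb$a$trait_id <- cfg$target
    lb$b$trait_id <- tr
    res <- local_rg_scan(lb$a, lb$b, loci, univ_alpha = cfg$univ_alpha,
                         n_null_sims = cfg$n_null_sims, seed = seed_i)
    local_results[[tr]] <- res
    local_summaries[[tr]] <- scan_and_summarise(res, biv_alpha = biv_alpha)
  }
  note("local_rg", "complete",
       sprintf("%d pairs at family threshold %.3g", length(panels), biv_alpha))

  # --- stage 7: concordance -----------------------------------------------
  concordance <- do.call(rbind, lapply(names(panels), function(tr) {
    rec <- classify_concordance(rg_estimates[[tr]], local_summaries[[tr]],
                                alpha_ldsc = cfg$alpha_pair)
    data.frame(trait_a = rec$trait_a, trait_b = rec$trait_b,
               ldsc_sig = rec$ldsc_sig, lava_sig = rec$lava_sig,
               ldsc_sign = rec$ldsc_sign, lava_sign = rec$lava_sign,
               category = rec$category, stringsAsFactors = FALSE)
  }))
  note("concordance", "complete", "")

  bundle <- list(config = cfg, rg_table = rg_table,
                 overlap_table = overlap_table, shared_genes = shared_genes,
                 multi_trait_genes = multi_trait, mr_results = mr_results,
                 local_results = do.call(rbind, local_results),
                 local_summaries = local_summaries,
                 concordance = concordance, manifest = manifest)
  if (!is.null(out_dir)) report_tables(bundle, out_dir)
  bundle
}

mr_result_row <- function(res) {
  fmt <- function(r) {
    if (is.null(r) || !isTRUE(r$run))

      return(data.frame(beta = NA_real_, se = NA_real_, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_))
    ci <- or_ci(r$beta, r$se)
    data.frame(beta = r$beta, se = r$se, or = ci[["or"]],
               ci_low = ci[["lo"]], ci_high = ci[["hi"]], p = r$p)
  }
  ivw <- fmt(res$ivw); wm <- fmt(res$weighted_median); eg <- fmt(res$egger)
  names(ivw) <- paste0("ivw_", names(ivw))
  names(wm) <- paste0("wm_", names(wm))
  names(eg) <- paste0("egger_", names(eg))
  presso <- res$presso
  cbind(
    data.frame(exposure = res$exposure, outcome = res$outcome,
               n_iv = res$n_iv, stringsAsFactors = FALSE),
    ivw, wm, eg,
    data.frame(
      egger_intercept = if (isTRUE(res$egger$run)) res$egger$intercept else NA_real_,
      p_pleiotropy = if (isTRUE(res$egger$run)) res$egger$intercept_p else NA_real_,
      q_stat = if (isTRUE(res$q$run)) res$q$q else NA_real_,
      p_heterogeneity = if (isTRUE(res$q$run)) res$q$p else NA_real_,
      presso_global_p = if (isTRUE(presso$run)) presso$global_p else NA_real_,
      presso_n_outliers = if (isTRUE(presso$run)) length(presso$outliers) else NA_integer_,
      presso_raw_beta = if (isTRUE(presso$run) && !is.null(presso$raw))
        presso$raw$beta else NA_real_,
      presso_corrected_beta = if (isTRUE(presso$run) && !is.null(presso$corrected))
        presso$corrected$beta else NA_real_,
      presso_distortion_p = if (isTRUE(presso$run)) presso$distortion_p else NA_real_))
}

#' Write the report bundle as delimited tables
#'
#' Emits the global-correlation, gene-overlap, shared-gene, MR, local
#' correlation and concordance tables, a per-chromosome count of significant
#' local correlations, a run manifest, and the resolved configuration. All
#' tables are tab-delimited text that re-parses with `read.delim`.
#'
#' @param bundle Result of [run_workflow()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
report_tables <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    wr(bundle$rg_table, "global_rg.tsv"),
    wr(bundle$overlap_table, "gene_overlap.tsv"),
    wr(bundle$shared_genes, "shared_genes.tsv"),
    wr(bundle$multi_trait_genes, "multi_trait_genes.tsv"),
    wr(bundle$local_results, "local_rg.tsv"),
    wr(bundle$concordance, "concordance.tsv"))

  if (length(bundle$mr_results) > 0) {
    mr_rows <- do.call(rbind, unlist(lapply(bundle$mr_results, function(bi) {
      if (inherits(bi, "error")) return(NULL)
      list(mr_result_row(bi$forward), mr_result_row(bi$reverse))
    }), recursive = FALSE))
    files <- c(files, wr(mr_rows, "mr.tsv"))
  }

  chrom_counts <- local_chromosome_counts(bundle$local_summaries)
  files <- c(files, wr(chrom_counts, "local_chromosome_counts.tsv"))

  manifest <- data.frame(
    stage = names(bundle$manifest),
    status = vapply(bundle$manifest, function(x) x$status, character(1)),
    detail = vapply(bundle$manifest, function(x) x$detail, character(1)),
    stringsAsFactors = FALSE)
  files <- c(files, wr(manifest, "manifest.tsv"))
  yaml::write_yaml(bundle$config, file.path(out_dir, "config.yaml"))
  invisible(c(files, file.path(out_dir, "config.yaml")))
}

#' Tally significant local correlations per chromosome and overall
#'
#' @param summaries List of `local_rg_summary` objects (one per trait pair).
#' @return data.frame with columns `chr`, `n_pairings` plus attributes-free
#'   totals in rows; includes `n_significant` total and `n_loci` distinct
#'   significant loci as attributes `total` and `distinct_loci`.
#' @export
local_chromosome_counts <- function(summaries) {
  counts <- list()
  total <- 0L
  loci <- c()
  for (s in summaries) {
    total <- total + s$n_significant
    loci <- c(loci, s$loci)
    for (ch in names(s$per_chromosome_counts)) {
      counts[[ch]] <- (counts[[ch]] %||% 0L) + s$per_chromosome_counts[[ch]]
    }
  }
  out <- if (length(counts) == 0) {
    data.frame(chr = character(0), n_pairings = integer(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chr = names(counts), n_pairings = unlist(counts),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "total") <- total
  attr(out, "distinct_loci") <- length(unique(loci))
  out
}
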
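#' Simulate a pair of GWAS summary-statistics tables under the LD-score model
#'
#' Draws per-SNP z-scores for two traits from a bivariate normal whose moments
#' follow the LD-score regression model: for SNP j with LD score l_j,
#' `E[z_A^2] = n_a h2_a l_j / M + 1`, analogously for trait B, and
#' `E[z_A z_B] = sqrt(n_a n_b) rg h_a h_b l_j / M + n_overlap pheno_corr /
#' sqrt(n_a n_b)` where `h_x = sqrt(h2_x)`. Sample overlap therefore enters
#' only through the cross-trait intercept, matching the model assumption that
#' LD-score regression exploits. Betas are derived as `z * se` with
#' `se = 1 / sqrt(n)`. LD scores are drawn per block as `1 + Gamma(shape 2)`
#' with block-specific mean `block_ld_mean - 1`, reproducing the long-tailed
#' LD-score distribution without real genotypes.
#'
#' @param m_snps Number of SNPs.
#' @param n_blocks Number of LD blocks the SNPs are split into.
#' @param block_ld_mean Mean LD score (must be > 1; the gamma part has mean
#'   `block_ld_mean - 1`).
#' @param h2_a,h2_b Trait heritabilities in `[0, 1]`.
#' @param rg_true Genetic correlation in `[-1, 1]`.
#' @param n_a,n_b GWAS sample sizes.
#' @param n_overlap Number of shared samples (`<= min(n_a, n_b)`).
#' @param pheno_corr Phenotypic correlation among shared samples.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return List with [sumstats] elements `a` and `b` and an `ld` table
#'   (columns `snp`, `chr`, `bp`, `l2`).
#' @export
simulate_sumstats_pair <- function(m_snps = 20000, n_blocks = 100,
                                   block_ld_mean = 4,
                                   h2_a = 0.3, h2_b = 0.3, rg_true = 0,
                                   n_a = 50000, n_b = 50000,
                                   n_overlap = 0, pheno_corr = 0,
                                   seed = 1) {
  stopifnot(h2_a >= 0, h2_a <= 1, h2_b >= 0, h2_b <= 1,
            abs(rg_true) <= 1, n_overlap <= min(n_a, n_b),
            block_ld_mean > 1, m_snps >= n_blocks)
  with_seed(seed, {
    block <- rep(seq_len(n_blocks), length.out = m_snps)
    block <- sort(block)
    block_mean <- stats::rgamma(n_blocks, shape = 2,
                                scale = (block_ld_mean - 1) / 2)
    l2 <- 1 + stats::rgamma(m_snps, shape = 2, scale = block_mean[block] / 2)

    m <- m_snps
    var_a <- n_a * h2_a * l2 / m + 1
    var_b <- n_b * h2_b * l2 / m + 1
    cov_ab <- sqrt(n_a * n_b) * rg_true * sqrt(h2_a * h2_b) * l2 / m +
      n_overlap * pheno_corr / sqrt(n_a * n_b)
    if (any(cov_ab^2 >= var_a * var_b)) {
      stop_format("degenerate per-SNP covariance: configuration implies a non-positive-definite z-score covariance")
    }
    # Cholesky draw: z_a = s_a u, z_b = (cov/s_a) u + sqrt(var_b - cov^2/var_a) v
    u <- stats::rnorm(m)
    v <- stats::rnorm(m)
    s_a <- sqrt(var_a)
    z_a <- s_a * u
    z_b <- (cov_ab / s_a) * u + sqrt(var_b - cov_ab^2 / var_a) * v

    snp <- sprintf("rs%07d", seq_len(m))
    chr <- 1L + (block - 1L) %% 22L
    bp <- integer(m)
    for (ch in unique(chr)) {
      idx <- which(chr == ch)
      bp[idx] <- seq(1e5, by = 1e4, length.out = length(idx))
    }
    frq <- stats::runif(m, 0.05, 0.95)
    mk <- function(z, n, id) {
      se <- rep(1 / sqrt(n), m)
      sumstats(id, data.frame(
        snp = snp, chr = chr, bp = bp,
        a1 = rep("A", m), a2 = rep("G", m),
        beta = z * se, se = se,
        p = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
        n = rep(n, m), z = z, frq = frq,
        stringsAsFactors = FALSE))
    }
    ld <- data.frame(snp = snp, chr = chr, bp = bp, l2 = l2,
                     stringsAsFactors = FALSE)
    class(ld) <- c("ldscore_table", "data.frame")
    list(a = mk(z_a, n_a, "trait_a"), b = mk(z_b, n_b, "trait_b"), ld = ld)
  })
}

#' Simulate a pair of gene-level association tables
#'
#' Associated genes receive `z ~ Normal(assoc_z_mean, 1)`, null genes
#' `z ~ Normal(0, 1)`; p-values are one-sided upper-tail normal. A fraction
#' `frac_shared` of trait A's associated genes is also associated in trait B
#' (counts rounded); B's remaining associated genes are drawn from the
#' non-shared pool.
#'
#' @param n_genes Number of genes in each table.
#' @param frac_assoc_a,frac_assoc_b Fractions of genes associated per trait.
#' @param frac_shared Fraction of A's associated genes also associated in B.
#' @param assoc_z_mean Mean z-statistic for associated genes.
#' @param seed Integer seed.
#' @return List with [gene_table] elements `a`, `b` and logical ground-truth
#'   vectors `truth_a`, `truth_b`.
#' @export
simulate_gene_tables <- function(n_genes = 18960, frac_assoc_a = 0.1,
                                 frac_assoc_b = 0.1, frac_shared = 0.5,
                                 assoc_z_mean = 4, seed = 1) {
  stopifnot(frac_assoc_a >= 0, frac_assoc_a <= 1,
            frac_assoc_b >= 0, frac_assoc_b <= 1)
  if (frac_shared < 0 || frac_shared > 1) {
    stop_format("frac_shared must lie in [0, 1]")
  }
  with_seed(seed, {
    n_a <- round(frac_assoc_a * n_genes)
    n_b <- round(frac_assoc_b * n_genes)
    n_sh <- min(round(frac_shared * n_a), n_b)
    assoc_a <- seq_len(n_a)
    shared <- if (n_sh > 0) sample(assoc_a, n_sh) else integer(0)
    pool_b <- setdiff(seq_len(n_genes), assoc_a)
    extra_b <- if (n_b - n_sh > 0) sample(pool_b, n_b - n_sh) else integer(0)
    assoc_b <- c(shared, extra_b)

    truth_a <- seq_len(n_genes) %in% assoc_a
    truth_b <- seq_len(n_genes) %in% assoc_b
    z_a <- stats::rnorm(n_genes, mean = ifelse(truth_a, assoc_z_mean, 0))
    z_b <- stats::rnorm(n_genes, mean = ifelse(truth_b, assoc_z_mean, 0))

    genes <- sprintf("GENE%05d", seq_len(n_genes))
    chr <- 1L + (seq_len(n_genes) - 1L) %% 22L
    start <- 1e5 + 1e5 * (seq_len(n_genes) - 1L)
    mk <- function(z, id) {
      gene_table(id, data.frame(
        gene = genes, chr = chr, start = start, stop = start + 5e4,
        n_snps = 10L, z = z,
        p = pmax(stats::pnorm(z, lower.tail = FALSE), 1e-300),
        stringsAsFactors = FALSE))
    }
    list(a = mk(z_a, "trait_a"), b = mk(z_b, "trait_b"),
         truth_a = truth_a, truth_b = truth_b)
  })
}

#' Simulate a harmonised instrument table for two-sample MR
#'
#' Each instrument's exposure effect is drawn uniformly from
#' `iv_strength_range` and observed with error `se_exp`; the outcome effect is
#' `beta_causal * beta_exp_true + pleiotropy + noise`. Pleiotropy is drawn
#' independently of instrument strength (InSIDE-respecting) as
#' `Normal(pleio_mean, pleio_sd)`; a `frac_outliers` fraction of instruments
#' instead receives inflated pleiotropy `Normal(0, outlier_pleio_sd)`. Set
#' `correlated_pleiotropy = TRUE` to make pleiotropy proportional to
#' instrument strength for stress tests.
#'
#' @param n_iv Number of instruments.
#' @param beta_causal True causal effect of exposure on outcome.
#' @param iv_strength_range Range of true exposure effects.
#' @param se_exp,se_out Standard errors of the exposure/outcome effects.
#' @param pleio_mean,pleio_sd Directional/balanced pleiotropy parameters.
#' @param frac_outliers Fraction of instruments given inflated pleiotropy.
#' @param outlier_pleio_sd SD of the outlier pleiotropy term.
#' @param correlated_pleiotropy Violate the InSIDE assumption if `TRUE`.
#' @param seed Integer seed.
#' @return data.frame with columns `snp`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, and logical `is_outlier` ground truth; class `instrument_set`
#'   with attributes `exposure`, `outcome`.
#' @export
simulate_mr_dataset <- function(n_iv = 50, beta_causal = 0,
                                iv_strength_range = c(0.05, 0.15),
                                se_exp = 0.01, se_out = 0.02,
                                pleio_mean = 0, pleio_sd = 0,
                                frac_outliers = 0, outlier_pleio_sd = 0.2,
                                correlated_pleiotropy = FALSE, seed = 1) {
  if (n_iv < 1) stop_format("n_iv must be >= 1")
  with_seed(seed, {
    bx_true <- stats::runif(n_iv, iv_strength_range[1], iv_strength_range[2])
    is_outlier <- stats::runif(n_iv) < frac_outliers
    pleio <- stats::rnorm(n_iv, pleio_mean, pleio_sd)
    if (correlated_pleiotropy) pleio <- pleio * bx_true / mean(bx_true)
    pleio[is_outlier] <- stats::rnorm(sum(is_outlier), 0, outlier_pleio_sd)
    bx <- bx_true + stats::rnorm(n_iv, 0, se_exp)
    by <- beta_causal * bx_true + pleio + stats::rnorm(n_iv, 0, se_out)
    out <- data.frame(snp = sprintf("iv%03d", seq_len(n_iv)),
                      beta_exp = bx, se_exp = se_exp,
                      beta_out = by, se_out = se_out,
                      is_outlier = is_outlier, stringsAsFactors = FALSE)
    instrument_set(out, exposure = "exposure", outcome = "outcome")
  })
}

#' Simulate locus-partitioned summary statistics with known local correlation
#'
#' Within each locus, per-SNP true effects for the two traits are drawn
#' jointly normal with per-SNP variance `h2_local / K` (K SNPs in the locus)
#' and correlation `per_locus_rho`; observed effects add sampling noise
#' `Normal(0, 1/n)`. LD is the identity (independent SNPs) in this bundled
#' setting.
#'
#' @param loci Locus-definition table (columns `locus`, `chr`, `start`,
#'   `stop`).
#' @param per_locus_rho Named numeric vector (names = locus ids) or single
#'   value: local genetic correlation per locus.
#' @param h2_local Named vector or single value: local heritability per locus
#'   (both traits).
#' @param snps_per_locus Number of SNPs placed in each locus.
#' @param n_a,n_b Sample sizes.
#' @param seed Integer seed.
#' @return List with [sumstats] `a`, `b` and an LD-score table (`l2 = 1`).
#' @export
simulate_local_blocks <- function(loci, per_locus_rho = 0, h2_local = 0.001,
                                  snps_per_locus = 200,
                                  n_a = 50000, n_b = 50000, seed = 1) {
  loci <- validate_loci(as.data.frame(loci))
  get_par <- function(par, id) {
    if (length(par) == 1 && is.null(names(par))) return(par)
    if (!as.character(id) %in% names(par)) {
      stop_format("no value supplied for locus %s", id)
    }
    unname(par[as.character(id)])
  }
  with_seed(seed, {
    rows_a <- list(); rows_b <- list()
    for (i in seq_len(nrow(loci))) {
      id <- loci$locus[i]
      rho <- get_par(per_locus_rho, id)
      if (abs(rho) > 1) stop_format("|rho| must be <= 1 (locus %s)", id)
      h2 <- get_par(h2_local, id)
      k <- snps_per_locus
      sd_g <- sqrt(h2 / k)
      u <- stats::rnorm(k); v <- stats::rnorm(k)
      g_a <- sd_g * u
      g_b <- sd_g * (rho * u + sqrt(1 - rho^2) * v)
      bhat_a <- g_a + stats::rnorm(k, 0, 1 / sqrt(n_a))
      bhat_b <- g_b + stats::rnorm(k, 0, 1 / sqrt(n_b))
      bp <- round(seq(loci$start[i], loci$stop[i], length.out = k))
      snp <- sprintf("rs%d_%03d", id, seq_len(k))
      rows_a[[i]] <- data.frame(
        snp = snp, chr = loci$chr[i], bp = bp, a1 = "A", a2 = "G",
        beta = bhat_a, se = 1 / sqrt(n_a),
        p = pmax(2 * stats::pnorm(-abs(bhat_a) * sqrt(n_a)), 1e-300),
        n = n_a, z = bhat_a * sqrt(n_a), stringsAsFactors = FALSE)
      rows_b[[i]] <- data.frame(
        snp = snp, chr = loci$chr[i], bp = bp, a1 = "A", a2 = "G",
        beta = bhat_b, se = 1 / sqrt(n_b),
        p = pmax(2 * stats::pnorm(-abs(bhat_b) * sqrt(n_b)), 1e-300),
        n = n_b, z = bhat_b * sqrt(n_b), stringsAsFactors = FALSE)
    }
    da <- do.call(rbind, rows_a)
    db <- do.call(rbind, rows_b)
    ld <- data.frame(snp = da$snp, chr = da$chr, bp = da$bp, l2 = 1)
    class(ld) <- c("ldscore_table", "data.frame")
    list(a = sumstats("trait_a", da), b = sumstats("trait_b", db), ld = ld)
  })
}
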
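# Small in-code fixtures shared across test files.

# quick sumstats builder with sensible defaults
make_ss <- function(snp, beta, se = 0.01, p = NULL, chr = 1L, bp = NULL,
                    a1 = "A", a2 = "G", n = 10000, trait = "toy", frq = NULL) {
  m <- length(snp)
  z <- beta / se
  d <- data.frame(
    snp = snp, chr = rep_len(chr, m),
    bp = bp %||% seq(1e5, by = 1e5, length.out = m),
    a1 = rep_len(a1, m), a2 = rep_len(a2, m),
    beta = beta, se = rep_len(se, m),
    p = p %||% pmax(2 * pnorm(-abs(z)), 1e-300),
    n = rep_len(n, m), z = z, stringsAsFactors = FALSE)
  if (!is.null(frq)) d$frq <- rep_len(frq, m)
  sumstats(trait, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gene table with prescribed significance structure: `small_p` genes get
# p = p_sig, the rest p = p_null
make_gene_table <- function(trait, n_genes, sig_idx, p_sig = 1e-3,
                            p_null = 0.5) {
  p <- rep(p_null, n_genes)
  p[sig_idx] <- p_sig
  gene_table(trait, data.frame(
    gene = sprintf("G%05d", seq_len(n_genes)),
    chr = 1L, start = seq_len(n_genes) * 1e5,
    stop = seq_len(n_genes) * 1e5 + 5e4,
    n_snps = 10L, z = qnorm(p, lower.tail = FALSE), p = p,
    stringsAsFactors = FALSE))
}

# instrument set with explicit effect pairs
make_ivs <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.02) {
  instrument_set(data.frame(
    snp = sprintf("iv%02d", seq_along(beta_exp)),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out, stringsAsFactors = FALSE))
}

example_local_rg_path <- function() {
  system.file("extdata", "local_rg_example.tsv", package = "crosstrait")
}
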
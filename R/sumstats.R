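#' GWAS summary-statistics container
#'
#' Validated per-variant association records for one trait. The record table
#' holds one row per SNP with the effect allele (`a1`), other allele (`a2`),
#' signed effect `beta` on the trait's reported scale, its standard error,
#' the association p-value, and the per-SNP sample size. A signed z-score and
#' the effect-allele frequency are optional but used where present (z for the
#' LD-score regressions, frq for palindromic-variant handling).
#'
#' @param trait_id Single character label for the trait.
#' @param data data.frame with columns `snp`, `chr`, `bp`, `a1`, `a2`,
#'   `beta`, `se`, `p`, `n` and optionally `z`, `frq`.
#' @param n_cases,n_controls Optional case/control counts for binary traits.
#'
#' @return An object of class `sumstats`: a list with elements `trait_id`,
#'   `data`, `n_cases`, `n_controls`.
#' @export
sumstats <- function(trait_id, data, n_cases = NULL, n_controls = NULL) {
  required <- c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_format("summary statistics missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (anyDuplicated(data$snp)) {
    stop_format("duplicate snp id: %s", data$snp[duplicated(data$snp)][1])
  }
  if (any(data$se <= 0)) stop_format("se must be > 0 for every record")
  if (any(data$p <= 0 | data$p > 1)) stop_format("p must lie in (0, 1]")
  if (any(data$a1 == data$a2)) stop_format("a1 and a2 must differ")
  bases <- c("A", "C", "G", "T")
  if (!all(data$a1 %in% bases) || !all(data$a2 %in% bases)) {
    stop_format("alleles must be single bases A/C/G/T")
  }
  if (!is.null(data$z)) {
    nz <- data$z != 0 & data$beta != 0
    if (any(sign(data$z[nz]) != sign(data$beta[nz]))) {
      stop_format("sign(z) must equal sign(beta)")
    }
  } else {
    data$z <- data$beta / data$se
  }
  rownames(data) <- NULL
  structure(
    list(trait_id = trait_id, data = data,
         n_cases = n_cases, n_controls = n_controls),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s': %d SNPs, chr %s\n",
              x$trait_id, nrow(x$data),
              paste(range(x$data$chr), collapse = "-")))
  invisible(x)
}

#' Effective sample size for a binary trait
#'
#' Returns total N by default; set `effective = TRUE` for the
#' 4 / (1/cases + 1/controls) convention.
#'
#' @param ss A [sumstats] object with `n_cases`/`n_controls` set.
#' @param effective Use the effective-N conversion instead of total N.
#' @return A single number.
#' @export
binary_trait_n <- function(ss, effective = FALSE) {
  if (is.null(ss$n_cases) || is.null(ss$n_controls)) {
    return(max(ss$data$n))
  }
  if (effective) 4 / (1 / ss$n_cases + 1 / ss$n_controls)
  else ss$n_cases + ss$n_controls
}

#' Read GWAS summary statistics from delimited text
#'
#' Expects a whitespace- or tab-delimited file with header
#' `SNP CHR BP A1 A2 BETA SE P N` (optionally `Z`, `FRQ`). `column_map`
#' renames nonstandard headers, e.g. `c(BETA = "OR")` accepts an odds-ratio
#' column that is log-transformed on read. Underflowed p-values of exactly 0
#' are clamped to `clamp_floor` with a warning; rows with missing alleles or
#' missing/non-positive SE are dropped with a reported count.
#'
#' @param path File path.
#' @param trait_id Trait label; defaults to the file name.
#' @param column_map Named character vector mapping standard names to the
#'   names used in the file.
#' @param clamp_floor Smallest representable p-value.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, trait_id = NULL, column_map = NULL,
                          clamp_floor = 1e-300) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  std <- c(SNP = "snp", CHR = "chr", BP = "bp", A1 = "a1", A2 = "a2",
           BETA = "beta", SE = "se", P = "p", N = "n", Z = "z", FRQ = "frq")
  used <- stats::setNames(names(std), names(std))
  if (!is.null(column_map)) used[names(column_map)] <- column_map
  or_scale <- identical(unname(used["BETA"]), "OR")

  out <- list()
  for (key in names(std)) {
    col <- used[[key]]
    if (col %in% names(raw)) {
      out[[std[[key]]]] <- raw[[col]]
    } else if (!key %in% c("Z", "FRQ")) {
      stop_format("missing mandatory column: %s (looked for '%s')",
                  tolower(std[[key]]), col)
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (or_scale) out$beta <- log(out$beta)

  keep <- !is.na(out$a1) & !is.na(out$a2) & out$a1 != "" & out$a2 != "" &
    !is.na(out$se) & out$se > 0
  if (any(!keep)) {
    message(sprintf("read_sumstats: dropped %d row(s) with missing alleles or se",
                    sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  if (any(out$p == 0)) {
    warning(sprintf("read_sumstats: %d p-value(s) of 0 clamped to %g",
                    sum(out$p == 0), clamp_floor), call. = FALSE)
    out$p[out$p == 0] <- clamp_floor
  }
  out$a1 <- toupper(out$a1)
  out$a2 <- toupper(out$a2)
  sumstats(trait_id %||% basename(path), out)
}

#' Write summary statistics in the package's tab-delimited exchange format
#'
#' @param ss A [sumstats] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  d <- ss$data
  out <- data.frame(SNP = d$snp, CHR = d$chr, BP = d$bp, A1 = d$a1, A2 = d$a2,
                    BETA = d$beta, SE = d$se, P = d$p, N = d$n, Z = d$z)
  if (!is.null(d$frq)) out$FRQ <- d$frq
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) STRAND_COMPLEMENT[a1] == a2

#' Harmonise allele coding of two summary-statistics tables
#'
#' For SNPs shared between `a` and `b`, aligns `b`'s effect allele to `a`'s:
#' swapped alleles sign-flip `b`'s beta and z; strand-complemented alleles are
#' complemented then matched. Palindromic variants (A/T or C/G) are dropped
#' when either trait's effect-allele frequency lies within
#' `palindrome_frq_window` of 0.5 or is absent, since strand cannot be
#' resolved. Unmatchable allele pairs are dropped. Non-shared SNPs pass
#' through untouched.
#'
#' @param a,b [sumstats] objects.
#' @param palindrome_frq_window Half-width of the ambiguity window around 0.5.
#' @return A list with elements `a`, `b` (harmonised) and `report`, a list of
#'   counts (`n_shared`, `flips`, `complements`, `drops`).
#' @export
harmonise <- function(a, b, palindrome_frq_window = 0.08) {
  da <- a$data
  db <- b$data
  shared <- intersect(da$snp, db$snp)
  ia <- match(shared, da$snp)
  ib <- match(shared, db$snp)

  a1a <- da$a1[ia]; a2a <- da$a2[ia]
  a1b <- db$a1[ib]; a2b <- db$a2[ib]

  pal <- is_palindromic(a1a, a2a)
  frq_a <- if (!is.null(da$frq)) da$frq[ia] else rep(NA_real_, length(ia))
  frq_b <- if (!is.null(db$frq)) db$frq[ib] else rep(NA_real_, length(ib))
  ambiguous <- function(f) is.na(f) | abs(f - 0.5) <= palindrome_frq_window
  drop_pal <- pal & (ambiguous(frq_a) | ambiguous(frq_b))

  same <- a1b == a1a & a2b == a2a
  swapped <- a1b == a2a & a2b == a1a
  comp_same <- STRAND_COMPLEMENT[a1b] == a1a & STRAND_COMPLEMENT[a2b] == a2a
  comp_swap <- STRAND_COMPLEMENT[a1b] == a2a & STRAND_COMPLEMENT[a2b] == a1a

  flip <- (swapped | comp_swap) & !same
  complemented <- (comp_same | comp_swap) & !(same | swapped)
  matched <- same | swapped | comp_same | comp_swap
  drop <- drop_pal | !matched

  keep <- !drop
  db$a1[ib[keep]] <- a1a[keep]
  db$a2[ib[keep]] <- a2a[keep]
  fl <- keep & flip
  db$beta[ib[fl]] <- -db$beta[ib[fl]]
  db$z[ib[fl]] <- -db$z[ib[fl]]
  if (!is.null(db$frq)) db$frq[ib[fl]] <- 1 - db$frq[ib[fl]]

  drop_ids <- shared[drop]
  da <- da[!da$snp %in% drop_ids, , drop = FALSE]
  db <- db[!db$snp %in% drop_ids, , drop = FALSE]

  report <- list(n_shared = length(shared),
                 flips = sum(fl),
                 complements = sum(keep & complemented),
                 drops = sum(drop))
  list(a = sumstats(a$trait_id, da, a$n_cases, a$n_controls),
       b = sumstats(b$trait_id, db, b$n_cases, b$n_controls),
       report = report)
}

#' Restrict two tables to their shared SNPs
#'
#' Both outputs contain exactly the intersection of SNP ids, in the same
#' order (the order of appearance in `a`).
#'
#' @param a,b [sumstats] objects.
#' @return List with `a`, `b` restricted and `n_shared`.
#' @export
restrict_shared <- function(a, b) {
  shared <- intersect(a$data$snp, b$data$snp)
  if (length(shared) == 0) stop_format("no shared SNPs between '%s' and '%s'",
                                       a$trait_id, b$trait_id)
  da <- a$data[match(shared, a$data$snp), , drop = FALSE]
  db <- b$data[match(shared, b$data$snp), , drop = FALSE]
  list(a = sumstats(a$trait_id, da, a$n_cases, a$n_controls),
       b = sumstats(b$trait_id, db, b$n_cases, b$n_controls),
       n_shared = length(shared))
}

#' Read a per-SNP LD-score table
#'
#' Tab- or whitespace-delimited with header `CHR SNP BP L2`. Small negative
#' LD scores are permitted (estimated LD scores can dip below zero).
#'
#' @param path File path.
#' @return An `ldscore_table`: data.frame with columns `snp`, `chr`, `bp`,
#'   `l2`.
#' @export
read_ldscores <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  for (col in c("CHR", "SNP", "BP", "L2")) {
    if (!col %in% names(raw)) stop_format("missing mandatory column: %s", col)
  }
  if (!is.numeric(raw$L2) || any(!is.finite(raw$L2))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(raw$L2))))[1]
    stop_format("malformed LD score at line %d", bad + 1L)
  }
  if (anyDuplicated(raw$SNP)) {
    stop_format("duplicate snp id in LD scores: %s",
                raw$SNP[duplicated(raw$SNP)][1])
  }
  out <- data.frame(snp = raw$SNP, chr = raw$CHR, bp = raw$BP, l2 = raw$L2,
                    stringsAsFactors = FALSE)
  class(out) <- c("ldscore_table", "data.frame")
  out
}

#' @rdname read_ldscores
#' @param ld data.frame with columns `snp`, `chr`, `bp`, `l2`.
#' @export
write_ldscores <- function(ld, path) {
  utils::write.table(
    data.frame(CHR = ld$chr, SNP = ld$snp, BP = ld$bp, L2 = ld$l2),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus-definition file
#'
#' Header `LOC CHR START STOP`; coordinates are 1-based inclusive. Loci must
#' not overlap within a chromosome.
#'
#' @param path File path.
#' @return data.frame with columns `locus`, `chr`, `start`, `stop`, class
#'   `locus_table`.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  for (col in c("LOC", "CHR", "START", "STOP")) {
    if (!col %in% names(raw)) stop_format("missing mandatory column: %s", col)
  }
  out <- data.frame(locus = raw$LOC, chr = raw$CHR,
                    start = raw$START, stop = raw$STOP)
  validate_loci(out)
}

#' Validate a locus-definition table
#' @param loci data.frame with columns `locus`, `chr`, `start`, `stop`.
#' @return The validated table with class `locus_table`.
#' @export
validate_loci <- function(loci) {
  if (any(loci$start > loci$stop)) stop_format("locus with start > stop")
  for (ch in unique(loci$chr)) {
    sub <- loci[loci$chr == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$stop[-nrow(sub)])) {
      stop_format("overlapping loci on chromosome %s", ch)
    }
  }
  class(loci) <- unique(c("locus_table", class(loci)))
  loci
}

#' Gene-level association table
#'
#' One row per gene with the gene z-statistic and p-value from a gene-based
#' association analysis (MAGMA-style `.genes.out` layout on disk).
#'
#' @param trait_id Trait label.
#' @param data data.frame with columns `gene`, `chr`, `start`, `stop`,
#'   `n_snps`, `z`, `p`.
#' @return A `gene_table` object.
#' @export
gene_table <- function(trait_id, data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$gene <- toupper(data$gene)
  if (anyDuplicated(data$gene)) {
    stop_format("duplicate gene: %s", data$gene[duplicated(data$gene)][1])
  }
  if (any(data$p <= 0 | data$p > 1)) stop_format("gene p must lie in (0, 1]")
  rownames(data) <- NULL
  structure(list(trait_id = trait_id, data = data), class = "gene_table")
}

#' Read a gene-based association table
#'
#' Header `GENE CHR START STOP NSNPS N ZSTAT P`.
#'
#' @param path File path.
#' @param trait_id Trait label; defaults to the file name.
#' @return A [gene_table] object.
#' @export
read_gene_table <- function(path, trait_id = NULL) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  for (col in c("GENE", "CHR", "START", "STOP", "NSNPS", "ZSTAT", "P")) {
    if (!col %in% names(raw)) stop_format("missing mandatory column: %s", col)
  }
  gene_table(trait_id %||% basename(path),
             data.frame(gene = raw$GENE, chr = raw$CHR, start = raw$START,
                        stop = raw$STOP, n_snps = raw$NSNPS, z = raw$ZSTAT,
                        p = raw$P, stringsAsFactors = FALSE))
}

#' @rdname read_gene_table
#' @param gt A [gene_table] object.
#' @export
write_gene_table <- function(gt, path) {
  d <- gt$data
  utils::write.table(
    data.frame(GENE = d$gene, CHR = d$chr, START = d$start, STOP = d$stop,
               NSNPS = d$n_snps, N = d$n_snps, ZSTAT = d$z, P = d$p),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
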
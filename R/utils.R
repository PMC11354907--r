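#' @keywords internal
"_PACKAGE"

# round-half-away-from-zero to `digits` decimals; base round() is banker's
round_half_away <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# clamp p-values away from 0 so log-space combination stays finite
clamp_p <- function(p, floor = 1e-300) {
  n_clamped <- sum(p < floor, na.rm = TRUE)
  if (n_clamped > 0) {
    warning(sprintf("%d p-value(s) below %g clamped to the floor", n_clamped, floor),
            call. = FALSE)
  }
  pmax(p, floor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# fixed-seed evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
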
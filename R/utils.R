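# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base \code{round} uses banker's rounding; report-time percentages follow the
#' conventional half-up rule instead (57.275 -> 57.28).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-stage seed derived from a root seed and a stage label, so
# adding a stage never perturbs the draws of earlier stages. Kept below 2^31.
stage_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  s <- (h * 69069 + as.numeric(seed)) %% 2147483647
  as.integer(s) + 1L
}

# Run an expression with a local RNG state (seed may be NULL = use current).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Truncated-normal draws by rejection (bounds generous for % methylation use).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
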
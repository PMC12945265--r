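#' @keywords internal
"_PACKAGE"

# Deterministic RNG helpers. Every sampler in the package takes an explicit
# seed; nothing consumes or mutates the caller's global RNG stream.

#' Evaluate an expression under a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()] that tolerates `NULL` (no seeding,
#' uses the current stream) so internal code can thread optional seeds.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed spawns named sub-streams (model fitting, Monte Carlo,
#' bootstrap, ...) so individual pipeline stages can be replayed in
#' isolation. Uses a Lehmer-style multiplicative step on the Mersenne-prime
#' modulus 2^31 - 1, keeping every derived seed a valid 32-bit R integer.
#'
#' @param seed Master seed (positive integer).
#' @param index Sub-stream index (non-negative integer), or a character
#'   stream name hashed to an index.
#' @return A positive integer seed < 2^31.
#' @export
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, "mc")
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  if (is.character(index)) {
    index <- sum(utf8ToInt(index) * seq_along(utf8ToInt(index)))
  }
  m <- 2147483647
  x <- (as.double(seed) %% m) + 1
  # fixed number of Lehmer steps keyed by the index
  a <- 48271
  x <- (x * a + as.double(index) * 69621) %% m
  x <- (x * a) %% m
  as.integer(x + 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent validation error class
#' @keywords internal
abort_invalid <- function(...) {
  stop(structure(
    class = c("phthalrisk_invalid", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Percentile summary used throughout the package
#'
#' Mean plus the P50/P75/P95/P99.9 quantiles of a draw vector, the summary
#' points at which exposure and risk are reported.
#'
#' @param x Numeric vector of draws.
#' @return Named numeric vector `mean`, `p50`, `p75`, `p95`, `p999`.
#' @export
percentile_summary <- function(x) {
  stopifnot(is.numeric(x), length(x) > 0)
  q <- stats::quantile(x, c(0.5, 0.75, 0.95, 0.999), names = FALSE, type = 7)
  c(mean = mean(x), p50 = q[1], p75 = q[2], p95 = q[3], p999 = q[4])
}
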
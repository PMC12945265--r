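# Generalized Pareto distribution with shape xi, scale sigma, location u.
# The |xi| < 1e-8 branch switches to the exponential-limit formulas to avoid
# catastrophic cancellation in (1 + xi z)^(-1/xi) near xi = 0.

XI_EPS <- 1e-8

check_gpd_params <- function(shape, scale, loc) {
  if (!is.numeric(shape) || !is.numeric(scale) || !is.numeric(loc) ||
      anyNA(c(shape, scale, loc))) {
    abort_invalid("gpd parameters must be finite numerics")
  }
  if (scale <= 0) abort_invalid("gpd scale must be > 0, got ", scale)
  invisible(TRUE)
}

#' Generalized Pareto density
#'
#' @param x Quantiles.
#' @param shape GPD shape \eqn{\xi}; negative values give a bounded upper
#'   support at `loc - scale/shape`.
#' @param scale GPD scale \eqn{\sigma > 0}.
#' @param loc Threshold / location \eqn{u} (support is `x >= loc`).
#' @param log Return log-density?
#' @return Density values; 0 (or `-Inf`) outside the support.
#' @export
dgpd <- function(x, shape, scale = 1, loc = 0, log = FALSE) {
  check_gpd_params(shape, scale, loc)
  z <- (x - loc) / scale
  if (abs(shape) < XI_EPS) {
    ld <- -z - log(scale)
    ld[z < 0] <- -Inf
  } else {
    arg <- 1 + shape * z
    ld <- ifelse(z >= 0 & arg > 0,
                 -(1 / shape + 1) * log(pmax(arg, .Machine$double.xmin)) - log(scale),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' Generalized Pareto CDF
#'
#' For `shape < 0` the support is bounded; the CDF is 1 beyond
#' `loc - scale/shape`.
#'
#' @inheritParams dgpd
#' @param q Quantiles.
#' @return Probabilities in `[0, 1]`.
#' @export
pgpd <- function(q, shape, scale = 1, loc = 0) {
  check_gpd_params(shape, scale, loc)
  z <- (q - loc) / scale
  if (abs(shape) < XI_EPS) {
    p <- 1 - exp(-pmax(z, 0))
  } else {
    arg <- 1 + shape * pmax(z, 0)
    p <- ifelse(arg > 0, 1 - arg^(-1 / shape), 1)
    p[z <= 0] <- 0
  }
  pmin(pmax(p, 0), 1)
}

#' Generalized Pareto quantile function
#'
#' @inheritParams dgpd
#' @param p Probabilities in (0, 1); endpoints map to the support bounds.
#' @export
qgpd <- function(p, shape, scale = 1, loc = 0) {
  check_gpd_params(shape, scale, loc)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_invalid("p must be in [0, 1]")
  if (abs(shape) < XI_EPS) {
    loc - scale * log1p(-p)
  } else {
    loc + scale / shape * ((1 - p)^(-shape) - 1)
  }
}

#' Generalized Pareto sampler
#'
#' @inheritParams dgpd
#' @param n Number of draws.
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @export
rgpd <- function(n, shape, scale = 1, loc = 0, seed = NULL) {
  with_seed_opt(seed, qgpd(stats::runif(n), shape, scale, loc))
}

# Closed-form MLE does not exist; exceedance fit used by the EVMM.
# Start per package convention: xi = 0.1, sigma = sd of exceedances.
fit_gpd_exceedances <- function(exc, loc = 0) {
  exc <- exc - loc
  if (length(exc) < 2) abort_invalid("need >= 2 exceedances for a GPD fit")
  nll <- function(par) {
    sig <- exp(par[2])
    -sum(dgpd(exc, shape = par[1], scale = sig, loc = 0, log = TRUE))
  }
  s0 <- stats::sd(exc)
  if (!is.finite(s0) || s0 <= 0) s0 <- mean(exc)
  opt <- stats::optim(c(0.1, log(s0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 500))
  list(shape = opt$par[1], scale = exp(opt$par[2]),
       loglik = -opt$value, converged = opt$convergence == 0L)
}
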
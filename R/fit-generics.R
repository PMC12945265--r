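# A small generic surface shared by the three fit classes (single
# parametric family, EVMM, finite mixture), so goodness-of-fit testing,
# Stage-3 scoring, exposure simulation and the bootstrap can treat any
# fitted concentration model uniformly.

#' CDF of a fitted concentration model
#' @param fit A `fit_result`, `evmm_fit` or `mixture_fit`.
#' @param q Quantiles.
#' @export
fit_cdf <- function(fit, q) UseMethod("fit_cdf")
#' @export
fit_cdf.fit_result <- function(fit, q) dist_cdf(fit$spec, q)
#' @export
fit_cdf.evmm_fit <- function(fit, q) evmm_cdf(fit$spec, q)
#' @export
fit_cdf.mixture_fit <- function(fit, q) mixture_cdf(fit$spec, q)

#' Quantile function of a fitted concentration model
#' @inheritParams fit_cdf
#' @param p Probabilities strictly inside (0, 1).
#' @export
fit_quantile <- function(fit, p) UseMethod("fit_quantile")
#' @export
fit_quantile.fit_result <- function(fit, p) dist_quantile(fit$spec, p)
#' @export
fit_quantile.evmm_fit <- function(fit, p) evmm_quantile(fit$spec, p)
#' @export
fit_quantile.mixture_fit <- function(fit, p) mixture_quantile(fit$spec, p)

#' Sample from a fitted concentration model
#' @inheritParams fit_cdf
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @export
fit_sample <- function(fit, n, seed = NULL) UseMethod("fit_sample")
#' @export
fit_sample.fit_result <- function(fit, n, seed = NULL) dist_sample(fit$spec, n, seed)
#' @export
fit_sample.evmm_fit <- function(fit, n, seed = NULL) evmm_sample(fit$spec, n, seed)
#' @export
fit_sample.mixture_fit <- function(fit, n, seed = NULL) mixture_sample(fit$spec, n, seed)

#' Refit the same model family to new data
#'
#' Used inside parametric-bootstrap goodness-of-fit tests and the
#' data-level bootstrap: the model FAMILY (and fitting settings, possibly
#' overridden by `...`) is reused, parameters are re-estimated.
#'
#' @inheritParams fit_cdf
#' @param data New strictly positive data vector.
#' @param ... Overrides passed to the underlying fitter (e.g. a coarser
#'   `threshold_grid` for EVMM refits inside a bootstrap loop).
#' @export
fit_refit <- function(fit, data, ...) UseMethod("fit_refit")
#' @export
fit_refit.fit_result <- function(fit, data, ...) fit_mle(data, fit$spec$family)
#' @export
fit_refit.evmm_fit <- function(fit, data, ...) {
  args <- list(data = data, bulk_family = fit$spec$bulk$family,
               tail_fraction = fit$spec$tail_fraction)
  do.call(evmm_fit, utils::modifyList(args, list(...)))
}
#' @export
fit_refit.mixture_fit <- function(fit, data, ...) {
  args <- list(data = data, family = fit$spec$family, g = fit$spec$g)
  do.call(mixture_fit_em, utils::modifyList(args, list(...)))
}

#' Human-readable label of a fitted model ("lognormal", "lognormal-gpd",
#' "2-gamma", ...)
#' @inheritParams fit_cdf
#' @export
fit_label <- function(fit) UseMethod("fit_label")
#' @export
fit_label.fit_result <- function(fit) fit$spec$family
#' @export
fit_label.evmm_fit <- function(fit) paste0(fit$spec$bulk$family, "-gpd")
#' @export
fit_label.mixture_fit <- function(fit) paste0(fit$spec$g, "-", fit$spec$family)
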
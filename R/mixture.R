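# Two-component finite mixtures f(x) = sum_i pi_i f_i(x | theta_i) of
# lognormal, weibull or gamma components, fitted by EM with weighted
# M-steps (closed form for lognormal; 1-D root-finding for the weibull and
# gamma shapes). Label switching is resolved by sorting components by mean.

MIX_FAMILIES <- c("lognormal", "weibull", "gamma")

#' Construct a finite mixture specification
#'
#' @param weights Mixing proportions, strictly positive, summing to 1.
#' @param components List of [dist_spec()] objects, all of the same family
#'   (lognormal, weibull or gamma). Stored sorted by increasing component
#'   mean (identifiability convention).
#' @return An object of class `mixture_spec`.
#' @export
#' @examples
#' mixture_spec(c(0.4, 0.6),
#'              list(dist_spec("gamma", shape = 2, rate = 8),
#'                   dist_spec("gamma", shape = 30, rate = 20)))
mixture_spec <- function(weights, components) {
  if (!is.numeric(weights) || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort_invalid("weights must be positive and sum to 1")
  }
  if (length(weights) != length(components) || length(components) < 1) {
    abort_invalid("need one weight per component")
  }
  fams <- vapply(components, function(s) {
    stopifnot(inherits(s, "dist_spec")); s$family
  }, character(1))
  if (length(unique(fams)) != 1 || !fams[1] %in% MIX_FAMILIES) {
    abort_invalid("components must share one family among ",
                  paste(MIX_FAMILIES, collapse = ", "))
  }
  means <- vapply(components, dist_mean, numeric(1))
  ord <- order(means)
  structure(list(g = length(weights), family = fams[1],
                 weights = weights[ord] / sum(weights),
                 components = components[ord]),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %d-%s | pi = (%s)\n", x$g, x$family,
              paste(signif(x$weights, 4), collapse = ", ")))
  for (cm in x$components) print(cm)
  invisible(x)
}

#' Mixture density
#' @param spec A [mixture_spec()].
#' @param x Quantiles (mg/kg).
#' @param log Return log densities?
#' @export
mixture_pdf <- function(spec, x, log = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"))
  dens <- Reduce(`+`, Map(function(w, cm) w * dist_pdf(cm, x),
                          spec$weights, spec$components))
  if (log) log(dens) else dens
}

#' Mixture CDF
#' @inheritParams mixture_pdf
#' @param q Quantiles.
#' @export
mixture_cdf <- function(spec, q) {
  stopifnot(inherits(spec, "mixture_spec"))
  Reduce(`+`, Map(function(w, cm) w * dist_cdf(cm, q),
                  spec$weights, spec$components))
}

#' Mixture quantile function (bracketed root-finding)
#'
#' Brackets each root between the smallest and largest component quantile
#' and solves `F(x) = p` with [stats::uniroot()] to 1e-12 tolerance, so the
#' round trip `cdf(quantile(p)) = p` holds to ~1e-9.
#'
#' @inheritParams mixture_pdf
#' @param p Probabilities strictly inside (0, 1).
#' @export
mixture_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (any(p <= 0 | p >= 1)) abort_invalid("p must be strictly inside (0, 1)")
  vapply(p, function(pp) {
    qs <- vapply(spec$components, dist_quantile, numeric(1), p = pp)
    lo <- min(qs); hi <- max(qs)
    if (hi - lo < 1e-14) return(lo)
    stats::uniroot(function(x) mixture_cdf(spec, x) - pp, c(lo, hi),
                   tol = 1e-12, extendInt = "upX")$root
  }, numeric(1))
}

#' Sample from a mixture
#'
#' Component labels drawn categorically from the weights, then a component
#' draw; deterministic under a fixed seed.
#'
#' @inheritParams mixture_pdf
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @export
mixture_sample <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed_opt(seed, {
    lab <- sample.int(spec$g, n, replace = TRUE, prob = spec$weights)
    out <- numeric(n)
    for (i in seq_len(spec$g)) {
      idx <- lab == i
      if (any(idx)) out[idx] <- dist_sample(spec$components[[i]], sum(idx))
    }
    out
  })
}

#' Theoretical mixture mean
#' @param spec A [mixture_spec()].
#' @export
mixture_mean <- function(spec) {
  sum(spec$weights * vapply(spec$components, dist_mean, numeric(1)))
}

# --- weighted M-steps ------------------------------------------------------

wmle_lognormal <- function(x, w) {
  lx <- log(x)
  mu <- sum(w * lx) / sum(w)
  s2 <- sum(w * (lx - mu)^2) / sum(w)
  if (s2 <= 1e-12) return(NULL) # variance collapse
  dist_spec("lognormal", meanlog = mu, sdlog = sqrt(s2))
}

wmle_gamma <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  mlog <- sum(w * log(x)) / sw
  s <- log(m) - mlog
  if (s <= 1e-12) return(NULL)
  f <- function(a) log(a) - digamma(a) - s
  a <- tryCatch(
    stats::uniroot(f, c(1e-4, 1e6), tol = 1e-12)$root,
    error = function(e) NULL)
  if (is.null(a)) return(NULL)
  dist_spec("gamma", shape = a, rate = a / m)
}

wmle_weibull <- function(x, w) {
  sw <- sum(w)
  # normalize by the geometric mean so x^k stays finite for large k
  lx <- log(x)
  mlog <- sum(w * lx) / sw
  xs <- x / exp(mlog)
  lxs <- lx - mlog
  f <- function(k) {
    xk <- xs^k
    if (any(!is.finite(xk))) return(NA_real_)
    sum(w * xk * lxs) / sum(w * xk) - 1 / k
  }
  # adaptive bracket around a moment-based start
  m1 <- sum(w * x) / sw
  cv <- sqrt(max(sum(w * (x - m1)^2) / sw, 1e-12)) / m1
  k0 <- max(min(cv^(-1.086), 100), 0.05)
  lo <- k0; hi <- k0
  for (i in 1:60) { lo <- lo / 1.5; v <- f(lo); if (is.finite(v) && v < 0) break }
  for (i in 1:60) { hi <- hi * 1.5; v <- f(hi); if (!is.finite(v)) { hi <- hi / 1.5; break }; if (v > 0) break }
  vlo <- f(lo); vhi <- f(hi)
  if (!is.finite(vlo) || !is.finite(vhi) || vlo * vhi > 0) return(NULL)
  k <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                error = function(e) NULL)
  if (is.null(k)) return(NULL)
  sc <- exp(mlog) * (sum(w * xs^k) / sw)^(1 / k)
  dist_spec("weibull", shape = k, scale = sc)
}

wmle_component <- function(x, w, family) {
  switch(family,
    lognormal = wmle_lognormal(x, w),
    gamma = wmle_gamma(x, w),
    weibull = wmle_weibull(x, w))
}

# one EM run from a given hard split of the data
em_run <- function(data, family, g, init_groups, max_iter, tol) {
  n <- length(data)
  comps <- vector("list", g)
  for (i in seq_len(g)) {
    xi <- data[init_groups == i]
    if (length(xi) < 3) return(NULL)
    comps[[i]] <- tryCatch(fit_mle(xi, family)$spec, error = function(e) NULL)
    if (is.null(comps[[i]])) return(NULL)
  }
  wts <- rep(1 / g, g)
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # E-step: responsibilities from log densities
    lmat <- vapply(seq_len(g),
                   function(i) log(wts[i]) + dist_pdf(comps[[i]], data, log = TRUE),
                   numeric(n))
    mx <- apply(lmat, 1, max)
    pmat <- exp(lmat - mx)
    rs <- rowSums(pmat)
    ll <- sum(mx + log(rs))
    resp <- pmat / rs
    # M-step
    wts_new <- colMeans(resp)
    if (any(wts_new < 1e-6)) return(list(degenerate = TRUE))
    comps_new <- vector("list", g)
    for (i in seq_len(g)) {
      comps_new[[i]] <- wmle_component(data, resp[, i], family)
      if (is.null(comps_new[[i]])) return(list(degenerate = TRUE))
    }
    wts <- wts_new; comps <- comps_new
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      return(list(weights = wts, components = comps, loglik = ll,
                  n_iter = iter, converged = TRUE, trace = trace,
                  degenerate = FALSE))
    }
    ll_old <- ll
  }
  list(weights = wts, components = comps, loglik = ll_old, n_iter = max_iter,
       converged = FALSE, trace = trace, degenerate = FALSE)
}

#' Fit a finite mixture by expectation-maximization
#'
#' E-step computes posterior responsibilities; the M-step does weighted
#' maximum likelihood per component (closed form for lognormal, 1-D
#' root-finding for the gamma/weibull shape). Initialization splits the data
#' at the median (further restarts use random quantile splits); the best of
#' `n_restarts` runs is returned with components sorted by increasing mean.
#' Runs collapsing a component (weight < 1e-6 or variance collapse) are
#' discarded; if every restart degenerates the fit fails.
#'
#' @param data Strictly positive numeric vector, `n >= 5 g`.
#' @param family `"lognormal"`, `"weibull"` or `"gamma"`.
#' @param g Number of components (default 2).
#' @param n_restarts Number of EM restarts (default 10).
#' @param seed Optional integer seed controlling restart splits.
#' @param max_iter Maximum EM iterations per run (default 1000).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @return A `mixture_fit` with `spec`, `loglik`, `n`,
#'   `k = 2g + (g - 1)`, `aic`, `bic`, `n_iter`, `converged`, and the
#'   per-iteration log-likelihood `trace` of the winning run.
#' @export
#' @examples
#' truth <- mixture_spec(c(0.4, 0.6),
#'                       list(dist_spec("gamma", shape = 2, rate = 8),
#'                            dist_spec("gamma", shape = 30, rate = 20)))
#' x <- mixture_sample(truth, 400, seed = 11)
#' mixture_fit_em(x, "gamma", n_restarts = 3, seed = 1)
mixture_fit_em <- function(data, family, g = 2, n_restarts = 10, seed = NULL,
                           max_iter = 1000, tol = 1e-8) {
  family <- match.arg(family, MIX_FAMILIES)
  if (length(data) < 5 * g) abort_invalid("need n >= 5 g observations")
  if (anyNA(data) || any(data <= 0)) abort_invalid("data must be strictly positive")
  n <- length(data)
  qsplits <- with_seed_opt(seed, {
    first <- 0.5 # median split
    extra <- if (n_restarts > 1) stats::runif(n_restarts - 1, 0.15, 0.85) else numeric(0)
    c(first, extra)
  })
  best <- NULL
  n_degenerate <- 0L
  for (r in seq_len(n_restarts)) {
    if (g == 1) {
      groups <- rep(1L, n)
    } else {
      # split at g-1 quantiles centred on qsplits[r]
      probs <- seq_len(g - 1) * qsplits[r] * 2 / g
      probs <- pmin(pmax(probs, 0.05), 0.95)
      cuts <- stats::quantile(data, sort(unique(probs)), names = FALSE)
      groups <- findInterval(data, unique(cuts)) + 1L
      if (length(unique(groups)) < g) { n_degenerate <- n_degenerate + 1L; next }
    }
    run <- em_run(data, family, g, groups, max_iter, tol)
    if (is.null(run) || isTRUE(run$degenerate)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best)) {
    abort_invalid("all ", n_restarts, " EM restarts degenerated")
  }
  spec <- mixture_spec(best$weights, best$components)
  k <- 2L * g + (g - 1L)
  ll <- best$loglik
  structure(list(
    spec = spec, loglik = ll, n = n, k = k,
    aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
    n_iter = best$n_iter, converged = best$converged,
    trace = best$trace, n_degenerate_restarts = n_degenerate
  ), class = c("mixture_fit", "conc_fit"))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> %d-%s | n=%d logLik=%.3f AIC=%.2f BIC=%.2f iter=%d converged=%s\n",
    x$spec$g, x$spec$family, x$n, x$loglik, x$aic, x$bic, x$n_iter, x$converged))
  print(x$spec)
  invisible(x)
}
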
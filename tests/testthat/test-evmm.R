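# evmm: spliced bulk + GPD tail distribution and its joint MLE.

test_that("cdf is continuous at the threshold and equals H(u) there", {
  sp <- lgpd_truth()
  hu <- dist_cdf(sp$bulk, sp$threshold)
  expect_lt(abs(evmm_cdf(sp, sp$threshold - 1e-12) - evmm_cdf(sp, sp$threshold)),
            1e-12)
  expect_equal(evmm_cdf(sp, sp$threshold), hu)
  # normalization
  expect_equal(evmm_cdf(sp, 1e9), 1, tolerance = 1e-9)
  expect_equal(evmm_cdf(sp, 1e-12), 0, tolerance = 1e-9)
})

test_that("quantile inverts the spliced cdf, checked against numeric root-finding", {
  sp <- evmm_spec(dist_spec("lognormal", meanlog = 0, sdlog = 1),
                  threshold = stats::qlnorm(0.90, 0, 1),
                  gpd_shape = 0.2, gpd_scale = 0.5)
  for (p in c(0.3, 0.89, 0.95, 0.999)) {
    q <- evmm_quantile(sp, p)
    expect_equal(evmm_cdf(sp, q), p, tolerance = 1e-10)
    # independent oracle: bisection on evmm_cdf
    oracle <- stats::uniroot(function(x) evmm_cdf(sp, x) - p,
                             c(1e-8, 1e6), tol = 1e-12)$root
    expect_equal(q, oracle, tolerance = 1e-6)
  }
})

test_that("xi < 0 gives a finite upper endpoint never exceeded", {
  sp <- evmm_spec(dist_spec("gamma", shape = 2, rate = 2),
                  threshold = stats::qgamma(0.9, 2, 2),
                  gpd_shape = -0.4, gpd_scale = 0.5)
  endpoint <- sp$threshold - sp$gpd_scale / sp$gpd_shape
  expect_lte(evmm_quantile(sp, 1 - 1e-12), endpoint)
  expect_equal(evmm_cdf(sp, endpoint + 1), 1)
})

test_that("sampler: deterministic, correct tail fraction, mean matches integral", {
  sp <- lgpd_truth()
  a <- evmm_sample(sp, 1000, seed = 31)
  expect_identical(a, evmm_sample(sp, 1000, seed = 31))
  # fraction of draws >= u within 3 binomial sd at n = 1e5
  n <- 1e5
  x <- evmm_sample(sp, n, seed = 17)
  phi <- 1 - dist_cdf(sp$bulk, sp$threshold)
  expect_lt(abs(mean(x >= sp$threshold) - phi), 3 * sqrt(phi * (1 - phi) / n))
  # mean of 1e6 draws vs numeric/closed-form integral, within 1% (xi < 1)
  xm <- mean(evmm_sample(sp, 1e6, seed = 18))
  expect_equal(xm, evmm_mean(sp), tolerance = 0.01)
})

test_that("empirical CDF of a large sample matches evmm_cdf within the DKW band", {
  sp <- lgpd_truth()
  n <- 2e5 # scaled down from 1e6 for runtime; DKW band shrinks with n anyway
  x <- evmm_sample(sp, n, seed = 4)
  eps <- sqrt(log(2 / 0.01) / (2 * n))
  grid <- evmm_quantile(sp, seq(0.001, 0.999, length.out = 201))
  ec <- stats::ecdf(x)
  expect_lt(max(abs(ec(grid) - evmm_cdf(sp, grid))), eps)
})

test_that("joint MLE self-consistency: refit of own sample reproduces loglik/obs", {
  sp <- lgpd_truth()
  x <- evmm_sample(sp, 10000, seed = 8)
  f <- evmm_fit(x, "lognormal", threshold_grid = seq(0.6, 0.95, 0.05))
  ll_truth <- sum(evmm_pdf(sp, x, log = TRUE)) / length(x)
  expect_equal(f$loglik / f$n, ll_truth, tolerance = 0.02)
  expect_gte(f$loglik / f$n, ll_truth - 1e-8) # MLE at least as good in-sample
  expect_equal(f$k, 5L)
  expect_equal(f$aic, 2 * 5 - 2 * f$loglik)
  expect_equal(f$bic, 5 * log(f$n) - 2 * f$loglik)
  expect_equal(f$n_exceedances, sum(x >= f$spec$threshold))
})

test_that("degenerate input: bounded data with forced high threshold still fits", {
  x <- withr::with_seed(3, stats::runif(200, 0.01, 1))
  f <- evmm_fit(x, "weibull", threshold_grid = 0.9, refine = FALSE)
  expect_s3_class(f, "evmm_fit")
  expect_true(is.finite(f$loglik))
  expect_gte(f$n_exceedances, 2)
})

test_that("fewer than 2 exceedances at every candidate threshold errors", {
  x <- c(rep(0.1, 9), 5) # only one point can ever exceed a P95-ish cut
  expect_error(evmm_fit(x, "lognormal", threshold_grid = 0.95),
               "exceedances")
  expect_error(evmm_fit(c(1, 2, 3), "lognormal"), "n >= 10")
  expect_error(evmm_fit(c(rep(1, 20), -1), "gamma"), "positive")
})

test_that("free tail-fraction variant matches the exceedance proportion", {
  sp <- lgpd_truth()
  x <- evmm_sample(sp, 500, seed = 21)
  f <- evmm_fit(x, "lognormal", threshold_grid = seq(0.7, 0.9, 0.1),
                refine = FALSE, tail_fraction = "free")
  expect_equal(f$spec$phi, f$n_exceedances / f$n, tolerance = 1e-9)
  expect_equal(f$k, 6L)
  # spliced cdf still proper
  expect_equal(evmm_cdf(f$spec, 1e9), 1, tolerance = 1e-9)
})

test_that("invalid evmm specs are rejected at construction", {
  bulk <- dist_spec("lognormal", meanlog = 0, sdlog = 1)
  expect_error(evmm_spec(bulk, threshold = -1, gpd_shape = 0.1, gpd_scale = 1),
               "threshold")
  expect_error(evmm_spec(bulk, threshold = 1, gpd_shape = 0.1, gpd_scale = 0),
               "gpd_scale")
  expect_error(evmm_spec(dist_spec("exponential", rate = 1), 1, 0.1, 1),
               "bulk family")
})

test_that("parameter recovery at n = 2000 (3 seeds; full study in acceptance)", {
  sp <- lgpd_truth()
  xi <- vapply(1:3, function(s) {
    x <- evmm_sample(sp, 2000, seed = derive_seed(100, s))
    evmm_fit(x, "lognormal")$spec$gpd_shape
  }, numeric(1))
  expect_lt(abs(stats::median(xi) - sp$gpd_shape), 0.25)
})
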
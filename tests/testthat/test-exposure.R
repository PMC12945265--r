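# exposure_engine: censored datasets, consumption calibration,
# zero-inflated concentration simulation and EDI arithmetic.

test_that("concentration dataset: construction, detection rate, CSV round trip", {
  ds <- make_dataset(seed = 2)
  expect_equal(ds$n_total, 91)
  expect_equal(ds$detection_rate, ds$n_detected / 91)
  expect_error(concentration_dataset(c(1, NA), c(TRUE, TRUE), lod = 0.1),
               "carry a value")
  expect_error(concentration_dataset(c(1, 2), c(TRUE, FALSE), lod = -1), "lod")
  td <- withr::local_tempdir()
  p <- file.path(td, "conc.csv")
  write_concentration_csv(ds, p)
  ds2 <- read_concentration_csv(p)
  expect_equal(ds2$detection_rate, ds$detection_rate)
  expect_equal(positive_values(ds2), positive_values(ds), tolerance = 1e-12)
  expect_equal(ds2$lod, ds$lod)
})

test_that("consumption calibration: exact 2-point inversion and round trip", {
  m <- consumption_from_percentiles(c(0.5, 0.975),
                                    exp(c(3, 3 + stats::qnorm(0.975) * 0.5)))
  expect_equal(m$log_mean, 3, tolerance = 1e-9)
  expect_equal(m$log_sd, 0.5, tolerance = 1e-6)
  # model -> quantiles -> refit recovers parameters to 1e-9
  ps <- c(0.25, 0.5, 0.75, 0.95)
  m2 <- consumption_from_percentiles(ps, consumption_quantile(m, ps))
  expect_equal(m2$log_mean, m$log_mean, tolerance = 1e-9)
  expect_equal(m2$log_sd, m$log_sd, tolerance = 1e-9)
  expect_error(consumption_from_percentiles(c(0.5, 0.75), c(2, 1)), "increasing")
})

test_that("published-percentile calibration reproduces the P50 within 15%", {
  # adult-male stratum targets (g/day)
  m <- consumption_from_percentiles(c(0.50, 0.75, 0.95), c(51.3, 88.8, 140.6))
  expect_lt(abs(consumption_quantile(m, 0.5) - 51.3) / 51.3, 0.15)
})

test_that("simulate_consumption: median accuracy, truncation, sd->0 limit", {
  m <- consumption_model(log_mean = 3.5, log_sd = 0.6)
  x <- simulate_consumption(m, 1e6, seed = 5)
  expect_equal(stats::median(x), exp(3.5), tolerance = 0.005)
  mt <- consumption_model(3.5, 0.6, lower = 20, upper = 60)
  xt <- simulate_consumption(mt, 5000, seed = 6)
  expect_true(all(xt >= 20 & xt <= 60))
  m0 <- consumption_model(3.5, 1e-6)
  expect_equal(mean(simulate_consumption(m0, 100, seed = 7)), exp(3.5),
               tolerance = 1e-4)
  # truncation interval with negligible mass errors out
  expect_error(simulate_consumption(consumption_model(3.5, 0.1,
                                                      lower = 1, upper = 1.5),
                                    10, seed = 1),
               "mass")
})

test_that("zero-inflated concentration simulation follows the detection law", {
  f <- fit_mle(dist_sample(dist_spec("lognormal", meanlog = -1, sdlog = 0.5),
                           200, seed = 3), "lognormal")
  # detection 1: all from the positive model (none below a tiny floor)
  x1 <- simulate_concentration(f, 1, lod = 0.1, n = 2000, seed = 9)
  expect_identical(x1, simulate_concentration(f, 1, lod = 0.1, n = 2000, seed = 9))
  # detection 0: uniform sub-LOD imputation
  x0 <- simulate_concentration(f, 0, lod = 0.1, n = 1e5, seed = 10)
  expect_true(all(x0 > 0 & x0 < 0.1))
  expect_lt(abs(mean(x0) - 0.05), 3 * (0.1 / sqrt(12)) / sqrt(1e5))
  # mixed: closed-form mean p*m_pos + (1-p)*LOD/2 within 3 MC sd at n = 1e4
  p <- 0.55
  n <- 1e4
  xm <- simulate_concentration(f, p, lod = 0.1, n = n, seed = 11)
  m_pos <- dist_mean(f$spec)
  mu <- p * m_pos + (1 - p) * 0.05
  expect_lt(abs(mean(xm) - mu), 3 * stats::sd(xm) / sqrt(n))
  expect_error(simulate_concentration(f, 1.2, 0.1, 10), "detection_rate")
})

test_that("EDI arithmetic: units, zero, independence of streams", {
  expect_equal(compute_edi(100, 0.5, 50), 1.0)
  expect_equal(compute_edi(100, 0, 50), 0)
  expect_error(compute_edi(c(1, 2), 1, 50), "paired")
  expect_error(compute_edi(1, 1, 0), "weight_kg")
  g <- test_group()
  f <- fit_mle(dist_sample(dist_spec("lognormal", meanlog = -2, sdlog = 0.4),
                           200, seed = 13), "lognormal")
  ex <- simulate_exposure(f, 0.5, 0.1, g, n_sim = 1e4, seed = 21)
  # stream independence: correlation of cons and conc ~ 0 +/- 0.03
  cons <- simulate_consumption(g$consumption, 1e4, seed = derive_seed(21, "cons"))
  conc <- simulate_concentration(f, 0.5, 0.1, 1e4, seed = derive_seed(21, "conc"))
  expect_lt(abs(stats::cor(cons, conc)), 0.03)
  expect_equal(ex$draws, compute_edi(cons, conc, g$weight_kg))
  # mean EDI ~ product of means / W under independence (within MC error)
  expect_lt(abs(mean(ex$draws) - mean(cons) * mean(conc) / g$weight_kg),
            3 * stats::sd(ex$draws) / sqrt(length(ex$draws)))
})

test_that("exposure summaries are monotone and 1/W-equivariant", {
  f <- fit_mle(dist_sample(dist_spec("lognormal", meanlog = -2, sdlog = 0.6),
                           150, seed = 1), "lognormal")
  g1 <- test_group()
  g2 <- demographic_group("G2", "18-49", "male", weight_kg = 120,
                          g1$consumption)
  e1 <- simulate_exposure(f, 0.5, 0.1, g1, n_sim = 5000, seed = 30)
  e2 <- simulate_exposure(f, 0.5, 0.1, g2, n_sim = 5000, seed = 30)
  s <- e1$summary
  expect_true(all(diff(s[c("p50", "p75", "p95", "p999")]) >= 0))
  expect_equal(e2$summary, s * 60 / 120, tolerance = 1e-12)
})

test_that("demographics reader accepts log-params and percentile blocks", {
  td <- withr::local_tempdir()
  p <- file.path(td, "demo.csv")
  df <- data.frame(label = c("A", "B"), age_band = "18-49",
                   sex = c("male", "female"), weight_kg = c(60, 55),
                   log_mean = c(4, NA), log_sd = c(0.5, NA),
                   p50 = c(NA, 40), p95 = c(NA, 120))
  utils::write.csv(df, p, row.names = FALSE)
  gs <- read_demographics(p)
  expect_length(gs, 2)
  expect_equal(gs$A$consumption$log_mean, 4)
  expect_equal(consumption_quantile(gs$B$consumption, 0.5), 40, tolerance = 1e-6)
})
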
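# model_selection: GOF statistics, bootstrap p-values, stage-3 deviations
# and the three-stage protocol.

test_that("KS statistic hand computation: {1,2,3,4} vs Uniform(0,4) gives 0.25", {
  data <- c(1, 2, 3, 4)
  expect_equal(ks_statistic(data, data / 4), 0.25)
})

test_that("relative_difference reproduces printed table cells", {
  expect_equal(round(relative_difference(0.5332, 0.5813), 2), 8.27)
  expect_equal(round(relative_difference(13.6600, 13.0517), 2), 4.66)
  expect_equal(relative_difference(3.2, 3.2), 0)
  expect_error(relative_difference(1, 0), "> 0")
})

test_that("AD statistic matches its definition on a small case", {
  # direct evaluation of -n - mean((2i-1)(log F_i + log(1-F_{n+1-i})))
  data <- c(0.2, 0.5, 0.9)
  Fi <- data # uniform(0,1) cdf
  n <- 3
  manual <- -n - mean((2 * seq_len(n) - 1) * (log(Fi) + log(1 - rev(Fi))))
  expect_equal(ad_statistic(data, Fi), manual)
})

test_that("gof p-values: sane under the null, exchange-invariant, power on misfit", {
  x <- dist_sample(dist_spec("lognormal", meanlog = -1, sdlog = 0.8), 60, seed = 3)
  f <- fit_mle(x, "lognormal")
  g <- gof_test(x, f, B = 99, seed = 10)
  expect_gt(g$ks_p, 0.05)  # truth should not be rejected here
  expect_gt(g$ad_p, 0.05)
  expect_false(g$flagged)
  # permutation of the data leaves the statistics and p-values unchanged
  xp <- withr::with_seed(5, sample(x))
  fp <- fit_mle(xp, "lognormal")
  gp <- gof_test(xp, fp, B = 99, seed = 10)
  expect_equal(g$ks_stat, gp$ks_stat, tolerance = 1e-12)
  expect_equal(g$ks_p, gp$ks_p)
  expect_equal(g$ad_p, gp$ad_p)
})

test_that("power smoke: exponential fit rejected on heavy-tailed lognormal data", {
  rej <- vapply(1:20, function(s) {
    x <- dist_sample(dist_spec("lognormal", meanlog = 0, sdlog = 1.5), 50,
                     seed = derive_seed(400, s))
    f <- fit_mle(x, "exponential")
    gof_test(x, f, B = 99, seed = derive_seed(401, s))$ks_p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("stage3_deviation: deterministic under seed, small for a perfect model", {
  x <- dist_sample(dist_spec("lognormal", meanlog = -1, sdlog = 0.5), 5000, seed = 2)
  f <- fit_mle(x, "lognormal")
  d1 <- stage3_deviation(f, x, n_sim = 10000, seed = 7)
  expect_identical(d1, stage3_deviation(f, x, n_sim = 10000, seed = 7))
  expect_named(d1, c("mean", "p95", "p999"))
  expect_lt(d1[["mean"]], 5)
  expect_lt(d1[["p95"]], 5)
})

test_that("three-stage protocol: ordering, shortlist, no-adequate-model", {
  x <- dist_sample(dist_spec("lognormal", meanlog = -1.5, sdlog = 0.7), 120,
                   seed = 14)
  rep <- suppressWarnings(select_model(
    x, candidates = c("lognormal", "gamma", "exponential"),
    B = 60, n_sim = 4000, seed = 3))
  tab <- rep$table
  expect_equal(rep$status, "ok")
  expect_equal(rep$winner, "lognormal")
  # stage ordering: models failing stage 1 carry no stage-3 deviations
  failed <- tab$model[!tab$stage1_pass]
  expect_true(all(is.na(tab$dev_p999[match(failed, tab$model)])))
  # the winner is rank 1 among survivors
  expect_equal(tab$rank[tab$model == rep$winner], 1L)
  # single candidate failing stage 1 => explicit no-adequate-model status
  bad <- suppressWarnings(select_model(x, candidates = "exponential",
                                       B = 60, n_sim = 2000, seed = 3))
  expect_equal(bad$status, "no adequate model")
  expect_true(is.na(bad$winner))
})

test_that("adding an irrelevant candidate never reorders the others (stages 1-2)", {
  x <- dist_sample(dist_spec("lognormal", meanlog = -1, sdlog = 0.6), 100, seed = 25)
  r1 <- suppressWarnings(select_model(x, candidates = c("lognormal", "gamma"),
                                      B = 60, n_sim = 2000, seed = 11))
  r2 <- suppressWarnings(select_model(
    x, candidates = c("lognormal", "gamma", "exponential"),
    B = 60, n_sim = 2000, seed = 11))
  shared <- intersect(r1$table$model, r2$table$model)
  b1 <- r1$table$bic[match(shared, r1$table$model)]
  b2 <- r2$table$bic[match(shared, r2$table$model)]
  expect_equal(order(b1), order(b2))
  expect_equal(b1, b2, tolerance = 1e-9) # fits independent of the candidate set
})

test_that("mixture candidates are excluded below the positives cutoff", {
  x <- dist_sample(dist_spec("lognormal", meanlog = -2, sdlog = 0.5), 25, seed = 6)
  rep <- suppressWarnings(select_model(x, candidates = c("lognormal", "2-gamma"),
                                       B = 40, n_sim = 1000, seed = 2,
                                       min_pos_mixture = 30))
  expect_equal(rep$excluded_small_n, "2-gamma")
  expect_false("2-gamma" %in% rep$table$model)
})

test_that("selection report serializes to JSON", {
  x <- dist_sample(dist_spec("lognormal", meanlog = -1, sdlog = 0.6), 60, seed = 8)
  rep <- suppressWarnings(select_model(x, candidates = "lognormal", B = 40,
                                       n_sim = 1000, seed = 4))
  p <- file.path(withr::local_tempdir(), "sel.json")
  write_selection_report(rep, p)
  js <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(js$winner, rep$winner)
  expect_equal(nrow(js$table), nrow(rep$table))
})
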
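# Three-stage model selection for positive concentration data:
#   Stage 1  KS / AD goodness-of-fit screening with parametric-bootstrap
#            p-values (parameters are estimated, so textbook tables are
#            invalid)
#   Stage 2  information-criterion ranking of the survivors (BIC primary,
#            AIC reported and used as tie-break), shortlist of top-k
#   Stage 3  Monte Carlo percentile deviations at the mean, P95 and P99.9;
#            the winner minimizes the P99.9 deviation (conservative
#            upper-tail priority), tie-broken by mean then P95.

#' Kolmogorov-Smirnov statistic against a fitted CDF
#'
#' `sup |ECDF - F|` computed on the sorted sample.
#'
#' @param data Numeric data vector.
#' @param cdf_values CDF of the candidate model evaluated at `sort(data)`.
#' @return The KS statistic.
#' @export
ks_statistic <- function(data, cdf_values) {
  n <- length(data)
  stopifnot(length(cdf_values) == n)
  Fi <- sort(cdf_values)
  i <- seq_len(n)
  max(pmax(i / n - Fi, Fi - (i - 1) / n))
}

#' Anderson-Darling statistic against a fitted CDF
#'
#' The quadratic ECDF statistic
#' \eqn{A^2 = -n - \frac{1}{n}\sum (2i-1)[\log F_{(i)} + \log(1-F_{(n+1-i)})]},
#' which up-weights tail discrepancies relative to KS.
#'
#' @inheritParams ks_statistic
#' @export
ad_statistic <- function(data, cdf_values) {
  n <- length(data)
  stopifnot(length(cdf_values) == n)
  Fi <- sort(cdf_values)
  eps <- 1e-12
  Fi <- pmin(pmax(Fi, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(Fi) + log(1 - rev(Fi))))
}

#' Parametric-bootstrap goodness-of-fit test (KS and AD)
#'
#' Because model parameters are estimated from the data, KS/AD p-values are
#' obtained by parametric bootstrap: simulate `B` datasets of size `n` from
#' the fitted model, refit the same family, recompute both statistics, and
#' report `p = (1 + #\{stat_b >= stat_obs\}) / (B + 1)`. Bootstrap refit
#' failures are dropped and counted; more than 20% failures flags the
#' p-values as unreliable.
#'
#' @param data The data the model was fitted on.
#' @param fitted A fitted model (`fit_result`, `evmm_fit`, `mixture_fit`).
#' @param B Bootstrap replicates, `>= 200` recommended (default 1000).
#' @param seed Integer seed for the bootstrap stream.
#' @param refit_args Named list of overrides for [fit_refit()] inside the
#'   loop (e.g. a coarser EVMM `threshold_grid` for speed).
#' @return A `gof_result` list: `ks_stat`, `ad_stat`, `ks_p`, `ad_p`, `B`,
#'   `n_failed`, `flagged`.
#' @export
gof_test <- function(data, fitted, B = 1000, seed = NULL, refit_args = list()) {
  stopifnot(inherits(fitted, "conc_fit"))
  if (B < 2) abort_invalid("B must be at least 2")
  n <- length(data)
  Fobs <- fit_cdf(fitted, sort(data))
  ks_obs <- ks_statistic(data, Fobs)
  ad_obs <- ad_statistic(data, Fobs)
  seeds <- vapply(seq_len(B), function(b) derive_seed(seed %||% 0, b), integer(1))
  ks_b <- ad_b <- rep(NA_real_, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    sim <- fit_sample(fitted, n, seed = seeds[b])
    ref <- tryCatch(do.call(fit_refit, c(list(fitted, sim), refit_args)),
                    error = function(e) NULL)
    if (is.null(ref)) { n_failed <- n_failed + 1L; next }
    Fb <- fit_cdf(ref, sort(sim))
    ks_b[b] <- ks_statistic(sim, Fb)
    ad_b[b] <- ad_statistic(sim, Fb)
  }
  ok <- !is.na(ks_b)
  Beff <- sum(ok)
  structure(list(
    ks_stat = ks_obs, ad_stat = ad_obs,
    ks_p = (1 + sum(ks_b[ok] >= ks_obs)) / (Beff + 1),
    ad_p = (1 + sum(ad_b[ok] >= ad_obs)) / (Beff + 1),
    B = B, n_failed = n_failed,
    flagged = n_failed > 0.2 * B
  ), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> KS=%.4f (p=%.3f)  AD=%.4f (p=%.3f)  B=%d%s\n",
              x$ks_stat, x$ks_p, x$ad_stat, x$ad_p, x$B,
              if (x$flagged) sprintf("  [FLAGGED: %d refit failures]", x$n_failed)
              else ""))
  invisible(x)
}

#' Relative difference between an estimated and an observed value
#'
#' `100 * |estimated - original| / original`, the percentile-deviation
#' measure used in Stage 3.
#'
#' @param estimated Model-simulated value (mg/kg).
#' @param original Observed value (mg/kg), strictly positive.
#' @return Percent relative difference.
#' @export
#' @examples
#' relative_difference(0.5332, 0.5813) # 8.27
relative_difference <- function(estimated, original) {
  if (any(original <= 0)) abort_invalid("original value must be > 0")
  100 * abs(estimated - original) / original
}

#' Stage-3 Monte Carlo percentile deviations
#'
#' Simulates `n_sim` draws from the fitted model and reports the percent
#' relative difference between the simulated and the empirical mean, P95
#' and P99.9.
#'
#' @param fitted A fitted concentration model.
#' @param data The observed positive concentrations.
#' @param n_sim Monte Carlo size (default 10000).
#' @param seed Integer seed.
#' @return Named vector `mean`, `p95`, `p999` of percent deviations.
#' @export
stage3_deviation <- function(fitted, data, n_sim = 10000, seed = NULL) {
  sim <- fit_sample(fitted, n_sim, seed = seed)
  emp <- c(mean(data),
           stats::quantile(data, c(0.95, 0.999), names = FALSE, type = 7))
  est <- c(mean(sim),
           stats::quantile(sim, c(0.95, 0.999), names = FALSE, type = 7))
  out <- relative_difference(est, emp)
  names(out) <- c("mean", "p95", "p999")
  out
}

#' Canonical candidate model labels for the selection protocol
#'
#' Four traditional parametric families, three bulk-GPD extreme value
#' mixtures, and three two-component finite mixtures.
#' @export
CANDIDATE_LABELS <- c("lognormal", "weibull", "gamma", "exponential",
                      "lognormal-gpd", "weibull-gpd", "gamma-gpd",
                      "2-lognormal", "2-weibull", "2-gamma")

fit_candidate <- function(data, label, evmm_args = list(), mixture_args = list()) {
  if (label %in% c("lognormal", "weibull", "gamma", "exponential")) {
    fit_mle(data, label)
  } else if (grepl("-gpd$", label)) {
    do.call(evmm_fit, c(list(data = data, bulk_family = sub("-gpd$", "", label)),
                        evmm_args))
  } else if (grepl("^2-", label)) {
    do.call(mixture_fit_em, c(list(data = data, family = sub("^2-", "", label),
                                   g = 2), mixture_args))
  } else {
    abort_invalid("unknown candidate label: ", label)
  }
}

#' Run the three-stage model-selection protocol
#'
#' Fits every candidate, screens them by parametric-bootstrap KS/AD tests
#' at level `alpha` (Stage 1: both p-values must reach `alpha`), ranks the
#' survivors by BIC with AIC as tie-break (Stage 2), scores the `top_k`
#' shortlist by Monte Carlo percentile deviations (Stage 3), and selects
#' the model with the smallest P99.9 deviation (tie-break: mean, then P95).
#' A weighted-sum Stage-3 aggregation is available via `stage3_weights`.
#'
#' @param data Positive concentration vector.
#' @param candidates Character vector of candidate labels among
#'   `"lognormal"`, `"weibull"`, `"gamma"`, `"exponential"`,
#'   `"lognormal-gpd"`, `"weibull-gpd"`, `"gamma-gpd"`, `"2-lognormal"`,
#'   `"2-weibull"`, `"2-gamma"`.
#' @param alpha Stage-1 significance level (default 0.05).
#' @param B Bootstrap replicates for the GOF tests (default 1000).
#' @param n_sim Stage-3 Monte Carlo size (default 10000).
#' @param top_k Stage-2 shortlist size (default 3).
#' @param seed Integer master seed for the stage sub-streams.
#' @param min_pos_mixture Mixture candidates are skipped when the number of
#'   positives is below this cutoff (default 30; small positive counts make
#'   two-component mixtures unidentifiable).
#' @param stage3_weights Optional numeric weights `(mean, p95, p999)`; when
#'   given, Stage 3 minimizes the weighted sum instead of the
#'   P99.9-first lexicographic rule.
#' @param evmm_args,mixture_args,gof_args Named lists of overrides threaded
#'   to [evmm_fit()], [mixture_fit_em()] and [gof_test()].
#' @return A `selection_report`: data frame `table` (one row per candidate
#'   with GOF p-values, AIC/BIC, stage flags, Stage-3 deviations and rank),
#'   `winner` label (or `NA` with status `"no adequate model"`), `alpha`,
#'   `tie` flag, and the fitted winner object `winner_fit`.
#' @export
select_model <- function(data, candidates = CANDIDATE_LABELS, alpha = 0.05,
                         B = 1000, n_sim = 10000, top_k = 3, seed = 1,
                         min_pos_mixture = 30, stage3_weights = NULL,
                         evmm_args = list(), mixture_args = list(),
                         gof_args = list(), verbose = FALSE) {
  candidates <- unique(match.arg(candidates, CANDIDATE_LABELS, several.ok = TRUE))
  n <- length(data)
  drop_mix <- grepl("^2-", candidates) & n < min_pos_mixture
  excluded <- candidates[drop_mix]
  candidates <- candidates[!drop_mix]

  rows <- list(); fits <- list()
  for (i in seq_along(candidates)) {
    lab <- candidates[i]
    if (verbose) message("fitting ", lab, " ...")
    f <- tryCatch(fit_candidate(data, lab, evmm_args, mixture_args),
                  error = function(e) NULL)
    if (is.null(f)) {
      rows[[lab]] <- data.frame(model = lab, ks_p = NA, ad_p = NA,
                                aic = NA, bic = NA, converged = FALSE,
                                stage1_pass = FALSE)
      next
    }
    # bootstrap refits must mirror the observed fitting procedure exactly:
    # a settings mismatch (e.g. coarser refit grid) biases p-values upward
    matched_refit <- if (inherits(f, "evmm_fit")) evmm_args
                     else if (inherits(f, "mixture_fit")) mixture_args
                     else list()
    if (verbose) message("  gof bootstrap for ", lab, " ...")
    ga <- utils::modifyList(list(B = B, refit_args = matched_refit), gof_args)
    g <- do.call(gof_test, c(list(data, f, seed = derive_seed(seed, i)), ga))
    rows[[lab]] <- data.frame(model = lab, ks_p = g$ks_p, ad_p = g$ad_p,
                              aic = f$aic, bic = f$bic,
                              converged = f$converged,
                              stage1_pass = g$ks_p >= alpha & g$ad_p >= alpha)
    fits[[lab]] <- f
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$dev_mean <- tab$dev_p95 <- tab$dev_p999 <- NA_real_
  tab$rank <- NA_integer_

  surv <- tab$model[which(tab$stage1_pass)]
  if (length(surv) == 0) {
    return(structure(list(table = tab, winner = NA_character_,
                          winner_fit = NULL, status = "no adequate model",
                          alpha = alpha, tie = FALSE,
                          excluded_small_n = excluded),
                     class = "selection_report"))
  }
  # Stage 2: rank survivors by BIC, AIC tie-break
  sv <- tab[tab$model %in% surv, ]
  ord <- order(sv$bic, sv$aic)
  shortlist <- sv$model[ord][seq_len(min(top_k, nrow(sv)))]

  # Stage 3: percentile deviations on the shortlist
  for (lab in shortlist) {
    d <- stage3_deviation(fits[[lab]], data, n_sim = n_sim,
                          seed = derive_seed(seed, paste0("s3-", lab)))
    tab[tab$model == lab, c("dev_mean", "dev_p95", "dev_p999")] <-
      as.list(round(d[c("mean", "p95", "p999")], 2))
  }
  sl <- tab[tab$model %in% shortlist, ]
  if (is.null(stage3_weights)) {
    ord3 <- order(sl$dev_p999, sl$dev_mean, sl$dev_p95)
  } else {
    w <- stage3_weights / sum(stage3_weights)
    score <- as.matrix(sl[, c("dev_mean", "dev_p95", "dev_p999")]) %*% w
    ord3 <- order(score)
  }
  ranked <- sl$model[ord3]
  tab$rank[match(ranked, tab$model)] <- seq_along(ranked)
  winner <- ranked[1]
  tie <- nrow(sl) > 1 &&
    isTRUE(all.equal(sl$dev_p999[ord3][1], sl$dev_p999[ord3][2])) &&
    isTRUE(all.equal(sl$dev_mean[ord3][1], sl$dev_mean[ord3][2])) &&
    isTRUE(all.equal(sl$dev_p95[ord3][1], sl$dev_p95[ord3][2]))

  structure(list(table = tab, winner = winner, winner_fit = fits[[winner]],
                 status = "ok", alpha = alpha, tie = tie,
                 excluded_small_n = excluded),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  print(x$table, digits = 4)
  if (length(x$excluded_small_n)) {
    cat("excluded (too few positives):", paste(x$excluded_small_n, collapse = ", "), "\n")
  }
  if (x$status == "ok") {
    cat("winner:", x$winner, if (x$tie) "(tie flagged)" else "", "\n")
  } else {
    cat("status:", x$status, "\n")
  }
  invisible(x)
}

#' Serialize a selection report to JSON
#' @param report A `selection_report`.
#' @param path Output file path.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(
    list(table = report$table, winner = report$winner, status = report$status,
         alpha = report$alpha, tie = report$tie,
         excluded_small_n = report$excluded_small_n),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' ECDF overlay plot for one or more fitted models
#'
#' Steps the empirical CDF of the data and overlays each fitted model's
#' CDF, the visual diagnostic backing the selection protocol.
#'
#' @param data Positive concentration vector.
#' @param fits Named list of fitted models.
#' @param main Plot title.
#' @export
plot_ecdf_overlay <- function(data, fits, main = "ECDF overlay") {
  xs <- seq(min(data) * 0.5, max(data) * 1.05, length.out = 400)
  plot(stats::ecdf(data), main = main, xlab = "concentration (mg/kg)",
       ylab = "F(x)", col = "grey30")
  cols <- grDevices::hcl.colors(max(length(fits), 2), "Dark 3")
  for (i in seq_along(fits)) {
    graphics::lines(xs, fit_cdf(fits[[i]], xs), col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(fits), col = cols[seq_along(fits)],
                   lwd = 2, bty = "n")
  invisible(NULL)
}
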
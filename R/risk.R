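# Risk characterization: hazard quotients (EDI/TDI), the cumulative hazard
# index with relative potency factors, and bootstrap confidence intervals
# for exposure percentiles.
#
# Defaults follow the EFSA guidance values: TDI 50 ug/(kg bw)/day for DEHP
# and 10 for DBP; RPFs 1 (DEHP) and 5 (DBP) against a Group-TDI of 50
# expressed in DEHP equivalents.

#' Toxicological parameters for one analyte
#'
#' @param analyte Analyte name (`"DEHP"`, `"DBP"`, ...).
#' @param tdi Tolerable daily intake, ug/(kg bw)/day, `> 0`.
#' @param rpf Relative potency factor (DEHP equivalents), `> 0`.
#' @param group_tdi Group TDI for the cumulative index, ug/(kg bw)/day.
#' @return A `tox_params` object.
#' @export
tox_params <- function(analyte, tdi, rpf = 1, group_tdi = 50) {
  if (tdi <= 0 || rpf <= 0 || group_tdi <= 0) {
    abort_invalid("tdi, rpf and group_tdi must all be > 0")
  }
  structure(list(analyte = analyte, tdi = tdi, rpf = rpf,
                 group_tdi = group_tdi), class = "tox_params")
}

#' Default toxicological parameters (EFSA): DEHP and DBP
#' @return Named list of [tox_params()].
#' @export
default_tox_params <- function() {
  list(DEHP = tox_params("DEHP", tdi = 50, rpf = 1, group_tdi = 50),
       DBP = tox_params("DBP", tdi = 10, rpf = 5, group_tdi = 50))
}

#' Hazard quotient
#'
#' `HQ = EDI / TDI`, applied pointwise (so the HQ at P95 is the P95 EDI
#' over the TDI). Values below 1 indicate no significant non-carcinogenic
#' risk.
#'
#' @param edi EDI value(s), ug/(kg bw)/day, nonnegative.
#' @param tdi Tolerable daily intake, `> 0`.
#' @return Dimensionless HQ value(s).
#' @export
#' @examples
#' hazard_quotient(0.975, 50) # 0.0195
hazard_quotient <- function(edi, tdi) {
  if (any(tdi <= 0)) abort_invalid("tdi must be > 0")
  if (any(edi < 0)) abort_invalid("edi must be nonnegative")
  edi / tdi
}

#' Cumulative hazard index with relative potency factors
#'
#' `HI = (EDI_DEHP * RPF_DEHP + EDI_DBP * RPF_DBP) / Group-TDI`, applied at
#' matched percentiles of the two analytes' EDI distributions. Both
#' analytes are required; a single-analyte HI is refused rather than
#' silently computed.
#'
#' @param edi_dehp,edi_dbp EDI value(s) for DEHP and DBP, ug/(kg bw)/day.
#' @param tox Named list with `DEHP` and `DBP` [tox_params()] (defaults to
#'   [default_tox_params()]).
#' @return Dimensionless HI value(s).
#' @export
#' @examples
#' hazard_index(34.025, 2.232) # 0.9037
hazard_index <- function(edi_dehp, edi_dbp, tox = default_tox_params()) {
  if (is.null(edi_dehp) || is.null(edi_dbp) ||
      length(edi_dehp) == 0 || length(edi_dbp) == 0) {
    abort_invalid("HI needs both DEHP and DBP exposures")
  }
  if (!all(c("DEHP", "DBP") %in% names(tox))) {
    abort_invalid("tox must name both DEHP and DBP")
  }
  if (any(edi_dehp < 0) || any(edi_dbp < 0)) abort_invalid("EDIs must be nonnegative")
  gt <- tox$DEHP$group_tdi
  (edi_dehp * tox$DEHP$rpf + edi_dbp * tox$DBP$rpf) / gt
}

#' Bootstrap confidence intervals for exposure percentiles
#'
#' Data-level bootstrap (default mode `"data"`): in each of `B` replicates
#' the sample rows are resampled with replacement preserving each row's
#' detect/non-detect status, the detection rate is recomputed, the SELECTED
#' model family is refit on the resampled positives (the family is fixed;
#' no per-replicate reselection), the Monte Carlo exposure simulation is
#' rerun under a fresh sub-seed, and each percentile is recorded. The CI is
#' the 2.5th-97.5th percentile band of the replicate values. A cheaper mode
#' `"edi"` resamples only the simulated EDI vector (parameter uncertainty
#' excluded), for comparison.
#'
#' @param dataset A [concentration_dataset()].
#' @param fitted The selected fitted model (fixes the refit family).
#' @param group A [demographic_group()].
#' @param B Bootstrap replicates, `>= 50` (default 100).
#' @param n_sim Monte Carlo size per replicate (default 10000).
#' @param seed Integer master seed.
#' @param mode `"data"` (default) or `"edi"`.
#' @param refit_args Overrides for [fit_refit()] in the loop.
#' @param analyte Analyte label.
#' @return A `bootstrap_ci` object: matrix `replicates` (B x 5 summary
#'   points), data frame `ci` with `lower`/`upper` per summary point,
#'   `n_failed`, `flagged`.
#' @export
bootstrap_ci <- function(dataset, fitted, group, B = 100, n_sim = 10000,
                         seed = 1, mode = c("data", "edi"),
                         refit_args = list(), analyte = dataset$analyte) {
  mode <- match.arg(mode)
  if (B < 50) abort_invalid("B must be >= 50")
  stopifnot(inherits(dataset, "concentration_dataset"))
  reps <- matrix(NA_real_, B, 5,
                 dimnames = list(NULL, c("mean", "p50", "p75", "p95", "p999")))
  n_failed <- 0L
  if (mode == "edi") {
    base <- simulate_exposure(fitted, dataset$detection_rate, dataset$lod,
                              group, n_sim, seed = derive_seed(seed, "base"),
                              analyte = analyte)
    for (b in seq_len(B)) {
      idx <- with_seed_opt(derive_seed(seed, b),
                           sample.int(n_sim, n_sim, replace = TRUE))
      reps[b, ] <- percentile_summary(base$draws[idx])
    }
  } else {
    n <- dataset$n_total
    for (b in seq_len(B)) {
      sub <- derive_seed(seed, b)
      idx <- with_seed_opt(sub, sample.int(n, n, replace = TRUE))
      det <- dataset$detected[idx]
      pos <- dataset$values[idx][det]
      rate <- mean(det)
      ref <- tryCatch(
        do.call(fit_refit, c(list(fitted, pos), refit_args)),
        error = function(e) NULL)
      if (is.null(ref)) { n_failed <- n_failed + 1L; next }
      ex <- simulate_exposure(ref, rate, dataset$lod, group, n_sim,
                              seed = derive_seed(sub, "mc"), analyte = analyte)
      reps[b, ] <- ex$summary
    }
  }
  ok <- stats::complete.cases(reps)
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  structure(list(
    analyte = analyte, group = group$label, mode = mode, B = B,
    replicates = reps,
    ci = data.frame(point = colnames(reps), lower = ci[1, ], upper = ci[2, ],
                    row.names = NULL),
    n_failed = n_failed, flagged = n_failed > 0.2 * B
  ), class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %s | %s | B=%d mode=%s%s\n", x$analyte, x$group,
              x$B, x$mode,
              if (x$flagged) sprintf(" [FLAGGED: %d refit failures]", x$n_failed)
              else ""))
  print(x$ci, digits = 4)
  invisible(x)
}

#' Assemble a per-group risk report
#'
#' Combines per-analyte exposure distributions into HQ summaries and the
#' cumulative HI at matched percentile points (mean, P50, P75, P95, P99.9),
#' with optional bootstrap CIs. HQ/HI are reported at 3 decimals in the
#' table output; full precision is retained in the object and JSON.
#'
#' @param exposures Named list of `exposure_distribution` objects, names
#'   are analytes (must include `DEHP` and `DBP` for the HI).
#' @param tox Named list of [tox_params()].
#' @param cis Optional named list of `bootstrap_ci` objects per analyte.
#' @return A `risk_report` with `edi` (per-analyte summaries), `hq`, `hi`,
#'   `ci`, `group`.
#' @export
risk_report <- function(exposures, tox = default_tox_params(), cis = NULL) {
  stopifnot(length(exposures) >= 1)
  group <- unique(vapply(exposures, function(e) e$group, character(1)))
  if (length(group) != 1) abort_invalid("exposures must share one demographic group")
  edi <- do.call(rbind, lapply(exposures, function(e) e$summary))
  rownames(edi) <- names(exposures)
  hq <- t(vapply(names(exposures), function(a) {
    if (is.null(tox[[a]])) abort_invalid("no tox params for ", a)
    hazard_quotient(exposures[[a]]$summary, tox[[a]]$tdi)
  }, numeric(5)))
  hi <- if (all(c("DEHP", "DBP") %in% names(exposures))) {
    hazard_index(exposures[["DEHP"]]$summary, exposures[["DBP"]]$summary, tox)
  } else NULL
  structure(list(group = group, edi = edi, hq = hq, hi = hi, ci = cis,
                 tox = tox), class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report>", x$group, "\n EDI ug/(kg bw)/day:\n")
  print(round(x$edi, 3))
  cat(" HQ:\n")
  print(round(x$hq, 3))
  if (!is.null(x$hi)) {
    cat(" HI:\n")
    print(round(x$hi, 3))
  }
  invisible(x)
}

#' Write risk-report tables (CSV mirror of the EDI/HQ and HI tables + JSON)
#'
#' Writes `<stem>_edi_hq.csv` (per-analyte EDI summaries with optional CIs
#' and HQ at mean/P95, 3-decimal rounding), `<stem>_hi.csv` (HI at the five
#' summary points) and `<stem>.json` (full precision).
#'
#' @param report A [risk_report()] or list of them (one per group).
#' @param stem Output path stem (no extension).
#' @return Invisibly, the paths written.
#' @export
write_risk_report <- function(report, stem) {
  reports <- if (inherits(report, "risk_report")) list(report) else report
  edi_rows <- list(); hi_rows <- list(); js <- list()
  for (r in reports) {
    for (a in rownames(r$edi)) {
      ci_txt <- rep("", 5)
      if (!is.null(r$ci[[a]])) {
        cif <- r$ci[[a]]$ci
        ci_txt <- sprintf("(%.3f, %.3f)", cif$lower, cif$upper)
      }
      edi_rows[[paste(r$group, a)]] <- data.frame(
        analyte = a, group = r$group,
        edi_mean = round(r$edi[a, "mean"], 3), ci_mean = ci_txt[1],
        edi_p50 = round(r$edi[a, "p50"], 3), ci_p50 = ci_txt[2],
        edi_p75 = round(r$edi[a, "p75"], 3), ci_p75 = ci_txt[3],
        edi_p95 = round(r$edi[a, "p95"], 3), ci_p95 = ci_txt[4],
        edi_p999 = round(r$edi[a, "p999"], 3), ci_p999 = ci_txt[5],
        hq_mean = round(r$hq[a, "mean"], 3),
        hq_p95 = round(r$hq[a, "p95"], 3))
    }
    if (!is.null(r$hi)) {
      hi_rows[[r$group]] <- data.frame(
        group = r$group, hi_mean = round(r$hi[["mean"]], 3),
        hi_p50 = round(r$hi[["p50"]], 3), hi_p75 = round(r$hi[["p75"]], 3),
        hi_p95 = round(r$hi[["p95"]], 3), hi_p999 = round(r$hi[["p999"]], 3))
    }
    js[[r$group]] <- list(edi = as.data.frame(r$edi), hq = as.data.frame(r$hq),
                          hi = as.list(r$hi))
  }
  paths <- c(paste0(stem, "_edi_hq.csv"), paste0(stem, "_hi.csv"),
             paste0(stem, ".json"))
  utils::write.csv(do.call(rbind, edi_rows), paths[1], row.names = FALSE)
  if (length(hi_rows)) {
    utils::write.csv(do.call(rbind, hi_rows), paths[2], row.names = FALSE)
  }
  jsonlite::write_json(js, paths[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
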
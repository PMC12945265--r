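# Zero-inflated concentration simulation, lognormal consumption modelling
# and Monte Carlo estimated daily intake (EDI).
#
# Units: concentrations in mg/kg (= ug/g), consumption in g/day, body
# weight in kg, so EDI = Cons * C / W lands in ug/(kg bw)/day with no
# conversion factor.

#' Construct a censored concentration dataset
#'
#' One row per analyzed sample. Detected rows carry a measured value;
#' non-detects are censored at the analyte LOD. Values between LOD and LOQ
#' are stored as given (quantifiability is not enforced).
#'
#' @param values Numeric measurements (mg/kg); `NA` for non-detects.
#' @param detected Logical (or 0/1) detection flags; defaults to
#'   `!is.na(values)`.
#' @param lod Analyte limit of detection (mg/kg), a single positive number.
#' @param analyte Analyte name.
#' @param sample_id Optional sample identifiers.
#' @return A `concentration_dataset` with `n_total`, `n_detected` and
#'   `detection_rate`.
#' @export
concentration_dataset <- function(values, detected = NULL, lod, analyte = "analyte",
                                  sample_id = NULL) {
  if (is.null(detected)) detected <- !is.na(values)
  detected <- as.logical(detected)
  if (length(values) != length(detected)) abort_invalid("values/detected length mismatch")
  if (!is.numeric(lod) || length(lod) != 1 || lod <= 0) {
    abort_invalid("lod must be a single positive number")
  }
  if (any(detected & is.na(values))) abort_invalid("detected rows must carry a value")
  if (any(detected & values <= 0, na.rm = TRUE)) {
    abort_invalid("detected concentrations must be > 0")
  }
  n <- length(values)
  structure(list(
    analyte = analyte,
    sample_id = sample_id %||% paste0("S", seq_len(n)),
    values = values, detected = detected, lod = lod,
    n_total = n, n_detected = sum(detected),
    detection_rate = sum(detected) / n
  ), class = "concentration_dataset")
}

#' @export
print.concentration_dataset <- function(x, ...) {
  cat(sprintf("<concentration_dataset> %s | n=%d, detected=%d (%.0f%%), LOD=%.3g mg/kg\n",
              x$analyte, x$n_total, x$n_detected, 100 * x$detection_rate, x$lod))
  if (x$n_detected > 0) {
    cat("positives:", paste(signif(stats::quantile(
      x$values[x$detected], c(0.5, 0.95)), 3), collapse = " / "),
      "(P50 / P95 mg/kg)\n")
  }
  invisible(x)
}

#' Positive (detected) concentrations of a dataset
#' @param dataset A [concentration_dataset()].
#' @export
positive_values <- function(dataset) {
  stopifnot(inherits(dataset, "concentration_dataset"))
  dataset$values[dataset$detected]
}

#' Read a concentration CSV
#'
#' Expected columns: `sample_id`, `analyte`, `value`, `detected` (0/1),
#' `lod`. The `value` field may be empty when `detected == 0`.
#'
#' @param path CSV file path.
#' @param analyte Optional analyte to filter on; by default a list of
#'   datasets, one per analyte present, is returned.
#' @return A [concentration_dataset()] (single analyte) or named list.
#' @export
read_concentration_csv <- function(path, analyte = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "analyte", "value", "detected", "lod")
  if (!all(need %in% names(df))) {
    abort_invalid("concentration CSV must have columns: ",
                  paste(need, collapse = ", "))
  }
  build <- function(d) {
    concentration_dataset(values = as.numeric(d$value),
                          detected = d$detected == 1,
                          lod = unique(as.numeric(d$lod))[1],
                          analyte = d$analyte[1], sample_id = d$sample_id)
  }
  if (!is.null(analyte)) return(build(df[df$analyte == analyte, ]))
  out <- lapply(split(df, df$analyte), build)
  if (length(out) == 1) out[[1]] else out
}

#' Write a concentration dataset to CSV
#' @param dataset A [concentration_dataset()].
#' @param path Output path.
#' @export
write_concentration_csv <- function(dataset, path) {
  df <- data.frame(sample_id = dataset$sample_id, analyte = dataset$analyte,
                   value = ifelse(dataset$detected, dataset$values, ""),
                   detected = as.integer(dataset$detected), lod = dataset$lod)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- consumption -----------------------------------------------------------

#' Construct a lognormal consumption model
#'
#' Daily intake (g/day) follows a lognormal law, optionally truncated to a
#' positive interval by rejection sampling.
#'
#' @param log_mean Mean of log-intake.
#' @param log_sd SD of log-intake, `> 0`.
#' @param lower,upper Optional truncation bounds (g/day), positive and
#'   ordered.
#' @return A `consumption_model`.
#' @export
consumption_model <- function(log_mean, log_sd, lower = NULL, upper = NULL) {
  if (!is.finite(log_mean) || !is.finite(log_sd) || log_sd <= 0) {
    abort_invalid("need finite log_mean and log_sd > 0")
  }
  if (!is.null(lower) || !is.null(upper)) {
    lower <- lower %||% 0
    upper <- upper %||% Inf
    if (lower < 0 || upper <= lower) abort_invalid("truncation bounds must be positive and ordered")
  }
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 lower = lower, upper = upper),
            class = "consumption_model")
}

#' @export
print.consumption_model <- function(x, ...) {
  cat(sprintf("<consumption_model> logN(%.4g, %.4g) g/day", x$log_mean, x$log_sd))
  if (!is.null(x$lower)) cat(sprintf(" truncated to [%.3g, %.3g]", x$lower, x$upper))
  cat("\n")
  invisible(x)
}

#' Calibrate a lognormal consumption model from intake percentiles
#'
#' Least-squares fit of `(log_mean, log_sd)` to the log-quantiles: with
#' `log q_p = mu + sigma * z_p`, a linear regression of `log(value)` on
#' `qnorm(p)` recovers the parameters, exactly so when only two percentile
#' pairs are supplied.
#'
#' @param probs Percentile levels in (0, 1), at least two.
#' @param values Corresponding intakes (g/day), positive and increasing.
#' @return A [consumption_model()].
#' @export
#' @examples
#' consumption_from_percentiles(c(0.5, 0.975), exp(c(3, 3 + 1.96 * 0.5)))
consumption_from_percentiles <- function(probs, values) {
  if (length(probs) < 2 || length(probs) != length(values)) {
    abort_invalid("need >= 2 (prob, value) pairs")
  }
  ord <- order(probs)
  probs <- probs[ord]; values <- values[ord]
  if (any(probs <= 0 | probs >= 1)) abort_invalid("probs must be in (0, 1)")
  if (any(values <= 0) || any(diff(values) <= 0)) {
    abort_invalid("values must be positive and increasing in prob")
  }
  z <- stats::qnorm(probs)
  fit <- stats::lm.fit(cbind(1, z), log(values))
  co <- fit$coefficients
  if (co[2] <= 0) abort_invalid("percentile targets imply non-positive log-sd")
  consumption_model(log_mean = unname(co[1]), log_sd = unname(co[2]))
}

#' Range-based fallback calibration
#'
#' Survey min-max intake ranges are mapped to lognormal parameters by
#' treating the endpoints as the P2.5 and P97.5 quantiles; a documented
#' fallback for when only ranges are published. Optionally truncates at the
#' range.
#'
#' @param min_gd,max_gd Range endpoints (g/day).
#' @param truncate Truncate draws to the range? Default `FALSE`.
#' @return A [consumption_model()].
#' @export
consumption_from_range <- function(min_gd, max_gd, truncate = FALSE) {
  if (min_gd <= 0 || max_gd <= min_gd) abort_invalid("need 0 < min < max")
  m <- consumption_from_percentiles(c(0.025, 0.975), c(min_gd, max_gd))
  if (truncate) {
    m <- consumption_model(m$log_mean, m$log_sd, lower = min_gd, upper = max_gd)
  }
  m
}

#' Quantiles of a consumption model (ignores truncation)
#' @param model A [consumption_model()].
#' @param p Probabilities.
#' @export
consumption_quantile <- function(model, p) {
  stats::qlnorm(p, model$log_mean, model$log_sd)
}

#' Simulate daily consumption
#'
#' Lognormal draws; with truncation bounds set, out-of-bounds draws are
#' resampled (rejection). A truncation interval holding less than 1e-4
#' probability mass errors out rather than stalling.
#'
#' @param model A [consumption_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Intake vector (g/day).
#' @export
simulate_consumption <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "consumption_model"), n >= 1)
  with_seed_opt(seed, {
    if (is.null(model$lower)) {
      stats::rlnorm(n, model$log_mean, model$log_sd)
    } else {
      mass <- stats::plnorm(model$upper, model$log_mean, model$log_sd) -
        stats::plnorm(model$lower, model$log_mean, model$log_sd)
      if (mass < 1e-4) abort_invalid("truncation interval mass < 1e-4")
      out <- numeric(0)
      while (length(out) < n) {
        draw <- stats::rlnorm(ceiling((n - length(out)) / mass * 1.1) + 10,
                              model$log_mean, model$log_sd)
        out <- c(out, draw[draw >= model$lower & draw <= model$upper])
      }
      out[seq_len(n)]
    }
  })
}

# --- demographic groups ----------------------------------------------------

#' Construct a demographic group
#'
#' @param label Group label (e.g. `"M, 7-13 years"`).
#' @param age_band Age band string (years).
#' @param sex `"male"` or `"female"`.
#' @param weight_kg Mean body weight (kg), `> 0`.
#' @param consumption A [consumption_model()].
#' @return A `demographic_group`.
#' @export
demographic_group <- function(label, age_band, sex, weight_kg, consumption) {
  if (!is.numeric(weight_kg) || weight_kg <= 0) abort_invalid("weight_kg must be > 0")
  stopifnot(inherits(consumption, "consumption_model"))
  structure(list(label = label, age_band = age_band, sex = sex,
                 weight_kg = weight_kg, consumption = consumption),
            class = "demographic_group")
}

#' Read a demographics table (CSV or JSON)
#'
#' CSV columns: `label`, `age_band`, `sex`, `weight_kg` and either
#' `log_mean`/`log_sd` or a percentile block `p50`, `p75`, `p95`, ...
#' (column names `p<percent>`). JSON mirrors the same fields per group.
#'
#' @param path File path (`.csv` or `.json`).
#' @return Named list of [demographic_group()] objects.
#' @export
read_demographics <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("label", "age_band", "sex", "weight_kg")
  if (!all(need %in% names(df))) {
    abort_invalid("demographics table needs columns: ", paste(need, collapse = ", "))
  }
  pcols <- grep("^p[0-9.]+$", names(df), value = TRUE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    cm <- if (all(c("log_mean", "log_sd") %in% names(df)) &&
              is.finite(row$log_mean) && is.finite(row$log_sd)) {
      consumption_model(row$log_mean, row$log_sd)
    } else if (length(pcols) >= 2) {
      probs <- as.numeric(sub("^p", "", pcols)) / 100
      consumption_from_percentiles(probs, as.numeric(row[pcols]))
    } else {
      abort_invalid("row ", i, ": need log_mean/log_sd or >= 2 percentile columns")
    }
    demographic_group(row$label, row$age_band, row$sex, row$weight_kg, cm)
  })
  names(out) <- df$label
  out
}

# --- zero-inflated concentration simulation and EDI ------------------------

#' Simulate zero-inflated concentrations with sub-LOD imputation
#'
#' Per iteration a Bernoulli detection indicator is drawn at the observed
#' detection rate; detected iterations draw from the fitted positive-
#' concentration model, non-detects are imputed as Uniform(0, LOD).
#'
#' @param fitted Fitted positive-concentration model (any `conc_fit`), the
#'   selection winner.
#' @param detection_rate Probability of detection in `[0, 1]`.
#' @param lod Limit of detection (mg/kg).
#' @param n Number of simulated concentrations.
#' @param seed Optional integer seed.
#' @return Concentration vector (mg/kg).
#' @export
simulate_concentration <- function(fitted, detection_rate, lod, n, seed = NULL) {
  if (detection_rate < 0 || detection_rate > 1) {
    abort_invalid("detection_rate must be in [0, 1]")
  }
  if (n < 1) abort_invalid("n must be >= 1")
  with_seed_opt(seed, {
    det <- stats::runif(n) < detection_rate
    out <- stats::runif(n, 0, lod) # sub-LOD imputation for non-detects
    if (any(det)) out[det] <- fit_sample(fitted, sum(det))
    out
  })
}

#' Estimated daily intake
#'
#' `EDI_i = Cons_i * C_i / W`: consumption (g/day) times concentration
#' (mg/kg, i.e. ug/g) over body weight (kg) gives ug/(kg bw)/day with no
#' extra unit factor. Inputs are paired per Monte Carlo iteration.
#'
#' @param cons Consumption draws (g/day), nonnegative.
#' @param conc Concentration draws (mg/kg), nonnegative, same length.
#' @param weight_kg Mean body weight (kg), `> 0`.
#' @return EDI vector, ug/(kg bw)/day.
#' @export
#' @examples
#' compute_edi(100, 0.5, 50) # 1 ug/(kg bw)/day
compute_edi <- function(cons, conc, weight_kg) {
  if (length(cons) != length(conc)) abort_invalid("cons and conc must be paired (same length)")
  if (weight_kg <= 0) abort_invalid("weight_kg must be > 0")
  if (any(cons < 0) || any(conc < 0)) abort_invalid("inputs must be nonnegative")
  cons * conc / weight_kg
}

#' Simulate the exposure distribution for one analyte and group
#'
#' Draws independent consumption and concentration streams (the pipeline
#' pairs them per iteration with no modelled dependence), computes the EDI
#' vector and its percentile summary.
#'
#' @param fitted Fitted positive-concentration model.
#' @param detection_rate Detection probability.
#' @param lod LOD (mg/kg).
#' @param group A [demographic_group()].
#' @param n_sim Monte Carlo size (default 10000).
#' @param seed Optional integer master seed (consumption and concentration
#'   use derived sub-seeds).
#' @param analyte Analyte label carried into the result.
#' @return An `exposure_distribution`: `draws`, `summary`
#'   (mean/P50/P75/P95/P99.9), `analyte`, `group`, `n_sim`.
#' @export
simulate_exposure <- function(fitted, detection_rate, lod, group,
                              n_sim = 10000, seed = NULL, analyte = "analyte") {
  stopifnot(inherits(group, "demographic_group"))
  cons <- simulate_consumption(group$consumption, n_sim,
                               seed = if (is.null(seed)) NULL else derive_seed(seed, "cons"))
  conc <- simulate_concentration(fitted, detection_rate, lod, n_sim,
                                 seed = if (is.null(seed)) NULL else derive_seed(seed, "conc"))
  edi <- compute_edi(cons, conc, group$weight_kg)
  structure(list(analyte = analyte, group = group$label, draws = edi,
                 summary = percentile_summary(edi), n_sim = n_sim),
            class = "exposure_distribution")
}

#' @export
print.exposure_distribution <- function(x, ...) {
  cat(sprintf("<exposure_distribution> %s | %s | n_sim=%d\n",
              x$analyte, x$group, x$n_sim))
  print(round(x$summary, 4))
  invisible(x)
}
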
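# High-level workflow: configuration, stage orchestration and provenance.
# Each stage writes outputs consumed by the next; every output embeds the
# config hash and master seed so runs are replayable and auditable.

#' Build and validate a run configuration
#'
#' @param concentration Path to the concentration CSV.
#' @param demographics Path to the demographics CSV/JSON.
#' @param tox Named list of [tox_params()] (default [default_tox_params()]).
#' @param candidates Candidate model labels for selection.
#' @param alpha Stage-1 level (default 0.05).
#' @param n_sim Monte Carlo size (default 10000).
#' @param gof_B GOF bootstrap replicates (default 1000).
#' @param boot_B CI bootstrap replicates (default 100).
#' @param top_k Stage-2 shortlist size (default 3).
#' @param min_pos_mixture Mixture small-n cutoff (default 30).
#' @param seed Master seed (default 1).
#' @param out_dir Output directory (default `"phthalrisk_out"`).
#' @return A validated `run_config`.
#' @export
run_config <- function(concentration, demographics,
                       tox = default_tox_params(),
                       candidates = CANDIDATE_LABELS, alpha = 0.05,
                       n_sim = 10000, gof_B = 1000, boot_B = 100,
                       top_k = 3, min_pos_mixture = 30, seed = 1,
                       out_dir = "phthalrisk_out") {
  if (alpha <= 0 || alpha >= 1) abort_invalid("alpha must be in (0, 1)")
  if (n_sim < 100) abort_invalid("n_sim must be >= 100")
  if (gof_B < 2) abort_invalid("gof_B must be >= 2")
  candidates <- match.arg(candidates, CANDIDATE_LABELS, several.ok = TRUE)
  cfg <- list(concentration = concentration, demographics = demographics,
              tox = tox, candidates = candidates, alpha = alpha,
              n_sim = as.integer(n_sim), gof_B = as.integer(gof_B),
              boot_B = as.integer(boot_B), top_k = as.integer(top_k),
              min_pos_mixture = as.integer(min_pos_mixture),
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; tox entries are rebuilt into [tox_params()].
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @param out_dir Optional output-directory override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_invalid("yaml package unavailable; use a JSON config")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("inputs", "analytes", "tox", "candidates", "selection",
             "bootstrap", "n_sim", "seed", "out_dir")
  extra <- setdiff(names(raw), known)
  if (length(extra)) abort_invalid("unknown config keys: ", paste(extra, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  tox <- default_tox_params()
  if (!is.null(raw$tox)) {
    for (a in names(raw$tox)) {
      t <- raw$tox[[a]]
      tox[[a]] <- tox_params(a, tdi = t$tdi,
                             rpf = t$rpf %||% 1, group_tdi = t$group_tdi %||% 50)
    }
  }
  sel <- raw$selection %||% list()
  run_config(
    concentration = resolve(raw$inputs$concentration),
    demographics = resolve(raw$inputs$demographics),
    tox = tox,
    candidates = raw$candidates %||% CANDIDATE_LABELS,
    alpha = sel$alpha %||% 0.05,
    n_sim = raw$n_sim %||% 10000,
    gof_B = sel$gof_B %||% 1000,
    boot_B = (raw$bootstrap %||% list())$B %||% 100,
    top_k = sel$top_k %||% 3,
    seed = raw$seed %||% 1,
    out_dir = out_dir %||% raw$out_dir %||% file.path(base, "out"))
}

#' MD5 hash of a configuration (provenance stamp)
#' @param cfg A `run_config` (or any JSON-serializable list).
#' @return Hex MD5 string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

# serialize a fitted model so downstream stages can rebuild it
fit_to_list <- function(fit) {
  list(label = fit_label(fit), spec = truth_to_list(fit$spec),
       loglik = fit$loglik, n = fit$n, k = fit$k, aic = fit$aic,
       bic = fit$bic, converged = fit$converged)
}

fit_from_list <- function(x) {
  spec <- truth_from_list(x$spec)
  cls <- switch(x$spec$kind, dist = c("fit_result", "conc_fit"),
                evmm = c("evmm_fit", "conc_fit"),
                mixture = c("mixture_fit", "conc_fit"))
  structure(list(spec = spec, loglik = x$loglik, n = x$n, k = x$k,
                 aic = x$aic, bic = x$bic, converged = x$converged),
            class = cls)
}

#' Run model selection for every analyte in a configuration
#'
#' Reads the concentration table, runs the three-stage protocol per
#' analyte on the detected positives, and writes
#' `select_<analyte>.json` (winner spec, full candidate table, config
#' hash, seed) into the output directory.
#'
#' @param cfg A [run_config()].
#' @param ... Overrides threaded to [select_model()].
#' @return Named list of `selection_report`s (invisible file side-effects).
#' @export
run_selection <- function(cfg, ...) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  datasets <- read_concentration_csv(cfg$concentration)
  if (inherits(datasets, "concentration_dataset")) {
    datasets <- stats::setNames(list(datasets), datasets$analyte)
  }
  hash <- config_hash(cfg)
  out <- list()
  for (a in names(datasets)) {
    ds <- datasets[[a]]
    rep <- select_model(positive_values(ds), candidates = cfg$candidates,
                        alpha = cfg$alpha, B = cfg$gof_B, n_sim = cfg$n_sim,
                        top_k = cfg$top_k,
                        seed = derive_seed(cfg$seed, paste0("select-", a)),
                        min_pos_mixture = cfg$min_pos_mixture, ...)
    out[[a]] <- rep
    payload <- list(analyte = a, config_hash = hash, seed = cfg$seed,
                    detection_rate = ds$detection_rate, lod = ds$lod,
                    n_total = ds$n_total, n_detected = ds$n_detected,
                    status = rep$status, winner = rep$winner,
                    table = rep$table,
                    winner_fit = if (!is.null(rep$winner_fit))
                      fit_to_list(rep$winner_fit))
    jsonlite::write_json(payload,
                         file.path(cfg$out_dir, paste0("select_", a, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(out)
}

read_selection_artifact <- function(cfg, analyte, stage = "assess") {
  p <- file.path(cfg$out_dir, paste0("select_", analyte, ".json"))
  if (!file.exists(p)) {
    abort_invalid("`", stage, "` needs ", p,
                  "; run the `select` subcommand first")
  }
  jsonlite::read_json(p, simplifyVector = FALSE)
}

#' Run the exposure and risk assessment stage
#'
#' Consumes the `select_<analyte>.json` artifacts, simulates exposure for
#' every demographic group and analyte, computes HQ (and HI when both DEHP
#' and DBP are present), and writes `assess.json` plus the report CSVs.
#'
#' @param cfg A [run_config()].
#' @param with_ci Also run the data-level bootstrap CIs (slower)?
#' @param ... Overrides threaded to [bootstrap_ci()] (e.g. `refit_args`).
#' @return Named list of [risk_report()]s per group.
#' @export
run_assessment <- function(cfg, with_ci = FALSE, ...) {
  stopifnot(inherits(cfg, "run_config"))
  groups <- read_demographics(cfg$demographics)
  datasets <- read_concentration_csv(cfg$concentration)
  if (inherits(datasets, "concentration_dataset")) {
    datasets <- stats::setNames(list(datasets), datasets$analyte)
  }
  hash <- config_hash(cfg)
  arts <- lapply(names(datasets), function(a) read_selection_artifact(cfg, a))
  names(arts) <- names(datasets)
  reports <- list()
  for (gl in names(groups)) {
    exposures <- list(); cis <- list()
    for (a in names(datasets)) {
      art <- arts[[a]]
      if (is.null(art$winner_fit) || length(art$winner_fit) == 0) {
        abort_invalid("selection for ", a, " found no adequate model")
      }
      fit <- fit_from_list(art$winner_fit)
      sd_ga <- derive_seed(cfg$seed, paste0("mc-", gl, "-", a))
      exposures[[a]] <- simulate_exposure(
        fit, art$detection_rate, art$lod, groups[[gl]],
        n_sim = cfg$n_sim, seed = sd_ga, analyte = a)
      if (with_ci) {
        cis[[a]] <- bootstrap_ci(
          datasets[[a]], fit, groups[[gl]], B = cfg$boot_B,
          n_sim = cfg$n_sim,
          seed = derive_seed(cfg$seed, paste0("ci-", gl, "-", a)), ...)
      }
    }
    reports[[gl]] <- risk_report(exposures, tox = cfg$tox,
                                 cis = if (with_ci) cis else NULL)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- lapply(reports, function(r) {
    list(group = r$group, edi = as.data.frame(r$edi), hq = as.data.frame(r$hq),
         hi = as.list(r$hi),
         ci = if (!is.null(r$ci)) lapply(r$ci, function(ci) ci$ci))
  })
  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed, groups = js),
                       file.path(cfg$out_dir, "assess.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_risk_report(reports, file.path(cfg$out_dir, "report"))
  invisible(reports)
}
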
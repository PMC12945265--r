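# Shared fixtures, all generated in code (no binary files).

# a lognormal-bulk EVMM with a moderately heavy tail, used across tests
lgpd_truth <- function() {
  evmm_spec(dist_spec("lognormal", meanlog = -1.5, sdlog = 0.9),
            threshold = stats::qlnorm(0.88, -1.5, 0.9),
            gpd_shape = 0.4, gpd_scale = 0.3)
}

# well-separated two-component gamma mixture
gamma2_truth <- function() {
  mixture_spec(c(0.4, 0.6),
               list(dist_spec("gamma", shape = 2, rate = 8),
                    dist_spec("gamma", shape = 30, rate = 20)))
}

# random valid single-family specs for property-style sweeps
random_spec <- function(family, seed) {
  withr::with_seed(seed, switch(family,
    lognormal = dist_spec("lognormal", meanlog = stats::runif(1, -2, 1),
                          sdlog = stats::runif(1, 0.2, 1.5)),
    weibull = dist_spec("weibull", shape = stats::runif(1, 0.5, 4),
                        scale = stats::runif(1, 0.1, 3)),
    gamma = dist_spec("gamma", shape = stats::runif(1, 0.5, 8),
                      rate = stats::runif(1, 0.3, 10)),
    exponential = dist_spec("exponential", rate = stats::runif(1, 0.2, 5)),
    gpd = dist_spec("gpd", shape = stats::runif(1, -0.3, 0.8),
                    scale = stats::runif(1, 0.2, 2), loc = stats::runif(1, 0, 1))
  ))
}

# small censored dataset with known truth for exposure/risk tests
make_dataset <- function(truth = dist_spec("lognormal", meanlog = -2, sdlog = 0.6),
                         n = 91, rate = 0.55, lod = 0.1, seed = 1) {
  withr::with_seed(seed, {
    det <- stats::runif(n) < rate
    v <- rep(NA_real_, n)
    v[det] <- pmax(dist_sample(truth, sum(det)), lod)
    concentration_dataset(v, det, lod = lod, analyte = "X")
  })
}

test_group <- function() {
  demographic_group("G1", "18-49", "male", weight_kg = 60,
                    consumption_model(log_mean = 4, log_sd = 0.5))
}
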
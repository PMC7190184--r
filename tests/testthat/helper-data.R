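# shared fixtures and independent oracles, all built in code at test time

# tiny datasets trip the small-n warning by design
toy_dataset <- function(time, event, exposure, mediators, covariates = NULL) {
  suppressWarnings(survival_dataset(time = time, event = event,
                                    exposure = exposure,
                                    mediators = mediators,
                                    covariates = covariates))
}

# brute-force Breslow log partial likelihood by explicit risk-set enumeration
loglik_oracle <- function(time, event, X, beta) {
  eta <- drop(as.matrix(X) %*% beta)
  s <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      R <- which(time >= time[i])
      s <- s + eta[i] - log(sum(exp(eta[R])))
    }
  }
  s
}

# quick simulated dataset with a fixed censoring bound (skips calibration)
sim_quick <- function(n, p, seed, c0 = 1.4, ...) {
  simulate_dataset(simulation_config(n = n, p = p, c0 = c0, ...),
                   seed = seed)
}
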
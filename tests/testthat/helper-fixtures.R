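# Shared fixtures, all built in code.

study_times <- c(-15, 15, 30, 60, 120, 360)

# three-compartment linear cascade (zero delays, no removal): impulse of
# 10 %DNA into n0 at t = 0, detection 0.4/min, processing 0.03/min
cascade_params <- function() {
  modelParameters(kcleav = 0,
                  fast = pathwayRates(k0 = 0.4, k1 = 0.03, k2 = 0, tr = 0),
                  bn = 0)
}

cascade_init <- function() {
  c(n0 = 10, n1_fast = 0, n1_slow = 0, n2_fast = 0, n2_slow = 0)
}

# independent oracle: matrix-exponential solution of the linear chain
cascade_exact <- function(times) {
  A <- matrix(c(-0.4, 0, 0,
                0.4, -0.03, 0,
                0, 0.03, 0), 3, 3, byrow = TRUE)
  vapply(times,
         function(t) as.numeric(Matrix::expm(A * t) %*% c(10, 0, 0)),
         numeric(3))
}

# compartment-wise max relative error of a cascade simulation vs the oracle
cascade_sim_error <- function(step, method = "rk4",
                              times = c(15, 30, 60, 120, 360)) {
  exact <- cascade_exact(times)
  tr <- simulateDamage(cascade_params(),
                       irradiationProtocol(dose = 0, pulseDuration = 2),
                       horizon = max(times) + 1,
                       solverConfig(step = step, method = method),
                       init = cascade_init())
  sim <- vapply(times, function(t) {
    i <- which.min(abs(tr@times - t))
    tr@states[i, c("n0", "n1_fast", "n2_fast")]
  }, numeric(3))
  max(abs(sim - exact) / pmax(abs(exact), 1e-8))
}

# noise-free median time-course implied by the pooled one-pathway truth
truth_series <- function() {
  truth <- pooledSarcomaParameters()
  pr <- irradiationProtocol()
  traj <- simulateDamage(truth, pr, max(study_times) + 3,
                         solverConfig(step = 0.05))
  y <- ifelse(study_times < 0, baselineSignal(truth), NA_real_)
  pos <- study_times >= 0
  y[pos] <- sampleObservable(traj, 2 + study_times[pos])
  observationSeries(study_times, y)
}

# small per-cell comet table with a known shift between T0 and T30
shifted_comet_records <- function(n = 300, shift = 10, seed = 99) {
  withr::with_seed(seed, {
    data.frame(
      patient = "P01", fraction = 1L,
      timepoint = rep(c("T0", "T30"), each = n),
      time_min = rep(c(-15, 30), each = n),
      cell = rep(seq_len(n), 2),
      tail_intensity = pmin(c(rgamma(n, 4, 1), rgamma(n, 4, 1) + shift),
                            100))
  })
}
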
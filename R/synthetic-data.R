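#' @include AllClasses.R dde-engine.R
NULL

#' Reference parameter sets for the pooled sarcoma time-course
#'
#' The kinetic constants estimated for the pooled soft-tissue-sarcoma
#' median %DNA-in-tail time-course under a 6 Gy fraction: the
#' one-pathway reduction (default) and the full two-pathway fit. These
#' serve as ground truth for the synthetic-data generators and as
#' worked-example inputs.
#'
#' @param pathwayMode `"one"` or `"two"`
#' @return a [ModelParameters-class]
#' @examples
#' pooledSarcomaParameters()
#' @export
pooledSarcomaParameters <- function(pathwayMode = c("one", "two")) {
  pathwayMode <- match.arg(pathwayMode)
  if (pathwayMode == "one")
    modelParameters(kcleav = 1.93,
                    fast = pathwayRates(k0 = 3.93e-1, k1 = 2.92e-2,
                                        k2 = 1.00e-2, tr = 12.8),
                    slow = pathwayRates(0, 0, 0, 0), bn = 4.23)
  else
    modelParameters(kcleav = 1.96,
                    fast = pathwayRates(k0 = 1.59e-1, k1 = 3.44e-2,
                                        k2 = 9.01e-3, tr = 10.9),
                    slow = pathwayRates(k0 = 3.22e-3, k1 = 1.01e-3,
                                        k2 = 1.23e2, tr = 7.07),
                    bn = 4.09)
}

#' Published difference-of-medians time-course fixture
#'
#' The printed differences of median tail intensity versus the
#' pre-treatment baseline at 15, 30, 60, 120 and 360 min after the end
#' of irradiation (10.80, 11.24, 7.11, 2.47, 1.24 %DNA), represented as
#' an observation series above a zero baseline with a pre-treatment
#' point of 0. Whether such published values are differences of pooled
#' medians or medians of paired differences is not stated; the fixture
#' treats them as a time-course of median excess over baseline and the
#' metadata records that assumption.
#'
#' @return an [ObservationSeries-class] with
#'   `metadata$difference_series = TRUE`
#' @export
table1Fixture <- function() {
  observationSeries(
    time = c(-15, 15, 30, 60, 120, 360),
    median = c(0, 10.80, 11.24, 7.11, 2.47, 1.24),
    metadata = list(
      difference_series = TRUE,
      assumption = "median excess over the pre-treatment baseline",
      ci_lower = c(NA, 6.56, 6.38, 4.52, -1.41, -0.86),
      ci_upper = c(NA, 15.04, 16.10, 9.71, 6.36, 3.33)))
}

.observable_at_design_times <- function(truth, protocol, times,
                                        solver = solverConfig()) {
  horizon <- protocol@pulseStart + protocol@pulseDuration +
    max(max(times), 1) + solver@step
  traj <- simulateDamage(truth, protocol, horizon, solver)
  t_abs <- protocol@pulseStart + protocol@pulseDuration + times
  obs <- numeric(length(times))
  pre <- t_abs < 0
  obs[pre] <- truth@bn
  if (any(!pre)) obs[!pre] <- sampleObservable(traj, t_abs[!pre])
  obs
}

.total_damage_at_design_times <- function(truth, protocol, times, tau,
                                          solver = solverConfig()) {
  horizon <- protocol@pulseStart + protocol@pulseDuration +
    max(max(times), 1) + solver@step
  traj <- simulateDamage(truth, protocol, horizon, solver)
  tot <- traj@observable - truth@bn
  if (tau > 0) {
    ## first-order persistence: foci linger after the underlying damage
    ## is removed (tau s' = damage - s), integrated on the solver grid
    s <- numeric(length(tot))
    dt <- diff(traj@times)
    for (i in seq_along(dt))
      s[i + 1] <- s[i] + dt[i] / tau * (tot[i] - s[i])
    tot <- s
  }
  t_abs <- protocol@pulseStart + protocol@pulseDuration + times
  out <- numeric(length(times))
  pre <- t_abs < 0
  if (any(!pre))
    out[!pre] <- stats::approx(traj@times, tot, xout = t_abs[!pre])$y
  out
}

#' Generate a synthetic per-cell comet dataset
#'
#' For every patient, fraction and time point of the design, per-cell
#' tail intensities are drawn from a Gamma distribution whose mean is
#' the model observable at that time multiplied by lognormal patient and
#' fraction heterogeneity factors, with the design's coefficient of
#' variation. A contamination fraction of cells is replaced by uniform
#' high-intensity draws (sanguineous contamination / early-apoptotic
#' cells), and all values are clipped to [0, 100] %DNA. Pre-treatment
#' time points draw around the baseline `bn`. The output is a pure
#' function of (inputs, seed).
#'
#' @param truth ground-truth [ModelParameters-class]
#' @param protocol an [IrradiationProtocol-class]
#' @param design a [SyntheticDesign-class]
#' @param seed RNG seed
#' @param solver a [SolverConfig-class]
#' @return data.frame of per-cell records (`patient`, `fraction`,
#'   `timepoint`, `time_min`, `cell`, `tail_intensity`)
#' @export
generateCometDataset <- function(truth, protocol, design, seed = 1,
                                 solver = solverConfig()) {
  stopifnot(is(design, "SyntheticDesign"))
  validObject(design)
  times <- design@timepoints
  obs <- .observable_at_design_times(truth, protocol, times, solver)
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(design@nPatients)) {
      fpat <- if (design@patientScale > 0)
        exp(rnorm(1, 0, design@patientScale)) else 1
      for (f in seq_len(design@nFractions)) {
        ffrac <- if (design@fractionScale > 0)
          exp(rnorm(1, 0, design@fractionScale)) else 1
        for (k in seq_along(times)) {
          m <- obs[k] * fpat * ffrac
          nc <- design@cellsPerSample
          if (nc == 0L) next
          if (design@noiseCV > 1e-8 && m > 0) {
            shape <- 1 / design@noiseCV^2
            x <- rgamma(nc, shape = shape, rate = shape / m)
          } else {
            x <- rep(m, nc)
          }
          if (design@contaminationFraction > 0) {
            contam <- runif(nc) < design@contaminationFraction
            if (any(contam))
              x[contam] <- runif(sum(contam), design@contaminationRange[1],
                                 design@contaminationRange[2])
          }
          rows[[length(rows) + 1L]] <- data.frame(
            patient = sprintf("P%02d", p), fraction = f,
            timepoint = names(times)[k], time_min = unname(times[k]),
            cell = seq_len(nc), tail_intensity = pmin(pmax(x, 0), 100))
        }
      }
    }
    if (!length(rows))
      return(data.frame(patient = character(), fraction = integer(),
                        timepoint = character(), time_min = numeric(),
                        cell = integer(), tail_intensity = numeric()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic per-cell focus-count dataset
#'
#' Raw per-nucleus focus counts are Poisson with mean
#' `baseline + signalScale * damage(t) * patient factor`, where
#' `damage(t)` is the total modelled damage, optionally passed through a
#' first-order persistence filter (time constant
#' `design@fociPersistenceTau`) that emulates the slower decay of
#' gamma-H2AX foci relative to the comet signal. Capping is NOT applied
#' here; it belongs to the scoring summaries ([applyFociCap()]).
#'
#' @inheritParams generateCometDataset
#' @return data.frame of per-cell records (`patient`, `timepoint`,
#'   `time_min`, `cell`, `foci_raw`); zero requested cells yields an
#'   empty data.frame
#' @export
generateH2axDataset <- function(truth, protocol, design, seed = 1,
                                solver = solverConfig()) {
  stopifnot(is(design, "SyntheticDesign"))
  validObject(design)
  times <- design@fociTimepoints
  dmg <- .total_damage_at_design_times(truth, protocol, times,
                                       design@fociPersistenceTau, solver)
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(design@nPatients)) {
      fpat <- if (design@patientScale > 0)
        exp(rnorm(1, 0, design@patientScale)) else 1
      for (k in seq_along(times)) {
        lambda <- design@fociBaselineRate +
          design@fociSignalScale * dmg[k] * fpat
        nc <- design@fociCellsPerSample
        if (nc == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          patient = sprintf("P%02d", p), timepoint = names(times)[k],
          time_min = unname(times[k]), cell = seq_len(nc),
          foci_raw = rpois(nc, lambda))
      }
    }
    if (!length(rows))
      return(data.frame(patient = character(), timepoint = character(),
                        time_min = numeric(), cell = integer(),
                        foci_raw = integer()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a generation manifest
#'
#' Records the ground-truth parameters, protocol, design and seed of a
#' generated dataset as JSON, so every synthetic dataset is fully
#' reproducible from its manifest.
#'
#' @param truth,protocol,design,seed the generator inputs
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
writeManifest <- function(truth, protocol, design, seed, path) {
  m <- list(
    truth = as.list(paramVector(truth)),
    protocol = list(dose = protocol@dose, pulse_start = protocol@pulseStart,
                    pulse_duration = protocol@pulseDuration),
    design = list(
      n_patients = design@nPatients, n_fractions = design@nFractions,
      timepoints = as.list(design@timepoints),
      cells_per_sample = design@cellsPerSample, noise_cv = design@noiseCV,
      patient_scale = design@patientScale,
      fraction_scale = design@fractionScale,
      contamination_fraction = design@contaminationFraction,
      contamination_range = design@contaminationRange,
      foci_timepoints = as.list(design@fociTimepoints),
      foci_baseline_rate = design@fociBaselineRate,
      foci_signal_scale = design@fociSignalScale,
      foci_persistence_tau = design@fociPersistenceTau,
      foci_cells_per_sample = design@fociCellsPerSample),
    seed = seed)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
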
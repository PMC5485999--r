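#' @import methods
#' @importFrom stats median quantile rnorm runif rgamma rpois optim setNames
#' @importFrom utils read.csv write.csv modifyList
#' @useDynLib cometRepair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.compartments <- c("n0", "n1_fast", "n1_slow", "n2_fast", "n2_slow")

## canonical flat key order shared by serialization, fitting and the CLI
.param_keys <- c("kcleav", "k0_fast", "k1_fast", "k2_fast", "tr_fast",
                 "k0_slow", "k1_slow", "k2_slow", "tr_slow", "bn", "epsilon")

#' Per-pathway kinetic rate constants
#'
#' One repair pathway of the damage model: first-order detection (`k0`),
#' first-order processing delayed by `tr`, and second-order final repair
#' (`k2`). Rates `k0` and `k1` are in 1/min, `k2` is per %DNA per min and
#' `tr` is in minutes.
#'
#' @slot k0 detection rate (1/min)
#' @slot k1 processing rate (1/min)
#' @slot k2 final-repair rate (per %DNA per min)
#' @slot tr processing delay (min)
#' @export
setClass("PathwayRates",
  representation(k0 = "numeric", k1 = "numeric", k2 = "numeric",
                 tr = "numeric"),
  prototype(k0 = 0, k1 = 0, k2 = 0, tr = 0))

setValidity("PathwayRates", function(object) {
  v <- c(k0 = object@k0, k1 = object@k1, k2 = object@k2, tr = object@tr)
  if (any(lengths(list(object@k0, object@k1, object@k2, object@tr)) != 1L))
    return("all rate slots must be length 1")
  if (any(!is.finite(v))) return("all rates must be finite")
  if (any(v < 0)) return("all rates and the delay must be >= 0")
  TRUE
})

#' @param k0,k1,k2,tr see the class slots
#' @rdname PathwayRates-class
#' @export
pathwayRates <- function(k0 = 0, k1 = 0, k2 = 0, tr = 0) {
  new("PathwayRates", k0 = as.numeric(k0), k1 = as.numeric(k1),
      k2 = as.numeric(k2), tr = as.numeric(tr))
}

#' Full parameter set of the two-pathway damage model
#'
#' Holds the cleavage constant `kcleav` (%DNA per Gy), the fast and slow
#' pathway rate blocks, the baseline comet signal `bn` (%DNA) and the
#' dose-equivalent `epsilon` (Gy) of pre-existing breaks used only by the
#' extended induction mode. A one-pathway model is represented by a slow
#' block whose rates are all zero (see [reduceToOnePathway()]).
#'
#' @slot kcleav cleavage constant (%DNA per Gy)
#' @slot fast,slow [PathwayRates-class] blocks
#' @slot bn baseline signal (%DNA)
#' @slot epsilon dose-equivalent of pre-existing breaks (Gy)
#' @export
setClass("ModelParameters",
  representation(kcleav = "numeric", fast = "PathwayRates",
                 slow = "PathwayRates", bn = "numeric", epsilon = "numeric"),
  prototype(kcleav = 0, bn = 0, epsilon = 0))

setValidity("ModelParameters", function(object) {
  if (length(object@kcleav) != 1L || !is.finite(object@kcleav) ||
      object@kcleav < 0)
    return("kcleav must be a single finite value >= 0")
  if (length(object@bn) != 1L || !is.finite(object@bn) || object@bn < 0)
    return("bn must be a single finite value >= 0")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon < 0)
    return("epsilon must be a single finite value >= 0")
  TRUE
})

#' @param kcleav,fast,slow,bn,epsilon see the class slots
#' @rdname ModelParameters-class
#' @export
modelParameters <- function(kcleav = 0, fast = pathwayRates(),
                            slow = pathwayRates(), bn = 0, epsilon = 0) {
  new("ModelParameters", kcleav = as.numeric(kcleav), fast = fast,
      slow = slow, bn = as.numeric(bn), epsilon = as.numeric(epsilon))
}

#' Irradiation protocol of one radiotherapy fraction
#'
#' A rectangular dose-rate pulse: `dose` Gy delivered at the constant rate
#' `dose / pulseDuration` between `pulseStart` and
#' `pulseStart + pulseDuration` (minutes). The default emulates a 6 Gy
#' fraction delivered over 2 min, the order of magnitude of a clinical
#' linac fraction.
#'
#' @slot dose absorbed dose of the fraction (Gy)
#' @slot pulseStart pulse onset (min); simulations start at t = 0
#' @slot pulseDuration beam-on time (min)
#' @export
setClass("IrradiationProtocol",
  representation(dose = "numeric", pulseStart = "numeric",
                 pulseDuration = "numeric"),
  prototype(dose = 6, pulseStart = 0, pulseDuration = 2))

setValidity("IrradiationProtocol", function(object) {
  if (object@dose < 0) return("dose must be >= 0")
  if (object@pulseStart < 0) return("pulseStart must be >= 0")
  if (object@pulseDuration <= 0) return("pulseDuration must be > 0")
  R <- object@dose / object@pulseDuration
  if (object@dose > 0 &&
      abs(R * object@pulseDuration - object@dose) > 1e-12 * object@dose)
    return("dose rate times duration must reproduce the dose")
  TRUE
})

#' @param dose,pulseStart,pulseDuration see the class slots
#' @rdname IrradiationProtocol-class
#' @export
irradiationProtocol <- function(dose = 6, pulseStart = 0,
                                pulseDuration = 2) {
  new("IrradiationProtocol", dose = as.numeric(dose),
      pulseStart = as.numeric(pulseStart),
      pulseDuration = as.numeric(pulseDuration))
}

#' Solver configuration for the delay-differential integrator
#'
#' @slot step fixed step size (min)
#' @slot method `"rk4"` or `"euler"`
#' @slot clampPolicy `"limit-outflow"` (scale the delayed outflow so no
#'   compartment can cross zero within a step, mass-preserving) or
#'   `"hard-clamp"` (floor negatives after the step)
#' @export
setClass("SolverConfig",
  representation(step = "numeric", method = "character",
                 clampPolicy = "character"),
  prototype(step = 0.05, method = "rk4", clampPolicy = "limit-outflow"))

setValidity("SolverConfig", function(object) {
  if (object@step <= 0) return("step must be > 0")
  if (!object@method %in% c("rk4", "euler"))
    return("method must be 'rk4' or 'euler'")
  if (!object@clampPolicy %in% c("limit-outflow", "hard-clamp"))
    return("clampPolicy must be 'limit-outflow' or 'hard-clamp'")
  TRUE
})

#' @param step,method,clampPolicy see the class slots
#' @rdname SolverConfig-class
#' @export
solverConfig <- function(step = 0.05, method = c("rk4", "euler"),
                         clampPolicy = c("limit-outflow", "hard-clamp")) {
  new("SolverConfig", step = as.numeric(step), method = match.arg(method),
      clampPolicy = match.arg(clampPolicy))
}

#' Simulated damage trajectory
#'
#' Grid times, the five damage compartments per grid point, and the
#' observable comet signal (sum of all compartments plus the baseline
#' `bn`).
#'
#' @slot times strictly increasing grid (min), starting at 0
#' @slot states numeric matrix with columns `n0`, `n1_fast`, `n1_slow`,
#'   `n2_fast`, `n2_slow` (%DNA)
#' @slot observable %DNA in tail per grid point
#' @slot nClamped number of steps on which the clamping policy activated
#' @slot parameters,protocol,config the inputs that produced the trajectory
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix",
                 observable = "numeric", nClamped = "integer",
                 parameters = "ModelParameters",
                 protocol = "IrradiationProtocol", config = "SolverConfig"))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (nrow(object@states) != n || length(object@observable) != n)
    return("times, states and observable must have equal lengths")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!identical(colnames(object@states), .compartments))
    return("states columns must be the five damage compartments")
  if (!identical(object@observable,
                 unname(rowSums(object@states)) + object@parameters@bn))
    return("observable must equal the compartment sum plus bn")
  TRUE
})

#' Observed median tail-intensity time-course
#'
#' Times are minutes after the end of the irradiation pulse; negative
#' times mark pre-treatment samples (the model predicts the baseline `bn`
#' there). Optional lower/upper quartiles may accompany each median.
#'
#' @slot time minutes after pulse end (strictly increasing)
#' @slot median median %DNA in tail per time point
#' @slot q1,q3 optional quartiles (NA when absent)
#' @slot metadata free-form list (patient/fraction ids, pooled flag, ...)
#' @export
setClass("ObservationSeries",
  representation(time = "numeric", median = "numeric", q1 = "numeric",
                 q3 = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("ObservationSeries", function(object) {
  n <- length(object@time)
  if (n == 0L) return("at least one observation is required")
  if (length(object@median) != n || length(object@q1) != n ||
      length(object@q3) != n)
    return("time, median, q1 and q3 must have equal lengths")
  if (n > 1 && any(diff(object@time) <= 0))
    return("times must be strictly increasing")
  if (any(object@median < 0 | object@median > 100))
    return("medians must lie in [0, 100] %DNA")
  ok <- is.na(object@q1) | is.na(object@q3) |
    (object@q1 <= object@median & object@median <= object@q3)
  if (!all(ok)) return("quartiles must bracket the median")
  TRUE
})

#' @param time,median,q1,q3,metadata see the class slots
#' @rdname ObservationSeries-class
#' @export
observationSeries <- function(time, median, q1 = NA_real_, q3 = NA_real_,
                              metadata = list()) {
  n <- length(time)
  new("ObservationSeries", time = as.numeric(time),
      median = as.numeric(median),
      q1 = rep_len(as.numeric(q1), n), q3 = rep_len(as.numeric(q3), n),
      metadata = metadata)
}

#' Configuration of the evolutionary parameter search
#'
#' Rates (including `kcleav`) are searched in log10 space, the delay `tr`
#' and the baseline `bn` linearly. `bounds` is a named list of
#' `c(lower, upper)` pairs in natural units; see [defaultFitBounds()].
#'
#' @slot pathwayMode `"one"` or `"two"`
#' @slot bounds named list of `c(lower, upper)` in natural units
#' @slot popSize,generations,eliteCount evolution-strategy budget
#' @slot mutationScale mutation s.d. in log10 units for rate parameters
#' @slot polish run a Nelder-Mead refinement from the best individual
#' @slot seed RNG seed recorded in the result
#' @export
setClass("FitConfig",
  representation(pathwayMode = "character", bounds = "list",
                 popSize = "integer", generations = "integer",
                 mutationScale = "numeric", eliteCount = "integer",
                 polish = "logical", seed = "integer"),
  prototype(pathwayMode = "one", bounds = list(), popSize = 32L,
            generations = 200L, mutationScale = 0.25, eliteCount = 4L,
            polish = TRUE, seed = 1L))

setValidity("FitConfig", function(object) {
  if (!object@pathwayMode %in% c("one", "two"))
    return("pathwayMode must be 'one' or 'two'")
  if (object@popSize < 2L) return("popSize must be >= 2")
  if (object@generations < 1L) return("generations must be >= 1")
  if (object@eliteCount < 1L || object@eliteCount >= object@popSize)
    return("eliteCount must be in [1, popSize)")
  if (object@mutationScale <= 0) return("mutationScale must be > 0")
  for (b in object@bounds) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2])
      return("each bound must be a finite ordered c(lower, upper) pair")
  }
  TRUE
})

#' @param pathwayMode,bounds,popSize,generations,mutationScale,eliteCount,polish,seed
#'   see the class slots
#' @rdname FitConfig-class
#' @export
fitConfig <- function(pathwayMode = c("one", "two"), bounds = list(),
                      popSize = 32, generations = 200, mutationScale = 0.25,
                      eliteCount = 4, polish = TRUE, seed = 1) {
  new("FitConfig", pathwayMode = match.arg(pathwayMode), bounds = bounds,
      popSize = as.integer(popSize), generations = as.integer(generations),
      mutationScale = as.numeric(mutationScale),
      eliteCount = as.integer(eliteCount), polish = as.logical(polish),
      seed = as.integer(seed))
}

#' Result of a parameter fit
#'
#' @slot parameters fitted [ModelParameters-class]
#' @slot error sum of squared errors over the observed medians,
#'   recomputed from `parameters` at report time
#' @slot rmse `sqrt(error / n)` over the n observed medians
#' @slot trace best error after each generation (non-increasing)
#' @slot seed RNG seed of the run
#' @slot config echo of the [FitConfig-class] used
#' @export
setClass("FitResult",
  representation(parameters = "ModelParameters", error = "numeric",
                 rmse = "numeric", trace = "numeric", seed = "integer",
                 config = "FitConfig"))

setValidity("FitResult", function(object) {
  if (length(object@trace) > 1 && any(diff(object@trace) > 1e-12))
    return("trace must be non-increasing")
  TRUE
})

#' Design of a synthetic per-cell assay study
#'
#' Describes the sampling design emulated by the generators: a
#' fractionated radiotherapy course with per-cell comet scoring at fixed
#' offsets around each fraction, Gamma-distributed per-cell tail
#' intensities, lognormal inter-patient and inter-fraction heterogeneity,
#' a small fraction of high-intensity contamination outliers, and
#' Poisson-distributed nuclear focus counts tied to total damage.
#'
#' @slot nPatients,nFractions,cellsPerSample study size
#' @slot timepoints named vector, label -> minutes after pulse end
#'   (negative = pre-treatment)
#' @slot noiseCV per-cell coefficient of variation of the Gamma noise
#' @slot patientScale,fractionScale lognormal sigma of the multiplicative
#'   patient and fraction random effects
#' @slot contaminationFraction,contaminationRange fraction of cells
#'   replaced by uniform draws in the stated %DNA range
#' @slot fociTimepoints named vector of focus-count sampling times
#' @slot fociBaselineRate,fociSignalScale Poisson mean =
#'   baseline + scale * total damage
#' @slot fociPersistenceTau time constant (min) of the optional
#'   first-order persistence filter applied to total damage before
#'   driving foci (0 disables it)
#' @slot fociCellsPerSample nuclei scored per focus-count sample
#' @export
setClass("SyntheticDesign",
  representation(nPatients = "integer", nFractions = "integer",
                 timepoints = "numeric", cellsPerSample = "integer",
                 noiseCV = "numeric", patientScale = "numeric",
                 fractionScale = "numeric",
                 contaminationFraction = "numeric",
                 contaminationRange = "numeric",
                 fociTimepoints = "numeric", fociBaselineRate = "numeric",
                 fociSignalScale = "numeric", fociPersistenceTau = "numeric",
                 fociCellsPerSample = "integer"))

setValidity("SyntheticDesign", function(object) {
  if (object@nPatients < 1L || object@nFractions < 1L)
    return("nPatients and nFractions must be >= 1")
  if (object@cellsPerSample < 0L || object@fociCellsPerSample < 0L)
    return("cell counts must be >= 0")
  if (object@noiseCV < 0) return("noiseCV must be >= 0")
  if (object@contaminationFraction < 0 || object@contaminationFraction >= 1)
    return("contaminationFraction must be in [0, 1)")
  if (is.null(names(object@timepoints)) ||
      is.null(names(object@fociTimepoints)))
    return("timepoints must be named (label -> minutes)")
  if (length(object@contaminationRange) != 2L ||
      object@contaminationRange[1] > object@contaminationRange[2])
    return("contaminationRange must be an ordered pair")
  TRUE
})

#' @param nPatients,nFractions,timepoints,cellsPerSample,noiseCV,patientScale,fractionScale,contaminationFraction,contaminationRange,fociTimepoints,fociBaselineRate,fociSignalScale,fociPersistenceTau,fociCellsPerSample
#'   see the class slots
#' @rdname SyntheticDesign-class
#' @export
syntheticDesign <- function(nPatients = 6, nFractions = 3,
                            timepoints = c(T0 = -15, T15 = 15, T30 = 30,
                                           T60 = 60, T120 = 120, T360 = 360),
                            cellsPerSample = 300, noiseCV = 0.6,
                            patientScale = 0.2, fractionScale = 0.3,
                            contaminationFraction = 0.02,
                            contaminationRange = c(60, 100),
                            fociTimepoints = c(T0 = -15, T30 = 30,
                                               T360 = 360),
                            fociBaselineRate = 0.25, fociSignalScale = 0.8,
                            fociPersistenceTau = 120,
                            fociCellsPerSample = 300) {
  new("SyntheticDesign", nPatients = as.integer(nPatients),
      nFractions = as.integer(nFractions),
      timepoints = timepoints,
      cellsPerSample = as.integer(cellsPerSample),
      noiseCV = as.numeric(noiseCV), patientScale = as.numeric(patientScale),
      fractionScale = as.numeric(fractionScale),
      contaminationFraction = as.numeric(contaminationFraction),
      contaminationRange = as.numeric(contaminationRange),
      fociTimepoints = fociTimepoints,
      fociBaselineRate = as.numeric(fociBaselineRate),
      fociSignalScale = as.numeric(fociSignalScale),
      fociPersistenceTau = as.numeric(fociPersistenceTau),
      fociCellsPerSample = as.integer(fociCellsPerSample))
}
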
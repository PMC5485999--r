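#' @include AllClasses.R
NULL

#' Constant dose rate of a protocol
#'
#' `dose / pulseDuration`, in Gy/min.
#'
#' @param object an [IrradiationProtocol-class]
#' @return dose rate (Gy/min)
#' @export
setGeneric("doseRate", function(object) standardGeneric("doseRate"))

#' @rdname doseRate
#' @export
setMethod("doseRate", "IrradiationProtocol", function(object) {
  object@dose / object@pulseDuration
})

#' Accessors for model parameters
#'
#' `kcleav()` returns the cleavage constant, `baselineSignal()` the
#' co-evolved baseline `bn`, and `pathwayRates()` has its own constructor;
#' `fastPathway()`/`slowPathway()` return the per-pathway rate blocks.
#'
#' @param object a [ModelParameters-class]
#' @name parameter-accessors
NULL

#' @rdname parameter-accessors
#' @export
setGeneric("kcleav", function(object) standardGeneric("kcleav"))
#' @rdname parameter-accessors
#' @export
setMethod("kcleav", "ModelParameters", function(object) object@kcleav)

#' @rdname parameter-accessors
#' @export
setGeneric("baselineSignal", function(object)
  standardGeneric("baselineSignal"))
#' @rdname parameter-accessors
#' @export
setMethod("baselineSignal", "ModelParameters", function(object) object@bn)

#' @rdname parameter-accessors
#' @export
setGeneric("fastPathway", function(object) standardGeneric("fastPathway"))
#' @rdname parameter-accessors
#' @export
setMethod("fastPathway", "ModelParameters", function(object) object@fast)

#' @rdname parameter-accessors
#' @export
setGeneric("slowPathway", function(object) standardGeneric("slowPathway"))
#' @rdname parameter-accessors
#' @export
setMethod("slowPathway", "ModelParameters", function(object) object@slow)

#' Fitted parameters and error of a fit result
#'
#' @param object a [FitResult-class]
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("fittedParameters", function(object)
  standardGeneric("fittedParameters"))
#' @rdname fit-accessors
#' @export
setMethod("fittedParameters", "FitResult", function(object)
  object@parameters)

#' @rdname fit-accessors
#' @export
setGeneric("fitError", function(object) standardGeneric("fitError"))
#' @rdname fit-accessors
#' @export
setMethod("fitError", "FitResult", function(object) object@error)

#' @rdname fit-accessors
#' @export
setGeneric("fitTrace", function(object) standardGeneric("fitTrace"))
#' @rdname fit-accessors
#' @export
setMethod("fitTrace", "FitResult", function(object) object@trace)

setMethod("show", "PathwayRates", function(object) {
  cat(sprintf("PathwayRates: k0=%g/min k1=%g/min k2=%g/(%%DNA min) tr=%g min\n",
              object@k0, object@k1, object@k2, object@tr))
})

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters (", if (isOnePathway(object)) "one" else "two",
      "-pathway)\n", sep = "")
  cat(sprintf("  kcleav: %g %%DNA/Gy   bn: %g %%DNA   epsilon: %g Gy\n",
              object@kcleav, object@bn, object@epsilon))
  cat("  fast: "); show(object@fast)
  cat("  slow: "); show(object@slow)
})

setMethod("show", "IrradiationProtocol", function(object) {
  cat(sprintf(
    "IrradiationProtocol: %g Gy over %g min from t=%g (R = %g Gy/min)\n",
    object@dose, object@pulseDuration, object@pulseStart, doseRate(object)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d points over [0, %g] min (step %g, %s, %d clamped)\n",
    length(object@times), max(object@times), object@config@step,
    object@config@method, object@nClamped))
  cat(sprintf("  observable range: [%.3f, %.3f] %%DNA\n",
              min(object@observable), max(object@observable)))
})

setMethod("show", "ObservationSeries", function(object) {
  cat(sprintf("ObservationSeries: %d time points (%g to %g min)\n",
              length(object@time), min(object@time), max(object@time)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s-pathway): SSE %.6g, RMSE %.6g, seed %d\n",
              object@config@pathwayMode, object@error, object@rmse,
              object@seed))
  show(object@parameters)
})

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(
    "SyntheticDesign: %d patients x %d fractions, %d cells/sample\n",
    object@nPatients, object@nFractions, object@cellsPerSample))
  cat(sprintf("  comet timepoints: %s\n",
              paste(names(object@timepoints), collapse = " ")))
  cat(sprintf("  noise CV %.2f, patient/fraction scales %.2f/%.2f, %.1f%% contamination\n",
              object@noiseCV, object@patientScale, object@fractionScale,
              100 * object@contaminationFraction))
})

#' @describeIn Trajectory-class coerce a trajectory to a data.frame with
#'   columns `time_min`, the five compartments, and `observable`
#' @param x a [Trajectory-class]
#' @param ... unused
#' @export
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(time_min = x@times, as.data.frame(x@states),
              observable = x@observable)
}

#' @describeIn ObservationSeries-class coerce to a data.frame with columns
#'   `time_min`, `median_pct_dna`, `q1`, `q3`
#' @param x an [ObservationSeries-class]
#' @param ... unused
#' @export
as.data.frame.ObservationSeries <- function(x, ...) {
  data.frame(time_min = x@time, median_pct_dna = x@median, q1 = x@q1,
             q3 = x@q3)
}
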
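#' @include AllClasses.R repair-model.R
NULL

.method_code <- c(euler = 0L, rk4 = 1L)
.clamp_code <- c("limit-outflow" = 0L, "hard-clamp" = 1L)
.mode_code <- c(simple = 0L, extended = 1L)

#' Simulate the delayed damage system
#'
#' Fixed-step method-of-steps integration of the two-pathway damage
#' model. The delayed terms `n1,p(t - tr,p)` are read from the stored
#' trajectory by linear interpolation; the history is zero before the
#' simulation start (t = 0, pulse onset). Within each step the
#' rectangular dose-rate pulse enters through its analytic average over
#' the step, which makes the induction quadrature exact regardless of
#' where the pulse edges fall.
#'
#' @param params a [ModelParameters-class]
#' @param protocol an [IrradiationProtocol-class]
#' @param horizon simulation end time (min), must cover the pulse
#' @param config a [SolverConfig-class]
#' @param init optional initial state (named numeric of the five
#'   compartments); defaults to all-zero
#' @param mode induction mode, see [inductionRate()]
#' @return a [Trajectory-class]
#' @examples
#' tr <- simulateDamage(pooledSarcomaParameters(), irradiationProtocol(),
#'                      horizon = 60, config = solverConfig(step = 0.05))
#' head(as.data.frame(tr))
#' @export
simulateDamage <- function(params, protocol, horizon,
                           config = solverConfig(), init = NULL,
                           mode = c("simple", "extended")) {
  mode <- match.arg(mode)
  stopifnot(is(params, "ModelParameters"),
            is(protocol, "IrradiationProtocol"),
            is(config, "SolverConfig"))
  validObject(params); validObject(protocol); validObject(config)
  if (horizon <= 0) stop("horizon must be > 0")
  if (horizon < protocol@pulseStart + protocol@pulseDuration)
    stop("horizon must cover the irradiation pulse")
  delays <- c(params@fast@tr, params@slow@tr)
  pos <- delays[delays > 0]
  if (length(pos) && config@step > min(pos))
    warning("step exceeds the smallest positive delay; ",
            "delayed lookups are clamped to the current grid point")
  iv <- rep(0, 5)
  if (!is.null(init)) {
    init <- init[.compartments]
    if (anyNA(init)) stop("init must name the five compartments")
    if (any(init < 0)) stop("negative compartment in init")
    iv <- as.numeric(init)
  }
  sim <- cpp_dde_integrate(paramVector(params), protocol@dose,
                           protocol@pulseStart, protocol@pulseDuration,
                           horizon, config@step,
                           .method_code[[config@method]],
                           .clamp_code[[config@clampPolicy]],
                           .mode_code[[mode]], iv)
  new("Trajectory", times = sim$times, states = sim$states,
      observable = unname(rowSums(sim$states)) + params@bn,
      nClamped = as.integer(sim$n_clamped), parameters = params,
      protocol = protocol, config = config)
}

#' Delayed-history lookup
#'
#' Value of a stored series at an earlier query time: 0 before the series
#' start (the zero pre-simulation history), linear interpolation between
#' grid points otherwise. Querying beyond the last stored time is an
#' error — the integrator never looks into its own future.
#'
#' @param times strictly increasing grid times
#' @param values stored values, same length
#' @param query query time (min); vectorized
#' @return interpolated value(s)
#' @export
historyValue <- function(times, values, query) {
  stopifnot(length(times) == length(values))
  if (any(query > times[length(times)] + 1e-12))
    stop("query time beyond the stored history")
  out <- rep(0, length(query))
  inside <- query >= times[1]
  if (any(inside))
    out[inside] <- stats::approx(times, values, xout = pmin(query[inside],
                                 times[length(times)]))$y
  out
}

#' Sample the observable of a trajectory
#'
#' Linear interpolation of the observable %DNA-in-tail at the requested
#' times, which must lie within the trajectory span.
#'
#' @param trajectory a [Trajectory-class]
#' @param times times (min) within the trajectory span
#' @return numeric vector of %DNA values (empty for empty `times`)
#' @export
sampleObservable <- function(trajectory, times) {
  stopifnot(is(trajectory, "Trajectory"))
  if (length(times) == 0L) return(numeric(0))
  tr <- trajectory@times
  if (any(times < tr[1] - 1e-12 | times > tr[length(tr)] + 1e-12))
    stop("requested time outside the trajectory span")
  stats::approx(tr, trajectory@observable, xout = times, rule = 2)$y
}

#' Export a trajectory to CSV
#'
#' Columns: `time_min`, `n0`, `n1_fast`, `n1_slow`, `n2_fast`, `n2_slow`,
#' `observable`.
#'
#' @param trajectory a [Trajectory-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
exportTrajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
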
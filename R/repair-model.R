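#' @include AllClasses.R
NULL

## flat named vector in the canonical key order; the layout the C++
## integrator and the serializers share
paramVector <- function(params) {
  stopifnot(is(params, "ModelParameters"))
  c(kcleav = params@kcleav,
    k0_fast = params@fast@k0, k1_fast = params@fast@k1,
    k2_fast = params@fast@k2, tr_fast = params@fast@tr,
    k0_slow = params@slow@k0, k1_slow = params@slow@k1,
    k2_slow = params@slow@k2, tr_slow = params@slow@tr,
    bn = params@bn, epsilon = params@epsilon)
}

paramsFromVector <- function(v) {
  v <- v[.param_keys]
  if (anyNA(v)) {
    miss <- .param_keys[is.na(v)]
    miss <- setdiff(miss, "epsilon")   # epsilon is optional, defaults to 0
    if (length(miss))
      stop("missing parameter key(s): ", paste(miss, collapse = ", "))
    v["epsilon"] <- 0
  }
  modelParameters(
    kcleav = v[["kcleav"]],
    fast = pathwayRates(v[["k0_fast"]], v[["k1_fast"]], v[["k2_fast"]],
                        v[["tr_fast"]]),
    slow = pathwayRates(v[["k0_slow"]], v[["k1_slow"]], v[["k2_slow"]],
                        v[["tr_slow"]]),
    bn = v[["bn"]], epsilon = v[["epsilon"]])
}

#' Is a parameter set in one-pathway form?
#'
#' The one-pathway model is the two-pathway model with all slow-pathway
#' rates forced to zero.
#'
#' @param params a [ModelParameters-class]
#' @return logical
#' @export
isOnePathway <- function(params) {
  params@slow@k0 == 0 && params@slow@k1 == 0 && params@slow@k2 == 0
}

#' Instantaneous dose rate of a rectangular pulse
#'
#' Returns `dose / pulseDuration` for times inside
#' `[pulseStart, pulseStart + pulseDuration)` and 0 outside.
#'
#' @param protocol an [IrradiationProtocol-class]
#' @param t time (min); vectorized
#' @return dose rate (Gy/min)
#' @examples
#' p <- irradiationProtocol(dose = 6, pulseDuration = 2)
#' doseRateAt(p, 1)   # 3 Gy/min
#' doseRateAt(p, 5)   # 0
#' @export
doseRateAt <- function(protocol, t) {
  stopifnot(is(protocol, "IrradiationProtocol"))
  validObject(protocol)
  if (protocol@dose == 0) return(rep(0, length(t)))
  R <- doseRate(protocol)
  inside <- t >= protocol@pulseStart &
    t < protocol@pulseStart + protocol@pulseDuration
  ifelse(inside, R, 0)
}

#' Damage induction rate
#'
#' In `simple` mode primary damage is produced at `kcleav * R`; the
#' `extended` mode adds the dependence on the already absorbed dose and a
#' dose-equivalent of pre-existing breaks, `kcleav * R * (epsilon + D)`.
#' No saturation of target sites is applied.
#'
#' @param params a [ModelParameters-class]
#' @param R dose rate (Gy/min), >= 0
#' @param D cumulative absorbed dose (Gy), >= 0; used only in extended mode
#' @param mode `"simple"` (default) or `"extended"`
#' @return induction rate (%DNA/min)
#' @export
inductionRate <- function(params, R, D = 0, mode = c("simple", "extended")) {
  mode <- match.arg(mode)
  stopifnot(R >= 0, D >= 0)
  if (mode == "simple") params@kcleav * R
  else params@kcleav * R * (params@epsilon + D)
}

#' Right-hand side of the delayed damage system
#'
#' Evaluates the compartment derivatives at time `t` given the current
#' state and the delayed detected-damage levels `n1,p(t - tr,p)`:
#' \deqn{dn_0/dt = \mathrm{induction} - (k_{0,f} + k_{0,s}) n_0}
#' \deqn{dn_{1,p}/dt = k_{0,p} n_0 - k_{1,p} n_{1,p}(t - t_{r,p})}
#' \deqn{dn_{2,p}/dt = k_{1,p} n_{1,p}(t - t_{r,p}) - k_{2,p} n_{2,p}^2}
#' The delayed transfer term appears identically in the outflow of
#' `n1,p` and the inflow of `n2,p`, so mass is preserved exactly by the
#' transfer.
#'
#' @param t time (min)
#' @param state named numeric of the five compartments (`n0`, `n1_fast`,
#'   `n1_slow`, `n2_fast`, `n2_slow`), all >= 0
#' @param delayedN1Fast,delayedN1Slow `n1,p` at `t - tr,p` (0 before the
#'   simulation start)
#' @param params a [ModelParameters-class]
#' @param protocol an [IrradiationProtocol-class]
#' @param mode induction mode, see [inductionRate()]
#' @return named numeric of the five derivatives (%DNA/min)
#' @export
stateDerivative <- function(t, state, delayedN1Fast, delayedN1Slow, params,
                            protocol, mode = c("simple", "extended")) {
  mode <- match.arg(mode)
  state <- state[.compartments]
  if (anyNA(state)) stop("state must contain the five named compartments")
  if (any(state < 0)) stop("negative compartment in input state")
  R <- doseRateAt(protocol, t)
  D <- if (mode == "extended") {
    Rc <- doseRate(protocol)
    max(0, Rc * (min(t, protocol@pulseStart + protocol@pulseDuration) -
                   protocol@pulseStart))
  } else 0
  ind <- inductionRate(params, R, D, mode)
  tf <- params@fast@k1 * delayedN1Fast
  ts <- params@slow@k1 * delayedN1Slow
  c(n0 = ind - (params@fast@k0 + params@slow@k0) * state[["n0"]],
    n1_fast = params@fast@k0 * state[["n0"]] - tf,
    n1_slow = params@slow@k0 * state[["n0"]] - ts,
    n2_fast = tf - params@fast@k2 * state[["n2_fast"]]^2,
    n2_slow = ts - params@slow@k2 * state[["n2_slow"]]^2)
}

#' Observable comet signal of a damage state
#'
#' All damage species migrate into the comet tail, so the observable
#' %DNA in tail is the sum of the five compartments plus the baseline
#' `bn`.
#'
#' @param state named numeric of the five compartments, or a matrix with
#'   the five compartment columns
#' @param bn baseline signal (%DNA)
#' @return %DNA in tail
#' @export
observableSignal <- function(state, bn) {
  if (is.matrix(state)) return(unname(rowSums(state[, .compartments])) + bn)
  sum(state[.compartments]) + bn
}

#' Swap the fast and slow parameter blocks
#'
#' The model is symmetric in its two pathways: exchanging the blocks
#' leaves the observable trajectory unchanged.
#'
#' @param params a [ModelParameters-class]
#' @return a [ModelParameters-class] with the blocks exchanged
#' @export
swapPathways <- function(params) {
  modelParameters(kcleav = params@kcleav, fast = params@slow,
                  slow = params@fast, bn = params@bn,
                  epsilon = params@epsilon)
}

#' Read and write model parameters as flat YAML/JSON
#'
#' The serialized form is a flat mapping with the keys `kcleav`,
#' `k0_fast`, `k1_fast`, `k2_fast`, `tr_fast`, `k0_slow`, `k1_slow`,
#' `k2_slow`, `tr_slow`, `bn` and optionally `epsilon`. The format is
#' chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param params a [ModelParameters-class]
#' @param path file path ending in `.yaml`, `.yml` or `.json`
#' @return `readModelParameters` returns a [ModelParameters-class];
#'   `writeModelParameters` returns `path` invisibly
#' @export
writeModelParameters <- function(params, path) {
  v <- as.list(paramVector(params))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(v, path)
  } else if (ext == "json") {
    jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported parameter file extension: ", ext)
  invisible(path)
}

#' @rdname writeModelParameters
#' @export
readModelParameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported parameter file extension: ", ext)
  v <- setNames(rep(NA_real_, length(.param_keys)), .param_keys)
  for (k in intersect(names(lst), .param_keys)) v[k] <- as.numeric(lst[[k]])
  paramsFromVector(v)
}
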
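#' @include AllClasses.R dde-engine.R
NULL

## transformed search space: rates (incl. kcleav) in log10, delays and
## baseline linear; fitted values span several orders of magnitude
.fit_dims <- function(mode) {
  if (mode == "one")
    list(keys = c("kcleav", "k0_fast", "k1_fast", "k2_fast", "tr_fast",
                  "bn"),
         logs = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  else
    list(keys = c("kcleav", "k0_fast", "k1_fast", "k2_fast", "tr_fast",
                  "k0_slow", "k1_slow", "k2_slow", "tr_slow", "bn"),
         logs = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                  FALSE))
}

#' Default search bounds for a fit
#'
#' Rate constants (including `kcleav`) are bounded to `[1e-4, 1e3]`
#' (searched in log10 space), delays to `[0, 60]` min, and the baseline
#' `bn` to `[0, min(observed medians)]` — the baseline cannot exceed the
#' smallest observed signal.
#'
#' @param obs an [ObservationSeries-class]
#' @param pathwayMode `"one"` or `"two"`
#' @return named list of `c(lower, upper)` pairs in natural units
#' @export
defaultFitBounds <- function(obs, pathwayMode = c("one", "two")) {
  pathwayMode <- match.arg(pathwayMode)
  d <- .fit_dims(pathwayMode)
  b <- list()
  for (i in seq_along(d$keys)) {
    k <- d$keys[i]
    b[[k]] <- if (d$logs[i]) c(1e-4, 1e3)
    else if (k == "bn") c(0, max(0, min(obs@median)))
    else c(0, 60)   # delays
  }
  b
}

## map a transformed point to the 11-element parameter vector
.theta_to_vec <- function(theta, keys, logs) {
  v <- setNames(rep(0, length(.param_keys)), .param_keys)
  nat <- ifelse(logs, 10^theta, theta)
  v[keys] <- nat
  v
}

.obs_abs_times <- function(obs, protocol) {
  protocol@pulseStart + protocol@pulseDuration + obs@time
}

## fast SSE objective on the flat parameter vector
.sse_of_vec <- function(v, obs, protocol, config) {
  pred <- cpp_dde_predict(v, protocol@dose, protocol@pulseStart,
                          protocol@pulseDuration,
                          .obs_abs_times(obs, protocol), config@step,
                          .method_code[[config@method]],
                          .clamp_code[[config@clampPolicy]], 0L)
  sum((pred - obs@median)^2)
}

#' Error of fit between model and observed medians
#'
#' Simulates the model under the protocol, samples the observable at the
#' observation times (pre-treatment times predict the baseline `bn`),
#' and returns the sum of squared errors together with the RMSE and the
#' predicted values.
#'
#' @param params a [ModelParameters-class]
#' @param obs an [ObservationSeries-class]
#' @param protocol an [IrradiationProtocol-class]
#' @param config a [SolverConfig-class]
#' @return list with elements `sse`, `rmse`, `predicted`, `residuals`
#' @export
errorOfFit <- function(params, obs, protocol = irradiationProtocol(),
                       config = solverConfig()) {
  stopifnot(is(params, "ModelParameters"), is(obs, "ObservationSeries"))
  if (length(obs@time) == 0L) stop("empty observation series")
  pred <- cpp_dde_predict(paramVector(params), protocol@dose,
                          protocol@pulseStart, protocol@pulseDuration,
                          .obs_abs_times(obs, protocol), config@step,
                          .method_code[[config@method]],
                          .clamp_code[[config@clampPolicy]], 0L)
  res <- pred - obs@median
  list(sse = sum(res^2), rmse = sqrt(mean(res^2)), predicted = pred,
       residuals = res)
}

#' Reduce a parameter set to the one-pathway model
#'
#' Forces the slow-pathway reaction rates to zero; the slow delay is
#' irrelevant once the rates vanish and all other fields are unchanged.
#' By the fast/slow symmetry of the model this is equivalent to zeroing
#' the fast pathway instead.
#'
#' @param params a [ModelParameters-class]
#' @return a one-pathway [ModelParameters-class]
#' @export
reduceToOnePathway <- function(params) {
  modelParameters(kcleav = params@kcleav, fast = params@fast,
                  slow = pathwayRates(0, 0, 0, params@slow@tr),
                  bn = params@bn, epsilon = params@epsilon)
}

.reflect <- function(x, lb, ub) {
  r <- ub - lb
  deg <- r <= 0
  x[deg] <- lb[deg]
  i <- !deg & (x < lb | x > ub)
  if (any(i)) {
    y <- (x[i] - lb[i]) %% (2 * r[i])
    y <- ifelse(y > r[i], 2 * r[i] - y, y)
    x[i] <- lb[i] + y
  }
  x
}

.transform_bounds <- function(bounds, keys, logs) {
  lb <- vapply(keys, function(k) bounds[[k]][1], 0)
  ub <- vapply(keys, function(k) bounds[[k]][2], 0)
  lb[logs] <- log10(pmax(lb[logs], 1e-12))
  ub[logs] <- log10(pmax(ub[logs], 1e-12))
  list(lb = lb, ub = ub)
}

#' Evolutionary parameter search with gradient refinement
#'
#' A (mu + lambda) evolution strategy with Gaussian mutation and elitism,
#' searching rate constants in log10 space and delay/baseline linearly,
#' followed by an optional Nelder-Mead refinement from the best
#' individual. The baseline `bn` is co-evolved with the kinetic
#' parameters. In one-pathway mode the slow rates are pinned at zero.
#' All random draws come from one generator seeded by `config@seed`, so
#' results are fully reproducible.
#'
#' `initParams` supplies optional warm-start parameter sets: each is
#' injected into the initial population (clamped into the search bounds)
#' and additionally kept verbatim as a final candidate, so the reported
#' error never exceeds the error of any warm start. Injecting a fitted
#' one-pathway optimum into a two-pathway fit therefore guarantees the
#' nested-model property (two-pathway error <= one-pathway error).
#'
#' @param obs an [ObservationSeries-class]
#' @param protocol an [IrradiationProtocol-class]
#' @param config a [FitConfig-class]; bounds not listed in
#'   `config@bounds` fall back to [defaultFitBounds()]
#' @param solver a [SolverConfig-class]
#' @param initParams optional list of [ModelParameters-class] warm starts
#' @return a [FitResult-class]
#' @export
evolutionaryFit <- function(obs, protocol = irradiationProtocol(),
                            config = fitConfig(), solver = solverConfig(),
                            initParams = list()) {
  stopifnot(is(obs, "ObservationSeries"), is(config, "FitConfig"))
  validObject(config)
  if (length(obs@time) == 0L) stop("empty observation series")
  mode <- config@pathwayMode
  d <- .fit_dims(mode)
  bounds <- modifyList(defaultFitBounds(obs, mode), config@bounds)
  tb <- .transform_bounds(bounds, d$keys, d$logs)
  lb <- tb$lb; ub <- tb$ub
  p <- length(d$keys)
  if (all(ub - lb <= 0) && p > 0 && length(initParams) == 0L)
    stop("degenerate bounds: no searchable dimension")

  obj <- function(theta)
    .sse_of_vec(.theta_to_vec(theta, d$keys, d$logs), obs, protocol, solver)

  sigma <- ifelse(d$logs, config@mutationScale,
                  config@mutationScale * (ub - lb) / 5)
  sigma[ub - lb <= 0] <- 0

  pop <- config@popSize
  nelite <- config@eliteCount
  nparent <- max(nelite, pop %/% 2L)

  res <- withr::with_seed(config@seed, {
    theta <- matrix(runif(pop * p, rep(lb, each = pop), rep(ub, each = pop)),
                    nrow = pop)
    if (length(initParams)) {
      for (i in seq_len(min(length(initParams), pop))) {
        v <- paramVector(initParams[[i]])
        t0 <- v[d$keys]
        t0[d$logs] <- log10(pmax(t0[d$logs], 1e-12))
        theta[i, ] <- pmin(pmax(t0, lb), ub)
      }
    }
    sse <- apply(theta, 1L, obj)
    trace <- numeric(config@generations)
    for (g in seq_len(config@generations)) {
      ord <- order(sse)        # ties broken by insertion order
      theta <- theta[ord, , drop = FALSE]
      sse <- sse[ord]
      noff <- pop - nelite
      parents <- theta[sample.int(nparent, noff, replace = TRUE), ,
                       drop = FALSE]
      ## gentle annealing of the mutation scale: coarse exploration
      ## early, fine refinement late
      sig_g <- sigma * max(0.995^(g - 1), 0.05)
      off <- parents + matrix(rnorm(noff * p, sd = rep(sig_g, each = noff)),
                              nrow = noff)
      off <- t(apply(off, 1L, .reflect, lb = lb, ub = ub))
      osse <- apply(off, 1L, obj)
      theta <- rbind(theta[seq_len(nelite), , drop = FALSE], off)
      sse <- c(sse[seq_len(nelite)], osse)
      trace[g] <- min(sse)
    }
    ord <- order(sse)
    theta_best <- theta[ord[1], ]
    sse_best <- sse[ord[1]]
    if (config@polish && any(ub - lb > 0)) {
      pen <- function(th) {
        if (any(th < lb - 1e-9) || any(th > ub + 1e-9))
          return(1e12 + sum(pmax(lb - th, 0) + pmax(th - ub, 0)))
        obj(pmin(pmax(th, lb), ub))
      }
      ## polish the few best individuals: the elite of a multimodal run
      ## often sits in different basins
      for (i in seq_len(min(4L, pop))) {
        op <- optim(theta[ord[i], ], pen, method = "Nelder-Mead",
                    control = list(maxit = 800, reltol = 1e-12))
        if (op$value < sse_best) {
          theta_best <- pmin(pmax(op$par, lb), ub)
          sse_best <- op$value
        }
      }
    }
    list(theta = theta_best, sse = sse_best, trace = cummin(trace))
  })

  best_params <- paramsFromVector(.theta_to_vec(res$theta, d$keys, d$logs))
  best_sse <- res$sse
  ## warm starts compete verbatim (outside the transform), so e.g. an
  ## injected one-pathway optimum with exactly-zero slow rates is never
  ## lost to the log-space lower bound
  for (ip in initParams) {
    s <- .sse_of_vec(paramVector(ip), obs, protocol, solver)
    if (s < best_sse) { best_sse <- s; best_params <- ip }
  }
  fit <- errorOfFit(best_params, obs, protocol, solver)
  new("FitResult", parameters = best_params, error = fit$sse,
      rmse = fit$rmse, trace = res$trace, seed = config@seed,
      config = config)
}

#' Local gradient-style refinement of a parameter set
#'
#' Nelder-Mead descent in the transformed (log-rate) space starting from
#' `params`. The returned parameter set never has a larger error than
#' the input: if no improvement is found, the input is returned.
#'
#' @param params starting [ModelParameters-class]
#' @param obs an [ObservationSeries-class]
#' @param protocol an [IrradiationProtocol-class]
#' @param pathwayMode `"one"`, `"two"`, or `NULL` to infer from `params`
#' @param bounds named bound list; defaults to [defaultFitBounds()]
#' @param solver a [SolverConfig-class]
#' @param maxit Nelder-Mead iteration cap
#' @return a [ModelParameters-class]
#' @export
gradientPolish <- function(params, obs, protocol = irradiationProtocol(),
                           pathwayMode = NULL, bounds = NULL,
                           solver = solverConfig(), maxit = 600) {
  if (is.null(pathwayMode))
    pathwayMode <- if (isOnePathway(params)) "one" else "two"
  d <- .fit_dims(pathwayMode)
  if (is.null(bounds)) bounds <- defaultFitBounds(obs, pathwayMode)
  tb <- .transform_bounds(bounds, d$keys, d$logs)
  lb <- tb$lb; ub <- tb$ub
  v <- paramVector(params)
  th <- v[d$keys]
  th[d$logs] <- log10(pmax(th[d$logs], 1e-12))
  th <- pmin(pmax(th, lb), ub)
  obj <- function(theta)
    .sse_of_vec(.theta_to_vec(theta, d$keys, d$logs), obs, protocol, solver)
  pen <- function(theta) {
    if (any(theta < lb - 1e-9) || any(theta > ub + 1e-9))
      return(1e12 + sum(pmax(lb - theta, 0) + pmax(theta - ub, 0)))
    obj(pmin(pmax(theta, lb), ub))
  }
  start_sse <- .sse_of_vec(v, obs, protocol, solver)
  op <- optim(th, pen, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-12))
  if (op$value < start_sse)
    paramsFromVector(.theta_to_vec(pmin(pmax(op$par, lb), ub), d$keys,
                                   d$logs))
  else params
}

#' Brute-force log-grid search
#'
#' Exhaustive evaluation of the one-pathway SSE objective on a full
#' factorial grid: log10-spaced points for rate constants, linear for the
#' delay and baseline. Degenerate bounds collapse an axis to a single
#' point. Intended as an independent optimality oracle for the
#' evolutionary search, not as a practical fitter.
#'
#' @param obs an [ObservationSeries-class]
#' @param protocol an [IrradiationProtocol-class]
#' @param bounds named bound list; defaults to [defaultFitBounds()]
#' @param pointsPerAxis grid resolution per non-degenerate axis
#' @param solver a [SolverConfig-class]
#' @return list with `parameters`, `error` (the grid minimum SSE) and
#'   `nEvaluated`
#' @export
gridSearchFit <- function(obs, protocol = irradiationProtocol(),
                          bounds = NULL, pointsPerAxis = 8,
                          solver = solverConfig()) {
  d <- .fit_dims("one")
  if (is.null(bounds)) bounds <- defaultFitBounds(obs, "one")
  tb <- .transform_bounds(bounds, d$keys, d$logs)
  axes <- lapply(seq_along(d$keys), function(i) {
    if (tb$ub[i] - tb$lb[i] <= 0) tb$lb[i]
    else seq(tb$lb[i], tb$ub[i], length.out = pointsPerAxis)
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  sse <- vapply(seq_len(nrow(grid)), function(i)
    .sse_of_vec(.theta_to_vec(grid[i, ], d$keys, d$logs), obs, protocol,
                solver), 0)
  best <- which.min(sse)
  list(parameters = paramsFromVector(.theta_to_vec(grid[best, ], d$keys,
                                                   d$logs)),
       error = sse[best], nEvaluated = nrow(grid))
}

#' Read and write observation series / fit results
#'
#' Observation series are CSV files with columns `time_min`,
#' `median_pct_dna` and optional `q1`, `q3`. Fit results are written as
#' flat JSON carrying the canonical parameter key names plus `error`,
#' `rmse`, `seed`, `pathway_mode` and the per-generation error trace.
#'
#' @param path file path
#' @return `readObservationSeries` returns an
#'   [ObservationSeries-class]
#' @export
readObservationSeries <- function(path) {
  df <- read.csv(path)
  need <- c("time_min", "median_pct_dna")
  if (!all(need %in% names(df)))
    stop("observation CSV must have columns: ", paste(need, collapse = ", "))
  observationSeries(df$time_min, df$median_pct_dna,
                    q1 = if ("q1" %in% names(df)) df$q1 else NA_real_,
                    q3 = if ("q3" %in% names(df)) df$q3 else NA_real_)
}

#' @param obs an [ObservationSeries-class]
#' @rdname readObservationSeries
#' @export
writeObservationSeries <- function(obs, path) {
  write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' @param fit a [FitResult-class]
#' @rdname readObservationSeries
#' @export
writeFitResult <- function(fit, path) {
  v <- as.list(paramVector(fit@parameters))
  v$error <- fit@error
  v$rmse <- fit@rmse
  v$seed <- fit@seed
  v$pathway_mode <- fit@config@pathwayMode
  v$trace <- fit@trace
  jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
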
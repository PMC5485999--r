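test_that("error of fit is the SSE over observed medians", {
  pr <- irradiationProtocol()
  # perfect prediction: a rate-free model against its own constant
  obs <- observationSeries(c(10, 20), c(5, 5))
  r <- errorOfFit(modelParameters(bn = 5), obs, pr)
  expect_equal(r$sse, 0)
  expect_equal(r$rmse, 0)
  # single point, predicted 6 vs observed 4
  r2 <- errorOfFit(modelParameters(bn = 6), observationSeries(30, 4), pr)
  expect_equal(r2$sse, 4)
  expect_equal(r2$rmse, 2)
  # published difference series against an all-zero prediction:
  # 10.80^2 + 11.24^2 + 7.11^2 + 2.47^2 + 1.24^2
  r3 <- errorOfFit(modelParameters(), table1Fixture(), pr)
  expect_equal(r3$sse, 301.1682, tolerance = 1e-9)
})

test_that("error of fit matches the simulate-and-sample composition", {
  p <- pooledSarcomaParameters()
  pr <- irradiationProtocol()
  obs <- table1Fixture()
  cfg <- solverConfig(step = 0.05)
  r <- errorOfFit(p, obs, pr, cfg)
  traj <- simulateDamage(p, pr, 365, cfg)
  pred <- ifelse(obs@time < 0, baselineSignal(p), NA_real_)
  pos <- obs@time >= 0
  pred[pos] <- sampleObservable(traj, 2 + obs@time[pos])
  expect_equal(r$predicted, pred, tolerance = 1e-10)
  expect_equal(r$sse, sum((pred - obs@median)^2), tolerance = 1e-10)
  expect_error(errorOfFit(p, observationSeries(1, 1)[0], pr))
})

test_that("one-pathway reduction zeroes the slow block and nothing else", {
  p <- pooledSarcomaParameters("two")
  q <- reduceToOnePathway(p)
  expect_true(isOnePathway(q))
  expect_equal(kcleav(q), kcleav(p))
  expect_equal(fastPathway(q)@k1, fastPathway(p)@k1)
  expect_equal(baselineSignal(q), baselineSignal(p))
  expect_equal(reduceToOnePathway(q), q)        # idempotent
  # structural equivalence: zero-slow full model == reduced model
  pr <- irradiationProtocol()
  a <- simulateDamage(q, pr, 100, solverConfig(0.05))
  manual <- modelParameters(kcleav = kcleav(p), fast = fastPathway(p),
                            slow = pathwayRates(0, 0, 0, 0),
                            bn = baselineSignal(p))
  b <- simulateDamage(manual, pr, 100, solverConfig(0.05))
  expect_equal(a@observable, b@observable)
})

test_that("fits are deterministic given the seed", {
  obs <- table1Fixture()
  cfg <- fitConfig(seed = 5, popSize = 12, generations = 25)
  f1 <- evolutionaryFit(obs, config = cfg)
  f2 <- evolutionaryFit(obs, config = cfg)
  expect_identical(f1@error, f2@error)
  expect_identical(f1@trace, f2@trace)
  expect_equal(fittedParameters(f1), fittedParameters(f2))
})

test_that("a constant series is explained by the baseline alone", {
  obs <- observationSeries(c(-15, 15, 60, 120), rep(6, 4))
  cfg <- fitConfig(seed = 2, popSize = 16, generations = 40,
                   bounds = list(kcleav = c(1e-4, 1e-4)))
  f <- evolutionaryFit(obs, config = cfg)
  expect_lt(abs(baselineSignal(fittedParameters(f)) - 6), 0.01)
  expect_lt(fitError(f), 1e-4)
})

test_that("warm-started fit retains a supplied optimum exactly", {
  truth <- pooledSarcomaParameters()
  obs <- truth_series()
  f <- evolutionaryFit(obs, config = fitConfig(seed = 1, popSize = 16,
                                               generations = 30),
                       initParams = list(truth))
  expect_lt(fitError(f), 1e-8)
  expect_equal(fittedParameters(f), truth)
})

test_that("random-start fit reaches a close fit on noise-free data", {
  obs <- truth_series()
  f <- evolutionaryFit(obs, config = fitConfig(seed = 3, popSize = 48,
                                               generations = 250))
  expect_lt(fitError(f), 1.0)   # RMSE < 0.41 %DNA on signals of ~5-16 %DNA
  expect_true(all(diff(fitTrace(f)) <= 1e-12))
  # the reported error is an independent recomputation from the parameters
  expect_equal(fitError(f),
               errorOfFit(fittedParameters(f), obs,
                          irradiationProtocol())$sse,
               tolerance = 1e-12)
})

test_that("gradient polish never worsens and improves a perturbed start", {
  truth <- pooledSarcomaParameters()
  obs <- truth_series()
  pr <- irradiationProtocol()
  # from the generating optimum the error cannot increase
  p0 <- gradientPolish(truth, obs, pr)
  expect_lte(errorOfFit(p0, obs, pr)$sse, errorOfFit(truth, obs, pr)$sse)
  # +0.1 log10 on all rates (and +1 min on the delay): strict decrease
  pert <- modelParameters(
    kcleav = kcleav(truth) * 10^0.1,
    fast = pathwayRates(fastPathway(truth)@k0 * 10^0.1,
                        fastPathway(truth)@k1 * 10^0.1,
                        fastPathway(truth)@k2 * 10^0.1,
                        fastPathway(truth)@tr + 1),
    bn = baselineSignal(truth))
  e0 <- errorOfFit(pert, obs, pr)$sse
  e1 <- errorOfFit(gradientPolish(pert, obs, pr), obs, pr)$sse
  expect_lt(e1, e0)
})

test_that("observation series and fit results round-trip through files", {
  obs <- table1Fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  writeObservationSeries(obs, f)
  back <- readObservationSeries(f)
  expect_equal(back@time, obs@time)
  expect_equal(back@median, obs@median)
  fit <- evolutionaryFit(obs, config = fitConfig(seed = 1, popSize = 8,
                                                 generations = 10,
                                                 polish = FALSE))
  j <- withr::local_tempfile(fileext = ".json")
  writeFitResult(fit, j)
  parsed <- jsonlite::read_json(j)
  expect_true(all(c("kcleav", "k0_fast", "k1_fast", "k2_fast", "tr_fast",
                    "k0_slow", "k1_slow", "k2_slow", "tr_slow", "bn",
                    "error", "rmse", "seed", "trace") %in% names(parsed)))
  expect_equal(parsed$error, fit@error)
})
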
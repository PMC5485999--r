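test_that("rate-free model holds the baseline constant", {
  p <- modelParameters(bn = 5)
  tr <- simulateDamage(p, irradiationProtocol(dose = 0), 50,
                       solverConfig(step = 0.1))
  expect_true(all(tr@observable == 5))
})

test_that("pure second-order compartment follows the hyperbolic decay", {
  p <- modelParameters(fast = pathwayRates(k2 = 0.01))
  init <- c(n0 = 0, n1_fast = 0, n1_slow = 0, n2_fast = 10, n2_slow = 0)
  tr <- simulateDamage(p, irradiationProtocol(dose = 0), 400,
                       solverConfig(step = 0.01), init = init)
  # closed form n2(t) = n2(0) / (1 + k2 n2(0) t)
  ts <- c(5, 10, 50, 200, 390)
  exact <- 10 / (1 + 0.01 * 10 * ts)
  sim <- sampleObservable(tr, ts)
  expect_lt(max(abs(sim - exact) / exact), 1e-6)
  expect_equal(sim[2], 5, tolerance = 1e-8)
})

test_that("zero-delay cascade matches the matrix-exponential oracle", {
  expect_lt(cascade_sim_error(step = 0.01), 1e-4)
})

test_that("history lookup is zero before start and linear in between", {
  times <- c(0, 1, 2, 3)
  values <- c(0, 2, 4, 1)
  expect_equal(historyValue(times, values, -5), 0)
  expect_equal(historyValue(times, values, 2), 4)
  expect_equal(historyValue(times, values, 1.5), 3)
  expect_error(historyValue(times, values, 4), "beyond")
})

test_that("observable sampling interpolates and respects the span", {
  p <- modelParameters(bn = 4.23)
  tr <- simulateDamage(p, irradiationProtocol(dose = 0), 10,
                       solverConfig(step = 0.5))
  expect_equal(sampleObservable(tr, tr@times), tr@observable)
  expect_equal(sampleObservable(tr, 3.21), 4.23)
  expect_identical(sampleObservable(tr, numeric(0)), numeric(0))
  expect_error(sampleObservable(tr, 11), "span")
})

test_that("halving the step shrinks the rk4 cascade error ~16-fold", {
  ratio <- cascade_sim_error(1) / cascade_sim_error(0.5)
  expect_gte(ratio, 8)
  expect_lte(ratio, 32)
})

test_that("rk4 agrees with a fine-step euler oracle on delayed systems", {
  pr <- irradiationProtocol()
  ts <- 2 + c(15, 30, 60, 120, 360)
  for (s in 1:5) {
    p <- withr::with_seed(40 + s, modelParameters(
      kcleav = 10^runif(1, -0.5, 0.5),
      fast = pathwayRates(10^runif(1, -1.5, 0), 10^runif(1, -2, -1),
                          10^runif(1, -3, -1.5), runif(1, 1, 20)),
      slow = pathwayRates(10^runif(1, -2, -1), 10^runif(1, -3, -1),
                          10^runif(1, -3, -2), runif(1, 1, 20)),
      bn = runif(1, 0, 5)))
    a <- simulateDamage(p, pr, 365, solverConfig(step = 0.05))
    b <- simulateDamage(p, pr, 365, solverConfig(step = 0.001,
                                                 method = "euler"))
    va <- sampleObservable(a, ts)
    vb <- sampleObservable(b, ts)
    expect_lt(max(abs(va - vb) / pmax(vb, 1e-9)), 1e-3)
  }
})

test_that("without final repair the post-pulse total equals kcleav * dose", {
  pr <- irradiationProtocol()
  for (s in 1:3) {
    p <- withr::with_seed(70 + s, modelParameters(
      kcleav = 10^runif(1, -0.5, 0.5),
      fast = pathwayRates(10^runif(1, -1.5, 0), 10^runif(1, -2, -1), 0,
                          runif(1, 1, 15)),
      slow = pathwayRates(10^runif(1, -2, -1), 10^runif(1, -3, -1), 0,
                          runif(1, 1, 15)),
      bn = 0))
    tr <- simulateDamage(p, pr, 200, solverConfig(step = 0.05))
    tot <- rowSums(tr@states)
    post <- tot[tr@times >= 2]
    target <- kcleav(p) * 6
    expect_lt(max(abs(post - target)) / target, 1e-6)
  }
})

test_that("the total damage never grows after the pulse ends", {
  p <- pooledSarcomaParameters()
  tr <- simulateDamage(p, irradiationProtocol(), 365,
                       solverConfig(step = 0.05))
  tot <- rowSums(tr@states)
  post <- tot[tr@times >= 2]
  expect_true(all(diff(post) <= 1e-10))
})

test_that("clamping keeps compartments non-negative and preserves mass", {
  # strong delayed outflow overdraws n1 with a zero pre-start history
  p <- modelParameters(kcleav = 2,
                       fast = pathwayRates(k0 = 1, k1 = 0.8, k2 = 0,
                                           tr = 15),
                       bn = 0)
  pr <- irradiationProtocol()
  a <- simulateDamage(p, pr, 120, solverConfig(step = 0.05))
  expect_gt(a@nClamped, 0)
  expect_true(all(a@states >= 0))
  tot <- rowSums(a@states)
  expect_lt(max(abs(tot[a@times >= 2] - 12)) / 12, 1e-6)  # kcleav * dose
  b <- simulateDamage(p, pr, 120,
                      solverConfig(step = 0.05, clampPolicy = "hard-clamp"))
  expect_true(all(b@states >= 0))
})

test_that("trajectories export and validate", {
  p <- pooledSarcomaParameters()
  tr <- simulateDamage(p, irradiationProtocol(), 30, solverConfig(0.1))
  expect_true(validObject(tr))
  df <- as.data.frame(tr)
  expect_named(df, c("time_min", "n0", "n1_fast", "n1_slow", "n2_fast",
                     "n2_slow", "observable"))
  f <- withr::local_tempfile(fileext = ".csv")
  exportTrajectory(tr, f)
  back <- read.csv(f)
  expect_equal(back$observable, tr@observable, tolerance = 1e-12)
})

test_that("invalid solver inputs are rejected and large steps warn", {
  p <- pooledSarcomaParameters()
  expect_error(simulateDamage(p, irradiationProtocol(), -1), "horizon")
  expect_error(simulateDamage(p, irradiationProtocol(), 1), "pulse")
  expect_error(solverConfig(step = 0))
  expect_warning(
    simulateDamage(modelParameters(fast = pathwayRates(k1 = 0.1, tr = 0.5)),
                   irradiationProtocol(), 10, solverConfig(step = 1)),
    "delay")
})
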
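naive_quantile <- function(x, p) {
  # sort-based linear interpolation, written out independently
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

make_records <- function(values, timepoint = "T15", time_min = 15) {
  data.frame(patient = "P01", fraction = 1L, timepoint = timepoint,
             time_min = time_min, cell = seq_along(values),
             tail_intensity = values)
}

test_that("comet summaries use order statistics with linear quartiles", {
  s <- summarizeComet(make_records(c(2, 4, 6)), "per-sample", nBoot = 100)
  expect_equal(s$median, 4)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 5)
  expect_equal(s$iqr, 2)
  expect_equal(s$n, 3L)
  # identical values: zero-width IQR and CI
  s2 <- summarizeComet(make_records(rep(7, 20)), "per-sample", nBoot = 100)
  expect_equal(s2$median, 7)
  expect_equal(s2$iqr, 0)
  expect_equal(s2$ci_lower, 7)
  expect_equal(s2$ci_upper, 7)
  expect_error(summarizeComet(make_records(c(50, 120))), "\\[0, 100\\]")
})

test_that("median and IQR agree with a naive sort-based oracle", {
  withr::with_seed(123, {
    for (i in 1:100) {
      x <- round(runif(sample(3:40, 1), 0, 100), 2)
      s <- summarizeComet(make_records(x), "per-sample", nBoot = 2)
      expect_equal(s$median, naive_quantile(x, 0.5))
      expect_equal(s$q1, naive_quantile(x, 0.25))
      expect_equal(s$q3, naive_quantile(x, 0.75))
    }
  })
})

test_that("summaries are invariant to record order", {
  rec <- shifted_comet_records(n = 80)
  shuf <- withr::with_seed(1, rec[sample.int(nrow(rec)), ])
  expect_equal(summarizeComet(rec, "per-sample", nBoot = 200, seed = 4),
               summarizeComet(shuf, "per-sample", nBoot = 200, seed = 4))
})

test_that("bootstrap CI of the median brackets it and covers the truth", {
  x <- withr::with_seed(5, rgamma(200, 4, 0.4))
  ci <- bootstrapMedianCI(x, nBoot = 1000, seed = 2)
  expect_lte(ci[["lower"]], median(x))
  expect_gte(ci[["upper"]], median(x))
  expect_true(all(is.na(bootstrapMedianCI(5))))
})

test_that("baseline differences detect a known shift and not a null", {
  rec <- shifted_comet_records(n = 300, shift = 10)
  d <- differencesFromBaseline(rec, nBoot = 500, nPerm = 2000, seed = 1)
  expect_equal(d$timepoint, "T30")
  expect_lt(abs(d$difference - 10), 1)
  expect_lt(d$p.value, 0.001)
  expect_true(d$ci_lower <= d$difference && d$difference <= d$ci_upper)
  # identical distributions: difference 0, large p
  rec0 <- rec
  rec0$tail_intensity[rec0$timepoint == "T30"] <-
    rec0$tail_intensity[rec0$timepoint == "T0"]
  d0 <- differencesFromBaseline(rec0, nBoot = 200, nPerm = 1000, seed = 1)
  expect_equal(d0$difference, 0)
  expect_gt(d0$p.value, 0.5)
  # degenerate single-cell groups: difference computed, CI/p unavailable
  tiny <- rbind(make_records(5, "T0", -15), make_records(9, "T30", 30))
  d1 <- differencesFromBaseline(tiny, seed = 1)
  expect_equal(d1$difference, 4)
  expect_true(is.na(d1$p.value) && is.na(d1$ci_lower))
  expect_error(differencesFromBaseline(make_records(1:3)), "T0")
})

test_that("pooling averages medians and quartiles per time point", {
  a <- observationSeries(c(15, 30), c(4, 8), q1 = c(3, 6), q3 = c(5, 10))
  b <- observationSeries(c(15, 30), c(6, 10), q1 = c(5, 8), q3 = c(7, 12))
  p <- poolTimecourses(list(a, b))
  expect_equal(p@median, c(5, 9))
  expect_equal(p@q1, c(4, 7))
  expect_equal(poolTimecourses(list(a))@median, a@median)
  expect_equal(poolTimecourses(list(b, a))@median, p@median)  # symmetric
  expect_error(poolTimecourses(list(a, observationSeries(15, 4))), "time")
})

test_that("focus capping is literal at the boundary and idempotent", {
  expect_equal(applyFociCap(7), 7)
  expect_equal(applyFociCap(10), 10)
  expect_equal(applyFociCap(11), 25)
  x <- c(0, 3, 10, 11, 40)
  expect_equal(applyFociCap(x), c(0, 3, 10, 25, 25))
  expect_equal(applyFociCap(applyFociCap(x)), applyFociCap(x))
  expect_error(applyFociCap(-1), "negative")
})

test_that("focus summaries report positivity and capped medians", {
  rec <- data.frame(patient = "P01", timepoint = "T30", time_min = 30,
                    cell = 1:4, foci_raw = c(0, 2, 3, 12))
  s <- summarizeH2ax(rec, threshold = 1, nBoot = 100)
  expect_equal(s$pct_positive, 75)
  expect_equal(s$median_foci, 2.5)          # median of capped {0,2,3,25}
  rec0 <- transform(rec, foci_raw = 0)
  s0 <- summarizeH2ax(rec0, nBoot = 100)
  expect_equal(s0$pct_positive, 0)
  expect_equal(s0$median_foci, 0)
  # baseline survey mode: one row per tumor-type group
  base <- data.frame(patient = rep(sprintf("P%02d", 1:8), each = 10),
                     cell = rep(1:10, 8),
                     group = rep(c("sarcoma", "melanoma", "carcinoma",
                                   "lymphoma"), each = 20),
                     foci_raw = withr::with_seed(8, rpois(80, 2.5)))
  sb <- summarizeH2ax(base, by = "group", nBoot = 100)
  expect_equal(nrow(sb), 4)
  expect_setequal(sb$group, c("sarcoma", "melanoma", "carcinoma",
                              "lymphoma"))
  expect_true(all(c("pct_positive", "pct_ci_lower", "median_foci",
                    "foci_ci_lower") %in% names(sb)))
})

test_that("CSV readers skip malformed rows by line, or error in strict mode", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient,fraction,timepoint,time_min,cell,tail_intensity",
               "P01,1,T0,-15,1,4.5",
               "P01,1,T0,-15,2,oops",
               "P01,1,T15,15,1,250",
               "P01,1,T15,15,2,14.2"), f)
  expect_warning(rec <- readCometRecords(f), "3, 4")
  expect_equal(nrow(rec), 2)
  expect_error(readCometRecords(f, strict = TRUE), "malformed")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient,timepoint,time_min,cell,foci_raw",
               "P01,T0,-15,1,2",
               "P01,T0,-15,2,-3"), g)
  expect_warning(fr <- readFociRecords(g), "3")
  expect_equal(nrow(fr), 1)
})
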
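#' @include AllClasses.R
NULL

## Quartile convention: linear interpolation (stats::quantile type 7).
## Tukey hinges differ on small samples; the choice is documented in the
## methods vignette.
.q <- function(x, p) unname(quantile(x, p, type = 7, names = FALSE))

#' Percentile-bootstrap confidence interval of the median
#'
#' @param x numeric sample
#' @param nBoot bootstrap resamples
#' @param level confidence level
#' @param seed RNG seed (one seeded generator drives all resampling)
#' @return named numeric `c(lower, upper)`; `NA` for samples of size 1
#' @export
bootstrapMedianCI <- function(x, nBoot = 2000, level = 0.95, seed = 1) {
  x <- sort(x)    # resampling is then invariant to record order
  n <- length(x)
  if (n < 2L) return(c(lower = NA_real_, upper = NA_real_))
  meds <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
    apply(idx, 2L, function(i) median(x[i]))
  })
  a <- (1 - level) / 2
  ci <- .q(meds, c(a, 1 - a))
  c(lower = ci[1], upper = ci[2])
}

#' Two-sided permutation test on the difference of medians
#'
#' Statistic: `median(x) - median(y)`. The p-value is the fraction of
#' label permutations whose absolute statistic is at least the observed
#' one, with the add-one correction `(1 + k)/(1 + nPerm)`.
#'
#' @param x,y numeric samples
#' @param nPerm number of permutations
#' @param seed RNG seed
#' @return list with `difference` and `p.value` (`NA` p for degenerate
#'   single-observation groups)
#' @export
permutationMedianTest <- function(x, y, nPerm = 10000, seed = 1) {
  x <- sort(x)    # order-invariant permutation draws
  y <- sort(y)
  d <- median(x) - median(y)
  if (length(x) < 2L || length(y) < 2L)
    return(list(difference = d, p.value = NA_real_))
  z <- c(x, y)
  nx <- length(x)
  stat <- withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(i) {
      ix <- sample.int(length(z), nx)
      median(z[ix]) - median(z[-ix])
    }, 0)
  })
  p <- (1 + sum(abs(stat) >= abs(d) - 1e-12)) / (1 + nPerm)
  list(difference = d, p.value = p)
}

.check_comet <- function(records) {
  need <- c("patient", "fraction", "timepoint", "time_min", "cell",
            "tail_intensity")
  if (!all(need %in% names(records)))
    stop("comet records need columns: ", paste(need, collapse = ", "))
  if (any(records$tail_intensity < 0 | records$tail_intensity > 100))
    stop("tail intensity outside [0, 100]")
  records
}

#' Summarize per-cell comet records into median time-courses
#'
#' Per group and time point: cell count, median, quartiles and IQR by
#' direct order statistics (linear-interpolation quartiles), and a 95%
#' percentile-bootstrap confidence interval of the median.
#'
#' @param records data.frame with columns `patient`, `fraction`,
#'   `timepoint`, `time_min`, `cell`, `tail_intensity`
#' @param grouping `"per-sample"` (patient x fraction), `"per-fraction"`
#'   (pooled over patients) or `"per-patient"` (pooled over fractions)
#' @param nBoot bootstrap resamples for the CI
#' @param seed RNG seed
#' @return data.frame, one row per group x time point, with columns
#'   `n`, `median`, `q1`, `q3`, `iqr`, `ci_lower`, `ci_upper`
#' @export
summarizeComet <- function(records,
                           grouping = c("per-sample", "per-fraction",
                                        "per-patient"),
                           nBoot = 2000, seed = 1) {
  grouping <- match.arg(grouping)
  records <- .check_comet(records)
  keys <- switch(grouping,
                 "per-sample" = c("patient", "fraction"),
                 "per-fraction" = "fraction",
                 "per-patient" = "patient")
  keys <- c(keys, "timepoint", "time_min")
  groups <- split(records,
                  lapply(keys, function(k) records[[k]]), drop = TRUE)
  if (any(vapply(groups, nrow, 0L) == 0L)) stop("empty group")
  rows <- lapply(groups, function(g) {
    x <- g$tail_intensity
    ci <- bootstrapMedianCI(x, nBoot = nBoot, seed = seed)
    out <- g[1, keys, drop = FALSE]
    out$n <- length(x)
    out$median <- median(x)
    out$q1 <- .q(x, 0.25)
    out$q3 <- .q(x, 0.75)
    out$iqr <- out$q3 - out$q1
    out$ci_lower <- ci[["lower"]]
    out$ci_upper <- ci[["upper"]]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differences of median tail intensity from the pre-treatment baseline
#'
#' For every post-baseline time point: difference of medians versus the
#' baseline group, a percentile-bootstrap CI of the difference, and a
#' two-sided permutation p-value on the difference of medians. Cells are
#' pooled over patients and fractions within each time point.
#'
#' @param records per-cell comet data.frame (see [summarizeComet()])
#' @param baseline timepoint label of the pre-treatment group
#' @param nBoot bootstrap resamples
#' @param nPerm permutations
#' @param seed RNG seed
#' @return data.frame with one row per non-baseline time point:
#'   `timepoint`, `time_min`, `difference`, `ci_lower`, `ci_upper`,
#'   `p.value` (CI and p are `NA` for single-cell groups)
#' @export
differencesFromBaseline <- function(records, baseline = "T0", nBoot = 2000,
                                    nPerm = 10000, seed = 1) {
  records <- .check_comet(records)
  if (!baseline %in% records$timepoint)
    stop("baseline timepoint '", baseline, "' not present")
  x0 <- sort(records$tail_intensity[records$timepoint == baseline])
  tps <- unique(records[records$timepoint != baseline,
                        c("timepoint", "time_min")])
  tps <- tps[order(tps$time_min), , drop = FALSE]
  rows <- lapply(seq_len(nrow(tps)), function(i) {
    xk <- sort(records$tail_intensity[records$timepoint == tps$timepoint[i]])
    diff <- median(xk) - median(x0)
    if (length(xk) < 2L || length(x0) < 2L) {
      ci <- c(NA_real_, NA_real_); p <- NA_real_
    } else {
      boot <- withr::with_seed(seed, {
        vapply(seq_len(nBoot), function(b) {
          median(xk[sample.int(length(xk), replace = TRUE)]) -
            median(x0[sample.int(length(x0), replace = TRUE)])
        }, 0)
      })
      ci <- .q(boot, c(0.025, 0.975))
      p <- permutationMedianTest(xk, x0, nPerm = nPerm, seed = seed)$p.value
    }
    data.frame(timepoint = tps$timepoint[i], time_min = tps$time_min[i],
               difference = diff, ci_lower = ci[1], ci_upper = ci[2],
               p.value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool per-fraction median time-courses
#'
#' Per time point, the arithmetic mean of the per-series medians;
#' quartile fields are pooled as means of the quartiles. All series must
#' share the same time grid.
#'
#' @param seriesList list of [ObservationSeries-class] objects
#' @return a pooled [ObservationSeries-class]
#' @export
poolTimecourses <- function(seriesList) {
  stopifnot(length(seriesList) >= 1L)
  t0 <- seriesList[[1]]@time
  for (s in seriesList)
    if (!isTRUE(all.equal(s@time, t0)))
      stop("all series must share the same time points")
  med <- rowMeans(vapply(seriesList, function(s) s@median,
                         numeric(length(t0))))
  q1 <- rowMeans(vapply(seriesList, function(s) s@q1, numeric(length(t0))))
  q3 <- rowMeans(vapply(seriesList, function(s) s@q3, numeric(length(t0))))
  observationSeries(t0, med, q1 = q1, q3 = q3,
                    metadata = list(pooled = TRUE,
                                    n_series = length(seriesList)))
}

#' Cap overlapping focus counts
#'
#' At early times after irradiation individual foci overlap and cannot
#' be resolved; cells scored with more than 10 foci are recorded as 25
#' foci per cell. The rule is applied literally: counts of exactly 10
#' are kept.
#'
#' @param raw integer focus counts, >= 0
#' @return capped counts
#' @examples
#' applyFociCap(c(7, 10, 11))   # 7 10 25
#' @export
applyFociCap <- function(raw) {
  if (any(raw < 0)) stop("negative focus count")
  ifelse(raw > 10, 25, raw)
}

#' Summarize gamma-H2AX focus counts
#'
#' Per group: percentage of positive cells (capped count >= `threshold`)
#' with a bootstrap CI, and the median capped foci per nucleus with a
#' bootstrap CI. Grouping is by time point by default; `by = "group"`
#' summarizes a baseline survey by an arbitrary `group` column (e.g.
#' tumor type).
#'
#' @param records data.frame with columns `patient`, `timepoint`,
#'   `time_min`, `cell`, `foci_raw` (plus `group` for baseline mode)
#' @param threshold minimum capped focus count of a positive cell; the
#'   assay itself does not define positivity, so this is a documented
#'   package default, not a measured property
#' @param by `"timepoint"` or `"group"`
#' @param nBoot bootstrap resamples
#' @param seed RNG seed
#' @return data.frame with one row per group: `n`, `pct_positive`,
#'   `pct_ci_lower`, `pct_ci_upper`, `median_foci`, `foci_ci_lower`,
#'   `foci_ci_upper`
#' @export
summarizeH2ax <- function(records, threshold = 1,
                          by = c("timepoint", "group"), nBoot = 2000,
                          seed = 1) {
  by <- match.arg(by)
  need <- c("cell", "foci_raw", if (by == "timepoint") "timepoint" else
              "group")
  if (!all(need %in% names(records)))
    stop("foci records need columns: ", paste(need, collapse = ", "))
  if (any(records$foci_raw < 0)) stop("negative focus count")
  key <- if (by == "timepoint") "timepoint" else "group"
  groups <- split(records, records[[key]], drop = TRUE)
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    if (nrow(g) == 0L) stop("empty group")
    capped <- sort(applyFociCap(g$foci_raw))
    pos <- as.numeric(capped >= threshold)
    pct <- 100 * mean(pos)
    n <- length(capped)
    if (n >= 2L) {
      pct_boot <- withr::with_seed(seed, {
        vapply(seq_len(nBoot), function(b)
          100 * mean(pos[sample.int(n, replace = TRUE)]), 0)
      })
      pct_ci <- .q(pct_boot, c(0.025, 0.975))
      foci_ci <- bootstrapMedianCI(capped, nBoot = nBoot, seed = seed)
    } else {
      pct_ci <- c(NA_real_, NA_real_)
      foci_ci <- c(NA_real_, NA_real_)
    }
    out <- data.frame(n = n, pct_positive = pct,
                      pct_ci_lower = pct_ci[1], pct_ci_upper = pct_ci[2],
                      median_foci = median(capped),
                      foci_ci_lower = unname(foci_ci[1]),
                      foci_ci_upper = unname(foci_ci[2]))
    out[[key]] <- gn
    tm <- if ("time_min" %in% names(g)) g$time_min[1] else NA_real_
    out$time_min <- tm
    out[, c(key, "time_min", setdiff(names(out), c(key, "time_min")))]
  })
  out <- do.call(rbind, rows)
  if (by == "timepoint" && !anyNA(out$time_min))
    out <- out[order(out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write per-cell assay tables
#'
#' Plain comma-separated files with a header row and decimal points, the
#' dialect produced by comet/foci scoring software exports. In
#' non-strict mode malformed rows (non-numeric or out-of-range values)
#' are dropped with a warning naming the offending line numbers; strict
#' mode raises an error instead.
#'
#' @param path CSV file
#' @param strict error on malformed rows instead of skipping them
#' @return data.frame of records
#' @export
readCometRecords <- function(path, strict = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "fraction", "timepoint", "time_min", "cell",
            "tail_intensity")
  if (!all(need %in% names(df)))
    stop("comet CSV must have columns: ", paste(need, collapse = ", "))
  ti <- suppressWarnings(as.numeric(df$tail_intensity))
  tm <- suppressWarnings(as.numeric(df$time_min))
  bad <- which(is.na(ti) | is.na(tm) | ti < 0 | ti > 100)
  if (length(bad)) {
    msg <- paste0("malformed row(s) at line ",
                  paste(bad + 1L, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; skipped")
    df <- df[-bad, , drop = FALSE]
    ti <- ti[-bad]; tm <- tm[-bad]
  }
  df$tail_intensity <- ti
  df$time_min <- tm
  df
}

#' @rdname readCometRecords
#' @export
readFociRecords <- function(path, strict = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "timepoint", "time_min", "cell", "foci_raw")
  if (!all(need %in% names(df)))
    stop("foci CSV must have columns: ", paste(need, collapse = ", "))
  fr <- suppressWarnings(as.numeric(df$foci_raw))
  bad <- which(is.na(fr) | fr < 0 | fr != round(fr))
  if (length(bad)) {
    msg <- paste0("malformed row(s) at line ",
                  paste(bad + 1L, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; skipped")
    df <- df[-bad, , drop = FALSE]
    fr <- fr[-bad]
  }
  df$foci_raw <- as.integer(fr)
  df
}

#' @param records a records data.frame
#' @rdname readCometRecords
#' @export
writeRecords <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
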
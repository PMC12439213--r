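#' Percentile-and-mean summary of a group of values
#'
#' The standard group descriptor used throughout the cohort reports: the
#' 5-25-50-75-95 percentiles, the arithmetic mean and the sample standard
#' deviation. Percentiles are computed by linear interpolation between
#' closest order statistics (R's default type-7 quantile), so the median of
#' an even-sized sample is the mean of its two central values. The SD uses
#' the n-1 denominator and is 0 for a single value.
#'
#' @param values numeric vector, length >= 1, `NA`s removed.
#' @return One-row data.frame with `n`, `mean`, `sd`, `p5`, `p25`, `p50`,
#'   `p75`, `p95`.
#' @examples
#' group_summary(c(1, 2, 3, 4))  # p50 = 2.5
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("group_summary of an empty set")
  q <- stats::quantile(values, c(0.05, 0.25, 0.50, 0.75, 0.95),
                       names = FALSE, type = 7)
  data.frame(n = length(values), mean = mean(values),
             sd = if (length(values) >= 2) stats::sd(values) else 0,
             p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5])
}

#' Inter-observer variability of one metric for one organ
#'
#' Variability is quantified as the sample standard deviation of the metric
#' pooled across all observers and all patients of a group for the given
#' organ. With fewer than two usable records the SD is undefined and `NA`
#' is returned with a message attribute.
#'
#' @param records data.frame with at least columns `oar_name` and the metric
#'   column; typically the record table of a [run_study()] group.
#' @param oar organ name to subset on.
#' @param metric name of the metric column (e.g. `"msd_mm"`).
#' @return Sample SD (same units as the metric), or `NA` if < 2 records.
#' @export
observer_variability <- function(records, oar, metric) {
  vals <- records[[metric]][records$oar_name == oar]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("fewer than 2 records for OAR '%s'", oar)
    return(out)
  }
  stats::sd(vals)
}

#' Mean of per-organ observer variabilities
#'
#' The group-level variability headline: the unweighted arithmetic mean over
#' organs of the per-organ observer SDs. `NA` per-organ SDs (too few
#' records) are dropped.
#'
#' @param sds numeric vector of per-organ SDs.
#' @return Mean SD.
#' @export
mean_variability <- function(sds) {
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0) stop("no per-OAR SDs to average")
  mean(sds)
}

#' Signed percent change, rounded to an integer
#'
#' `100 * (comparison - reference) / reference`, rounded half away from
#' zero to the nearest integer percent (so -43.75 reports as -44). The
#' unrounded value is kept as an attribute `"raw"`.
#'
#' @param reference baseline value (non-zero).
#' @param comparison value being compared.
#' @return Integer percent (signed), with attribute `raw`.
#' @examples
#' percent_change(0.587, 0.293)  # -50
#' @export
percent_change <- function(reference, comparison) {
  if (reference == 0) stop("percent change from a zero reference is undefined")
  raw <- 100 * (comparison - reference) / reference
  out <- round_half_away(raw)
  attr(out, "raw") <- raw
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Contouring time saved by AI assistance
#'
#' Compares group medians of per-patient contouring time: time saved is
#' `median(manual) - median(adjusted)` with the percent saved reported as
#' the magnitude of the corresponding percent change. The with-processing
#' variant adds the AI processing/import time to the adjusted median before
#' differencing, representing the full workflow cost.
#'
#' @param manual,adjusted numeric vectors of per-patient minutes (or
#'   data.frames with a `minutes` column).
#' @param processing_min median AI processing + import time in minutes.
#' @return List with `median_manual_min`, `median_adjusted_min`,
#'   `median_saved_min`, `pct_saved`, `median_saved_with_processing_min`,
#'   `pct_saved_with_processing`.
#' @examples
#' time_saving(55, 17, processing_min = 10)  # 38 min (69%), 28 min (51%)
#' @export
time_saving <- function(manual, adjusted, processing_min = 0) {
  if (is.data.frame(manual)) manual <- manual$minutes
  if (is.data.frame(adjusted)) adjusted <- adjusted$minutes
  if (!length(manual) || !length(adjusted)) stop("empty timing group")
  if (processing_min < 0) stop("processing time must be >= 0")
  m <- stats::median(manual)
  a <- stats::median(adjusted)
  list(median_manual_min = m,
       median_adjusted_min = a,
       median_saved_min = m - a,
       pct_saved = -as.numeric(percent_change(m, a)),
       median_saved_with_processing_min = m - (a + processing_min),
       pct_saved_with_processing = -as.numeric(percent_change(m, a + processing_min)))
}

#' Do the timing quartiles separate completely?
#'
#' `TRUE` iff the worst quartile of adjusted times beats the best quartile
#' of manual times, i.e. `p75(adjusted) < p25(manual)`.
#'
#' @inheritParams time_saving
#' @return Logical.
#' @export
quartile_separation <- function(manual, adjusted) {
  if (is.data.frame(manual)) manual <- manual$minutes
  if (is.data.frame(adjusted)) adjusted <- adjusted$minutes
  if (!length(manual) || !length(adjusted)) stop("empty timing group")
  stats::quantile(adjusted, 0.75, names = FALSE) <
    stats::quantile(manual, 0.25, names = FALSE)
}

#' Contour-count bookkeeping
#'
#' Number of contours in a fully crossed patients-by-organs-by-observers
#' design, minus recorded exceptions (absent organs, skipped delineations).
#'
#' @param n_patients,n_oars,n_observers non-negative integers.
#' @param n_exceptions number of missing contours, at most the full product.
#' @return Integer count.
#' @examples
#' contour_count(20, 12, 11, 11)  # 2629
#' @export
contour_count <- function(n_patients, n_oars, n_observers, n_exceptions = 0) {
  args <- c(n_patients, n_oars, n_observers, n_exceptions)
  if (any(args < 0) || any(args != floor(args)))
    stop("counts must be non-negative integers")
  total <- n_patients * n_oars * n_observers
  if (n_exceptions > total) stop("more exceptions than contours in the design")
  as.integer(total - n_exceptions)
}
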
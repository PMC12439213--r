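geometry_metric_cols <- c("msd_mm", "dsc", "hd_mm", "vd_cc", "cmd_mm")

#' Configuration of a cohort analysis run
#'
#' @param processing_time_min AI processing + import minutes used in the
#'   with-processing time-saving headline; if `NULL` the median of the
#'   study's `processing` timing records is used.
#' @param geometry_excluded organ names excluded from the geometric tables
#'   (they stay in the dose and time analyses). Defaults to the cochleas,
#'   whose extreme relative size discrepancies distort geometric
#'   aggregates.
#' @param tubular_organs organ names receiving the caudal cut-off before
#'   geometric comparison; if `NULL`, taken from the study's organ table.
#' @param metric_policy named character vector overriding
#'   [organ_metric_policy()] entries.
#' @param dose compute dose-difference records (can be disabled for
#'   geometry-only runs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(processing_time_min = NULL,
                       geometry_excluded = c("cochlea_l", "cochlea_r"),
                       tubular_organs = NULL,
                       metric_policy = NULL,
                       dose = TRUE) {
  structure(list(processing_time_min = processing_time_min,
                 geometry_excluded = geometry_excluded,
                 tubular_organs = tubular_organs,
                 metric_policy = metric_policy, dose = dose),
            class = "run_config")
}

#' Run the full cohort analysis
#'
#' Orchestrates the complete evaluation of a multi-observer contouring
#' study against its ground truth: caudal-cut-off harmonization of tubular
#' organs (applied per patient across the ground truth and *all* groups'
#' masks of that organ), the five geometric agreement metrics per contour,
#' dose-metric differences under the per-organ clinical-goal policy,
#' and cohort aggregation into percentile summaries, inter-observer
#' variabilities, SD-reduction percentages and time-saving headlines.
#' Organs on the geometric exclusion list are dropped from geometric
#' aggregates only. Contours that cannot be evaluated (e.g. an empty mask)
#' become `NA` records with a reason and are excluded listwise from each
#' aggregation; a missing ground truth skips the organ with a logged
#' exception.
#'
#' @param study a `contour_study` from [make_cohort()], or a study
#'   directory written by [write_study()].
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, `records.csv`,
#'   `summaries.csv`, `headline.json` and `run.log` are written there.
#' @return A `run_report`: list with `records` (one row per contour),
#'   `summaries` (per organ/group/metric [group_summary()] rows),
#'   `variability` (per group/metric mean observer SD and percent change
#'   vs manual), `timing`, `headline`, and `exceptions`.
#' @export
run_study <- function(study, config = run_config(), out_dir = NULL) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "contour_study"))
  tubular <- config$tubular_organs %||%
    study$organs$oar_name[study$organs$tubular]
  log_lines <- character()
  exceptions <- study$exceptions
  if (!is.null(exceptions) && nrow(exceptions))
    log_lines <- c(log_lines, sprintf("exception [%s]: %s/%s/%s/%s",
                                      exceptions$reason, exceptions$patient_id,
                                      exceptions$oar_name, exceptions$group,
                                      exceptions$observer_id))

  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  push_row <- function(...) acc$rows[[length(acc$rows) + 1L]] <- list(...)
  for (pid in names(study$patients)) {
    pat <- study$patients[[pid]]
    dose_cache <- new.env(parent = emptyenv())
    for (organ in unique(unlist(lapply(pat$groups, function(g)
      unlist(lapply(g, names)))))) {
      gt <- pat$gt[[organ]]
      if (is.null(gt) || is_empty_mask(gt)) {
        log_lines <- c(log_lines,
                       sprintf("skip [missing-gt]: %s/%s", pid, organ))
        next
      }
      # collect every contour of this organ across groups/observers
      tests <- list()
      for (grp in names(pat$groups))
        for (obs in names(pat$groups[[grp]])) {
          m <- pat$groups[[grp]][[obs]][[organ]]
          if (!is.null(m))
            tests[[paste(grp, obs, sep = "\r")]] <- m
        }
      if (!length(tests)) next
      if (organ %in% tubular) {
        cut <- apply_caudal_cutoff(c(list(gt), unname(tests)))
        gt <- cut[[1]]
        tests <- stats::setNames(cut[-1], names(tests))
      }
      gt_dose_val <- NA_real_
      dose_metric <- NA_character_
      if (isTRUE(config$dose)) {
        dose_metric <- organ_metric_policy(organ, config$metric_policy)
        dose <- get_patient_dose(pat, gt$grid, dose_cache)
        gt_dose_val <- dose_metric_value(dose, gt, dose_metric)
      }
      for (key in names(tests)) {
        grp_obs <- strsplit(key, "\r", fixed = TRUE)[[1]]
        geom <- eval_pair_core(tests[[key]], gt)
        if (!is.na(geom$reason))
          log_lines <- c(log_lines, sprintf("degraded [%s]: %s/%s/%s/%s",
                                            geom$reason, pid, organ,
                                            grp_obs[1], grp_obs[2]))
        delta <- NA_real_
        if (isTRUE(config$dose) && !is_empty_mask(tests[[key]])) {
          dose <- get_patient_dose(pat, tests[[key]]$grid, dose_cache)
          delta <- dose_metric_value(dose, tests[[key]], dose_metric) -
            gt_dose_val
        }
        push_row(patient_id = pid, oar_name = organ, group = grp_obs[1],
                 observer_id = grp_obs[2], msd_mm = geom$msd_mm,
                 dsc = geom$dsc, hd_mm = geom$hd_mm, vd_cc = geom$vd_cc,
                 vd_rel_pct = geom$vd_rel_pct, cmd_mm = geom$cmd_mm,
                 reason = geom$reason, dose_metric = dose_metric,
                 dose_delta_gy = delta)
      }
    }
  }
  cols <- names(acc$rows[[1]])
  records <- as.data.frame(
    stats::setNames(lapply(cols, function(cn)
      unlist(lapply(acc$rows, `[[`, cn), use.names = FALSE)), cols),
    stringsAsFactors = FALSE)

  report <- aggregate_records(records, study$timing, config)
  report$exceptions <- exceptions
  report$log <- log_lines
  class(report) <- "run_report"

  check_report_consistency(report)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Dose for one patient evaluated on a mask subgrid; cached per subgrid.
get_patient_dose <- function(pat, grid, cache) {
  key <- paste(c(grid$shape, round(grid$origin, 6)), collapse = ",")
  if (!is.null(cache[[key]])) return(cache[[key]])
  ds <- pat$dose_spec
  d <- if (!is.null(pat[["dose"]])) dose_on_grid(pat[["dose"]], grid)
       else make_dose(grid, ds$target_center_mm, ds$prescription_gy, ds$falloff_mm)
  cache[[key]] <- d
  d
}

aggregate_records <- function(records, timing, config) {
  geo <- records[!(records$oar_name %in% config$geometry_excluded), ]

  # per (oar, group, metric) percentile summaries
  summaries <- list()
  metr_cols <- c(geometry_metric_cols, "vd_rel_pct")
  for (metric in metr_cols) {
    for (grp in unique(geo$group)) {
      for (oar in unique(geo$oar_name)) {
        vals <- geo[[metric]][geo$group == grp & geo$oar_name == oar]
        vals <- vals[!is.na(vals)]
        if (!length(vals)) next
        summaries[[length(summaries) + 1L]] <- cbind(
          data.frame(oar_name = oar, group = grp, metric = metric,
                     stringsAsFactors = FALSE),
          group_summary(vals))
      }
    }
  }
  if (isTRUE(config$dose)) {
    for (grp in unique(records$group)) {
      for (oar in unique(records$oar_name)) {
        sel <- records$group == grp & records$oar_name == oar
        vals <- records$dose_delta_gy[sel]
        vals <- vals[!is.na(vals)]
        if (!length(vals)) next
        summaries[[length(summaries) + 1L]] <- cbind(
          data.frame(oar_name = oar, group = grp,
                     metric = paste0("delta_", records$dose_metric[sel][1]),
                     stringsAsFactors = FALSE),
          group_summary(vals))
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL

  # inter-observer variability: per-OAR pooled SD, averaged over OARs
  variability <- list()
  groups <- unique(geo$group)
  for (metric in geometry_metric_cols) {
    per_group <- stats::setNames(lapply(groups, function(grp) {
      sub <- geo[geo$group == grp, ]
      sds <- vapply(unique(sub$oar_name), function(oar)
        as.numeric(observer_variability(sub, oar, metric)), numeric(1))
      # a group observed once per cell has no defined variability
      if (all(is.na(sds))) NA_real_ else mean_variability(sds)
    }), groups)
    for (grp in groups) {
      ref <- per_group[["manual"]]
      pc <- if (grp != "manual" && "manual" %in% groups &&
                !is.na(ref) && ref != 0 && !is.na(per_group[[grp]]))
        as.numeric(percent_change(ref, per_group[[grp]]))
      else NA_real_
      variability[[length(variability) + 1L]] <- data.frame(
        metric = metric, group = grp, mean_sd = per_group[[grp]],
        pct_change_vs_manual = pc, stringsAsFactors = FALSE)
    }
  }
  variability <- do.call(rbind, variability)
  rownames(variability) <- NULL

  # timing headlines
  manual_t <- timing$minutes[timing$group == "manual"]
  adjusted_t <- timing$minutes[timing$group == "adjusted"]
  processing_t <- timing$minutes[timing$group == "processing"]
  proc_min <- config$processing_time_min %||%
    (if (length(processing_t)) stats::median(processing_t) else 0)
  ts <- time_saving(manual_t, adjusted_t, proc_min)

  headline <- c(ts, list(
    processing_time_min = proc_min,
    quartile_separation = quartile_separation(manual_t, adjusted_t),
    n_records = nrow(records),
    n_missing_metric = sum(is.na(records$dsc))))
  for (metric in geometry_metric_cols) {
    for (grp in groups) {
      row <- variability[variability$metric == metric & variability$group == grp, ]
      headline[[paste0("mean_sd_", metric, "_", grp)]] <- row$mean_sd
      if (grp != "manual")
        headline[[paste0("sd_change_pct_", metric, "_", grp)]] <-
          row$pct_change_vs_manual
    }
  }

  list(records = records, summaries = summaries, variability = variability,
       timing = timing, headline = headline)
}

# Every headline percent must be recomputable from the emitted tables.
check_report_consistency <- function(report) {
  h <- report$headline
  t <- report$timing
  m <- stats::median(t$minutes[t$group == "manual"])
  a <- stats::median(t$minutes[t$group == "adjusted"])
  stopifnot(isTRUE(all.equal(h$median_saved_min, m - a)),
            isTRUE(all.equal(h$pct_saved, -as.numeric(percent_change(m, a)))))
  v <- report$variability
  for (i in seq_len(nrow(v))) {
    if (v$group[i] == "manual" || is.na(v$pct_change_vs_manual[i])) next
    ref <- v$mean_sd[v$metric == v$metric[i] & v$group == "manual"]
    stopifnot(isTRUE(all.equal(v$pct_change_vs_manual[i],
                               as.numeric(percent_change(ref, v$mean_sd[i])))))
  }
  invisible(TRUE)
}

#' Write a run report to disk
#'
#' Emits `records.csv` (one row per contour with all metrics),
#' `summaries.csv` (percentile summaries), `headline.json` and `run.log`.
#'
#' @param report a `run_report` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$timing, file.path(out_dir, "timing.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$headline, file.path(out_dir, "headline.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report$log %||% character(), file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Re-aggregate a report from a record-level table
#'
#' Rebuilds summary tables and headline numbers from a previously written
#' `records.csv` plus the timing table, without re-running any geometry.
#'
#' @param records_csv path to a `records.csv` written by [write_report()].
#' @param timing_csv path to the corresponding timing table.
#' @param config a [run_config()].
#' @return A `run_report` (without record-level logs).
#' @export
render_report <- function(records_csv, timing_csv, config = run_config()) {
  records <- utils::read.csv(records_csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "oar_name", "group", "observer_id",
            geometry_metric_cols, "vd_rel_pct", "dose_metric", "dose_delta_gy")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records table is missing columns: ", paste(miss, collapse = ", "))
  timing <- read_timing_csv(timing_csv)
  report <- aggregate_records(records, timing, config)
  report$log <- character()
  class(report) <- "run_report"
  check_report_consistency(report)
  report
}

#' @export
print.run_report <- function(x, ...) {
  h <- x$headline
  cat("contour-QA run report\n")
  cat(sprintf("  records: %d (missing metrics: %d)\n",
              h$n_records, h$n_missing_metric))
  cat(sprintf("  median contouring time: manual %g min, adjusted %g min\n",
              h$median_manual_min, h$median_adjusted_min))
  cat(sprintf("  time saved: %g min (%g%%); with processing: %g min (%g%%)\n",
              h$median_saved_min, h$pct_saved,
              h$median_saved_with_processing_min, h$pct_saved_with_processing))
  for (metric in geometry_metric_cols) {
    v <- x$variability[x$variability$metric == metric, ]
    man <- v$mean_sd[v$group == "manual"]
    if (!length(man)) next
    cat(sprintf("  mean observer SD [%s]: manual %.3f", metric, man))
    for (grp in setdiff(v$group, "manual"))
      cat(sprintf(", %s %.3f (%+d%%)", grp, v$mean_sd[v$group == grp],
                  as.integer(v$pct_change_vs_manual[v$group == grp])))
    cat("\n")
  }
  invisible(x)
}
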
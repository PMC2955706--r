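#' Read single-cell volume trajectories from CSV
#'
#' Expects a header `cell_id,time_h,volume_um3`. Rows are grouped by cell,
#' sorted by time and validated; malformed input raises an error naming
#' the offending row.
#'
#' @param path CSV file path.
#' @param schedule The [light_schedule()] the cohort was recorded under.
#' @return A list of [volume_trajectory()] objects, in order of first
#'   appearance of each cell.
#' @export
read_trajectories <- function(path, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character"))
  need <- c("cell_id", "time_h", "volume_um3")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in c("time_h", "volume_um3")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s at data row %d", path, col,
                   bad[1L]), call. = FALSE)
    if (anyNA(vals))
      stop(sprintf("%s: missing %s at data row %d", path, col,
                   which(is.na(vals))[1L]), call. = FALSE)
    df[[col]] <- vals
  }
  neg <- which(df$volume_um3 <= 0)
  if (length(neg))
    stop(sprintf("%s: non-positive volume at data row %d", path,
                 neg[1L]), call. = FALSE)
  dup <- which(duplicated(df[c("cell_id", "time_h")]))
  if (length(dup))
    stop(sprintf("%s: duplicate (cell_id, time_h) at data row %d", path,
                 dup[1L]), call. = FALSE)
  ids <- unique(df$cell_id)
  lapply(ids, function(id) {
    rows <- df[df$cell_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    volume_trajectory(id, rows$time_h, rows$volume_um3, schedule)
  })
}

#' Write trajectories or per-cell records to CSV
#'
#' `write_trajectories()` emits the standard long-format trajectory CSV
#' (`cell_id,time_h,volume_um3`); `write_records()` emits per-cell
#' analysis records. Both write RFC-4180 CSV with a fixed column order
#' and 6-significant-digit floats, so identical inputs give
#' byte-identical files.
#'
#' @param trajs List of [volume_trajectory()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, phase_labels = FALSE) {
  stopifnot(is.list(trajs))
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    out <- data.frame(cell_id = attr(tr, "cell_id"),
                      time_h = signif(tr$time_h, 6),
                      volume_um3 = signif(tr$volume_um3, 6))
    if (phase_labels) {
      ann <- attr(tr, "annotations")
      t_entry <- ann$cycle_result$t_division_entry
      out$phase_label <- if (is.null(t_entry) || is.na(t_entry))
        "interdivision"
      else ifelse(tr$time_h < t_entry, "interdivision", "division")
    }
    out
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param phase_labels If `TRUE`, annotated trajectories gain a
#'   `phase_label` column (`interdivision` / `division`).
#' @param records Data frame from [analyse_cohort()].
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  num <- vapply(records, is.numeric, logical(1L))
  records[num] <- lapply(records[num], signif, digits = 6)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end analysis in one validated object that
#' round-trips losslessly through JSON. Unknown keys in a config file are
#' rejected rather than silently ignored.
#'
#' @param params A [cycle_params()].
#' @param drop_fraction,min_samples Division-entry detector settings (see
#'   [detect_division_entry()]).
#' @param use_annotation Use generator ground truth for division-number
#'   classification when present.
#' @param seed Integer seed recorded in the report (the analysis itself
#'   is deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(params = cycle_params(),
                            drop_fraction = 0.05, min_samples = 5L,
                            use_annotation = FALSE, seed = 1L) {
  stopifnot(inherits(params, "cycle_params"),
            drop_fraction > 0, drop_fraction < 1, min_samples >= 1L)
  structure(list(params = params, drop_fraction = drop_fraction,
                 min_samples = as.integer(min_samples),
                 use_annotation = isTRUE(use_annotation),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  p <- config$params
  list(timer_threshold = p$timer_threshold,
       commitment_ratio = p$commitment_ratio,
       mitotic_cutpoint_low = p$mitotic_cutpoint_low,
       mitotic_cutpoint_high = p$mitotic_cutpoint_high,
       calibration = unclass(p$calib),
       subphase_durations = as.list(p$subphase_durations),
       cv_mu = p$cv_mu, cv_threshold = p$cv_threshold,
       cv_measurement = p$cv_measurement,
       v0_mean = p$v0_mean, v0_cv = p$v0_cv,
       stochastic_bands = p$stochastic_bands,
       shrinkage_fraction = p$shrinkage_fraction,
       drop_fraction = config$drop_fraction,
       min_samples = config$min_samples,
       use_annotation = config$use_annotation,
       seed = config$seed)
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("timer_threshold", "commitment_ratio", "mitotic_cutpoint_low",
             "mitotic_cutpoint_high", "calibration", "subphase_durations",
             "cv_mu", "cv_threshold", "cv_measurement", "v0_mean", "v0_cv",
             "stochastic_bands", "shrinkage_fraction", "drop_fraction",
             "min_samples", "use_annotation", "seed")
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_keys <- setdiff(known, names(obj))
  if (length(missing_keys))
    stop("missing config key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  calib <- growth_calibration(obj$calibration$mu_max, obj$calibration$K,
                              obj$calibration$par_compensation)
  params <- cycle_params(
    timer_threshold = obj$timer_threshold,
    commitment_ratio = obj$commitment_ratio,
    mitotic_cutpoint_low = obj$mitotic_cutpoint_low,
    mitotic_cutpoint_high = obj$mitotic_cutpoint_high,
    calib = calib,
    subphase_durations = unlist(obj$subphase_durations),
    cv_mu = obj$cv_mu, cv_threshold = obj$cv_threshold,
    cv_measurement = obj$cv_measurement,
    v0_mean = obj$v0_mean, v0_cv = obj$v0_cv,
    stochastic_bands = obj$stochastic_bands,
    shrinkage_fraction = obj$shrinkage_fraction)
  pipeline_config(params = params, drop_fraction = obj$drop_fraction,
                  min_samples = obj$min_samples,
                  use_annotation = obj$use_annotation, seed = obj$seed)
}

#' @rdname read_config
#' @param config A `pipeline_config` to serialise.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Reads a trajectory CSV and its schedule JSON, analyses every cell
#' (division-entry detection, per-light-period growth rates, timer
#' products, division-number classification), and summarises the cohort.
#' Optionally writes the per-cell records as CSV and the report — cohort
#' summary plus the fully resolved configuration, so no defaults are
#' hidden — as JSON. Identical inputs and configuration give identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param trajectories Path to the trajectory CSV, or a list of
#'   [volume_trajectory()] objects.
#' @param schedule Path to the schedule JSON, or a [light_schedule()]
#'   (required when `trajectories` is a path).
#' @param records_out,report_out Optional output paths.
#' @return A list with `records` (per-cell data frame), `summary`
#'   (a [summarise_cohort()] result) and `config` (the resolved
#'   configuration as a flat list).
#' @export
run_pipeline <- function(config = pipeline_config(), trajectories,
                         schedule = NULL, records_out = NULL,
                         report_out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(trajectories)) {
    if (is.character(schedule)) schedule <- read_schedule(schedule)
    if (!inherits(schedule, "light_schedule"))
      stop("a schedule (path or object) is required with a trajectory CSV",
           call. = FALSE)
    trajs <- read_trajectories(trajectories, schedule)
  } else {
    trajs <- trajectories
  }
  if (length(trajs) == 0L)
    stop("empty cohort: no trajectories to analyse", call. = FALSE)
  records <- analyse_cohort(trajs, params = config$params,
                            drop_fraction = config$drop_fraction,
                            min_samples = config$min_samples,
                            use_annotation = config$use_annotation)
  summ <- summarise_cohort(records)
  if (!is.null(records_out)) write_records(records, records_out)
  resolved <- config_to_list(config)
  if (!is.null(report_out)) {
    report <- list(summary = list(
                     n = summ$n, n_divided = summ$n_divided,
                     mean_T = summ$mean_T, sd_T = summ$sd_T,
                     cv_T = summ$cv_T,
                     mean_muT = summ$mean_muT, sd_muT = summ$sd_muT,
                     mean_ratio = summ$mean_ratio,
                     sd_ratio = summ$sd_ratio,
                     division_number_counts =
                       as.list(stats::setNames(
                         as.integer(summ$division_number_counts),
                         names(summ$division_number_counts)))),
                   config = resolved)
    jsonlite::write_json(report, report_out, auto_unbox = TRUE,
                         digits = NA)
  }
  list(records = records, summary = summ, config = resolved)
}
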
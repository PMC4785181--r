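#' Write / read a trial log as CSV
#'
#' Columns: `animal_id, day, session, trial, task, domain, level,
#' s_plus_side, choice, correct, is_correction`. Header mandatory; levels as
#' decimals (contrast 0-1, SF in cpd).
#'
#' @param trials trial data.frame from the task engine.
#' @param path CSV file path.
#' @return `path`, invisibly (writer); the trial data.frame (reader).
#' @export
write_trials <- function(trials, path) {
  cols <- c("animal_id", "day", "session", "trial", "task", "domain", "level",
            "s_plus_side", "choice", "correct", "is_correction")
  stopifnot(all(cols %in% names(trials)))
  utils::write.csv(trials[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$correct <- as.logical(df$correct)
  df$is_correction <- as.logical(df$is_correction)
  df
}

#' Write / read a frame stack as multi-page TIFF with JSON metadata
#'
#' Frames are stored as 32-bit float TIFF pages; acquisition metadata
#' (`frame_interval_s`, `pixel_size_um`, and the stimulus schedule) goes to a
#' JSON sidecar (`<path>.json`).
#'
#' @param stack a [frame_stack()].
#' @param path TIFF file path.
#' @return `path`, invisibly (writer); a [frame_stack()] (reader).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$data)
  # TIFF pages must lie in [0, 1]: store min-max scaled values and record
  # the affine transform in the sidecar so the reader restores raw units
  lo <- min(stack$data); hi <- max(stack$data)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(k) (stack$data[, , k] - lo) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(frame_interval_s = stack$frame_interval_s,
               pixel_size_um = stack$pixel_size_um,
               scale = list(offset = lo, span = span),
               schedule = unclass(stack$schedule))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(meta$scale))
    arr <- arr * meta$scale$span + meta$scale$offset
  sch <- meta$schedule
  if (!is.null(sch)) {
    sch <- if (identical(sch$mode, "periodic"))
      stimulus_schedule("periodic", f_stim_hz = sch$f_stim_hz,
                        duration_s = sch$duration_s)
    else
      stimulus_schedule("episodic", pre_s = sch$pre_s, stim_s = sch$stim_s,
                        window_s = unlist(sch$window_s), gap_s = sch$gap_s,
                        n_trials = sch$n_trials, sf_cpd = sch$sf_cpd)
  }
  frame_stack(arr, frame_interval_s = meta$frame_interval_s,
              pixel_size_um = meta$pixel_size_um, schedule = sch)
}

#' Read a cohort specification from a YAML config
#'
#' Keys: `profile`, `n_animals`, `domain`, `seed`, optional `eye`. Returns
#' the instantiated cohort.
#'
#' @param path YAML file.
#' @return list of `observer_state` objects.
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$profile), !is.null(cfg$n_animals))
  simulate_cohort(cfg$profile, n = cfg$n_animals,
                  domain = if (is.null(cfg$domain)) "contrast" else cfg$domain,
                  seed = if (is.null(cfg$seed)) 1L else cfg$seed,
                  eye = cfg$eye)
}

#' Write a cohort table as CSV (one row per animal)
#'
#' @param cohort list of `observer_state` objects.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort_table(cohort), path, row.names = FALSE)
  invisible(path)
}
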
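#' Assessment configuration for the visual water task
#'
#' Defaults follow the published procedure: contrast assessments start at
#' 100% contrast and descend in steps of 0.10; acuity assessments start at
#' 0.12 cpd and ascend in steps of 0.03 cpd. Performance at a level is judged
#' by a criterion test: pass on 4 consecutive correct choices or 7 correct in
#' a block of 10; fail if the block completes without either. A preliminary
#' threshold is recorded whenever a level is failed; the run terminates when
#' two successive preliminary thresholds agree within `stability_tol`
#' (default one step), and the final threshold is read from the pooled
#' frequency-of-seeing curve.
#'
#' @param domain `"contrast"` or `"spatial_frequency"`.
#' @param start_level easiest level (contrast 1.0; SF 0.12 cpd).
#' @param step level increment (contrast 0.10; SF 0.03 cpd).
#' @param criterion accuracy criterion (0.70).
#' @param block_size trials per criterion block (10).
#' @param streak consecutive correct choices that pass immediately (4).
#' @param hits correct choices within a block that pass (7).
#' @param stability_tol agreement (in level units) between successive
#'   preliminary thresholds that ends the assessment; defaults to `step`.
#' @param max_blocks safety cap on criterion blocks (200).
#' @param sessions_per_day session bookkeeping: 10 non-correction trials per
#'   session, this many sessions per day (2).
#' @return an `assessment_config` object.
#' @export
assessment_config <- function(domain = c("contrast", "spatial_frequency"),
                              start_level = NULL, step = NULL,
                              criterion = 0.70, block_size = 10L,
                              streak = 4L, hits = 7L,
                              stability_tol = NULL, max_blocks = 200L,
                              sessions_per_day = 2L) {
  domain <- match.arg(domain)
  if (is.null(start_level)) start_level <- if (domain == "contrast") 1.0 else 0.12
  if (is.null(step)) step <- if (domain == "contrast") 0.10 else 0.03
  if (is.null(stability_tol)) stability_tol <- step
  stopifnot(step > 0, start_level > 0, criterion > 0, criterion < 1,
            block_size >= 1, streak >= 1, hits >= 1, max_blocks >= 1)
  structure(list(domain = domain, start_level = start_level, step = step,
                 criterion = criterion, block_size = as.integer(block_size),
                 streak = as.integer(streak), hits = as.integer(hits),
                 stability_tol = stability_tol,
                 max_blocks = as.integer(max_blocks),
                 sessions_per_day = as.integer(sessions_per_day)),
            class = "assessment_config")
}

#' Draw the next S+ side under the pseudorandom side rule
#'
#' Sides are Bernoulli(0.5) except that no more than three consecutive
#' trials may present the S+ on the same side: after three equal sides the
#' opposite side is forced.
#'
#' @param history character vector of previous sides (`"left"`/`"right"`),
#'   oldest first; may be empty.
#' @return `"left"` or `"right"`.
#' @export
next_side <- function(history = character()) {
  n <- length(history)
  if (n >= 3 && length(unique(history[(n - 2):n])) == 1L)
    return(setdiff(c("left", "right"), history[n]))
  c("left", "right")[1L + (stats::runif(1) < 0.5)]
}

#' Evaluate the pass/fail criterion on a sequence of outcomes
#'
#' Sequential with early stopping: pass as soon as `streak` consecutive
#' correct choices occur or `hits` correct choices accumulate; fail only
#' when `block_size` outcomes complete without passing; `continue` while
#' undecided.
#'
#' @param outcomes logical vector of correctness flags, in order
#'   (correction trials must already be excluded).
#' @param streak,hits,block_size criterion parameters (defaults 4, 7, 10).
#' @return list with `status` (`"pass"`, `"fail"`, `"continue"`) and
#'   `trials` (outcomes consumed before the decision, or all of them).
#' @export
criterion_test <- function(outcomes, streak = 4L, hits = 7L, block_size = 10L) {
  if (length(outcomes) > block_size)
    stop("at most block_size outcomes per criterion block")
  run <- 0L; nc <- 0L
  for (i in seq_along(outcomes)) {
    if (outcomes[i]) { run <- run + 1L; nc <- nc + 1L } else run <- 0L
    if (run >= streak || nc >= hits)
      return(list(status = "pass", trials = i))
  }
  if (length(outcomes) == block_size)
    return(list(status = "fail", trials = block_size))
  list(status = "continue", trials = length(outcomes))
}

# step one level harder / easier on the grid, respecting physical bounds
.step_harder <- function(level, cfg) {
  if (cfg$domain == "contrast") level - cfg$step else level + cfg$step
}
.step_easier <- function(level, cfg) {
  if (cfg$domain == "contrast") min(level + cfg$step, cfg$start_level)
  else max(level - cfg$step, cfg$start_level)
}
.at_hard_bound <- function(level, cfg) {
  # contrast cannot drop to or below zero; SF has no hard bound
  cfg$domain == "contrast" && (level - cfg$step) < cfg$step / 2
}
.at_easy_bound <- function(level, cfg) {
  abs(level - cfg$start_level) < cfg$step / 2
}

# run one criterion block at a fixed level, simulating corrections after
# errors; returns the block outcome plus all trial rows
.run_block <- function(observer, level, cfg, sides_so_far, task, domain) {
  rows <- list(); outcomes <- logical(0)
  sides <- sides_so_far
  repeat {
    side <- next_side(sides)
    sides <- c(sides, side)
    tr <- simulate_choice(observer, level, side)
    rows[[length(rows) + 1L]] <- tr
    outcomes <- c(outcomes, tr$correct)
    if (!tr$correct) {
      # forced repeats at the same level and side until a correct choice
      # (capped: a real 2AFC observer guesses correctly at p >= 0.5)
      for (ci in 1:100) {
        trc <- simulate_choice(observer, level, side, is_correction = TRUE)
        rows[[length(rows) + 1L]] <- trc
        if (trc$correct) break
      }
    }
    res <- criterion_test(outcomes, cfg$streak, cfg$hits, cfg$block_size)
    if (res$status != "continue") {
      df <- do.call(rbind, rows)
      df$task <- task; df$domain <- domain
      return(list(status = res$status, trials = df, sides = sides))
    }
  }
}

# annotate pooled trials with trial/session/day bookkeeping
.number_trials <- function(df, cfg, animal_id) {
  df$animal_id <- animal_id
  df$trial <- seq_len(nrow(df))
  ncorr <- cumsum(!df$is_correction)
  df$session <- pmax(1L, as.integer(ceiling(ncorr / 10)))
  df$day <- as.integer(ceiling(df$session / cfg$sessions_per_day))
  df[, c("animal_id", "day", "session", "trial", "task", "domain", "level",
         "s_plus_side", "choice", "correct", "is_correction")]
}

#' Run a full adaptive threshold assessment
#'
#' Implements the staircase-with-criterion-testing procedure: starting at the
#' easiest level, each passed criterion block moves one step harder; a failed
#' block records a preliminary threshold and moves one step easier. The run
#' ends when two successive preliminary thresholds agree within
#' `stability_tol` (or at `max_blocks`). The threshold estimate is then read
#' from the frequency-of-seeing curve over all pooled non-correction trials
#' at the criterion accuracy.
#'
#' An observer that cannot perform above chance even at the easiest level
#' produces an estimate flagged undefined rather than an error.
#'
#' @param observer an `observer_state`, `psychometric_params`, or a function
#'   `level -> p` (deterministic test observers).
#' @param config an [assessment_config()].
#' @param animal_id id recorded in the trial log.
#' @param task task label recorded in the trial log (default `"V_vs_H"`).
#' @param include_corrections if `TRUE`, correction trials enter the
#'   frequency-of-seeing curve (they never enter criterion tests).
#' @return list with `trials` (the full trial log), `estimate` (a
#'   [threshold_at_criterion()] result), and `preliminary` (the sequence of
#'   preliminary thresholds).
#' @export
run_assessment <- function(observer, config = assessment_config(),
                           animal_id = 1L, task = "V_vs_H",
                           include_corrections = FALSE) {
  cfg <- config
  level <- cfg$start_level
  sides <- character(0)
  all_trials <- list()
  prelim <- numeric(0)
  hard_bound_passes <- 0L

  for (b in seq_len(cfg$max_blocks)) {
    blk <- .run_block(observer, level, cfg, sides, task, cfg$domain)
    sides <- blk$sides
    all_trials[[length(all_trials) + 1L]] <- blk$trials
    if (blk$status == "pass") {
      if (.at_hard_bound(level, cfg)) {
        hard_bound_passes <- hard_bound_passes + 1L
        if (hard_bound_passes >= 2L) break   # performance never falls below criterion
      } else {
        hard_bound_passes <- 0L
        level <- .step_harder(level, cfg)
      }
    } else {
      hard_bound_passes <- 0L
      prelim <- c(prelim, level)
      np <- length(prelim)
      if (np >= 2 && abs(prelim[np] - prelim[np - 1]) <= cfg$stability_tol + 1e-9)
        break
      if (.at_easy_bound(level, cfg)) {
        # cannot go easier; stay (repeated failures here end via agreement)
      } else {
        level <- .step_easier(level, cfg)
      }
    }
  }

  trials <- .number_trials(do.call(rbind, all_trials), cfg, animal_id)
  fos <- build_fos(trials, include_corrections = include_corrections)
  est <- threshold_at_criterion(fos, criterion = cfg$criterion)
  list(trials = trials, estimate = est, preliminary = prelim)
}

#' Assess a whole cohort and summarize group threshold statistics
#'
#' Runs [run_assessment()] on each observer (seeding each animal's RNG with
#' its child seed so cohorts are reproducible) and returns per-animal
#' estimates plus the group mean and SEM. Contrast-domain thresholds are also
#' reported as contrast sensitivity.
#'
#' @param cohort list of `observer_state` objects from [simulate_cohort()].
#' @param config an [assessment_config()].
#' @return list with `animals` (data.frame: animal_id, true_alpha, threshold,
#'   defined, cs if contrast domain) and `group` (a [group_summary()] of the
#'   defined thresholds, or sensitivities for the contrast domain).
#' @export
assess_cohort <- function(cohort, config = assessment_config()) {
  rows <- lapply(cohort, function(o) {
    set.seed(child_seed(o$seed, 104729L))  # assessment stream, distinct from the draw
    res <- run_assessment(o, config, animal_id = o$id)
    data.frame(animal_id = o$id, true_alpha = o$psy$alpha,
               threshold = if (res$estimate$defined) res$estimate$threshold else NA_real_,
               defined = res$estimate$defined)
  })
  animals <- do.call(rbind, rows)
  if (config$domain == "contrast")
    animals$cs <- ifelse(animals$defined, 1 / animals$threshold, NA_real_)
  vals <- if (config$domain == "contrast") animals$cs else animals$threshold
  list(animals = animals, group = group_summary(vals[!is.na(vals)]))
}
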
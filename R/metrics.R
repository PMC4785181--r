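#' Percent improvement from pre to post
#'
#' `[(post - pre) / pre] * 100`. Identical to `(post_pre_ratio - 1) * 100`.
#'
#' @param pre,post assessed values in the same units (CS or cpd); `pre > 0`.
#' @return signed percent.
#' @export
percent_improvement <- function(pre, post) {
  if (any(pre <= 0)) stop("pre-training value must be positive")
  (post - pre) / pre * 100
}

#' Post/pre ratio (PPR)
#'
#' @inheritParams percent_improvement
#' @return `post / pre`.
#' @export
post_pre_ratio <- function(pre, post) {
  if (any(pre <= 0)) stop("pre-training value must be positive")
  post / pre
}

#' Retention coefficient
#'
#' `(retest - pre) / (post - pre) * 100`: 100% when the retest equals the
#' post-training value, 0% when all learning is lost.
#'
#' @param pre,post,retest assessed values; `post` must differ from `pre`.
#' @return percent retained.
#' @export
retention_coefficient <- function(pre, post, retest) {
  if (any(post == pre)) stop("no learning to retain: post equals pre")
  (retest - pre) / (post - pre) * 100
}

#' Transfer index (TI)
#'
#' `TI = (post - naive)_untrained / (post - pre)_trained`. TI = 1 indicates
#' complete transfer of learning to the untrained condition, TI = 0 none.
#' The untrained condition is compared against a naive group because testing
#' it before training would itself train it.
#'
#' @param trained_pre,trained_post pre/post values of the trained condition.
#' @param untrained_naive naive-group value of the untrained condition.
#' @param untrained_post post-training value of the untrained condition.
#' @return dimensionless transfer index.
#' @examples
#' transfer_index(0.45, 0.73, 0.46, 0.73)  # ~0.96: orientation transfers
#' transfer_index(0.44, 0.74, 0.46, 0.48)  # ~0.07: detection -> discrimination does not
#' @export
transfer_index <- function(trained_pre, trained_post,
                           untrained_naive, untrained_post) {
  if (any(trained_post == trained_pre))
    stop("zero trained improvement: transfer index undefined")
  (untrained_post - untrained_naive) / (trained_post - trained_pre)
}

#' Sucrose preference
#'
#' `sucrose / (water + sucrose) * 100`, the standard anhedonia screen.
#'
#' @param sucrose_g,water_g consumed amounts (g); non-negative, not both 0.
#' @return percent preference in \[0, 100\].
#' @export
sucrose_preference <- function(sucrose_g, water_g) {
  if (any(sucrose_g < 0) || any(water_g < 0)) stop("consumption cannot be negative")
  if (any(sucrose_g + water_g == 0)) stop("no consumption recorded")
  sucrose_g / (sucrose_g + water_g) * 100
}

#' Dendritic spine density per 10 micrometers
#'
#' Spine counts are only meaningful on sufficiently long dendrite segments;
#' segments shorter than 25 um are rejected.
#'
#' @param spine_count number of spines on the segment.
#' @param segment_length_um segment length in micrometers (>= 25).
#' @return spines per 10 um of dendrite.
#' @examples
#' spine_density(21, 25)  # 8.4
#' @export
spine_density <- function(spine_count, segment_length_um) {
  if (any(spine_count < 0)) stop("spine count cannot be negative")
  if (any(segment_length_um < 25)) stop("segment too short: need at least 25 um")
  spine_count / segment_length_um * 10
}

#' Group summary as mean and SEM
#'
#' SEM uses the sample SD (n - 1 denominator). For a single value the SEM is
#' reported as 0 and flagged.
#'
#' @param values numeric vector (non-empty).
#' @return a `group_summary` list: `n`, `mean`, `sem`, `sem_degenerate`
#'   (`TRUE` when n = 1).
#' @export
group_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no values to summarize")
  n <- length(values)
  sem <- if (n == 1) 0 else stats::sd(values) / sqrt(n)
  structure(list(n = n, mean = mean(values), sem = sem,
                 sem_degenerate = n == 1),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d: %.4g +/- %.3g (mean +/- SEM)%s\n", x$n, x$mean, x$sem,
              if (x$sem_degenerate) " [n = 1: SEM reported as 0]" else ""))
  invisible(x)
}

#' Group pre/post statistics, per-animal or on group means
#'
#' The published group improvement figures average per-animal statistics
#' (ratios of means differ from means of ratios); the transfer index is
#' necessarily computed on group means because the naive comparison is a
#' different cohort. Both modes are provided; per-animal is the default for
#' improvement and PPR.
#'
#' @param pre,post vectors of per-animal values (paired).
#' @param mode `"per_animal"` (average per-animal statistics) or
#'   `"group_means"` (statistic of the group means).
#' @return list with `percent_improvement`, `ppr`, each a [group_summary()]
#'   in `"per_animal"` mode or a single number in `"group_means"` mode.
#' @export
group_prepost <- function(pre, post, mode = c("per_animal", "group_means")) {
  mode <- match.arg(mode)
  stopifnot(length(pre) == length(post), length(pre) >= 1)
  if (mode == "per_animal") {
    list(percent_improvement = group_summary(percent_improvement(pre, post)),
         ppr = group_summary(post_pre_ratio(pre, post)))
  } else {
    list(percent_improvement = percent_improvement(mean(pre), mean(post)),
         ppr = post_pre_ratio(mean(pre), mean(post)))
  }
}
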
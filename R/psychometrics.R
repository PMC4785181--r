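#' Michelson contrast of a grating
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` of the luminance extremes.
#'
#' @param l_max,l_min maximum and minimum luminance (cd/m^2); non-negative,
#'   `l_max >= l_min`, `l_max > 0`.
#' @return contrast in \[0, 1\].
#' @examples
#' michelson_contrast(64.5, 21.5)  # 0.5
#' @export
michelson_contrast <- function(l_max, l_min) {
  if (any(l_max < 0) || any(l_min < 0)) stop("luminance cannot be negative")
  if (any(l_max < l_min)) stop("l_max must be >= l_min")
  if (any(l_max + l_min == 0)) stop("l_max must be positive")
  (l_max - l_min) / (l_max + l_min)
}

#' Build a frequency-of-seeing curve from a trial log
#'
#' Aggregates accuracy per tested stimulus level. Correction trials (forced
#' repeats after an error) are excluded by default, since they follow a
#' predictable error and would bias accuracy.
#'
#' @param trials data.frame with columns `level`, `correct`, and
#'   `is_correction`; a `domain` column (or attribute) is propagated.
#' @param include_corrections count correction trials too (default `FALSE`).
#' @return a `fos` data.frame with columns `level`, `n`, `n_correct`,
#'   `accuracy`, sorted by level, carrying a `domain` attribute.
#' @export
build_fos <- function(trials, include_corrections = FALSE) {
  stopifnot(nrow(trials) > 0, all(c("level", "correct") %in% names(trials)))
  if (!include_corrections && "is_correction" %in% names(trials))
    trials <- trials[!trials$is_correction, , drop = FALSE]
  if (nrow(trials) == 0) stop("no scoreable trials")
  agg <- stats::aggregate(trials$correct, by = list(level = trials$level),
                          FUN = function(z) c(n = length(z), k = sum(z)))
  out <- data.frame(level = agg$level, n = agg$x[, "n"],
                    n_correct = agg$x[, "k"])
  out$accuracy <- out$n_correct / out$n
  out <- out[order(out$level), ]
  rownames(out) <- NULL
  dom <- if ("domain" %in% names(trials)) trials$domain[1] else attr(trials, "domain")
  attr(out, "domain") <- dom
  class(out) <- c("fos", "data.frame")
  out
}

#' Read the threshold off a frequency-of-seeing curve
#'
#' Finds where the curve crosses the criterion accuracy (70% by default) and
#' interpolates linearly between the two adjacent tested levels bracketing
#' the crossing nearest the easy end (high contrast / low SF). A level at
#' exactly the criterion is returned as-is. When sampling noise makes the
#' curve non-monotone, `mode = "isotonic"` first applies isotonic regression
#' along the difficulty axis.
#'
#' @param fos a [build_fos()] result (or a data.frame with `level` and
#'   `accuracy`), with a `domain` attribute or argument.
#' @param criterion accuracy criterion (default 0.70).
#' @param domain `"contrast"` or `"spatial_frequency"`; taken from `fos` if
#'   absent.
#' @param mode `"raw"` (linear interpolation on the raw points) or
#'   `"isotonic"`.
#' @return a `threshold_estimate`: list with `threshold`, `domain`,
#'   `criterion`, `defined`, `reason` (when undefined), and `fos`.
#' @export
threshold_at_criterion <- function(fos, criterion = 0.70, domain = NULL,
                                   mode = c("raw", "isotonic")) {
  mode <- match.arg(mode)
  if (is.null(domain)) domain <- attr(fos, "domain")
  if (is.null(domain)) stop("domain not given and not carried by the curve")
  stopifnot(nrow(fos) >= 1)

  # order from easiest to hardest
  easy_first <- if (domain == "contrast") order(-fos$level) else order(fos$level)
  lev <- fos$level[easy_first]
  acc <- fos$accuracy[easy_first]
  if (mode == "isotonic" && length(acc) > 1) {
    # accuracy should be nonincreasing with difficulty
    acc <- -stats::isoreg(seq_along(acc), -acc)$yf
  }

  done <- function(th, defined = TRUE, reason = NULL)
    structure(list(threshold = th, domain = domain, criterion = criterion,
                   defined = defined, reason = reason, fos = fos),
              class = "threshold_estimate")

  if (acc[1] < criterion)
    return(done(NA_real_, FALSE, "below criterion at easiest tested level"))
  for (i in seq_along(lev)) {
    if (abs(acc[i] - criterion) < 1e-12) return(done(lev[i]))
    if (acc[i] < criterion) {
      # first drop below criterion scanning from the easy end
      frac <- (acc[i - 1] - criterion) / (acc[i - 1] - acc[i])
      return(done(lev[i - 1] + frac * (lev[i] - lev[i - 1])))
    }
  }
  done(NA_real_, FALSE, "floor not reached: accuracy above criterion at all levels")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<threshold_estimate> %s threshold = %.4g at %.0f%% correct\n",
                x$domain, x$threshold, 100 * x$criterion))
  else
    cat(sprintf("<threshold_estimate> undefined (%s)\n", x$reason))
  invisible(x)
}

#' Contrast sensitivity from a contrast threshold
#'
#' CS is the reciprocal of the Michelson-contrast threshold.
#'
#' @param threshold contrast threshold(s) in (0, 1].
#' @return contrast sensitivity, `1/threshold`.
#' @export
contrast_sensitivity <- function(threshold) {
  if (any(!is.finite(threshold)) || any(threshold <= 0))
    stop("contrast threshold must be positive")
  if (any(threshold > 1)) stop("contrast threshold cannot exceed 1")
  1 / threshold
}

#' Assemble a contrast sensitivity function from per-SF estimates
#'
#' @param sf spatial frequencies (cpd) at which thresholds were measured.
#' @param estimates list of `threshold_estimate` objects (contrast domain),
#'   parallel to `sf`; undefined estimates are dropped with a warning.
#' @return a `csf` data.frame with columns `sf_cpd` and `cs`, sorted by SF.
#' @export
assemble_csf <- function(sf, estimates) {
  stopifnot(length(sf) == length(estimates))
  if (length(sf) == 0) stop("no estimates to assemble")
  defined <- vapply(estimates, function(e) isTRUE(e$defined), logical(1))
  if (!any(defined)) stop("no defined threshold estimates")
  if (any(!defined))
    warning(sum(!defined), " undefined estimate(s) omitted from the CSF")
  th <- vapply(estimates[defined], function(e) e$threshold, numeric(1))
  out <- data.frame(sf_cpd = sf[defined], cs = contrast_sensitivity(th))
  out <- out[order(out$sf_cpd), ]
  rownames(out) <- NULL
  class(out) <- c("csf", "data.frame")
  out
}

#' Naive-mouse contrast sensitivity profile (log-parabola)
#'
#' The generator's CS-vs-SF profile: a parabola in log10 CS over spatial
#' frequency anchored at the three calibrated points CS = 4.59 at 0.21 cpd,
#' CS = 3.75 at 0.33 cpd, and CS = 1 at the acuity limit 0.47 cpd (the
#' contrast threshold reaches 100% there). Inverted-U over the tested range
#' (peak near 0.24 cpd), used to place contrast thresholds at SFs where no
#' printed group mean exists.
#'
#' @param sf spatial frequency (cpd), vectorized.
#' @return contrast sensitivity at `sf`.
#' @export
naive_csf <- function(sf) {
  stopifnot(all(sf > 0))
  x <- c(0.21, 0.33, 0.47); y <- log10(c(4.59, 3.75, 1))
  co <- unname(solve(cbind(1, x, x^2), y))
  unname(10^(co[1] + co[2] * sf + co[3] * sf^2))
}
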
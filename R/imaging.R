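#' Stimulus schedule for intrinsic-signal imaging
#'
#' Two acquisition modes. Periodic: a bar drifts across the visual field at a
#' fixed stimulus frequency (default 0.1 Hz) for `duration_s` seconds, for
#' Fourier retinotopy. Episodic: drifting-grating trials with a 1 s
#' pre-stimulus baseline, 4 s stimulus, an analysis window 2-6 s after
#' stimulus onset (hemodynamic lag), and a 7 s inter-trial gap, repeated
#' over `n_trials` trials for single-condition maps.
#'
#' @param mode `"periodic"` or `"episodic"`.
#' @param f_stim_hz periodic stimulus frequency (Hz).
#' @param duration_s periodic acquisition length (s).
#' @param pre_s,stim_s,gap_s episodic trial phases (s).
#' @param window_s analysis window relative to stimulus onset (s).
#' @param n_trials episodic trial count (default 32).
#' @param sf_cpd grating SF label of the episodic condition.
#' @return a `stimulus_schedule` object.
#' @export
stimulus_schedule <- function(mode = c("episodic", "periodic"),
                              f_stim_hz = 0.1, duration_s = 600,
                              pre_s = 1, stim_s = 4, window_s = c(2, 6),
                              gap_s = 7, n_trials = 32L, sf_cpd = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "periodic") {
    stopifnot(f_stim_hz > 0, duration_s > 0)
    out <- list(mode = mode, f_stim_hz = f_stim_hz, duration_s = duration_s)
  } else {
    trial_s <- pre_s + stim_s + gap_s
    if (pre_s + window_s[2] > trial_s)
      stop("analysis window extends beyond the trial")
    out <- list(mode = mode, pre_s = pre_s, stim_s = stim_s,
                window_s = window_s, gap_s = gap_s,
                trial_s = trial_s, n_trials = as.integer(n_trials),
                sf_cpd = sf_cpd)
  }
  structure(out, class = "stimulus_schedule")
}

#' Frame stack container
#'
#' @param data numeric array, height x width x time.
#' @param frame_interval_s seconds between frames.
#' @param pixel_size_um microns per pixel (default 17).
#' @param schedule the [stimulus_schedule()] the stack was acquired under.
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(data, frame_interval_s, pixel_size_um = 17,
                        schedule = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, all(dim(data) > 0),
            frame_interval_s > 0)
  structure(list(data = data, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um, schedule = schedule),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %.3g s/frame (%.3g um/px)\n",
              d[1], d[2], d[3], x$frame_interval_s, x$pixel_size_um))
  invisible(x)
}

#' Ground-truth description of a synthetic cortex
#'
#' @param cutoff_cpd SF at which the cortical response extrapolates to zero
#'   (0.39 for trained animals, 0.27 for untrained, per the calibration
#'   anchors).
#' @param amplitude peak fractional reflectance decrease (delta-R/R) at the
#'   lowest SFs.
#' @param noise_sd per-pixel, per-frame Gaussian noise SD (same fractional
#'   units as `amplitude`).
#' @param drift_amp amplitude of a slow spatially uniform reflectance drift.
#' @param drift_period_s period of the drift (s).
#' @param blob_center,blob_sigma_frac center (fractional x, y) and width
#'   (fraction of image size) of the Gaussian responsive region emulating the
#'   V1 representation.
#' @param phase_span radians of retinotopic phase spanned across the
#'   horizontal axis in periodic mode.
#' @return a `cortex_truth` list.
#' @export
cortex_truth <- function(cutoff_cpd = 0.39, amplitude = 2e-3,
                         noise_sd = 5e-4, drift_amp = 2e-4,
                         drift_period_s = 90,
                         blob_center = c(0.5, 0.5), blob_sigma_frac = 0.22,
                         phase_span = pi) {
  stopifnot(cutoff_cpd > 0, amplitude >= 0, noise_sd >= 0)
  structure(list(cutoff_cpd = cutoff_cpd, amplitude = amplitude,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_period_s = drift_period_s, blob_center = blob_center,
                 blob_sigma_frac = blob_sigma_frac, phase_span = phase_span),
            class = "cortex_truth")
}

# Gaussian responsive-region map in [0, 1]
.blob_map <- function(h, w, truth) {
  cx <- truth$blob_center[1] * w; cy <- truth$blob_center[2] * h
  sg <- truth$blob_sigma_frac * min(h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
}

# trapezoidal hemodynamic time course within one episodic trial: the
# stimulus boxcar convolved with a 2 s boxcar kernel, peaking at 1 over the
# plateau that covers the analysis window
.hemo_profile <- function(t, pre_s, stim_s, kernel_s = 2) {
  on <- pre_s; off <- pre_s + stim_s
  # overlap of a boxcar kernel [t - kernel_s, t] with the stimulus [on, off]
  ov <- (pmin(t, off) - pmax(t - kernel_s, on)) / kernel_s
  pmax(0, pmin(1, ov))
}

#' Generate a synthetic intrinsic-signal frame stack
#'
#' Periodic mode embeds, in each responsive pixel, a sinusoidal reflectance
#' modulation at the stimulus frequency whose phase increases linearly along
#' the horizontal axis (a retinotopic gradient). Episodic mode embeds a
#' boxcar-convolved hemodynamic reflectance *decrease* whose amplitude falls
#' linearly with grating SF, reaching zero at the true cut-off SF (and zero
#' beyond). Both add white Gaussian noise and a slow uniform drift. Baseline
#' reflectance is 1.
#'
#' @param truth a [cortex_truth()].
#' @param schedule a [stimulus_schedule()].
#' @param dim_px image size `c(height, width)`.
#' @param fps frames per second (default 5).
#' @return a [frame_stack()].
#' @export
synth_cortex <- function(truth, schedule, dim_px = c(64, 64), fps = 5) {
  stopifnot(inherits(truth, "cortex_truth"), inherits(schedule, "stimulus_schedule"))
  h <- dim_px[1]; w <- dim_px[2]
  blob <- .blob_map(h, w, truth)
  if (schedule$mode == "periodic") {
    nt <- round(schedule$duration_s * fps)
    t <- (seq_len(nt) - 1) / fps
    phase <- matrix(rep(truth$phase_span * (seq_len(w) - 1) / max(w - 1, 1),
                        each = h), h, w)
    sig <- array(0, c(h, w, nt))
    amp <- truth$amplitude * blob
    for (k in seq_len(nt))
      sig[, , k] <- amp * cos(2 * pi * schedule$f_stim_hz * t[k] + phase)
    base <- 1 - sig
  } else {
    per_trial <- round(schedule$trial_s * fps)
    nt <- per_trial * schedule$n_trials
    t_trial <- (seq_len(per_trial) - 1) / fps
    hprof <- .hemo_profile(t_trial, schedule$pre_s, schedule$stim_s)
    hprof <- rep(hprof, schedule$n_trials)
    a <- truth$amplitude * max(0, 1 - schedule$sf_cpd / truth$cutoff_cpd)
    # outer product: (h*w) x nt fractional response, reflectance decrease
    base <- 1 - array(as.vector(blob) %o% (a * hprof), c(h, w, nt))
    t <- (seq_len(nt) - 1) / fps
  }
  drift <- truth$drift_amp * sin(2 * pi * t / truth$drift_period_s)
  base <- base + rep(drift, each = h * w)
  if (truth$noise_sd > 0)
    base <- base + array(stats::rnorm(length(base), 0, truth$noise_sd), dim(base))
  frame_stack(base, frame_interval_s = 1 / fps, schedule = schedule)
}

#' Per-pixel Fourier analysis at the stimulus frequency
#'
#' Extracts, pixel by pixel, the complex amplitude at `f_stim`: a magnitude
#' map (response strength) and a phase map (stimulus position / eccentricity)
#' in (-pi, pi]. The stack is truncated to a whole number of stimulus cycles
#' so a constant stack gives exactly zero magnitude; the magnitude is scaled
#' so a pure cosine of amplitude A returns A.
#'
#' @param stack a [frame_stack()].
#' @param f_stim stimulus frequency (Hz); must not exceed Nyquist.
#' @return a `retinotopy_map`: list with `magnitude` and `phase` matrices.
#' @export
fourier_map <- function(stack, f_stim = 0.1) {
  stopifnot(inherits(stack, "frame_stack"))
  dt <- stack$frame_interval_s
  if (f_stim > 1 / (2 * dt)) stop("stimulus frequency above Nyquist")
  d <- dim(stack$data); nt <- d[3]
  cycles <- floor(nt * dt * f_stim)
  if (cycles < 1) stop("stack shorter than one stimulus cycle")
  nuse <- min(nt, round(cycles / (f_stim * dt)))
  t <- (seq_len(nuse) - 1) * dt
  e <- exp(-2i * pi * f_stim * t)
  m <- matrix(stack$data[, , seq_len(nuse)], d[1] * d[2], nuse)
  z <- as.vector(m %*% e) * (2 / nuse)
  structure(list(magnitude = matrix(Mod(z), d[1], d[2]),
                 phase = matrix(Arg(z), d[1], d[2])),
            class = "retinotopy_map")
}

#' Single-condition delta-R/R map
#'
#' Per trial, the mean frame over the analysis window (2-6 s after stimulus
#' onset) has the blank frame (mean over the 1 s pre-stimulus interval)
#' subtracted and is divided by it, pixelwise; the per-trial maps are then
#' averaged over all trials. The map is signed: intrinsic responses are
#' reflectance decreases, so responsive pixels are negative.
#'
#' @param stack a [frame_stack()] acquired under an episodic schedule.
#' @param schedule optional override of `stack$schedule`.
#' @return a `condition_map`: matrix with attributes `sf_cpd`, `smoothed`,
#'   and `blank_sd` (SD of blank-frame pixel values, the noise floor
#'   reference).
#' @export
condition_map <- function(stack, schedule = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  sch <- if (is.null(schedule)) stack$schedule else schedule
  if (is.null(sch) || sch$mode != "episodic")
    stop("condition maps need an episodic stimulus schedule")
  fps <- 1 / stack$frame_interval_s
  d <- dim(stack$data)
  per_trial <- round(sch$trial_s * fps)
  if (per_trial * sch$n_trials > d[3]) stop("stack shorter than the schedule")
  blank_idx <- seq_len(max(1, round(sch$pre_s * fps)))
  w0 <- round((sch$pre_s + sch$window_s[1]) * fps) + 1
  w1 <- round((sch$pre_s + sch$window_s[2]) * fps)
  acc <- matrix(0, d[1], d[2]); blank_sds <- numeric(sch$n_trials)
  for (k in seq_len(sch$n_trials)) {
    off <- (k - 1) * per_trial
    blank <- .mean_frames(stack$data, off + blank_idx)
    if (any(blank == 0)) stop("division by zero baseline in blank frame")
    win <- .mean_frames(stack$data, (off + w0):(off + w1))
    acc <- acc + (win - blank) / blank
    blank_sds[k] <- stats::sd(blank)
  }
  out <- acc / sch$n_trials
  attr(out, "sf_cpd") <- sch$sf_cpd
  attr(out, "smoothed") <- FALSE
  attr(out, "blank_sd") <- mean(blank_sds)
  class(out) <- c("condition_map", "matrix", "array")
  out
}

.mean_frames <- function(arr, idx) {
  if (length(idx) == 1) return(arr[, , idx])
  rowMeans(matrix(arr[, , idx], dim(arr)[1] * dim(arr)[2], length(idx))) |>
    matrix(dim(arr)[1], dim(arr)[2])
}

#' Circular-average smoothing of a map
#'
#' Each pixel is replaced by the mean over a disk of the given radius
#' (default 3 px = 51 um at 17 um/px). Near borders the partial disk is
#' renormalized by the number of in-bounds pixels, avoiding padding
#' artifacts.
#'
#' @param map a matrix (e.g. a [condition_map()]).
#' @param radius_px disk radius in pixels (>= 1).
#' @return the smoothed map, attributes preserved, `smoothed = TRUE`.
#' @export
smooth_map <- function(map, radius_px = 3) {
  stopifnot(radius_px >= 1)
  h <- nrow(map); w <- ncol(map)
  off <- expand.grid(dy = -radius_px:radius_px, dx = -radius_px:radius_px)
  off <- off[off$dy^2 + off$dx^2 <= radius_px^2, ]
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]
    ys <- max(1, 1 - dy):min(h, h - dy)   # destination rows
    xs <- max(1, 1 - dx):min(w, w - dx)
    num[ys, xs] <- num[ys, xs] + map[ys + dy, xs + dx, drop = FALSE]
    den[ys, xs] <- den[ys, xs] + 1
  }
  out <- num / den
  attributes(out) <- attributes(map)
  dim(out) <- c(h, w)
  attr(out, "smoothed") <- TRUE
  out
}

#' Default region of interest from the lowest-SF condition
#'
#' Pixels in the top decile of smoothed response magnitude of the lowest-SF
#' condition map, emulating a hand-drawn binocular-V1 ROI.
#'
#' @param map a (smoothed) condition map.
#' @param top_frac fraction of pixels kept (default 0.1).
#' @return logical matrix ROI.
#' @export
default_roi <- function(map, top_frac = 0.1) {
  mag <- abs(unclass(map))
  thr <- stats::quantile(mag, 1 - top_frac)
  roi <- mag >= thr
  dim(roi) <- dim(mag)
  roi
}

#' ROI spatial-frequency tuning from condition maps
#'
#' Mean delta-R/R over the ROI per condition, with the intrinsic-signal sign
#' convention: reflectance decreases are reported as positive response
#' magnitudes.
#'
#' @param maps list of condition maps (each carrying its `sf_cpd`
#'   attribute).
#' @param roi logical matrix, same size as the maps; non-empty.
#' @return data.frame with `sf_cpd`, `response` (positive = stronger), and
#'   `noise_floor` (2 x mean blank SD propagated from the maps, `NA` when
#'   unavailable).
#' @export
roi_tuning <- function(maps, roi) {
  if (!any(roi)) stop("empty ROI")
  rows <- lapply(maps, function(m) {
    if (any(dim(m) != dim(roi))) stop("ROI does not match map dimensions")
    bs <- attr(m, "blank_sd")
    data.frame(sf_cpd = attr(m, "sf_cpd"),
               response = -mean(unclass(m)[roi]),
               noise_floor = if (is.null(bs)) NA_real_ else 2 * bs)
  })
  out <- do.call(rbind, rows)
  out[order(out$sf_cpd), ]
}

#' Cut-off spatial frequency by zero-crossing of a linear fit
#'
#' Fits an ordinary least-squares line to (SF, response) and returns the SF
#' at which the line crosses zero. By default, the fit uses the conditions
#' whose response exceeds the noise floor plus the first subthreshold
#' condition (a zero-crossing extrapolation); set `all_points = TRUE` to fit
#' every condition. The fit is only valid for declining tuning (negative
#' slope) with the crossing inside the tested range or within twice its
#' upper end.
#'
#' @param tuning data.frame from [roi_tuning()] (`sf_cpd`, `response`,
#'   optionally `noise_floor`).
#' @param noise_floor response level separating signal from noise; defaults
#'   to the tuning's propagated `noise_floor` scaled by the trial/ROI
#'   averaging, or 0 when unavailable.
#' @param all_points fit all conditions regardless of the floor.
#' @return a `cutoff_fit`: list with `points` (used in the fit), `slope`,
#'   `intercept`, `cutoff_cpd`.
#' @export
cutoff_sf <- function(tuning, noise_floor = NULL, all_points = FALSE) {
  stopifnot(nrow(tuning) >= 3)
  tuning <- tuning[order(tuning$sf_cpd), ]
  if (all_points) {
    use <- rep(TRUE, nrow(tuning))
  } else {
    if (is.null(noise_floor)) noise_floor <- 0
    supra <- tuning$response > noise_floor
    use <- supra
    if (any(supra)) {
      first_sub <- which(!supra & tuning$sf_cpd > max(tuning$sf_cpd[supra]))
      if (length(first_sub) > 0) use[min(first_sub)] <- TRUE
    }
  }
  if (sum(use) < 3) use <- rep(TRUE, nrow(tuning))
  fit <- stats::lm(response ~ sf_cpd, data = tuning[use, ])
  b <- stats::coef(fit)
  # a numerically flat line is not a declining fit
  eps <- 1e-9 * max(abs(tuning$response), 1e-300) / diff(range(tuning$sf_cpd))
  if (!is.finite(b[2]) || b[2] >= -eps)
    stop("no declining tuning; cutoff undefined")
  cutoff <- unname(-b[1] / b[2])
  hi <- max(tuning$sf_cpd)
  if (cutoff > 2 * hi || cutoff < min(tuning$sf_cpd))
    warning("cut-off extrapolates far outside the tested SF range")
  structure(list(points = tuning[use, c("sf_cpd", "response")],
                 slope = unname(b[2]), intercept = unname(b[1]),
                 cutoff_cpd = cutoff),
            class = "cutoff_fit")
}

#' @export
print.cutoff_fit <- function(x, ...) {
  cat(sprintf("<cutoff_fit> cutoff = %.3f cpd (slope %.3g, %d points)\n",
              x$cutoff_cpd, x$slope, nrow(x$points)))
  invisible(x)
}

#' Phase scatter of a retinotopic map
#'
#' Map-quality index: the mean absolute circular deviation between each
#' suprathreshold pixel's phase and the circular mean phase over the
#' surrounding disk (suprathreshold pixels only). Lower is cleaner; a
#' perfectly smooth phase gradient scores near zero, random phases near the
#' circular-uniform expectation.
#'
#' @param retmap a [fourier_map()] result.
#' @param magnitude_threshold pixels with magnitude >= this enter the
#'   analysis; default the 75th percentile of the magnitude map.
#' @param radius_px neighborhood disk radius (default 3).
#' @return mean absolute circular deviation (radians).
#' @export
map_scatter <- function(retmap, magnitude_threshold = NULL, radius_px = 3) {
  stopifnot(inherits(retmap, "retinotopy_map"))
  if (is.null(magnitude_threshold))
    magnitude_threshold <- stats::quantile(retmap$magnitude, 0.75)
  keep <- retmap$magnitude >= magnitude_threshold
  if (!any(keep)) stop("no pixels above the magnitude threshold")
  # local circular mean via smoothed unit phasors restricted to kept pixels
  zr <- cos(retmap$phase) * keep
  zi <- sin(retmap$phase) * keep
  n <- smooth_map(keep * 1, radius_px)
  mr <- smooth_map(zr, radius_px); mi <- smooth_map(zi, radius_px)
  mu <- atan2(mi, mr)
  dev <- abs(atan2(sin(retmap$phase - mu), cos(retmap$phase - mu)))
  mean(dev[keep & n > 0])
}

#' Phase-average two opposite-direction retinotopy maps
#'
#' Combines maps from opposite sweep directions to cancel the common
#' hemodynamic delay: the delay adds to the phase in both directions while
#' retinotopy enters with opposite signs, so averaging the phase of one map
#' with the negated phase of the other removes it.
#'
#' @param map_fwd,map_rev [fourier_map()] results for the two directions.
#' @return a `retinotopy_map` with averaged magnitude and delay-corrected
#'   phase.
#' @export
combine_directions <- function(map_fwd, map_rev) {
  stopifnot(inherits(map_fwd, "retinotopy_map"), inherits(map_rev, "retinotopy_map"))
  # (phi_f - phi_r)/2 = retinotopic phase; delay cancels
  ph <- Arg(exp(1i * (map_fwd$phase - map_rev$phase) / 2))
  structure(list(magnitude = (map_fwd$magnitude + map_rev$magnitude) / 2,
                 phase = ph),
            class = "retinotopy_map")
}

#' Full imaging pipeline for one synthetic animal
#'
#' Generates episodic stacks for each SF condition, computes smoothed
#' single-condition maps, selects the default ROI from the lowest-SF
#' condition, extracts the ROI tuning curve, and fits the cut-off SF.
#'
#' @param truth a [cortex_truth()].
#' @param sf_conditions grating SFs (cpd) to image.
#' @param dim_px,fps stack geometry.
#' @param n_trials trials per condition (default 32).
#' @return list with `tuning` (data.frame), `fit` (a `cutoff_fit`), `roi`.
#' @export
imaging_pipeline <- function(truth, sf_conditions = seq(0.05, 0.5, by = 0.05),
                             dim_px = c(64, 64), fps = 5, n_trials = 32L) {
  maps <- lapply(sf_conditions, function(sf) {
    sch <- stimulus_schedule("episodic", n_trials = n_trials, sf_cpd = sf)
    st <- synth_cortex(truth, sch, dim_px = dim_px, fps = fps)
    smooth_map(condition_map(st))
  })
  roi <- default_roi(maps[[which.min(sf_conditions)]])
  tuning <- roi_tuning(maps, roi)
  # noise floor for the fit: 2 x SD of ROI means under the blank, approximated
  # by the propagated blank SD shrunk by the averaging factor
  nf <- stats::median(tuning$noise_floor) / sqrt(sum(roi) * n_trials)
  if (!is.finite(nf)) nf <- 0
  fit <- cutoff_sf(tuning, noise_floor = nf)
  list(tuning = tuning, fit = fit, roi = roi)
}
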
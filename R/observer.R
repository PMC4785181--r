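#' Psychometric parameters for a 2AFC observer
#'
#' Describes one simulated eye/task combination as a logistic psychometric
#' function on the log10 stimulus axis. The threshold `alpha` is parameterized
#' directly at the performance criterion (70% correct by default), so printed
#' group thresholds map one-to-one onto `alpha`: `p_correct(params, alpha)`
#' equals the criterion exactly, whatever the lapse rate.
#'
#' @param domain `"contrast"` (Michelson contrast in (0, 1]) or
#'   `"spatial_frequency"` (grating SF in cycles per degree, cpd).
#' @param alpha threshold stimulus level, i.e. the level at which expected
#'   accuracy equals `criterion`.
#' @param beta psychometric slope (dimensionless, per log10 stimulus unit);
#'   must be positive.
#' @param lapse lapse rate lambda in \[0, 0.1\]; the upper asymptote is
#'   `1 - lapse`.
#' @param guess guess rate; fixed at 0.5 for 2AFC.
#' @param criterion the accuracy defining the threshold (default 0.70).
#' @return an object of class `psychometric_params`.
#' @seealso [p_correct()], [make_profile()]
#' @export
psychometric_params <- function(domain = c("contrast", "spatial_frequency"),
                                alpha, beta, lapse = 0.02, guess = 0.5,
                                criterion = 0.70) {
  domain <- match.arg(domain)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (domain == "contrast" && (alpha <= 0 || alpha > 1))
    stop("contrast threshold must lie in (0, 1]")
  if (domain == "spatial_frequency" && alpha <= 0)
    stop("spatial-frequency threshold must be positive")
  if (beta <= 0) stop("slope beta must be positive")
  if (lapse < 0 || lapse > 0.1) stop("lapse rate must lie in [0, 0.1]")
  if (guess != 0.5) stop("guess rate is fixed at 0.5 for 2AFC")
  if (criterion <= guess || criterion >= 1 - lapse)
    stop("criterion must lie strictly between guess and 1 - lapse")
  structure(list(domain = domain, alpha = alpha, beta = beta,
                 lapse = lapse, guess = guess, criterion = criterion),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf("<psychometric_params> %s: alpha = %.4g, beta = %.3g, lapse = %.3g (p(alpha) = %.2f)\n",
              x$domain, x$alpha, x$beta, x$lapse, x$criterion))
  invisible(x)
}

# Difficulty orientation: performance rises with contrast and falls with SF.
.difficulty_sign <- function(domain) if (domain == "contrast") 1 else -1

#' Probability of a correct 2AFC choice
#'
#' `p = guess + (1 - guess - lapse) * F(log10 level)`, with `F` a logistic
#' oriented so performance rises for easier stimuli (higher contrast, lower
#' SF). The logistic offset is chosen so that `p_correct(params, alpha)` is
#' exactly the criterion accuracy.
#'
#' @param params a [psychometric_params()] object.
#' @param level stimulus level(s); positive, and at most 1 for contrast.
#' @return expected proportion correct, in `[guess, 1 - lapse]`; vectorized
#'   over `level`.
#' @examples
#' p <- psychometric_params("contrast", alpha = 0.27, beta = 8)
#' p_correct(p, 0.27)  # 0.70 by construction
#' @export
p_correct <- function(params, level) {
  stopifnot(inherits(params, "psychometric_params"))
  if (any(!is.finite(level)) || any(level <= 0))
    stop("stimulus level must be positive")
  if (params$domain == "contrast" && any(level > 1))
    stop("contrast cannot exceed 1")
  span <- 1 - params$guess - params$lapse
  # offset so F(alpha) = (criterion - guess) / span, i.e. p(alpha) = criterion
  b0 <- stats::qlogis((params$criterion - params$guess) / span)
  s <- .difficulty_sign(params$domain)
  f <- stats::plogis(s * params$beta * (log10(level) - log10(params$alpha)) + b0)
  params$guess + span * f
}

#' Learning parameters of a simulated observer
#'
#' Perceptual learning is modeled as a saturating exponential in the
#' cumulative "effective dose" of near-threshold trials: after `d` trials
#' within `proximity_bandwidth` log10 units of the current threshold,
#' `alpha(d) = alpha_asymptote + (alpha_start - alpha_asymptote) * exp(-d/tau)`.
#' Trials far from threshold (easy control stimuli) contribute no dose, which
#' reproduces the inefficacy of easy-stimulus control training.
#'
#' @param alpha_start initial threshold.
#' @param alpha_asymptote post-training threshold the observer converges to.
#' @param tau learning time constant in effective near-threshold trials.
#' @param proximity_bandwidth half-width (log10 units) of the window around
#'   the current threshold within which a trial drives learning. The default
#'   must cover the one-step tracking range of the staircase the training
#'   protocol uses: a 0.1 contrast step near a post-training threshold of
#'   ~0.14 spans ~0.23 log10 units, so contrast-domain profiles use 0.25,
#'   while the much finer 0.03 cpd acuity grid is covered by 0.15. Easy
#'   control stimuli remain far outside either window.
#' @param interocular_transfer_fraction fraction of the trained eye's
#'   log-threshold shift inherited by the untrained eye under monocular
#'   training (default 0.63, calibrated to the printed 67%/42% trained /
#'   untrained eye improvements).
#' @param task_transfer fraction of the threshold shift shared with the other
#'   task class; a named vector with entries `discrimination_to_detection`
#'   and `detection_to_discrimination`.
#' @return an object of class `learning_params`.
#' @export
learning_params <- function(alpha_start, alpha_asymptote, tau = 150,
                            proximity_bandwidth = 0.15,
                            interocular_transfer_fraction = 0.63,
                            task_transfer = c(discrimination_to_detection = 0.90,
                                              detection_to_discrimination = 0.07)) {
  stopifnot(alpha_start > 0, alpha_asymptote > 0)
  if (tau <= 0) stop("tau must be positive")
  if (proximity_bandwidth <= 0) stop("proximity_bandwidth must be positive")
  if (interocular_transfer_fraction < 0 || interocular_transfer_fraction > 1)
    stop("interocular_transfer_fraction must lie in [0, 1]")
  if (any(task_transfer < 0) || any(task_transfer > 1))
    stop("task transfer fractions must lie in [0, 1]")
  structure(list(alpha_start = alpha_start, alpha_asymptote = alpha_asymptote,
                 tau = tau, proximity_bandwidth = proximity_bandwidth,
                 interocular_transfer_fraction = interocular_transfer_fraction,
                 task_transfer = task_transfer),
            class = "learning_params")
}

# threshold along the learning curve at cumulative dose d
.alpha_at_dose <- function(lp, dose) {
  lp$alpha_asymptote + (lp$alpha_start - lp$alpha_asymptote) * exp(-dose / lp$tau)
}

#' Named observer profiles calibrated to printed group values
#'
#' Presets bundle psychometric and learning parameters per stimulus domain
#' (and per eye for the amblyopic profile), plus the between-animal spread of
#' thresholds (log-normal, SD on the log10 axis). Calibration anchors:
#' naive contrast threshold at 0.33 cpd = 1/3.75 (contrast sensitivity 3.75),
#' naive acuity 0.47 cpd; trained asymptotes 1/7.05 and 0.72 cpd; amblyopic
#' deprived eye 0.28 cpd (fellow 0.46 cpd) recovering to 0.47 cpd with
#' training. The `old` preset is a configurable placeholder (no printed
#' baseline exists): lower acuity and a slower learning rate.
#'
#' @param name one of `"naive"`, `"nct_trained"`, `"nsft_trained"`,
#'   `"control"`, `"amblyopic"`, `"old"`.
#' @return an object of class `observer_profile` with elements `psy` (named
#'   list of [psychometric_params()] per domain), `learning` (per domain),
#'   optional `eye` (per-eye psychometric/learning overrides), and
#'   `sd_log10`.
#' @export
make_profile <- function(name) {
  presets <- c("naive", "nct_trained", "nsft_trained", "control",
               "amblyopic", "old")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop("unknown profile; available presets: ", paste(presets, collapse = ", "))

  beta_c <- 8    # contrast-domain slope per log10 unit
  beta_s <- 25   # SF-domain slope (acuity range is narrow on the log axis)
  cs_naive <- 1 / 3.75        # contrast threshold at 0.33 cpd
  cs_post  <- 1 / 7.05
  va_naive <- 0.47
  va_post  <- 0.72

  psy <- function(domain, alpha, beta) psychometric_params(domain, alpha, beta)
  base <- list(
    psy = list(contrast = psy("contrast", cs_naive, beta_c),
               spatial_frequency = psy("spatial_frequency", va_naive, beta_s)),
    learning = list(
      contrast = learning_params(cs_naive, cs_post, proximity_bandwidth = 0.25),
      spatial_frequency = learning_params(va_naive, va_post)),
    sd_log10 = 0.05)

  prof <- switch(name,
    naive = base,
    control = base,   # controls differ by regimen, not by visual system
    nct_trained = {
      b <- base
      b$psy$contrast <- psy("contrast", cs_post, beta_c)
      b$learning$contrast <- learning_params(cs_post, cs_post,
                                             proximity_bandwidth = 0.25)
      b
    },
    nsft_trained = {
      b <- base
      b$psy$spatial_frequency <- psy("spatial_frequency", va_post, beta_s)
      b$learning$spatial_frequency <- learning_params(va_post, va_post)
      b
    },
    amblyopic = {
      b <- base
      b$eye <- list(
        deprived = list(
          psy = psy("spatial_frequency", 0.28, beta_s),
          learning = learning_params(0.28, 0.47)),
        fellow = list(
          psy = psy("spatial_frequency", 0.46, beta_s),
          learning = learning_params(0.46, 0.50)))
      b$psy$spatial_frequency <- b$eye$deprived$psy
      b$learning$spatial_frequency <- b$eye$deprived$learning
      b
    },
    old = {
      # placeholder: no printed baseline; lower acuity, 3x slower learning
      b <- base
      b$psy$spatial_frequency <- psy("spatial_frequency", 0.40, beta_s)
      b$learning$spatial_frequency <- learning_params(0.40, 0.55, tau = 450)
      b$calibrated <- FALSE
      b
    })
  prof$name <- name
  if (is.null(prof$calibrated)) prof$calibrated <- TRUE
  class(prof) <- "observer_profile"
  prof
}

#' @export
print.observer_profile <- function(x, ...) {
  cat(sprintf("<observer_profile> '%s'%s\n", x$name,
              if (!x$calibrated) " (placeholder, uncalibrated)" else ""))
  for (d in names(x$psy))
    cat(sprintf("  %s: alpha = %.4g (asymptote %.4g)\n", d,
                x$psy[[d]]$alpha, x$learning[[d]]$alpha_asymptote))
  if (!is.null(x$eye))
    cat("  eyes:", paste(names(x$eye), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic child seed for one simulated animal
#'
#' Stable integer hash of `(seed, id)` so that a cohort is reproducible from
#' one master seed while animals get independent streams. Values stay below
#' 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param id animal index (integer).
#' @return an integer seed.
#' @export
child_seed <- function(seed, id) {
  m <- 2147483647
  h <- as.double(seed) %% m
  h <- (h * 48271 + as.double(id)) %% m
  h <- (h * 48271 + 11) %% m
  as.integer(h)
}

#' Instantiate one simulated observer from a profile
#'
#' Draws the animal's true threshold from a log-normal distribution centered
#' on the profile's calibrated `alpha` (SD `sd_log10` on the log10 axis) and
#' returns an `observer_state` carrying the current psychometric function,
#' learning parameters, and cumulative effective training dose.
#'
#' @param profile an [make_profile()] object (or preset name).
#' @param domain assessment domain, `"contrast"` or `"spatial_frequency"`.
#' @param id animal identifier (integer; used for the RNG child stream).
#' @param seed master seed; the observer uses [child_seed()]`(seed, id)`.
#' @param eye for profiles with per-eye parameters (amblyopic): `"deprived"`
#'   or `"fellow"`; otherwise ignored.
#' @return an object of class `observer_state`.
#' @export
make_observer <- function(profile, domain = c("contrast", "spatial_frequency"),
                          id = 1L, seed = 1L, eye = NULL) {
  if (is.character(profile)) profile <- make_profile(profile)
  stopifnot(inherits(profile, "observer_profile"))
  domain <- match.arg(domain)
  if (!is.null(eye) && !is.null(profile$eye)) {
    if (!eye %in% names(profile$eye)) stop("unknown eye: ", eye)
    psy <- profile$eye[[eye]]$psy
    lp <- profile$eye[[eye]]$learning
    if (psy$domain != domain) stop("per-eye parameters are ", psy$domain,
                                   "-domain; requested ", domain)
  } else {
    psy <- profile$psy[[domain]]
    lp <- profile$learning[[domain]]
  }
  cs <- child_seed(seed, id)
  set.seed(cs)
  shift <- stats::rnorm(1, 0, profile$sd_log10)
  alpha <- 10^(log10(psy$alpha) + shift)
  if (psy$domain == "contrast") alpha <- min(alpha, 1)
  psy$alpha <- alpha
  # animal-level variability shifts the whole learning curve with the animal
  lp$alpha_start <- 10^(log10(lp$alpha_start) + shift)
  lp$alpha_asymptote <- 10^(log10(lp$alpha_asymptote) + shift)
  if (psy$domain == "contrast") {
    lp$alpha_start <- min(lp$alpha_start, 1)
    lp$alpha_asymptote <- min(lp$alpha_asymptote, 1)
  }
  structure(list(profile_name = profile$name, id = id, seed = cs,
                 psy = psy, learning = lp, dose = 0,
                 untrained_alpha = NULL),
            class = "observer_state")
}

#' @export
print.observer_state <- function(x, ...) {
  cat(sprintf("<observer_state> animal %d (%s, %s): alpha = %.4g, dose = %.0f trials\n",
              x$id, x$profile_name, x$psy$domain, x$psy$alpha, x$dose))
  invisible(x)
}

#' Simulate one 2AFC choice
#'
#' The choice is correct with probability [p_correct()] at the presented
#' level; on an error the returned choice is the side opposite the S+.
#' Uses the current R RNG stream (seed it for reproducibility).
#'
#' @param observer an `observer_state`, a `psychometric_params` object, or a
#'   function `level -> p` (used for deterministic test observers).
#' @param level stimulus level.
#' @param s_plus_side `"left"` or `"right"`.
#' @param is_correction logical flag carried into the trial record.
#' @return a one-row data.frame (a `Trial`): `level`, `s_plus_side`,
#'   `choice`, `correct`, `is_correction`.
#' @export
simulate_choice <- function(observer, level, s_plus_side = c("left", "right"),
                            is_correction = FALSE) {
  s_plus_side <- match.arg(s_plus_side)
  p <- observer_p(observer, level)
  correct <- stats::runif(1) < p
  choice <- if (correct) s_plus_side else setdiff(c("left", "right"), s_plus_side)
  data.frame(level = level, s_plus_side = s_plus_side, choice = choice,
             correct = correct, is_correction = is_correction,
             stringsAsFactors = FALSE)
}

# expected accuracy of any observer representation at a level
observer_p <- function(observer, level) {
  if (is.function(observer)) return(observer(level))
  if (inherits(observer, "observer_state")) return(p_correct(observer$psy, level))
  if (inherits(observer, "psychometric_params")) return(p_correct(observer, level))
  stop("not an observer")
}

#' Update an observer's learning state from a day's trials
#'
#' Counts the non-correction trials lying within `proximity_bandwidth` log10
#' units of the observer's current threshold, adds them to the cumulative
#' effective dose, and moves the threshold along the saturating learning
#' curve. Easy control stimuli (100% contrast, 0.12 cpd) fall outside the
#' bandwidth for calibrated profiles and contribute nothing.
#'
#' For monocular training (`eye_weight < 1` on some updates) the untrained
#' eye can be tracked via `transfer_fraction`: its threshold receives that
#' fraction of the trained eye's log10 shift.
#'
#' @param state an `observer_state`.
#' @param trials a trial data.frame (as produced by the task engine); only
#'   non-correction rows drive learning.
#' @param transfer_fraction if not `NULL`, also update
#'   `state$untrained_alpha` with this fraction of the log-threshold shift.
#' @return the updated `observer_state`.
#' @export
update_learning <- function(state, trials, transfer_fraction = NULL) {
  stopifnot(inherits(state, "observer_state"))
  lp <- state$learning
  old_alpha <- state$psy$alpha
  if (!is.null(trials) && nrow(trials) > 0) {
    lv <- trials$level[!trials$is_correction]
    near <- abs(log10(lv) - log10(state$psy$alpha)) <= lp$proximity_bandwidth
    state$dose <- state$dose + sum(near)
  }
  new_alpha <- .alpha_at_dose(lp, state$dose)
  if (state$psy$domain == "contrast") new_alpha <- max(min(new_alpha, 1), 1e-6)
  state$psy$alpha <- new_alpha
  if (!is.null(transfer_fraction)) {
    if (is.null(state$untrained_alpha)) state$untrained_alpha <- old_alpha
    shift <- log10(new_alpha) - log10(old_alpha)
    state$untrained_alpha <- 10^(log10(state$untrained_alpha) +
                                   transfer_fraction * shift)
  }
  state
}

#' Simulate a cohort of observers
#'
#' @param profile preset name or `observer_profile`.
#' @param n number of animals.
#' @param domain assessment domain.
#' @param seed master seed; animal `i` uses [child_seed()]`(seed, i)`.
#' @param eye optional eye label for per-eye profiles.
#' @return list of `observer_state` objects (animal ids `1:n`).
#' @export
simulate_cohort <- function(profile, n, domain = c("contrast", "spatial_frequency"),
                            seed = 1L, eye = NULL) {
  domain <- match.arg(domain)
  if (is.character(profile)) profile <- make_profile(profile)
  lapply(seq_len(n), function(i)
    make_observer(profile, domain, id = i, seed = seed, eye = eye))
}

#' Export a cohort as a data.frame (one row per animal)
#'
#' @param cohort a list of `observer_state` objects.
#' @return data.frame with `animal_id`, `profile`, `domain`, `true_alpha`,
#'   `seed`.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(o)
    data.frame(animal_id = o$id, profile = o$profile_name,
               domain = o$psy$domain, true_alpha = o$psy$alpha,
               seed = o$seed, stringsAsFactors = FALSE)))
}
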
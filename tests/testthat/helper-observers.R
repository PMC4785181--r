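# deterministic-ish test observers used across files

# contrast-domain step observer: perfect above `cut`, guessing (or worse)
# below; pass a function so the task engine sees an arbitrary p(level)
step_observer <- function(cut, p_hi = 1, p_lo = 0.5) {
  function(level) ifelse(level > cut, p_hi, p_lo)
}

# quick naive observer with a fixed true threshold (no between-animal draw)
fixed_params <- function(domain = "contrast",
                         alpha = if (domain == "contrast") 1 / 3.75 else 0.47,
                         beta = if (domain == "contrast") 8 else 25,
                         lapse = 0.02) {
  psychometric_params(domain, alpha, beta, lapse = lapse)
}

# episodic frame stack with an exact fractional response r in the analysis
# window (window frames at baseline * (1 + r)); used to check delta-R/R
# linearity end to end
episodic_fixture <- function(r, baseline = 0.8, n_trials = 3, fps = 5,
                             h = 4, w = 4, sf = 0.2) {
  sch <- stimulus_schedule("episodic", n_trials = n_trials, sf_cpd = sf)
  per_trial <- sch$trial_s * fps
  arr <- array(baseline, c(h, w, per_trial * n_trials))
  w0 <- (sch$pre_s + sch$window_s[1]) * fps + 1
  w1 <- (sch$pre_s + sch$window_s[2]) * fps
  for (k in seq_len(n_trials)) {
    off <- (k - 1) * per_trial
    arr[, , (off + w0):(off + w1)] <- baseline * (1 + r)
  }
  frame_stack(arr, 1 / fps, schedule = sch)
}

# minimal trial data.frame for psychometrics tests
make_trials <- function(level, correct, is_correction = FALSE,
                        domain = "contrast") {
  data.frame(level = level, correct = correct,
             is_correction = rep_len(is_correction, length(level)),
             domain = domain, stringsAsFactors = FALSE)
}
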
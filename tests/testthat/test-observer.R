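test_that("psychometric function hits its anchors: criterion at alpha, guessing floor, lapse ceiling", {
  for (dom in c("contrast", "spatial_frequency")) {
    p <- fixed_params(dom)
    expect_equal(p_correct(p, p$alpha), 0.70, tolerance = 1e-12)
  }
  # easiest contrast stimulus with a tiny threshold: near the 1 - lapse ceiling
  easy <- psychometric_params("contrast", alpha = 0.01, beta = 8, lapse = 0.02)
  expect_gt(p_correct(easy, 1), 0.97)
  expect_lt(p_correct(easy, 1), 1 - 0.02 + 1e-9)
  # vanishing contrast: 2AFC guessing floor
  expect_equal(p_correct(fixed_params("contrast"), 1e-9), 0.5, tolerance = 1e-3)
})

test_that("p_correct is monotone in task difficulty and rejects bad levels", {
  pc <- fixed_params("contrast")
  lv <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(p_correct(pc, lv)) >= 0))
  ps <- fixed_params("spatial_frequency")
  sfs <- seq(0.1, 1.2, length.out = 50)
  expect_true(all(diff(p_correct(ps, sfs)) <= 0))
  expect_error(p_correct(pc, 0), "positive")
  expect_error(p_correct(pc, -0.2), "positive")
  expect_error(p_correct(pc, 1.3), "exceed")
})

test_that("simulate_choice is Bernoulli at p_correct and deterministic under a seed", {
  # binomial oracle at p = 0.5
  guesser <- function(level) 0.5
  set.seed(11)
  n <- 1e4
  hits <- sum(replicate(n, simulate_choice(guesser, 0.5, "left")$correct))
  se <- sqrt(0.25 / n)
  expect_lt(abs(hits / n - 0.5), 3 * se)
  # degenerate observer is always correct, and choice tracks the S+ side
  always <- function(level) 1
  tr <- simulate_choice(always, 0.3, "right")
  expect_true(tr$correct)
  expect_identical(tr$choice, "right")
  # fixed seed reproduces the whole trial sequence
  run <- function() {
    set.seed(99)
    do.call(rbind, replicate(50, simulate_choice(fixed_params(), 0.25, "left"),
                             simplify = FALSE))
  }
  expect_identical(run(), run())
})

test_that("learning update: dose zero keeps alpha, saturation reaches the asymptote, easy trials do not count", {
  o <- make_observer("naive", "contrast", id = 3, seed = 7)
  a0 <- o$psy$alpha
  # no trials: threshold unchanged
  o1 <- update_learning(o, NULL)
  expect_equal(o1$psy$alpha, a0, tolerance = 1e-12)
  # easy control trials (100% contrast) lie far outside the proximity window
  easy <- make_trials(rep(1.0, 40), rep(TRUE, 40))
  o2 <- update_learning(o, easy)
  expect_identical(o2$dose, 0)
  expect_equal(o2$psy$alpha, a0, tolerance = 1e-12)
  # near-threshold trials drive alpha toward the asymptote, monotonically
  near <- make_trials(rep(a0, 20), rep(TRUE, 20))
  alphas <- numeric(30)
  st <- o
  for (i in 1:30) { st <- update_learning(st, near); alphas[i] <- st$psy$alpha }
  expect_true(all(diff(alphas) <= 1e-12))  # contrast threshold falls with learning
  st$dose <- 1e9
  st <- update_learning(st, NULL)
  expect_equal(st$psy$alpha, st$learning$alpha_asymptote, tolerance = 1e-9)
})

test_that("interocular transfer moves the untrained eye by the configured log fraction", {
  o <- make_observer("naive", "spatial_frequency", id = 1, seed = 3)
  a0 <- o$psy$alpha
  near <- make_trials(rep(a0, 200), rep(TRUE, 200), domain = "spatial_frequency")
  o2 <- update_learning(o, near, transfer_fraction = 0.63)
  shift_trained <- log10(o2$psy$alpha) - log10(a0)
  shift_untrained <- log10(o2$untrained_alpha) - log10(a0)
  expect_gt(shift_trained, 0)  # acuity rises
  expect_equal(shift_untrained, 0.63 * shift_trained, tolerance = 1e-12)
})

test_that("profile presets reproduce the calibrated printed thresholds", {
  nv <- make_profile("naive")
  expect_equal(nv$psy$contrast$alpha, 1 / 3.75, tolerance = 1e-12)
  expect_equal(nv$psy$spatial_frequency$alpha, 0.47, tolerance = 1e-12)
  tr <- make_profile("nct_trained")
  expect_equal(tr$psy$contrast$alpha, 1 / 7.05, tolerance = 1e-12)
  ns <- make_profile("nsft_trained")
  expect_equal(ns$psy$spatial_frequency$alpha, 0.72, tolerance = 1e-12)
  am <- make_profile("amblyopic")
  expect_equal(am$eye$deprived$psy$alpha, 0.28, tolerance = 1e-12)
  expect_equal(am$eye$fellow$psy$alpha, 0.46, tolerance = 1e-12)
  expect_error(make_profile("labrador"), "naive")
})

test_that("cohorts are centered on the calibrated threshold and bit-reproducible", {
  coh <- simulate_cohort("naive", 150, "spatial_frequency", seed = 42)
  tab <- cohort_table(coh)
  sem <- sd(tab$true_alpha) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$true_alpha) - 0.47), 2 * sem)
  coh2 <- simulate_cohort("naive", 150, "spatial_frequency", seed = 42)
  expect_identical(cohort_table(coh2), tab)
  # different seeds give different cohorts
  coh3 <- simulate_cohort("naive", 150, "spatial_frequency", seed = 43)
  expect_false(identical(cohort_table(coh3)$true_alpha, tab$true_alpha))
})

test_that("parameter validation rejects out-of-range psychometric and learning settings", {
  expect_error(psychometric_params("contrast", alpha = 1.2, beta = 8), "contrast")
  expect_error(psychometric_params("spatial_frequency", alpha = -0.3, beta = 8))
  expect_error(psychometric_params("contrast", alpha = 0.3, beta = 0), "beta")
  expect_error(psychometric_params("contrast", alpha = 0.3, beta = 8, lapse = 0.2), "lapse")
  expect_error(learning_params(0.3, 0.2, tau = -5), "tau")
  expect_error(learning_params(0.3, 0.2, interocular_transfer_fraction = 1.4))
})
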
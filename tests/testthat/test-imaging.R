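test_that("fourier_map matches a naive per-pixel DFT and honors its anchors", {
  # single-frequency identity: pure cosine of amplitude A, phase phi
  h <- 6; w <- 5; nt <- 200; dt <- 0.2; f <- 0.1
  t <- (seq_len(nt) - 1) * dt
  A <- 3e-3; phi <- 0.8
  arr <- array(0, c(h, w, nt))
  for (k in seq_len(nt)) arr[, , k] <- A * cos(2 * pi * f * t[k] + phi)
  st <- frame_stack(arr, dt)
  rm <- fourier_map(st, f)
  expect_equal(max(abs(rm$magnitude - A)), 0, tolerance = 1e-10)
  expect_equal(max(abs(rm$phase - phi)), 0, tolerance = 1e-10)
  # constant stack: zero magnitude (whole-cycle truncation)
  st0 <- frame_stack(array(0.7, c(h, w, nt)), dt)
  expect_lt(max(fourier_map(st0, f)$magnitude), 1e-12)
  # arbitrary stack vs a literal per-pixel discrete Fourier sum
  set.seed(71)
  arr2 <- array(rnorm(16 * 16 * 256), c(16, 16, 256))
  st2 <- frame_stack(arr2, dt)
  rm2 <- fourier_map(st2, f)
  cycles <- floor(256 * dt * f); nuse <- round(cycles / (f * dt))
  oracle_mag <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    z <- sum(arr2[i, j, 1:nuse] * exp(-2i * pi * f * (0:(nuse - 1)) * dt)) * 2 / nuse
    oracle_mag[i, j] <- Mod(z)
  }
  expect_lt(max(abs(rm2$magnitude - oracle_mag)), 1e-8)
  expect_error(fourier_map(st2, 5), "Nyquist")
})

test_that("condition maps are exactly linear in the embedded fractional response", {
  expect_equal(max(abs(condition_map(episodic_fixture(0)))), 0)
  for (r in c(-2e-3, -5e-4, 1e-3)) {
    cm <- condition_map(episodic_fixture(r))
    expect_equal(max(abs(cm - r)), 0, tolerance = 1e-12)
  }
  # trial-averaged map equals the brute-force mean of per-trial maps
  set.seed(72)
  st <- episodic_fixture(-1e-3)
  st$data <- st$data + array(rnorm(length(st$data), 0, 1e-4), dim(st$data))
  cm <- condition_map(st)
  sch <- st$schedule; fps <- 1 / st$frame_interval_s
  per_trial <- sch$trial_s * fps
  oracle <- matrix(0, 4, 4)
  for (k in seq_len(sch$n_trials)) {
    off <- (k - 1) * per_trial
    blank <- apply(st$data[, , (off + 1):(off + fps), drop = FALSE], c(1, 2), mean)
    win <- apply(st$data[, , (off + 3 * fps + 1):(off + 7 * fps), drop = FALSE],
                 c(1, 2), mean)
    oracle <- oracle + (win - blank) / blank
  }
  expect_equal(unclass(cm), oracle / sch$n_trials, tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero baseline is an error, not an Inf map
  st0 <- episodic_fixture(-1e-3); st0$data[1, 1, 1:5] <- 0
  expect_error(condition_map(st0), "zero baseline")
})

test_that("circular smoothing: constant invariance, impulse response, mean preservation", {
  cst <- matrix(3.3, 20, 20)
  expect_equal(smooth_map(cst, 3), cst, tolerance = 1e-12, ignore_attr = TRUE)
  # impulse spreads over the disk, renormalized per-pixel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 5
  sm <- smooth_map(imp, 3)
  disk <- outer(-10:10, -10:10, function(a, b) a^2 + b^2 <= 9)
  npx <- sum(outer(-3:3, -3:3, function(a, b) a^2 + b^2 <= 9))
  expect_equal(sm[11, 11], 5 / npx, tolerance = 1e-12)
  expect_equal((sm > 0), disk)   # support is exactly the disk
  # interior pixels: direct disk-mask convolution oracle
  set.seed(73)
  m <- matrix(rnorm(100), 10, 10)
  sm2 <- smooth_map(m, 2)
  i <- 5; j <- 6
  acc <- c()
  for (dy in -2:2) for (dx in -2:2)
    if (dy^2 + dx^2 <= 4) acc <- c(acc, m[i + dy, j + dx])
  expect_equal(sm2[i, j], mean(acc), tolerance = 1e-12)
  # global mean approximately preserved on larger maps
  m2 <- matrix(rnorm(1e4, 10), 100, 100)
  expect_lt(abs(mean(smooth_map(m2, 3)) - mean(m2)) / abs(mean(m2)), 0.01)
})

test_that("ROI tuning is the sign-flipped masked mean and scales linearly", {
  mk <- function(vals, sf) {
    m <- matrix(vals, 4, 4)
    attr(m, "sf_cpd") <- sf; attr(m, "blank_sd") <- 1e-4
    class(m) <- c("condition_map", "matrix", "array"); m
  }
  roi <- matrix(FALSE, 4, 4); roi[2:3, 2:3] <- TRUE
  m1 <- mk(seq(-16, -1) * 1e-4, 0.1)
  tun <- roi_tuning(list(m1, mk(seq(-16, -1) * 5e-5, 0.2)), roi)
  expect_equal(tun$response[1], -mean(unclass(m1)[roi]), tolerance = 1e-12)
  expect_equal(tun$response[1] / tun$response[2], 2, tolerance = 1e-12)
  expect_true(!is.unsorted(tun$sf_cpd))
  expect_error(roi_tuning(list(m1), matrix(FALSE, 4, 4)), "empty ROI")
})

test_that("cut-off fit: exact line recovery, declining-tuning guard", {
  tun <- data.frame(sf_cpd = c(0.1, 0.2, 0.3), response = c(0.3, 0.2, 0.1))
  fit <- cutoff_sf(tun, all_points = TRUE)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.4, tolerance = 1e-12)
  expect_equal(fit$cutoff_cpd, 0.4, tolerance = 1e-12)
  flat <- data.frame(sf_cpd = c(0.1, 0.2, 0.3), response = c(0.2, 0.2, 0.2))
  expect_error(cutoff_sf(flat, all_points = TRUE), "cutoff undefined")
  rising <- data.frame(sf_cpd = c(0.1, 0.2, 0.3), response = c(0.1, 0.2, 0.3))
  expect_error(cutoff_sf(rising, all_points = TRUE), "cutoff undefined")
})

test_that("cutoff recovery is nearly unbiased under the default noise model", {
  cuts <- vapply(1:20, function(i) {
    set.seed(200 + i)
    imaging_pipeline(cortex_truth(0.39), dim_px = c(24, 24),
                     n_trials = 4L)$fit$cutoff_cpd
  }, numeric(1))
  expect_lt(abs(mean(cuts) - 0.39), 0.02)
})

test_that("phase scatter: smooth gradients score low, noise raises it toward the uniform expectation", {
  sch <- stimulus_schedule("periodic", duration_s = 100)
  set.seed(74)
  clean <- synth_cortex(cortex_truth(0.39, noise_sd = 1e-5), sch, dim_px = c(24, 24))
  noisy <- synth_cortex(cortex_truth(0.39, noise_sd = 5e-3), sch, dim_px = c(24, 24))
  s_clean <- map_scatter(fourier_map(clean, 0.1))
  s_noisy <- map_scatter(fourier_map(noisy, 0.1))
  expect_lt(s_clean, 0.2)
  expect_gt(s_noisy, s_clean)
  # uniform-random phases: scatter near the Monte-Carlo circular expectation
  set.seed(75)
  rmap <- structure(list(magnitude = matrix(1, 30, 30),
                         phase = matrix(runif(900, -pi, pi), 30, 30)),
                    class = "retinotopy_map")
  s_unif <- map_scatter(rmap)
  # oracle: mean absolute circular deviation of uniform phases from
  # independent local means, simulated directly
  mc <- mean(abs(atan2(sin(runif(2e4, -pi, pi)), cos(runif(2e4, -pi, pi)))))
  expect_lt(abs(s_unif - mc) / mc, 0.25)
})

test_that("opposite sweep directions cancel a common hemodynamic delay", {
  # retinotopic phase +q with delay d in one direction, -q + d in the other
  q <- matrix(seq(-1, 1, length.out = 12), 12, 12)
  d <- 0.7
  mk <- function(ph) structure(list(magnitude = matrix(1, 12, 12), phase = ph),
                               class = "retinotopy_map")
  comb <- combine_directions(mk(q + d), mk(-q + d))
  expect_equal(comb$phase, q, tolerance = 1e-12)
})

test_that("raising the true cutoff raises the estimated cutoff (trained vs untrained contrast)", {
  est <- function(cut) mean(vapply(1:5, function(i) {
    set.seed(300 + i)
    imaging_pipeline(cortex_truth(cut), dim_px = c(24, 24),
                     n_trials = 4L)$fit$cutoff_cpd
  }, numeric(1)))
  expect_gt(est(0.39), est(0.27))
})
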
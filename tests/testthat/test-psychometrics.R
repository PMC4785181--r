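test_that("Michelson contrast formula and its edge cases", {
  expect_equal(michelson_contrast(86, 0), 1.0)
  expect_equal(michelson_contrast(43, 43), 0.0)
  expect_equal(michelson_contrast(64.5, 21.5), 0.5)
  expect_error(michelson_contrast(10, -1), "negative")
  expect_error(michelson_contrast(5, 8), ">=")
})

test_that("frequency-of-seeing curves match a brute-force group-by and conserve trials", {
  set.seed(17)
  lv <- sample(c(0.2, 0.3, 0.5), 200, replace = TRUE)
  ok <- runif(200) < 0.7
  corr <- runif(200) < 0.15
  tr <- make_trials(lv, ok, corr)
  fos <- build_fos(tr)
  # brute-force recount over non-correction trials
  for (l in unique(lv)) {
    keep <- lv == l & !corr
    expect_equal(fos$n[fos$level == l], sum(keep))
    expect_equal(fos$n_correct[fos$level == l], sum(ok[keep]))
  }
  expect_identical(sum(fos$n), sum(!corr))
  expect_true(!is.unsorted(fos$level))
  # with corrections included, totals grow accordingly
  fos_all <- build_fos(tr, include_corrections = TRUE)
  expect_identical(sum(fos_all$n), 200L)
  # 7 of 10 at one level
  f1 <- build_fos(make_trials(rep(0.3, 10), c(rep(TRUE, 7), rep(FALSE, 3))))
  expect_equal(f1$accuracy, 0.7)
})

test_that("threshold interpolation: midpoint case, exact-criterion level, undefined flags", {
  f <- build_fos(make_trials(c(rep(0.3, 10), rep(0.2, 10)),
                             c(rep(TRUE, 8), rep(FALSE, 2),
                               rep(TRUE, 6), rep(FALSE, 4))))
  est <- threshold_at_criterion(f)
  expect_true(est$defined)
  expect_equal(est$threshold, 0.25, tolerance = 1e-12)
  # a level exactly at criterion is returned as-is
  f2 <- build_fos(make_trials(c(rep(0.4, 10), rep(0.3, 10)),
                              c(rep(TRUE, 9), FALSE, rep(TRUE, 7), rep(FALSE, 3))))
  expect_equal(threshold_at_criterion(f2)$threshold, 0.3)
  # all levels above criterion: floor not reached
  f3 <- build_fos(make_trials(rep(c(0.5, 0.8), each = 10), rep(TRUE, 20)))
  e3 <- threshold_at_criterion(f3)
  expect_false(e3$defined)
  expect_match(e3$reason, "floor not reached")
  # chance everywhere: undefined from the easy end
  f4 <- build_fos(make_trials(rep(c(0.5, 0.8), each = 10),
                              rep(c(TRUE, FALSE), 10)))
  expect_false(threshold_at_criterion(f4)$defined)
})

test_that("threshold estimates are trial-order invariant and recover alpha from dense sampling", {
  p <- fixed_params("contrast", alpha = 0.3)
  set.seed(23)
  levels <- seq(0.2, 0.44, by = 0.04)
  lv <- rep(levels, each = 2000)
  ok <- runif(length(lv)) < p_correct(p, lv)
  est1 <- threshold_at_criterion(build_fos(make_trials(lv, ok)))
  # analytic oracle: the generator's psychometric function inverted at 0.70
  # is alpha by construction; dense sampling must land within 0.01
  expect_lt(abs(est1$threshold - 0.3), 0.01)
  # permuting trials changes nothing
  perm <- sample(length(lv))
  est2 <- threshold_at_criterion(build_fos(make_trials(lv[perm], ok[perm])))
  expect_identical(est1$threshold, est2$threshold)
})

test_that("isotonic mode resolves non-monotone curves to a single crossing", {
  f <- build_fos(make_trials(c(rep(0.5, 10), rep(0.4, 10), rep(0.3, 10)),
                             c(rep(TRUE, 9), FALSE,          # 0.5: 0.9
                               rep(TRUE, 5), rep(FALSE, 5),  # 0.4: 0.5 (dip)
                               rep(TRUE, 8), rep(FALSE, 2)))) # 0.3: 0.8
  raw <- threshold_at_criterion(f, mode = "raw")
  iso <- threshold_at_criterion(f, mode = "isotonic")
  expect_true(raw$defined && iso$defined)
  # raw takes the crossing nearest the easy end (between 0.5 and 0.4)
  expect_gt(raw$threshold, 0.4)
  # isotonic pools the dip (0.65 at both lower levels): crossing moves harder
  expect_lte(iso$threshold, raw$threshold)
})

test_that("contrast sensitivity is the reciprocal threshold, a decreasing bijection on (0,1]", {
  expect_equal(contrast_sensitivity(1 / 3.75), 3.75, tolerance = 1e-12)
  expect_equal(contrast_sensitivity(1.0), 1.0)
  expect_equal(contrast_sensitivity(0.1418), 7.0521, tolerance = 1e-3)
  th <- seq(0.05, 1, by = 0.05)
  cs <- contrast_sensitivity(th)
  expect_true(all(diff(cs) < 0))
  expect_equal(cs * th, rep(1, length(th)), tolerance = 1e-12)
  expect_error(contrast_sensitivity(0), "positive")
  expect_error(contrast_sensitivity(1.2), "exceed")
})

test_that("CSF assembly sorts, drops undefined points with a warning, and the naive profile is an inverted U", {
  mk <- function(th, defined = TRUE)
    structure(list(threshold = th, domain = "contrast", criterion = 0.7,
                   defined = defined, fos = NULL), class = "threshold_estimate")
  expect_error(assemble_csf(numeric(0), list()), "no estimates")
  one <- assemble_csf(0.33, list(mk(1 / 3.75)))
  expect_equal(nrow(one), 1L)
  expect_warning(
    csf <- assemble_csf(c(0.33, 0.21, 0.42), list(mk(1 / 3.75), mk(1 / 4.59), mk(NA, FALSE))),
    "omitted")
  expect_identical(csf$sf_cpd, c(0.21, 0.33))     # sorted
  expect_equal(csf$cs, c(4.59, 3.75), tolerance = 1e-12)
  # generator profile: anchored at the printed naive values, CS 4.59 at 0.21 cpd
  expect_equal(naive_csf(0.21), 4.59, tolerance = 1e-9)
  expect_equal(naive_csf(0.33), 3.75, tolerance = 1e-9)
  sfs <- c(0.06, 0.12, 0.21, 0.33, 0.42, 0.46)
  cs <- naive_csf(sfs)
  pk <- which.max(cs)
  expect_true(pk > 1 && pk < length(sfs))          # interior peak
  expect_true(all(diff(cs[1:pk]) > 0) && all(diff(cs[pk:length(cs)]) < 0))
  expect_true(all(cs > 1))
})
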
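test_that("the interval deconvolution reproduces the nested-estimate example", {
  # integrated estimates 0.003 over five intervals and 0.0035 over six
  # intervals imply a rate of 0.006 in the 500-600 generation interval
  fitted <- tibble::tibble(x = seq(100, 600, by = 100),
                           fit = c(0.003, 0.003, 0.003, 0.003, 0.003, 0.0035))
  dec <- deconvolve_intervals(fitted)
  expect_identical(dec$interval_start[6], 500)
  expect_equal(dec$act_raw[6], 0.006, tolerance = 1e-15)
})

test_that("deconvolution is the exact inverse of the running mean", {
  # constant fitted curve: every interval rate equals the constant
  const <- tibble::tibble(x = seq(100, 1400, by = 100), fit = 0.004)
  expect_equal(deconvolve_intervals(const)$act_raw, rep(0.004, 14))
  # construct-then-invert on random non-negative schedules
  set.seed(3)
  for (r in 1:20) {
    act <- runif(30, 0, 1e-3)
    fit <- cumsum(act) / seq_along(act)
    rec <- deconvolve_intervals(
      tibble::tibble(x = seq(100, 3000, by = 100), fit = fit))$act_raw
    expect_equal(rec, act, tolerance = 1e-12)
  }
  # running-mean identity holds on every output
  dec <- deconvolve_intervals(
    tibble::tibble(x = seq(100, 900, by = 100),
                   fit = cumsum(runif(9)) / (1:9)))
  expect_equal(cumsum(dec$act_raw) / seq_along(dec$act_raw), dec$fit,
               tolerance = 1e-10)
  # negatives are preserved raw and clamped in the display column
  wiggly <- deconvolve_intervals(
    tibble::tibble(x = seq(100, 400, by = 100),
                   fit = c(0.01, 0.002, 0.004, 0.001)))
  expect_true(any(wiggly$act_raw < 0))
  expect_true(all(wiggly$act_clamped >= 0))
  expect_equal(wiggly$act_clamped, pmax(wiggly$act_raw, 0))
  expect_error(deconvolve_intervals(
    tibble::tibble(x = c(100, 300), fit = c(1, 2))), "contiguous")
})

test_that("spline smoothing reproduces flat and linear signals and tracks a sigmoid", {
  x <- seq(100, 14000, by = 100)
  flat <- smooth_t2(t2_trajectory(x, rep(2e-5, length(x))))
  expect_equal(flat$fit, rep(2e-5, length(x)), tolerance = 1e-9)
  lin <- smooth_t2(t2_trajectory(x, 1e-9 * x))
  expect_equal(lin$fit, 1e-9 * x, tolerance = 1e-7)
  expect_error(smooth_t2(t2_trajectory(c(100, 200, 300), rep(1, 3))),
               "at least 4")
  # noisy sigmoid: fitted curve stays within the noise envelope of truth
  sig <- 1e-5 + 3e-5 / (1 + exp(-(x - 7000) / 1500))
  set.seed(9)
  noisy <- pmax(sig + rnorm(length(x), 0, 2e-6), 0)
  fit <- smooth_t2(t2_trajectory(x, noisy))
  expect_lt(max(abs(fit$fit - sig)), 4 * 2e-6)
  # excluded points are omitted from fitting but predicted on the full grid
  excl <- rep(FALSE, length(x))
  excl[30:40] <- TRUE
  fit2 <- smooth_t2(t2_trajectory(x, noisy, excluded = excl))
  expect_equal(nrow(fit2), length(x))
  expect_lt(max(abs(fit2$fit[30:40] - sig[30:40])), 6 * 2e-6)
})

test_that("deconvolved rates track the generating trend and stay flat on constant truth", {
  x <- seq(100, 14000, by = 100)
  # declining gene flow (recent lower than old) survives noise + smoothing
  sched <- gene_flow_schedule(make_scenario(5), max_x = 14000)
  fx <- generate_scan_fixture(sched, noise_sd = 3e-6, n_pairs = 4, seed = 6)
  band <- bootstrap_band(fx$pairs, B = 100, seed = 2)
  recent <- band$act_raw[band$interval_end <= 2000]
  old <- band$act_raw[band$interval_end > 10000]
  expect_lt(mean(recent), mean(old))
  # constant truth: no systematic trend — the fitted drift across the whole
  # grid stays a small fraction of the level, whichever way the noise falls
  const <- tibble::tibble(interval_start = x - 100, interval_end = x,
                          rate = 3e-5)
  drifts <- vapply(c(9, 10, 11, 12, 13), function(s) {
    fxc <- generate_scan_fixture(const, noise_sd = 2e-6, n_pairs = 4,
                                 seed = s)
    mean_t2 <- rowMeans(vapply(fxc$pairs, function(p) p$t2,
                               numeric(length(x))))
    dec <- deconvolve_intervals(smooth_t2(t2_trajectory(x, mean_t2)))
    unname(coef(lm(act_raw ~ interval_end, data = dec))[2] * 14000)
  }, 1)
  # a real trend would drift one way in every replicate; noise-chasing
  # wiggle drifts both ways and stays small in the typical replicate
  expect_true(min(drifts) < 0 && max(drifts) > 0)
  expect_lt(abs(median(drifts)), 0.1 * 3e-5)
})

test_that("pair bootstrap bands behave at degenerate and enumerable cases", {
  x <- seq(100, 2000, by = 100)
  base <- cumsum(rep(2e-5, 20)) / (1:20)
  tr <- t2_trajectory(x, base)
  same <- bootstrap_band(list(tr, tr, tr), B = 50, seed = 4)
  expect_true(all(same$ci_high - same$ci_low < 1e-15))
  expect_equal(same$act_raw, rep(2e-5, 20), tolerance = 1e-9)
  # B = 1: the band collapses onto the single replicate
  one <- bootstrap_band(list(tr, tr), B = 1, seed = 4)
  expect_equal(one$ci_low, one$ci_high)
  # reproducible under a fixed seed
  a <- bootstrap_band(list(tr, t2_trajectory(x, base * 2)), B = 30, seed = 9)
  b <- bootstrap_band(list(tr, t2_trajectory(x, base * 2)), B = 30, seed = 9)
  expect_equal(a, b)
  expect_true(all(a$ci_low <= a$ci_high))
  # two divergent pairs: at large B the band covers both pairwise
  # deconvolutions (the resampling space is enumerable: 4 draws)
  lo <- t2_trajectory(x, base)
  hi <- t2_trajectory(x, base * 3)
  band <- bootstrap_band(list(lo, hi), B = 400, seed = 2)
  dec_lo <- deconvolve_intervals(smooth_t2(lo))$act_raw
  dec_hi <- deconvolve_intervals(smooth_t2(hi))$act_raw
  inner <- 3:18
  expect_true(all(band$ci_low[inner] <= pmin(dec_lo, dec_hi)[inner] + 1e-12))
  expect_true(all(band$ci_high[inner] >= pmax(dec_lo, dec_hi)[inner] - 1e-12))
})
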
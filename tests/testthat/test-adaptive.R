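test_that("SIAM step multipliers follow the adjustment matrix", {
  d8 <- siam_deltas(0.8)
  expect_equal(abs(d8[["miss"]]), 4)          # miss: 4x step toward easier
  expect_equal(abs(d8[["false_alarm"]]), 5)   # caught: 5x step
  expect_equal(d8[["correct_rejection"]], 0)
  # false alarms correct in the same (harder) direction as hits
  expect_equal(sign(d8[["false_alarm"]]), sign(d8[["hit"]]))
  d5 <- siam_deltas(0.5)
  expect_equal(abs(d5[["miss"]]), 1)          # 1-up 1-down behaviour
  expect_equal(abs(d5[["false_alarm"]]), 2)   # step doubles when caught
  # zero drift at the target probability on signal trials
  for (t in c(0.5, 0.75, 0.8)) {
    d <- siam_deltas(t)
    expect_equal(t * d[["hit"]] + (1 - t) * d[["miss"]], 0)
  }
  expect_error(siam_deltas(1), "in \\(0, 1\\)")
})

test_that("threshold estimation averages the selected reversals", {
  expect_equal(estimate_threshold(c(80, 60, 74, 66, 72, 68), 2, 4), 70)
  expect_equal(estimate_threshold(rep(55, 8), 2, 4), 55)
  # invariant to reversals occurring after the averaged window
  expect_equal(estimate_threshold(c(80, 60, 74, 66, 72, 68, 99, 12), 2, 4), 70)
  expect_error(estimate_threshold(c(70, 71), 2, 4), "insufficient")
})

test_that("SIAM tracks bracket a deterministic observer's threshold", {
  obs <- step_observer(62.7)   # yes iff level >= 62.7, no false alarms
  tr <- run_siam_track(obs, siam_preset("eAUD-N", initial = 85), seed = 4)
  expect_true(tr$valid)
  # final oscillation brackets the true threshold within one final step
  expect_lt(abs(tr$threshold - 62.7), 2 + 1e-9)
  expect_true(all(tr$trials$outcome != "false_alarm"))
  # reproducible
  tr2 <- run_siam_track(obs, siam_preset("eAUD-N", initial = 85), seed = 4)
  expect_identical(tr$trials, tr2$trials)
  expect_identical(tr$threshold, tr2$threshold)
})

test_that("an always-yes observer is driven to the harder bound and
           invalidated", {
  obs <- function(present, value) TRUE
  tr <- run_siam_track(obs, siam_preset("eAUD-N", initial = 85), seed = 1)
  expect_false(tr$valid)
  expect_equal(tr$invalid_reason, "bounds_hit")
  expect_true(is.na(tr$threshold))
})

test_that("SIAM converges to the target-probability point of the
           psychometric function", {
  # unbiased observer: the track's mean threshold approaches the level where
  # the hit probability equals t (small catch-trial correction tolerated)
  obs_theta <- 70
  th <- vapply(1:60, function(s) {
    run_siam_track(logistic_observer(obs_theta, sigma = 2, fa = 0.05),
                   siam_preset("eAUD-N", initial = 85), seed = s)$threshold
  }, numeric(1))
  expect_lt(abs(mean(th, na.rm = TRUE) - obs_theta), 1)
})

test_that("2-AFC frequency track recovers a hard frequency limit", {
  hard <- function(fmax) function(f) stats::runif(1) < 0.5 + 0.5 * (f <= fmax)
  set.seed(99)
  est <- vapply(1:30, function(s) {
    run_2afc_frequency_track(hard(800), twoafc_config(),
                             seed = s)$threshold
  }, numeric(1))
  expect_lt(abs(mean(log2(est / 800), na.rm = TRUE)), 1 / 6)
  # chance-only observer: no stable tracking point, so runs either drift to
  # the easy bound (invalid) or scatter far more than informed runs
  set.seed(100)
  est0 <- vapply(1:30, function(s) {
    run_2afc_frequency_track(function(f) stats::runif(1) < 0.5,
                             twoafc_config(), seed = 400 + s)$threshold
  }, numeric(1))
  expect_true(mean(is.na(est0)) > 0.3 ||
                stats::var(log2(est0), na.rm = TRUE) >
                  3 * stats::var(log2(est), na.rm = TRUE))
  # perfect below 1 kHz, chance above, start at 0.5 kHz -> estimate ~1 kHz
  set.seed(101)
  est1 <- vapply(1:30, function(s) {
    run_2afc_frequency_track(hard(1000),
                             twoafc_config(initial_freq = 500),
                             seed = 800 + s)$threshold
  }, numeric(1))
  expect_lt(abs(mean(log2(est1 / 1000))), 1 / 6)
})

test_that("2-AFC step sizes never increase after a reversal", {
  tr <- run_2afc_frequency_track(function(f) stats::runif(1) < 0.7,
                                 twoafc_config(), seed = 12)
  steps <- abs(tr$trials$step_applied[tr$trials$step_applied != 0])
  rev_at <- which(tr$trials$reversal[tr$trials$step_applied != 0])
  if (length(rev_at) > 1)
    expect_true(all(diff(steps[rev_at]) <= 1e-12))
})

test_that("loudness scaling covers the dynamic range and respects the
           threshold", {
  p <- listener_profile()
  # linear-loudness observer CU(L) = 0.5 (L - 20), noiseless
  lin <- function(level) {
    cu <- min(max(0.5 * (level - 20), 0), 50)
    seq(0, 50, 5)[which.min(abs(seq(0, 50, 5) - cu))]
  }
  pairs <- run_acalos_track(lin, acalos_config(), seed = 2)
  expect_gte(diff(range(pairs$cu)), 45)
  # observer with 40-dB threshold: never a CU > 0 below 40 dB
  thr40 <- function(level) if (level < 40) 0 else lin(level)
  pairs2 <- run_acalos_track(thr40, acalos_config(), seed = 3)
  expect_true(all(pairs2$cu[pairs2$level < 40] == 0))
})

test_that("loudness pairs from a simulated listener recover the generating
           parameters", {
  lp <- loudness_params(L_cut = 72, m_lo = 0.4, m_hi = 1.0,
                        response_noise_sd = 0)
  p <- listener_profile(loudness = list(`1000` = lp), deterministic = TRUE)
  pairs <- run_acalos_track(function(lv) respond_loudness(p, 1000, lv),
                            acalos_config(band = 1000), seed = 7)
  fit <- fit_loudness_function(pairs$level, pairs$cu)
  expect_equal(fit$mcl, 72, tolerance = 0.05)
  expect_equal(fit$slope, 0.4, tolerance = 0.05)
})

test_that("sentence staircase recovers the SRT and scores fixed lists", {
  obs <- function(snr) stats::runif(1) < stats::plogis((snr - (-1)) / 1)
  srt <- vapply(1:50, function(s)
    run_hint(obs, "adaptive_srt", hint_config(), seed = s)$threshold,
    numeric(1))
  expect_lt(abs(mean(srt) - (-1)), 0.8)
  # presented SNRs stay on the procedure's step grid
  tr <- run_hint(obs, "adaptive_srt", hint_config(), seed = 3)
  expect_true(all(tr$trials$snr %% 2 == 0))
  expect_equal(run_hint(function(snr) TRUE, "fixed_snr", hint_config(),
                        seed = 1), 100)
  sc <- run_hint(function(snr) stats::runif(1) < 0.8, "fixed_snr",
                 hint_config(), seed = 2)
  expect_true(sc >= 0 && sc <= 100 && sc %% 5 == 0)
})

test_that("repetition policy accepts, repeats and declares missing", {
  r <- repetition_policy(c(70, 71))
  expect_equal(r$action, "accept")
  expect_equal(r$value, 70.5)
  r2 <- repetition_policy(c(70, 71, 95))
  expect_equal(r2$action, "repeat")
  expect_equal(which(r2$outliers), 3L)
  r3 <- repetition_policy(c(NA, NA), at_bounds = c(TRUE, TRUE))
  expect_equal(r3$action, "missing")
  expect_true(is.na(r3$value))
})

test_that("track runs are bit-reproducible from (config, observer, seed)", {
  p <- listener_profile(seed = 5)
  t1 <- run_siam_track(function(pr, v) respond_yesno(p, "eAUD-N.LF", pr, v),
                       siam_preset("eAUD-N"), seed = 77)
  t2 <- run_siam_track(function(pr, v) respond_yesno(p, "eAUD-N.LF", pr, v),
                       siam_preset("eAUD-N"), seed = 77)
  expect_identical(t1$trials, t2$trials)
})
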
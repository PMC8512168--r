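test_that("corrected d-prime reproduces the design's ceiling and floor", {
  # 10/10 modulated detected, 0/5 false alarms: ceiling
  expect_equal(dprime_screening(10, 0), 3.0736, tolerance = 1e-4)
  # no yes-responses at all: floor
  expect_equal(dprime_screening(0, 0), -0.3076, tolerance = 1e-4)
  # equal corrected rates cancel
  expect_equal(dprime_screening(3, 3, n_modulated = 5, n_catch = 5), 0)
  expect_error(dprime_screening(11, 0), "hits")
  expect_error(dprime_screening(5, 6), "false_alarms")
})

test_that("d-prime is monotone in hits and antitone in false alarms", {
  d_h <- vapply(0:10, function(h) dprime_screening(h, 2), numeric(1))
  expect_true(all(diff(d_h) > 0))
  d_f <- vapply(0:5, function(f) dprime_screening(7, f), numeric(1))
  expect_true(all(diff(d_f) < 0))
  # swapping corrected hit and false-alarm rates flips the sign
  expect_equal(dprime_screening(4, 1, 9, 3),
               -dprime_screening(1, 4, 3, 9), tolerance = 1e-12)
})

test_that("word-recognition fit recovers a known psychometric function", {
  true <- list(mid = 33, spread = 4, lower = 0, upper = 0.95)
  gen <- function(seed) {
    set.seed(seed)
    levels <- c(20, 30, 40, 50)
    p <- true$lower + (true$upper - true$lower) *
      stats::plogis((levels - true$mid) / true$spread)
    list(levels = levels, scores = stats::rbinom(4, 25, p) / 25)
  }
  true_srt <- true$mid + true$spread *
    stats::qlogis((0.5 - true$lower) / (true$upper - true$lower))
  res <- t(vapply(1:60, function(s) {
    d <- gen(s)
    fit <- fit_wrs_psychometric(d$levels, d$scores, 25)
    c(fit$srt, fit$max_score)
  }, numeric(2)))
  expect_lt(stats::median(abs(res[, 1] - true_srt)), 3)
  expect_lt(stats::median(abs(res[, 2] - 95)), 5)
})

test_that("word-recognition fit flags degenerate data and keeps free
           asymptotes", {
  # all-ceiling data: maxDS 100, SRT not identifiable
  fit <- fit_wrs_psychometric(c(20, 30, 40, 50), c(1, 1, 1, 1), 25)
  expect_gt(fit$max_score, 99)
  expect_false(fit$reliable)
  # plateau at 80%: upper asymptote is not forced to 100%
  set.seed(11)
  levels <- c(10, 20, 30, 40, 50)
  p <- 0.8 * stats::plogis((levels - 18) / 3)
  scores <- stats::rbinom(5, 50, p) / 50
  fit2 <- fit_wrs_psychometric(levels, scores, 50)
  expect_lt(abs(fit2$max_score - 80), 8)
  expect_error(fit_wrs_psychometric(c(20, 30), c(0.5, 0.9)), "4 levels")
})

test_that("loudness fit inverts the broken-stick model exactly on clean
           data", {
  levels <- seq(25, 115, by = 5)
  cu <- pmin(pmax(25 + 0.5 * (levels - 70), 0), 50)
  fit <- fit_loudness_function(levels, cu)
  expect_equal(unname(fit$par["L_cut"]), 70, tolerance = 0.01)
  expect_equal(unname(fit$par["m_lo"]), 0.5, tolerance = 0.01)
  expect_equal(unname(fit$par["m_hi"]), 0.5, tolerance = 0.01)
  expect_equal(fit$mcl, 70, tolerance = 1e-3)
  # DynR: level(CU 50) - level(CU 0.5) = 120 - 21 = 99
  expect_equal(fit$dyn_range, 99, tolerance = 0.01)
  expect_equal(fit$htl, 25, tolerance = 0.01)     # level at CU 2.5
  expect_true(fit$reliable)
  expect_equal(predict(fit, 70), 25)
})

test_that("loudness fit recovers slopes from noisy categorical responses", {
  lp <- loudness_params(75, 0.45, 0.9, response_noise_sd = 3)
  err <- vapply(1:60, function(s) {
    set.seed(s)
    levels <- seq(20, 110, length.out = 25)
    cu <- vapply(levels, function(L) {
      v <- loudness_cu(L, lp) + stats::rnorm(1, 0, 3)
      if (loudness_cu(L, lp) == 0) v <- 0
      seq(0, 50, 5)[which.min(abs(seq(0, 50, 5) - min(max(v, 0), 50)))]
    }, numeric(1))
    fit_loudness_function(levels, cu)$slope - 0.45
  }, numeric(1))
  expect_lt(stats::median(abs(err)), 0.05)
  # non-spanning data flagged
  fit <- fit_loudness_function(seq(60, 70, 2), rep(25, 6))
  expect_false(fit$reliable)
})

test_that("masking release is a linear difference with sign preserved", {
  expect_equal(masking_release(70, 55), 15)
  expect_equal(masking_release(64, 64), 0)
  expect_equal(masking_release(60, 65), -5)
  expect_true(is.na(masking_release(NA, 55)))
  # shift invariance
  expect_equal(masking_release(70 + 7, 55 + 7), masking_release(70, 55))
})

test_that("binaural-pitch scoring uses dichotic contours only", {
  expect_equal(score_binaural_pitch(c(10, 10)), 100)
  expect_equal(score_binaural_pitch(c(7, 9)), 80)
  expect_error(score_binaural_pitch(c(11, 4)), "range")
})

test_that("reduction to the analysis record pools bands and ears", {
  raw <- list(
    id = "X",
    audiogram = c(`250` = 10, `500` = 10, `1000` = 10, `2000` = 20,
                  `4000` = 30, `6000` = 40, `8000` = 45),
    flft = 12000,
    acalos = data.frame(
      band = rep(c(250, 500, 1000, 2000, 4000, 6000), 2),
      ear = rep(c("LE", "RE"), each = 6),
      htl = rep(5, 12), mcl = rep(70, 12),
      slope = rep(c(0.3, 0.3, 0.4, 0.5, 0.5, 0.5), 2),
      dynr = rep(95, 12)),
    wrs = data.frame(ear = c("LE", "RE"), srt = c(30, 34),
                     maxds = c(98, 96)),
    hint = data.frame(ear = c("LE", "RE"), srt_n = c(4, 6),
                      sscore = c(80, 90)),
    sstm = c(`8` = 2.1, `4k` = 1.0),
    fstm = data.frame(ear = rep(c("LE", "RE"), each = 2),
                      cond = rep(c("8", "4k"), 2),
                      threshold = c(-7, -4, -9, NA)),
    tin = data.frame(ear = rep(c("LE", "RE"), each = 6),
                     cond = rep(c("N", "N", "S", "S", "T", "T"), 2),
                     band = rep(c("LF", "HF"), 6),
                     threshold = c(70, 71, 50, 45, 62, 60,
                                   72, 71, 52, 47, 64, 62)),
    s0n0 = 70, spin0 = 54, ipd_fmax = 900, bp20 = 85)
  rec <- reduce_to_bear3(raw)
  expect_setequal(setdiff(names(rec), "id"), bear3_variables())
  expect_equal(rec$Slope_LF, mean(c(0.3, 0.3, 0.4)))
  expect_equal(rec$SRT_N, 5)                      # ear average
  expect_equal(rec$AUD_HF, 30)
  expect_equal(rec$TiN_LF, 71)                    # mean of 70 and 72
  expect_equal(rec$SMR_LF, 71 - 51)
  expect_equal(rec$BMR, 16)
  expect_equal(rec$IPD_fmax, 0.9)
  # single-ear fSTM_4k used and flagged
  expect_equal(rec$fSTM_4k, -4)
  expect_true(any(grepl("fSTM_4k", attr(rec, "flags"))))
  # both ears missing -> variable missing
  raw$wrs$srt <- c(NA, NA)
  expect_true(is.na(reduce_to_bear3(raw)$SRT_Q))
  # analysis set: 26 variables, dropping the HF modulation conditions
  expect_length(bear3_analysis_variables(), 26)
  expect_false(any(c("fSTM_4k", "sSTM_4k") %in% bear3_analysis_variables()))
})
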
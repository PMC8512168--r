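## Outcome estimation: turning raw responses and trial logs into the
## battery's outcome measures, and reducing them to the 26-variable analysis
## record (low/high-frequency split at 1 kHz, ears averaged).

#' Corrected d-prime for the screening modulation-detection set
#'
#' `d' = z(H) - z(F)` with the log-linear small-sample correction
#' `H = (h + 0.5)/(n_mod + 1)`, `F = (f + 0.5)/(n_catch + 1)`, which keeps
#' perfect and empty response sets finite.  With the battery's 10 modulated
#' and 5 catch trials the ceiling is 3.07 and the floor (no yes-responses at
#' all) is -0.31.
#'
#' @param hits yes-responses on modulated trials
#' @param false_alarms yes-responses on catch trials
#' @param n_modulated,n_catch trial counts (battery default 10 and 5)
#' @return d-prime (numeric scalar)
#' @export
dprime_screening <- function(hits, false_alarms, n_modulated = 10, n_catch = 5) {
  if (hits < 0 || hits > n_modulated) stop("hits out of range")
  if (false_alarms < 0 || false_alarms > n_catch) stop("false_alarms out of range")
  H <- (hits + 0.5) / (n_modulated + 1)
  F <- (false_alarms + 0.5) / (n_catch + 1)
  stats::qnorm(H) - stats::qnorm(F)
}

#' Fit a word-recognition psychometric function
#'
#' Maximum-likelihood logistic fit with two free asymptotes:
#' `p(L) = lower + (upper - lower) * F((L - mid)/spread)`.  The speech
#' reception threshold is the level at *absolute* 50% correct; the maximum
#' discrimination score is the upper asymptote.
#'
#' @param levels presentation levels, dB
#' @param scores fraction of words correct at each level
#' @param n_per_level words per level (scalar or vector)
#' @return object of class `wrs_fit` with elements `srt`, `max_score` (%),
#'   `lower_asymptote` (%), `slope` (%/dB at the inflection), `deviance`,
#'   `reliable`, `par`
#' @export
fit_wrs_psychometric <- function(levels, scores, n_per_level = 25) {
  if (length(levels) < 4) stop("need at least 4 levels")
  if (length(n_per_level) == 1) n_per_level <- rep(n_per_level, length(levels))
  k <- round(scores * n_per_level)
  # parameters: mid, log spread, qlogis(lower scaled to [0,.5]), qlogis(upper)
  nll <- function(par) {
    mid <- par[1]; spread <- exp(par[2])
    lower <- 0.5 * stats::plogis(par[3])
    upper <- stats::plogis(par[4])
    p <- lower + (upper - lower) * stats::plogis((levels - mid) / spread)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(stats::dbinom(k, n_per_level, p, log = TRUE))
  }
  # several starts: the likelihood can trade the upper asymptote against the
  # spread when the sampled levels barely reach the plateau
  starts <- expand.grid(mid = stats::quantile(levels, c(0.25, 0.5)),
                        upper = c(0.8, 0.95, 0.999))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(c(starts$mid[i], log(diff(range(levels)) / 4),
                   stats::qlogis(0.1), stats::qlogis(starts$upper[i])),
                 nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  mid <- fit$par[1]; spread <- exp(fit$par[2])
  lower <- 0.5 * stats::plogis(fit$par[3]); upper <- stats::plogis(fit$par[4])
  reliable <- TRUE
  if (upper <= 0.5 + 1e-6) {            # function never crosses 50%
    srt <- NA_real_; reliable <- FALSE
  } else {
    srt <- mid + spread * stats::qlogis((0.5 - lower) / (upper - lower))
    rng <- range(levels)
    if (srt < rng[1] - 20 || srt > rng[2] + 20) {
      srt <- min(max(srt, rng[1] - 20), rng[2] + 20)
      reliable <- FALSE
    }
    if (all(scores >= 0.999) || all(scores <= 0.001)) reliable <- FALSE
  }
  # saturated-model deviance as a goodness-of-fit measure
  phat <- pmin(pmax(scores, 1e-9), 1 - 1e-9)
  dev <- 2 * (sum(stats::dbinom(k, n_per_level, phat, log = TRUE)) + fit$value)
  structure(list(srt = srt, max_score = 100 * upper,
                 lower_asymptote = 100 * lower,
                 slope = 100 * (upper - lower) / (4 * spread),
                 deviance = dev, reliable = reliable,
                 par = c(mid = mid, spread = spread, lower = lower,
                         upper = upper),
                 levels = levels, scores = scores, n = n_per_level),
            class = "wrs_fit")
}

#' @export
print.wrs_fit <- function(x, ...) {
  cat(sprintf("<wrs_fit> SRT %.1f dB, maxDS %.1f%%, slope %.1f %%/dB%s\n",
              x$srt, x$max_score, x$slope,
              if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' @export
coef.wrs_fit <- function(object, ...) object$par

#' @export
plot.wrs_fit <- function(x, ...) {
  grid <- seq(min(x$levels) - 10, max(x$levels) + 10, length.out = 200)
  graphics::plot(x$levels, 100 * x$scores, xlab = "Level (dB)",
                 ylab = "Words correct (%)", ylim = c(0, 100),
                 pch = 19, ...)
  graphics::lines(grid, 100 * predict(x, grid))
  if (!is.na(x$srt)) graphics::abline(v = x$srt, lty = 2)
  invisible(x)
}

#' @export
predict.wrs_fit <- function(object, levels, ...) {
  p <- object$par
  unname(p["lower"] + (p["upper"] - p["lower"]) *
           stats::plogis((levels - p["mid"]) / p["spread"]))
}

#' Fit a categorical loudness function
#'
#' Least-squares broken-stick fit of categorical units vs level: two linear
#' branches of slope `m_lo` and `m_hi` joined at CU 25 (level `L_cut`),
#' clipped to [0, 50].  Derived outcomes: hearing threshold level (HTL, level
#' at `htl_cu`, default CU 2.5, via the lower branch), most comfortable level
#' (MCL = `L_cut`), Slope (`m_lo`), and dynamic range (level at CU 50 minus
#' level at `dynr_low_cu`, default CU 0.5).
#'
#' @param levels presentation levels, dB
#' @param cu categorical-unit responses (0-50)
#' @param htl_cu CU anchor for the hearing threshold
#' @param dynr_low_cu lower CU anchor of the dynamic range
#' @return object of class `loudness_fit`
#' @export
fit_loudness_function <- function(levels, cu, htl_cu = 2.5, dynr_low_cu = 0.5) {
  stopifnot(length(levels) == length(cu))
  reliable <- length(levels) >= 8 && diff(range(cu)) >= 20
  model <- function(par) {
    L_cut <- par[1]; m_lo <- exp(par[2]); m_hi <- exp(par[3])
    m <- ifelse(levels <= L_cut, m_lo, m_hi)
    pmin(pmax(25 + m * (levels - L_cut), 0), 50)
  }
  sse <- function(par) sum((cu - model(par))^2)
  # init from the mid-range responses
  mid <- cu > 2 & cu < 48
  init_slope <- if (sum(mid) >= 2)
    max(stats::coef(stats::lm(cu[mid] ~ levels[mid]))[2], 0.05, na.rm = TRUE)
  else 0.4
  init_cut <- if (length(unique(cu[mid])) >= 2)
    stats::approx(cu[mid], levels[mid], xout = 25, ties = mean, rule = 2)$y
  else stats::median(levels)
  fit <- stats::optim(c(init_cut, log(init_slope), log(init_slope)), sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  # polish from a second start to avoid local minima of the kinked surface
  fit2 <- stats::optim(fit$par + c(5, 0.2, -0.2), sse, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-12))
  if (fit2$value < fit$value) fit <- fit2
  L_cut <- fit$par[1]; m_lo <- exp(fit$par[2]); m_hi <- exp(fit$par[3])
  structure(list(htl = L_cut - (25 - htl_cu) / m_lo,
                 mcl = L_cut, slope = m_lo,
                 dyn_range = 25 / m_hi + (25 - dynr_low_cu) / m_lo,
                 par = c(L_cut = L_cut, m_lo = m_lo, m_hi = m_hi),
                 sse = fit$value, reliable = reliable),
            class = "loudness_fit")
}

#' @export
print.loudness_fit <- function(x, ...) {
  cat(sprintf("<loudness_fit> HTL %.1f, MCL %.1f dB, slope %.2f CU/dB, DynR %.1f dB%s\n",
              x$htl, x$mcl, x$slope, x$dyn_range,
              if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' @export
coef.loudness_fit <- function(object, ...) object$par

#' @export
plot.loudness_fit <- function(x, levels = NULL, cu = NULL, ...) {
  p <- x$par
  grid <- seq(x$htl - 15, p["L_cut"] + 25 / p["m_hi"] + 10, length.out = 200)
  graphics::plot(grid, predict(x, grid), type = "l", xlab = "Level (dB HL)",
                 ylab = "Loudness (CU)", ylim = c(0, 50), ...)
  if (!is.null(levels)) graphics::points(levels, cu, pch = 1)
  graphics::abline(h = 25, v = x$mcl, lty = 3)
  invisible(x)
}

#' @export
predict.loudness_fit <- function(object, levels, ...) {
  p <- object$par
  m <- ifelse(levels <= p["L_cut"], p["m_lo"], p["m_hi"])
  unname(pmin(pmax(25 + m * (levels - p["L_cut"]), 0), 50))
}

#' Masking release
#'
#' Threshold improvement of a test condition relative to its reference:
#' `ref - cond` in dB (positive = release).  Missing values propagate.
#'
#' @param tin_ref reference threshold, dB
#' @param tin_cond condition threshold, dB
#' @export
masking_release <- function(tin_ref, tin_cond) tin_ref - tin_cond

#' Binaural-pitch score
#'
#' Percentage of *dichotic* contours detected, averaged over repetitions;
#' diotic detections do not enter the score.
#'
#' @param dichotic_hits integer vector, detected dichotic contours per run
#' @param n_dichotic dichotic contours per run
#' @export
score_binaural_pitch <- function(dichotic_hits, n_dichotic = 10) {
  if (any(dichotic_hits < 0 | dichotic_hits > n_dichotic))
    stop("dichotic hit counts out of range")
  100 * mean(dichotic_hits / n_dichotic)
}

## ---- the reduced outcome record -------------------------------------------

#' Names of the reduced outcome variables
#'
#' All 28 computed outcomes of the battery after low/high-frequency pooling
#' (LF = bands at or below 1 kHz, HF above) and ear averaging.
#' @export
bear3_variables <- function() c(
  "AUD_LF", "AUD_HF", "FLFT", "HTL_LF", "HTL_HF", "MCL_LF", "MCL_HF",
  "DynR_LF", "DynR_HF", "Slope_LF", "Slope_HF", "SRT_Q", "maxDS", "SRT_N",
  "SScore_4dB", "sSTM_8", "sSTM_4k", "fSTM_8", "fSTM_4k", "TiN_LF", "TiN_HF",
  "SMR_LF", "SMR_HF", "TMR_LF", "TMR_HF", "IPD_fmax", "BP_20", "BMR")

#' Names of the 26 analysis variables
#'
#' The analysis set drops the two high-frequency-condition modulation
#' outcomes (`fSTM_4k`, at or near floor for most impaired listeners, and the
#' screening counterpart `sSTM_4k`), leaving 26 variables in six groups.
#' @export
bear3_analysis_variables <- function()
  setdiff(bear3_variables(), c("fSTM_4k", "sSTM_4k"))

#' Reduce raw per-ear, per-frequency outcomes to the analysis record
#'
#' Frequency-specific outcomes are pooled into LF (0.25, 0.5, 1 kHz) and HF
#' (2, 4, 6 kHz) means; monaural outcomes are averaged across ears (a single
#' available ear is used and flagged); missing values propagate.
#'
#' @param raw nested list as produced by [run_full_battery()]; see Details
#' @details `raw` holds: `audiogram` (named dB HL), `flft` (Hz),
#'   `acalos` (data.frame band, ear, htl, mcl, slope, dynr),
#'   `wrs` (data.frame ear, srt, maxds), `hint` (data.frame ear, srt_n,
#'   sscore), `sstm` (named d-primes "8", "4k"), `fstm` (data.frame ear,
#'   cond, threshold), `tin` (data.frame ear, cond, band, threshold),
#'   `s0n0`, `spin0` (dB), `ipd_fmax` (Hz), `bp20` (%).
#' @return one-row data.frame with the 28 columns of [bear3_variables()]
#'   plus `id`; attribute `"flags"` lists single-ear substitutions
#' @export
reduce_to_bear3 <- function(raw) {
  lf_bands <- c(250, 500, 1000); hf_bands <- c(2000, 4000, 6000)
  # tolerate partially run batteries: absent components reduce to NA
  if (is.null(raw$acalos))
    raw$acalos <- data.frame(band = numeric(0), ear = character(0),
                             htl = numeric(0), mcl = numeric(0),
                             slope = numeric(0), dynr = numeric(0))
  if (is.null(raw$tin))
    raw$tin <- data.frame(ear = character(0), cond = character(0),
                          band = character(0), threshold = numeric(0))
  if (is.null(raw$wrs))
    raw$wrs <- data.frame(ear = character(0), srt = numeric(0),
                          maxds = numeric(0))
  if (is.null(raw$hint))
    raw$hint <- data.frame(ear = character(0), srt_n = numeric(0),
                           sscore = numeric(0))
  if (is.null(raw$fstm))
    raw$fstm <- data.frame(ear = character(0), cond = character(0),
                           threshold = numeric(0))
  if (is.null(raw$sstm)) raw$sstm <- c(`8` = NA_real_, `4k` = NA_real_)
  for (f in c("flft", "s0n0", "spin0", "ipd_fmax", "bp20"))
    if (is.null(raw[[f]])) raw[[f]] <- NA_real_
  flags <- character(0)
  ear_mean <- function(v, what) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    if (length(v) == 1) flags <<- c(flags, paste0(what, ": single ear"))
    mean(v)
  }
  band_mean <- function(df, bands, col) {
    vals <- vapply(bands, function(b) {
      x <- df[df$band == b, col]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  ac <- raw$acalos
  tin <- raw$tin
  tin_val <- function(cond, band_lab) {
    x <- tin$threshold[tin$cond == cond & tin$band == band_lab]
    ear_mean(x, paste0("TiN-", cond, ".", band_lab))
  }
  tin_n_lf <- tin_val("N", "LF"); tin_n_hf <- tin_val("N", "HF")
  out <- data.frame(
    id = raw$id %||% NA_character_,
    AUD_LF = mean(raw$audiogram[as.character(lf_bands)]),
    AUD_HF = mean(raw$audiogram[as.character(hf_bands)]),
    FLFT = raw$flft / 1000,
    HTL_LF = band_mean(ac[, ], lf_bands, "htl"),
    HTL_HF = band_mean(ac[, ], hf_bands, "htl"),
    MCL_LF = band_mean(ac[, ], lf_bands, "mcl"),
    MCL_HF = band_mean(ac[, ], hf_bands, "mcl"),
    DynR_LF = band_mean(ac[, ], lf_bands, "dynr"),
    DynR_HF = band_mean(ac[, ], hf_bands, "dynr"),
    Slope_LF = band_mean(ac[, ], lf_bands, "slope"),
    Slope_HF = band_mean(ac[, ], hf_bands, "slope"),
    SRT_Q = ear_mean(raw$wrs$srt, "SRT_Q"),
    maxDS = ear_mean(raw$wrs$maxds, "maxDS"),
    SRT_N = ear_mean(raw$hint$srt_n, "SRT_N"),
    SScore_4dB = ear_mean(raw$hint$sscore, "SScore_4dB"),
    sSTM_8 = raw$sstm[["8"]], sSTM_4k = raw$sstm[["4k"]],
    fSTM_8 = ear_mean(raw$fstm$threshold[raw$fstm$cond == "8"], "fSTM_8"),
    fSTM_4k = ear_mean(raw$fstm$threshold[raw$fstm$cond == "4k"], "fSTM_4k"),
    TiN_LF = tin_n_lf, TiN_HF = tin_n_hf,
    SMR_LF = masking_release(tin_n_lf, tin_val("S", "LF")),
    SMR_HF = masking_release(tin_n_hf, tin_val("S", "HF")),
    TMR_LF = masking_release(tin_n_lf, tin_val("T", "LF")),
    TMR_HF = masking_release(tin_n_hf, tin_val("T", "HF")),
    IPD_fmax = raw$ipd_fmax / 1000,
    BP_20 = raw$bp20,
    BMR = masking_release(raw$s0n0, raw$spin0),
    row.names = NULL)
  attr(out, "flags") <- flags
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
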
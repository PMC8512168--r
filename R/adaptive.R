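## Adaptive psychophysical procedures: SIAM yes/no tracking with catch
## trials, 2-AFC frequency tracking, adaptive categorical loudness scaling,
## and the sentence-in-noise staircase, plus the battery's repetition and
## validity policy.
##
## Observers are plain closures; the tracking engines never render audio, so
## whole-battery simulations stay cheap.

#' SIAM step multipliers
#'
#' For a single-interval adjustment-matrix procedure targeting probability
#' `t`, the tracked value moves (in units of the current step size): one step
#' toward "harder" after a hit, `t/(1-t)` steps toward "easier" after a miss,
#' `1/(1-t)` steps toward "harder" after a false alarm (the corrective step
#' on a caught catch trial), and not at all after a correct rejection.
#' Positive values are "easier", negative "harder"; at `t = 0.8` the miss and
#' false-alarm magnitudes are 4 and 5, at `t = 0.5` a false alarm doubles the
#' step.
#'
#' @param t target probability, 0 < t < 1
#' @return named numeric: hit, miss, false_alarm, correct_rejection
#' @export
siam_deltas <- function(t) {
  if (t <= 0 || t >= 1) stop("t must be in (0, 1)")
  c(hit = -1, miss = t / (1 - t), false_alarm = -1 / (1 - t),
    correct_rejection = 0)
}

#' SIAM track configuration
#'
#' @param t target probability
#' @param initial starting value of the tracked variable
#' @param steps step-size schedule: `steps[k]` is used after `k-1` reversals
#'   (the last entry persists)
#' @param catch_rate probability that a trial is a catch trial (no stimulus)
#' @param max_trials hard trial cap
#' @param bounds allowed range of the tracked variable; moves beyond a bound
#'   are clamped, and a run that keeps pressing against a bound
#'   (`bound_patience` clamps while already sitting on it) is invalidated
#' @param bound_patience clamps tolerated at a bound before the run is
#'   declared invalid
#' @param discard,average reversal-handling policy: discard the first
#'   `discard` reversals, average the next `average`
#' @param direction_on_hit direction the tracked value moves after a hit
#'   ("down" for level/modulation-level tracks, "up" for frequency tracks)
#' @param preset optional preset name; see [siam_preset()]
#' @export
siam_config <- function(t = 0.5, initial = 85, steps = c(8, 4, 2),
                        catch_rate = 0.2, max_trials = 120,
                        bounds = c(-10, 110), bound_patience = 3,
                        discard = 2, average = 4,
                        direction_on_hit = c("down", "up"), preset = NULL) {
  direction_on_hit <- match.arg(direction_on_hit)
  if (t <= 0 || t >= 1) stop("t must be in (0, 1)")
  if (any(steps <= 0)) stop("step sizes must be positive")
  structure(list(t = t, initial = initial, steps = steps,
                 catch_rate = catch_rate, max_trials = max_trials,
                 bounds = bounds, bound_patience = bound_patience,
                 discard = discard, average = average,
                 direction_on_hit = direction_on_hit, preset = preset),
            class = "siam_config")
}

#' Named SIAM presets used by the battery
#'
#' `"eAUD-HF"` tracks log2 frequency upward at a fixed level (t = 0.5,
#' discard 4 / average 2); `"eAUD-N"`, `"eAUD-S"`, `"eAUD-T"`, `"S0N0"` and
#' `"SpiN0"` track tone level in noise (t = 0.5, discard 2 / average 4,
#' final step 2 dB); `"fSTM"` tracks modulation level at the 80% point
#' (t = 0.8, miss/false-alarm multipliers 4 and 5).
#'
#' @param name preset name
#' @param initial optional override of the starting value
#' @export
siam_preset <- function(name, initial = NULL) {
  cfg <- switch(name,
    "eAUD-HF" = siam_config(t = 0.5, initial = log2(8000),
                            steps = c(1 / 2, 1 / 4, 1 / 8), catch_rate = 0.2,
                            bounds = log2(c(2000, 20000)),
                            discard = 4, average = 2,
                            direction_on_hit = "up", preset = name),
    "eAUD-N" = , "eAUD-S" = , "eAUD-T" = , "S0N0" = , "SpiN0" =
      siam_config(t = 0.5, initial = 85, steps = c(8, 4, 2),
                  catch_rate = 0.2, bounds = c(-10, 110),
                  discard = 2, average = 4,
                  direction_on_hit = "down", preset = name),
    "fSTM" = siam_config(t = 0.8, initial = 0, steps = c(4, 2, 1),
                         catch_rate = 0.2, bounds = c(-40, 0),
                         discard = 2, average = 4,
                         direction_on_hit = "down", preset = name),
    stop("unknown SIAM preset: ", name))
  if (!is.null(initial)) cfg$initial <- initial
  cfg
}

#' Run one SIAM yes/no track
#'
#' @param observer function(stimulus_present, value) returning TRUE ("yes")
#'   or FALSE; it is also called on catch trials with
#'   `stimulus_present = FALSE`
#' @param config a [siam_config()]
#' @param seed integer seed (governs catch-trial placement only; observer
#'   randomness is the observer's own)
#' @return a `track_result`: trial log, reversal values, threshold estimate,
#'   validity flag and reason
#' @export
run_siam_track <- function(observer, config, seed = 1) {
  stopifnot(inherits(config, "siam_config"))
  d <- siam_deltas(config$t)
  # map "harder" onto the tracked axis
  axis <- if (config$direction_on_hit == "down") +1 else -1
  n_target <- config$discard + config$average
  value <- config$initial
  last_move <- 0
  reversals <- numeric(0)
  trials <- vector("list", config$max_trials)
  invalid_reason <- "none"
  clamp_streak <- 0
  with_seed(seed, {
    for (i in seq_len(config$max_trials)) {
      is_catch <- stats::runif(1) < config$catch_rate
      resp <- isTRUE(observer(!is_catch, value))
      outcome <- if (!is_catch && resp) "hit"
        else if (!is_catch) "miss"
        else if (resp) "false_alarm" else "correct_rejection"
      step <- config$steps[min(length(reversals) + 1, length(config$steps))]
      move <- d[[outcome]] * step * axis
      trials[[i]] <- list(index = i, stimulus_present = !is_catch,
                          tracked_value = value, response = resp,
                          outcome = outcome, step_applied = move,
                          reversal = FALSE)
      if (move != 0) {
        if (last_move != 0 && sign(move) != sign(last_move)) {
          reversals <- c(reversals, value)
          trials[[i]]$reversal <- TRUE
        }
        last_move <- move
      }
      at_bound <- value <= config$bounds[1] || value >= config$bounds[2]
      value <- value + move
      if (value <= config$bounds[1] || value >= config$bounds[2]) {
        value <- min(max(value, config$bounds[1]), config$bounds[2])
        clamp_streak <- if (at_bound) clamp_streak + 1 else 1
        if (clamp_streak >= config$bound_patience) {
          invalid_reason <- "bounds_hit"
          break
        }
      } else clamp_streak <- 0
      if (length(reversals) >= n_target) break
    }
  })
  trials <- do.call(rbind, lapply(trials[!vapply(trials, is.null, TRUE)],
                                  as.data.frame))
  valid <- invalid_reason == "none" && length(reversals) >= n_target
  if (valid) {
    threshold <- estimate_threshold(reversals, config$discard, config$average)
  } else {
    threshold <- NA_real_
    if (invalid_reason == "none") invalid_reason <- "inconsistent"
  }
  structure(list(trials = trials, reversal_values = reversals,
                 threshold = threshold, valid = valid,
                 invalid_reason = invalid_reason, config = config),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("<track_result> %d trials, %d reversals, %s\n",
              nrow(x$trials), length(x$reversal_values),
              if (x$valid) sprintf("threshold %.2f", x$threshold)
              else paste("invalid:", x$invalid_reason)))
  invisible(x)
}

#' Threshold from reversal values
#'
#' Mean of reversals `discard_n + 1` through `discard_n + average_m`.
#'
#' @param track a `track_result` or a numeric vector of reversal values
#' @param discard_n reversals to discard
#' @param average_m reversals to average
#' @export
estimate_threshold <- function(track, discard_n = 2, average_m = 4) {
  rev_vals <- if (inherits(track, "track_result")) track$reversal_values
              else track
  if (length(rev_vals) < discard_n + average_m)
    stop("insufficient reversals for threshold estimation")
  mean(rev_vals[discard_n + seq_len(average_m)])
}

#' 2-AFC frequency-track configuration
#'
#' Adaptive tracking in log2 frequency: `n_correct_up` consecutive correct
#' responses raise the tone frequency (harder), one incorrect response
#' lowers it.  The default of 2 targets the 70.7% point, which is required
#' for convergence in a two-interval task whose chance rate is 50% (a plain
#' 1-up-1-down, `n_correct_up = 1`, has no equilibrium against a 50% guessing
#' floor and drifts upward).  Step sizes shrink from `step_start` to
#' `step_final` octaves per reversal.
#'
#' @param initial_freq starting frequency, Hz
#' @param step_start,step_final octaves
#' @param n_correct_up consecutive correct responses required to step up
#' @param n_reversals_average reversals averaged for the threshold (the last
#'   `n_reversals_average` of `n_reversals` total)
#' @param n_reversals reversals at which the track terminates
#' @param bounds frequency bounds, Hz
#' @param max_trials cap
#' @export
twoafc_config <- function(initial_freq = 250, step_start = 2 / 3,
                          step_final = 1 / 6, n_correct_up = 2,
                          n_reversals_average = 6,
                          n_reversals = 8, bounds = c(50, 4000),
                          max_trials = 120) {
  structure(list(initial_freq = initial_freq, step_start = step_start,
                 step_final = step_final, n_correct_up = n_correct_up,
                 n_reversals_average = n_reversals_average,
                 n_reversals = n_reversals, bounds = bounds,
                 max_trials = max_trials),
            class = "twoafc_config")
}

#' Run one 2-AFC frequency track
#'
#' @param observer function(freq_hz) returning TRUE if the interval with the
#'   dichotic sequence was identified correctly
#' @param config a [twoafc_config()]
#' @param seed integer
#' @return a `track_result`; the threshold is in Hz
#' @export
run_2afc_frequency_track <- function(observer, config, seed = 1) {
  stopifnot(inherits(config, "twoafc_config"))
  # geometric step schedule from step_start to step_final, then constant
  steps <- config$step_start * (config$step_final / config$step_start)^
    (seq(0, 1, length.out = max(2, ceiling(log2(config$step_start /
                                                  config$step_final)) + 1)))
  value <- log2(config$initial_freq)
  lb <- log2(config$bounds)
  last_move <- 0
  streak <- 0
  reversals <- numeric(0)
  trials <- vector("list", config$max_trials)
  invalid_reason <- "none"
  with_seed(seed, {
    for (i in seq_len(config$max_trials)) {
      correct <- isTRUE(observer(2^value))
      step <- steps[min(length(reversals) + 1, length(steps))]
      streak <- if (correct) streak + 1 else 0
      move <- if (!correct) -step                    # down = easier
              else if (streak >= config$n_correct_up) { streak <- 0; +step }
              else 0
      trials[[i]] <- list(index = i, freq = 2^value, correct = correct,
                          step_applied = move, reversal = FALSE)
      if (move == 0) next
      if (last_move != 0 && sign(move) != sign(last_move)) {
        reversals <- c(reversals, value)
        trials[[i]]$reversal <- TRUE
      }
      last_move <- move
      value <- value + move
      if (value <= lb[1] || value >= lb[2]) {
        value <- min(max(value, lb[1]), lb[2])
        invalid_reason <- "bounds_hit"
        break
      }
      if (length(reversals) >= config$n_reversals) break
    }
  })
  trials <- do.call(rbind, lapply(trials[!vapply(trials, is.null, TRUE)],
                                  as.data.frame))
  valid <- invalid_reason == "none" &&
    length(reversals) >= config$n_reversals
  threshold <- if (valid) {
    k <- config$n_reversals_average
    2^mean(utils::tail(reversals, k))
  } else NA_real_
  if (!valid && invalid_reason == "none") invalid_reason <- "inconsistent"
  structure(list(trials = trials, reversal_values = reversals,
                 threshold = threshold, valid = valid,
                 invalid_reason = invalid_reason, config = config),
            class = "track_result")
}

#' Adaptive categorical loudness-scaling configuration
#'
#' Eleven response categories mapped to categorical units (CU) 0, 5, ...,
#' 50.  Phase 1 brackets the dynamic range (ascending until a high-loudness
#' response, descending until "not heard"); phase 2 places
#' `phase2_n` presentations uniformly across the estimated range in
#' pseudorandom order.
#'
#' @param band band centre frequency, Hz (bookkeeping only)
#' @param start starting level, dB
#' @param step_up,step_down phase-1 step sizes, dB
#' @param phase2_n number of phase-2 presentations
#' @param bounds level bounds, dB
#' @param high_cu CU at/above which the ascending phase stops
#' @export
acalos_config <- function(band = 1000, start = 65, step_up = 10,
                          step_down = 15, phase2_n = 22,
                          bounds = c(-10, 120), high_cu = 45) {
  structure(list(band = band, start = start, step_up = step_up,
                 step_down = step_down, phase2_n = phase2_n, bounds = bounds,
                 high_cu = high_cu),
            class = "acalos_config")
}

#' Run one adaptive categorical loudness-scaling track
#'
#' @param observer function(level_db) returning a CU category (0-50 in steps
#'   of 5)
#' @param config an [acalos_config()]
#' @param seed integer (order of phase-2 presentations)
#' @return data.frame with columns level, cu, phase; invalid (all-unheard)
#'   runs return zero rows
#' @export
run_acalos_track <- function(observer, config, seed = 1) {
  stopifnot(inherits(config, "acalos_config"))
  with_seed(seed, {
    lev <- config$start
    pairs <- list()
    push <- function(level, cu, phase)
      pairs[[length(pairs) + 1]] <<- list(level = level, cu = cu, phase = phase)
    # ascend until something is heard
    cu <- observer(lev)
    push(lev, cu, 1L)
    while (cu == 0 && lev < config$bounds[2]) {
      lev <- min(lev + config$step_down, config$bounds[2])
      cu <- observer(lev); push(lev, cu, 1L)
    }
    if (cu == 0) return(data.frame(level = numeric(0), cu = numeric(0),
                                   phase = integer(0)))
    first_heard <- lev
    # ascend to a high-loudness response
    while (cu < config$high_cu && lev < config$bounds[2]) {
      lev <- min(lev + config$step_up, config$bounds[2])
      cu <- observer(lev); push(lev, cu, 1L)
    }
    l_high <- lev
    # descend to "not heard"
    lev <- first_heard - config$step_down
    while (lev > config$bounds[1]) {
      cu <- observer(lev); push(lev, cu, 1L)
      if (cu == 0) break
      lev <- lev - config$step_down
    }
    l_low <- max(lev, config$bounds[1])
    levels2 <- seq(l_low, l_high, length.out = config$phase2_n)
    for (lv in sample(levels2)) push(lv, observer(lv), 2L)
    do.call(rbind, lapply(pairs, as.data.frame))
  })
}

#' Sentence-in-noise test configuration
#'
#' @param n_sentences sentences per list
#' @param start_snr starting SNR, dB
#' @param step_initial step for the first four sentences, dB
#' @param step step thereafter, dB
#' @param fixed_snr SNR of the fixed-level scored list, dB
#' @param srt_from first sentence entering the SRT average (a virtual
#'   (n+1)-th SNR is included)
#' @param bounds SNR bounds
#' @export
hint_config <- function(n_sentences = 20, start_snr = 0, step_initial = 4,
                        step = 2, fixed_snr = 4, srt_from = 5,
                        bounds = c(-25, 25)) {
  structure(list(n_sentences = n_sentences, start_snr = start_snr,
                 step_initial = step_initial, step = step,
                 fixed_snr = fixed_snr, srt_from = srt_from, bounds = bounds),
            class = "hint_config")
}

#' Run a sentence-in-noise test
#'
#' Adaptive mode: whole-sentence 1-down/1-up staircase (first four sentences
#' use the larger initial step); the speech reception threshold is the mean
#' presented SNR over sentences `srt_from..n` plus the virtual next
#' presentation.  Fixed mode: percent of sentences correct at `fixed_snr`.
#'
#' @param observer function(snr_db) returning TRUE if the sentence was
#'   repeated correctly
#' @param mode "adaptive_srt" or "fixed_snr"
#' @param config a [hint_config()]
#' @param seed integer
#' @return for adaptive mode a `track_result` (threshold = SRT in dB SNR);
#'   for fixed mode the sentence score in percent
#' @export
run_hint <- function(observer, mode = c("adaptive_srt", "fixed_snr"),
                     config = hint_config(), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "hint_config"))
  if (mode == "fixed_snr") {
    correct <- with_seed(seed, vapply(seq_len(config$n_sentences),
                                      function(i) isTRUE(observer(config$fixed_snr)),
                                      TRUE))
    return(100 * mean(correct))
  }
  snr <- config$start_snr
  snrs <- numeric(config$n_sentences + 1)
  trials <- vector("list", config$n_sentences)
  with_seed(seed, {
    for (i in seq_len(config$n_sentences)) {
      snrs[i] <- snr
      correct <- isTRUE(observer(snr))
      step <- if (i <= 4) config$step_initial else config$step
      snr <- snr + if (correct) -step else +step
      snr <- min(max(snr, config$bounds[1]), config$bounds[2])
      trials[[i]] <- list(index = i, snr = snrs[i], correct = correct)
    }
  })
  snrs[config$n_sentences + 1] <- snr      # virtual next presentation
  srt <- mean(snrs[config$srt_from:(config$n_sentences + 1)])
  structure(list(trials = do.call(rbind, lapply(trials, as.data.frame)),
                 reversal_values = numeric(0), threshold = srt,
                 valid = TRUE, invalid_reason = "none", config = config),
            class = "track_result")
}

#' Repetition and validity policy for repeated threshold runs
#'
#' Repeated estimates are accepted (as their mean) when consistent.  An
#' estimate farther than three scaled median absolute deviations from the
#' median flags the set for an extra run.  If all runs are invalid (e.g. the
#' track reached a bound) the outcome is missing.
#'
#' @param estimates numeric vector of threshold estimates (may contain NA
#'   for invalid runs)
#' @param at_bounds logical vector, TRUE where the run hit a tracking bound
#' @return list(action = "accept"|"repeat"|"missing", value, outliers)
#' @export
repetition_policy <- function(estimates, at_bounds = rep(FALSE, length(estimates))) {
  ok <- !is.na(estimates) & !at_bounds
  if (sum(ok) == 0)
    return(list(action = "missing", value = NA_real_, outliers = logical(0)))
  x <- estimates[ok]
  if (length(x) == 1)
    return(list(action = "accept", value = x, outliers = FALSE))
  dev <- abs(x - stats::median(x))
  smad <- stats::mad(x)                  # scaled MAD (constant 1.4826)
  outl <- smad > 0 & dev > 3 * smad
  if (any(outl))
    return(list(action = "repeat", value = NA_real_, outliers = outl))
  list(action = "accept", value = mean(x), outliers = outl)
}
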
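## Battery orchestration: run every test for a listener or a cohort, apply
## the repetition/validity policy, reduce to the analysis record, and keep a
## manifest of what was run.  Tracking engines work on psychometric
## responses only, so whole cohorts simulate in seconds.

#' Battery configuration
#'
#' @param tests tests to run (default all)
#' @param repetitions threshold runs per adaptive test before the repetition
#'   policy is applied
#' @param max_extra extra runs allowed when the policy requests a repetition
#' @param noise_level TEN presentation level for the tone-in-noise family,
#'   dB HL per ERB
#' @param wrs_levels_above_pta word-list levels relative to the pure-tone
#'   average, dB
#' @param calibration named numeric of dB HL -> dB SPL offsets per frequency
#'   (identity by default; real transducer tables out of scope)
#' @param master_seed integer; per-test seeds are derived deterministically
#' @export
battery_config <- function(tests = c("AUD", "eAUD-HF", "ACALOS", "WRS",
                                     "HINT", "sSTM", "fSTM", "eAUD", "IPD",
                                     "BP", "BMR"),
                           repetitions = 2, max_extra = 2, noise_level = 70,
                           wrs_levels_above_pta = c(10, 20, 30, 40),
                           calibration = NULL, master_seed = 1) {
  structure(list(tests = tests, repetitions = repetitions,
                 max_extra = max_extra, noise_level = noise_level,
                 wrs_levels_above_pta = wrs_levels_above_pta,
                 calibration = calibration, master_seed = master_seed),
            class = "battery_config")
}

## run an adaptive test `repetitions` times (plus policy-driven extras) and
## reduce the estimates; returns value, status and run count
run_repeated <- function(run_one, repetitions, max_extra, seed0) {
  est <- numeric(0); at_bounds <- logical(0)
  run_idx <- 0
  add_run <- function() {
    run_idx <<- run_idx + 1
    tr <- run_one(derive_seed(seed0, "run", run_idx))
    est <<- c(est, if (tr$valid) tr$threshold else NA_real_)
    at_bounds <<- c(at_bounds, tr$invalid_reason == "bounds_hit")
  }
  for (i in seq_len(repetitions)) add_run()
  pol <- repetition_policy(est, at_bounds)
  extra <- 0
  while (pol$action == "repeat" && extra < max_extra) {
    add_run(); extra <- extra + 1
    pol <- repetition_policy(est, at_bounds)
  }
  if (pol$action == "repeat") {
    # still inconsistent: drop the flagged outliers and accept the rest
    ok <- !is.na(est) & !at_bounds
    x <- est[ok]
    keep <- abs(x - stats::median(x)) <= 3 * stats::mad(x)
    pol <- list(action = "accept", value = mean(x[keep]))
  }
  list(value = pol$value, status = if (pol$action == "missing") "missing"
       else if (extra > 0) "repeated" else "done",
       n_runs = run_idx, extra = extra)
}

#' Run the full test battery for one simulated listener
#'
#' Every enabled test is run with its adaptive engine against the profile's
#' response model; adaptive thresholds are measured at least twice and
#' reduced by [repetition_policy()]; results are pooled into the reduced
#' outcome record.  Fully reproducible from (profile, config).
#'
#' @param profile a [listener_profile()]
#' @param config a [battery_config()]
#' @return list: `outcomes` (one-row data.frame, see [reduce_to_bear3()]),
#'   `manifest` (per-test status and run counts), `raw` (per-test results)
#' @export
run_full_battery <- function(profile, config = battery_config()) {
  stopifnot(inherits(profile, "listener_profile"),
            inherits(config, "battery_config"))
  seed0 <- derive_seed(config$master_seed, profile$id)
  manifest <- list()
  note <- function(test, res)
    manifest[[test]] <<- list(status = res$status, n_runs = res$n_runs,
                              extra = res$extra)
  raw <- list(id = profile$id, audiogram = profile$audiogram)
  ears <- c("LE", "RE")

  ## -- extended audiometry at high frequencies (highest audible frequency)
  if ("eAUD-HF" %in% config$tests) {
    res <- run_repeated(function(s) {
      run_siam_track(function(present, v)
        respond_yesno(profile, "eAUD-HF", present, v),
        siam_preset("eAUD-HF"), seed = s)
    }, config$repetitions, config$max_extra, derive_seed(seed0, "eAUD-HF"))
    raw$flft <- if (is.na(res$value)) NA_real_ else 2^res$value
    note("eAUD-HF", res)
  }

  ## -- adaptive categorical loudness scaling, per ear and band
  if ("ACALOS" %in% config$tests) {
    rows <- list()
    for (ear in ears) for (b in c(250, 500, 1000, 2000, 4000, 6000)) {
      pairs <- run_acalos_track(function(lv) respond_loudness(profile, b, lv),
                                acalos_config(band = b),
                                seed = derive_seed(seed0, "ACALOS", ear, b))
      if (nrow(pairs) == 0) {
        rows[[paste(ear, b)]] <- data.frame(band = b, ear = ear,
                                            htl = NA, mcl = NA,
                                            slope = NA, dynr = NA)
        next
      }
      fit <- fit_loudness_function(pairs$level, pairs$cu)
      rows[[paste(ear, b)]] <- data.frame(band = b, ear = ear, htl = fit$htl,
                                          mcl = fit$mcl, slope = fit$slope,
                                          dynr = fit$dyn_range)
    }
    raw$acalos <- do.call(rbind, rows)
    manifest$ACALOS <- list(status = "done", n_runs = length(rows), extra = 0)
  }

  ## -- word recognition in quiet, per ear
  if ("WRS" %in% config$tests) {
    pta <- mean(profile$audiogram[c("500", "1000", "2000")])
    levels <- pta + config$wrs_levels_above_pta
    rows <- lapply(ears, function(ear) {
      scores <- with_seed(derive_seed(seed0, "WRS", ear), {
        vapply(levels, function(L) {
          p <- psychometric_prob(L, profile$speech_quiet)
          if (profile$deterministic) as.numeric(p >= 0.5)
          else mean(stats::runif(25) < p)
        }, numeric(1))
      })
      fit <- fit_wrs_psychometric(levels, scores, 25)
      data.frame(ear = ear, srt = fit$srt, maxds = fit$max_score)
    })
    raw$wrs <- do.call(rbind, rows)
    manifest$WRS <- list(status = "done", n_runs = 2, extra = 0)
  }

  ## -- sentence recognition in noise, per ear
  if ("HINT" %in% config$tests) {
    rows <- lapply(ears, function(ear) {
      obs <- function(snr) {
        p <- psychometric_prob(snr, profile$speech_noise)
        if (profile$deterministic) p >= 0.5 else stats::runif(1) < p
      }
      tr <- run_hint(obs, "adaptive_srt", hint_config(),
                     seed = derive_seed(seed0, "HINT", ear, "srt"))
      sc <- run_hint(obs, "fixed_snr", hint_config(),
                     seed = derive_seed(seed0, "HINT", ear, "fix"))
      data.frame(ear = ear, srt_n = tr$threshold, sscore = sc)
    })
    raw$hint <- do.call(rbind, rows)
    manifest$HINT <- list(status = "done", n_runs = 4, extra = 0)
  }

  ## -- screening spectro-temporal modulation sensitivity (diotic)
  if ("sSTM" %in% config$tests) {
    raw$sstm <- vapply(c("8", "4k"), function(cond) {
      with_seed(derive_seed(seed0, "sSTM", cond), {
        hits <- sum(vapply(1:10, function(i)
          respond_yesno(profile, paste0("sSTM.", cond), TRUE, -3), TRUE))
        fas <- sum(vapply(1:5, function(i)
          respond_yesno(profile, paste0("sSTM.", cond), FALSE, -3), TRUE))
        dprime_screening(hits, fas, 10, 5)
      })
    }, numeric(1))
    manifest$sSTM <- list(status = "done", n_runs = 2, extra = 0)
  }

  ## -- fast spectro-temporal modulation threshold, per ear and condition
  if ("fSTM" %in% config$tests) {
    rows <- list()
    for (ear in ears) for (cond in c("8", "4k")) {
      res <- run_repeated(function(s) {
        run_siam_track(function(present, v)
          respond_yesno(profile, paste0("fSTM.", cond), present, v),
          siam_preset("fSTM"), seed = s)
      }, config$repetitions, config$max_extra,
      derive_seed(seed0, "fSTM", ear, cond))
      rows[[paste(ear, cond)]] <- data.frame(ear = ear, cond = cond,
                                             threshold = res$value)
      note(paste0("fSTM.", cond, ".", ear), res)
    }
    raw$fstm <- do.call(rbind, rows)
  }

  ## -- extended audiometry in noise (tone in TEN), per ear
  if ("eAUD" %in% config$tests) {
    rows <- list()
    for (ear in ears) for (cond in c("N", "S", "T"))
      for (band in c("LF", "HF")) {
        test_id <- paste0("eAUD-", cond, ".", band)
        res <- run_repeated(function(s) {
          run_siam_track(function(present, v)
            respond_yesno(profile, test_id, present, v),
            siam_preset(paste0("eAUD-", cond),
                        initial = config$noise_level + 15), seed = s)
        }, config$repetitions, config$max_extra,
        derive_seed(seed0, "eAUD", ear, cond, band))
        rows[[paste(ear, cond, band)]] <-
          data.frame(ear = ear, cond = cond, band = band,
                     threshold = res$value)
        note(paste0(test_id, ".", ear), res)
      }
    raw$tin <- do.call(rbind, rows)
  }

  ## -- maximum frequency for interaural-phase detection (binaural)
  if ("IPD" %in% config$tests) {
    runs <- vapply(1:2, function(r) {
      tr <- run_2afc_frequency_track(function(f) respond_2afc_ipd(profile, f),
                                     twoafc_config(),
                                     seed = derive_seed(seed0, "IPD", r))
      if (tr$valid) tr$threshold else NA_real_
    }, numeric(1))
    raw$ipd_fmax <- if (all(is.na(runs))) NA_real_
                    else 2^mean(log2(runs), na.rm = TRUE)
    manifest$IPD <- list(status = if (all(is.na(runs))) "missing" else "done",
                         n_runs = 2, extra = 0)
  }

  ## -- binaural pitch (dichotic contour detection)
  if ("BP" %in% config$tests) {
    hits <- with_seed(derive_seed(seed0, "BP"), {
      vapply(1:2, function(r)
        sum(stats::runif(10) < profile$bp_detect_prob), numeric(1))
    })
    raw$bp20 <- score_binaural_pitch(hits, 10)
    manifest$BP <- list(status = "done", n_runs = 2, extra = 0)
  }

  ## -- binaural masking release (diotic vs antiphasic tone in noise)
  if ("BMR" %in% config$tests) {
    for (cond in c("S0N0", "SpiN0")) {
      res <- run_repeated(function(s) {
        run_siam_track(function(present, v)
          respond_yesno(profile, cond, present, v),
          siam_preset(cond, initial = config$noise_level + 15), seed = s)
      }, config$repetitions, config$max_extra, derive_seed(seed0, cond))
      if (cond == "S0N0") raw$s0n0 <- res$value else raw$spin0 <- res$value
      note(cond, res)
    }
  }

  outcomes <- reduce_to_bear3(raw)
  outcomes$group <- profile$group
  list(outcomes = outcomes, manifest = manifest, raw = raw)
}

#' Run the battery over a cohort
#'
#' @param cohort a `listener_cohort` from [make_cohort()]
#' @param config a [battery_config()]
#' @param retest if TRUE, re-run everything with fresh derived seeds to
#'   produce a retest table
#' @return list: `outcomes` (data.frame, one row per listener), `retest`
#'   (same shape or NULL), `manifests`
#' @export
run_cohort_study <- function(cohort, config = battery_config(),
                             retest = FALSE) {
  run_all <- function(cfg) {
    res <- lapply(cohort, run_full_battery, config = cfg)
    list(outcomes = do.call(rbind, lapply(res, `[[`, "outcomes")),
         manifests = lapply(res, `[[`, "manifest"))
  }
  first <- run_all(config)
  out <- list(outcomes = first$outcomes, retest = NULL,
              manifests = first$manifests)
  if (retest) {
    cfg2 <- config
    cfg2$master_seed <- derive_seed(config$master_seed, "retest")
    out$retest <- run_all(cfg2)$outcomes
  }
  out
}

#' Recovery errors of battery outcomes against the generative ground truth
#'
#' @param outcomes outcome table from [run_cohort_study()]
#' @param truth matching table from [cohort_truth()]
#' @param vars variables to compare (default: all shared numeric columns)
#' @return data.frame: variable, median_abs_error, bias, n
#' @export
recovery_stats <- function(outcomes, truth, vars = NULL) {
  if (is.null(vars))
    vars <- intersect(names(truth)[vapply(truth, is.numeric, TRUE)],
                      names(outcomes))
  stopifnot(all(outcomes$id == truth$id))
  do.call(rbind, lapply(vars, function(v) {
    err <- outcomes[[v]] - truth[[v]]
    data.frame(variable = v,
               median_abs_error = stats::median(abs(err), na.rm = TRUE),
               bias = mean(err, na.rm = TRUE), n = sum(!is.na(err)))
  }))
}

#' Select response foils by edit distance
#'
#' Returns the `k` corpus words closest to the target in Levenshtein
#' distance (plain character-level by default); occurrences of the target
#' itself are excluded; ties are broken lexicographically.
#'
#' @param target_word target word
#' @param corpus candidate words
#' @param k number of foils
#' @param distance optional custom distance function(word, target) (e.g. a
#'   phoneme-based metric); defaults to [utils::adist()]
#' @export
select_foils <- function(target_word, corpus, k = 3, distance = NULL) {
  corpus <- corpus[corpus != target_word]
  if (k > length(corpus)) stop("k exceeds available corpus words")
  d <- if (is.null(distance)) drop(utils::adist(target_word, corpus))
       else vapply(corpus, distance, numeric(1), target = target_word)
  corpus[order(d, corpus)][seq_len(k)]
}
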
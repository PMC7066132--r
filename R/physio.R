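#' Generate synchronized physiological traces for a trial table
#'
#' Respiration (chest volume) shows an inhalation peak shortly before the
#' first utterance of each trial and a slow exhalation during production;
#' chin pressure deflects during each of the utterance windows (the silent
#' gaps). Voiced and whispered trials are generated from the identical
#' model, emulating the matched-respiration premise of the design: the two
#' conditions are exchangeable by construction.
#'
#' @param trial_table data frame (onset_s, run, task, item).
#' @param config an [experiment_config()] (uses `physio_fs_hz`, `tr_s`,
#'   `utterances_per_trial`, `silent_gap_s`).
#' @param n_vol volumes per run (defines trace length).
#' @return list of per-run `physio_trace` objects, each with `fs_hz`,
#'   `respiration`, `chin_pressure` (equal-length numeric series) and
#'   `tr_triggers` (sample indices of TR onsets, spacing `tr_s * fs_hz`).
#' @export
generate_physio <- function(trial_table, config, n_vol) {
  fs <- config$physio_fs_hz
  tr <- config$tr_s
  runs <- sort(unique(trial_table$run))
  if (length(runs) == 0) runs <- 1
  out <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    ev <- trial_table[trial_table$run == r, , drop = FALSE]
    dur_s <- n_vol * tr
    n <- as.integer(dur_s * fs)
    t_s <- (seq_len(n) - 1) / fs
    # quiet-breathing baseline plus slow noise
    resp <- 0.4 * sin(2 * pi * 0.25 * t_s + stats::runif(1, 0, 2 * pi))
    chin <- rep(0, n)
    for (k in seq_len(nrow(ev))) {
      on <- ev$onset_s[k]
      if (on + 6 > dur_s) stop("trial onset beyond run duration")
      tt <- t_s - on
      # inhalation peak ~0.4 s after cue, i.e. before articulation onset
      resp <- resp + 2.0 * exp(-(tt - 0.4)^2 / (2 * 0.6^2)) -
        1.2 * exp(-(tt - 3.5)^2 / (2 * 2.0^2))
      for (u in seq_len(config$utterances_per_trial) - 1) {
        mid <- on + u * tr + (tr - config$silent_gap_s) + config$silent_gap_s / 2
        chin <- chin + exp(-(t_s - mid)^2 / (2 * 0.15^2))
      }
    }
    # smooth measurement noise (identical model for both conditions)
    coarse <- stats::rnorm(ceiling(dur_s * 10) + 2, sd = 0.05)
    noise_r <- stats::approx(seq(0, by = 0.1, length.out = length(coarse)),
                             coarse, xout = t_s)$y
    coarse2 <- stats::rnorm(ceiling(dur_s * 10) + 2, sd = 0.03)
    noise_c <- stats::approx(seq(0, by = 0.1, length.out = length(coarse2)),
                             coarse2, xout = t_s)$y
    trace <- list(fs_hz = fs, respiration = resp + noise_r,
                  chin_pressure = chin + noise_c,
                  tr_triggers = as.integer(round((seq_len(n_vol) - 1) * tr * fs)) + 1L,
                  run = r)
    class(trace) <- "physio_trace"
    out[[ri]] <- trace
  }
  out
}

#' Trial-locked average physiological traces per condition
#'
#' Cuts each trial's window out of the per-run trace, averages within each
#' task condition, and returns one trace per condition for use with
#' [compare_traces()].
#'
#' @param physio list of `physio_trace` objects (one per run).
#' @param trial_table trial table matching the traces.
#' @param channel `"respiration"` or `"chin_pressure"`.
#' @param window_s 2-vector, window around trial onset in seconds.
#' @param decimate keep every `decimate`-th sample (default 100: 10 ms grid).
#' @return list with one matrix per task level (trials x time), plus
#'   `time_s`.
#' @export
physio_trial_traces <- function(physio, trial_table,
                                channel = c("respiration", "chin_pressure"),
                                window_s = c(-2, 10), decimate = 100) {
  channel <- match.arg(channel)
  runs <- vapply(physio, function(p) p$run, numeric(1))
  fs <- physio[[1]]$fs_hz
  rel <- seq(window_s[1] * fs, window_s[2] * fs, by = decimate)
  out <- list()
  for (task in unique(trial_table$task)) {
    ev <- trial_table[trial_table$task == task, , drop = FALSE]
    rows <- matrix(NA_real_, nrow(ev), length(rel))
    for (k in seq_len(nrow(ev))) {
      p <- physio[[match(ev$run[k], runs)]]
      i0 <- round(ev$onset_s[k] * fs) + 1
      idx <- i0 + rel
      ok <- idx >= 1 & idx <= length(p[[channel]])
      rows[k, ok] <- p[[channel]][idx[ok]]
    }
    out[[task]] <- rows
  }
  out$time_s <- rel / fs
  out
}

# invented per-item vocal-tract resonances (Hz); whispered F1 is raised,
# as observed for whispered vowels
.item_formants <- function(item, task) {
  tab <- list(bb = c(450, 1000), dd = c(400, 1800), mm = c(300, 900),
              nn = c(350, 1700), schwa = c(500, 1500))
  f <- tab[[item]]
  if (is.null(f)) stop("unknown item: ", item)
  if (task == "whispered") f[1] <- f[1] * 1.15
  f
}

#' Synthesize one utterance waveform
#'
#' Vowel-like token: a source signal (periodic glottal pulse train at 120 Hz
#' for voiced speech, white noise at lower amplitude for whispered speech)
#' excites an all-pole filter with two resonances. The resonance frequencies
#' are item-specific and returned as ground truth, so formant estimators can
#' be validated against the synthesis parameters. Duration 0.8 s fits the
#' 900 ms silent gap.
#'
#' @param item one of `"bb"`, `"dd"`, `"mm"`, `"nn"`, `"schwa"`.
#' @param task `"voiced"` or `"whispered"`.
#' @param fs_hz sampling rate (default 22400).
#' @param seed integer RNG seed.
#' @param duration_s token duration in seconds.
#' @return numeric waveform with attributes `fs_hz`, `formants_hz`
#'   (ground-truth resonances), `task`, `item`.
#' @export
generate_utterance_audio <- function(item, task, fs_hz = 22400, seed = 1,
                                     duration_s = 0.8) {
  if (!item %in% .items) stop("unknown item: ", item)
  if (!task %in% .tasks) stop("unknown task: ", task)
  f <- .item_formants(item, task)
  n <- round(duration_s * fs_hz)
  withr::with_seed(seed, {
    if (task == "voiced") {
      src <- rep(0, n)
      period <- round(fs_hz / 120)
      src[seq(1, n, by = period)] <- 1
      src <- src + stats::rnorm(n, sd = 0.01)
      amp <- 1
    } else {
      src <- stats::rnorm(n)
      amp <- 0.08
    }
    y <- .all_pole_filter(src, f, bw_hz = c(80, 100), fs_hz = fs_hz)
    y <- y / max(abs(y)) * amp
    # onset/offset taper so the token starts and ends silently
    ramp <- round(0.05 * fs_hz)
    env <- rep(1, n)
    env[1:ramp] <- (1 - cos(pi * (1:ramp) / ramp)) / 2
    env[(n - ramp + 1):n] <- rev(env[1:ramp])
    y <- y * env
  })
  attr(y, "fs_hz") <- fs_hz
  attr(y, "formants_hz") <- f
  attr(y, "task") <- task
  attr(y, "item") <- item
  y
}

# excite resonators at the given center frequencies / bandwidths in cascade
.all_pole_filter <- function(x, freqs_hz, bw_hz, fs_hz) {
  y <- x
  for (i in seq_along(freqs_hz)) {
    r <- exp(-pi * bw_hz[i] / fs_hz)
    theta <- 2 * pi * freqs_hz[i] / fs_hz
    # denominator 1 - 2 r cos(theta) z^-1 + r^2 z^-2
    y <- stats::filter(y, filter = c(2 * r * cos(theta), -r^2),
                       method = "recursive")
    y <- as.numeric(y)
  }
  y
}
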
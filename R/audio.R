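#' Speech amplitude envelope via the Hilbert transform
#'
#' Fixed pipeline: zero-phase (forward-backward) 4th-order Butterworth
#' high-pass at 150 Hz, analytic-signal magnitude via the FFT Hilbert
#' construction, then zero-phase 4th-order Butterworth low-pass at 8 Hz.
#' Forward-backward filtering doubles the effective order; both passes use
#' [signal::filtfilt()]. Output length equals input length.
#'
#' @param waveform numeric vector.
#' @param fs_hz sampling rate; must exceed 300 Hz so the 150 Hz high-pass
#'   cutoff lies below Nyquist.
#' @return nonnegative envelope, same length as `waveform`.
#' @export
compute_envelope <- function(waveform, fs_hz) {
  if (fs_hz <= 300) stop("fs_hz must exceed 300 Hz (high-pass cutoff 150 Hz)")
  hp <- signal::butter(4, 150 / (fs_hz / 2), type = "high")
  x <- signal::filtfilt(hp, as.numeric(waveform))
  env <- Mod(.analytic_signal(x))
  lp <- signal::butter(4, 8 / (fs_hz / 2), type = "low")
  out <- signal::filtfilt(lp, env)
  pmax(out, 0)
}

# analytic signal: zero the negative frequencies, double the positive ones
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Loudness of an utterance
#'
#' Mean absolute signal in a 100 ms window centered at the peak of the
#' speech envelope (earliest sample wins ties); the window is truncated at
#' the signal edges.
#'
#' @param waveform numeric vector.
#' @param envelope its envelope (same length); computed via
#'   [compute_envelope()] if missing.
#' @param fs_hz sampling rate.
#' @return scalar loudness >= 0.
#' @export
compute_loudness <- function(waveform, envelope = NULL, fs_hz) {
  if (length(waveform) == 0) stop("empty signal")
  if (is.null(envelope)) envelope <- compute_envelope(waveform, fs_hz)
  stopifnot(length(envelope) == length(waveform))
  peak <- which.max(envelope)              # earliest index on ties
  half <- round(0.05 * fs_hz)
  lo <- max(1, peak - half)
  hi <- min(length(waveform), peak + half)
  mean(abs(waveform[lo:hi]))
}

#' Short-time Fourier magnitude spectrogram
#'
#' Segment length 100 samples with 90% overlap (hop 10) and 128 one-sided
#' frequency bins (zero-padded FFT), periodic Hann taper. An n-sample input
#' yields `floor((n - 100) / 10) + 1` frames.
#'
#' @param waveform numeric vector, length >= 100.
#' @param fs_hz sampling rate (for the frequency axis attribute).
#' @return 128 x n_frames magnitude matrix; attributes `freq_hz`, `time_s`.
#' @export
compute_spectrogram <- function(waveform, fs_hz = 22400) {
  n <- length(waveform)
  seg <- 100L; hop <- 10L; nbins <- 128L
  if (n < seg) stop("input shorter than one 100-sample segment")
  nfft <- 2L * (nbins - 1L)                # one-sided bins = nfft/2 + 1 = 128
  win <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / seg))   # periodic Hann
  n_frames <- (n - seg) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  frames <- vapply(starts, function(s) {
    seg_x <- waveform[s:(s + seg - 1)] * win
    Mod(stats::fft(c(seg_x, rep(0, nfft - seg)))[1:nbins])
  }, numeric(nbins))
  S <- matrix(frames, nrow = nbins)
  attr(S, "freq_hz") <- (0:(nbins - 1)) * fs_hz / nfft
  attr(S, "time_s") <- (starts - 1 + seg / 2) / fs_hz
  S
}

#' First two formant frequencies by linear prediction
#'
#' Fits an all-pole (LPC) model by the autocorrelation method with the
#' standard order heuristic `2 + fs_hz/1000` (rounded), takes the roots of
#' the prediction polynomial with positive imaginary part, discards
#' real-axis and over-damped roots (bandwidth > 400 Hz) and roots outside
#' (90 Hz, Nyquist - 50 Hz), converts to Hz and sorts ascending. The first
#' two are F1 and F2.
#'
#' @param waveform steady voiced-like segment, >= 30 ms.
#' @param fs_hz sampling rate.
#' @param order LPC order; default `round(2 + fs_hz / 1000)`.
#' @return list: `f1_hz`, `f2_hz` (NA on failure), `failed` (logical),
#'   `candidates_hz` (all retained root frequencies).
#' @export
estimate_formants <- function(waveform, fs_hz, order = round(2 + fs_hz / 1000)) {
  x <- as.numeric(waveform)
  if (length(x) < 0.03 * fs_hz) stop("segment shorter than 30 ms")
  x <- x - mean(x)
  if (stats::sd(x) == 0) {
    return(list(f1_hz = NA_real_, f2_hz = NA_real_, failed = TRUE,
                candidates_hz = numeric(0)))
  }
  a <- .lpc(x, order)
  # poles solve z^p + a1 z^(p-1) + ... + ap = 0, i.e. polyroot(rev(a))
  rts <- polyroot(rev(a))
  rts <- rts[Im(rts) > 1e-8]
  freq <- Arg(rts) * fs_hz / (2 * pi)
  bw <- -log(pmin(Mod(rts), 1 - 1e-12)) * fs_hz / pi
  keep <- freq > 90 & freq < fs_hz / 2 - 50 & bw < 400
  cand <- sort(freq[keep])
  if (length(cand) < 2) {
    return(list(f1_hz = if (length(cand) >= 1) cand[1] else NA_real_,
                f2_hz = NA_real_, failed = TRUE, candidates_hz = cand))
  }
  list(f1_hz = cand[1], f2_hz = cand[2], failed = FALSE, candidates_hz = cand)
}

# autocorrelation-method LPC coefficients c(1, a_1, ..., a_p) of the
# prediction-error filter A(z) = 1 + sum a_k z^-k
.lpc <- function(x, p) {
  n <- length(x)
  r <- vapply(0:p, function(k) sum(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
  R <- stats::toeplitz(r[1:p])
  a <- solve(R + diag(1e-9 * r[1], p), -r[2:(p + 1)])
  c(1, a)
}

#' Pointwise comparison of two sets of matched traces
#'
#' Paired two-tailed t-tests across subjects at every time point, with
#' uncorrected significance at `alpha` and Benjamini-Hochberg FDR
#' significance at `fdr_q` across time points.
#'
#' @param traces_a,traces_b subjects x time matrices of trial-averaged
#'   traces (same dimensions, >= 3 subjects).
#' @param alpha uncorrected threshold (default 0.05).
#' @param fdr_q FDR level across time points (default 0.05).
#' @return data frame: `t`, `p`, `sig_uncorrected`, `sig_fdr` per time point.
#' @export
compare_traces <- function(traces_a, traces_b, alpha = 0.05, fdr_q = 0.05) {
  traces_a <- as.matrix(traces_a); traces_b <- as.matrix(traces_b)
  if (!all(dim(traces_a) == dim(traces_b))) stop("trace dimensions differ")
  if (nrow(traces_a) < 3) stop("need at least 3 subjects")
  res <- .col_one_sample_t(traces_a - traces_b)
  fdr <- fdr_bh(res$p, q = fdr_q)
  data.frame(t = res$t, p = res$p,
             sig_uncorrected = res$p < alpha,
             sig_fdr = fdr$rejected)
}

#' Trial-locked gray-matter average response (respiratory IRF proxy)
#'
#' For every trial, extracts the TR-grid epoch (lags 0, TR, ..., 16 s)
#' locked to trial onset, averages over gray-matter voxels and trials, and
#' subtracts the lag-0 value so curves start at zero. The result proxies the
#' respiration-driven global signal change.
#'
#' @param dataset a `speech_dataset`, or a list as returned by
#'   [dataset_matrix()].
#' @param subject subject index (when `dataset` is a `speech_dataset`).
#' @param trial_subset optional integer subset of trial rows.
#' @param epoch_s epoch length in seconds (default 16).
#' @return list of class `resp_irf`: `timepoints_s`, `mean_response`
#'   (lag-0-anchored), `per_trial` (trials x lags matrix), `n_trials`.
#' @export
compute_resp_irf <- function(dataset, subject = 1, trial_subset = NULL,
                             epoch_s = 16) {
  dm <- if (inherits(dataset, "speech_dataset")) {
    dataset_matrix(dataset, subject)
  } else dataset
  if (ncol(dm$Y) == 0) stop("empty gray-matter mask")
  tr <- dm$tr_s
  n_lags <- as.integer(epoch_s / tr) + 1L
  g <- rowMeans(dm$Y)
  ev <- dm$events
  if (!is.null(trial_subset)) ev <- ev[trial_subset, , drop = FALSE]
  run_offsets <- c(0, cumsum(tabulate(dm$runs)))
  per_trial <- matrix(NA_real_, nrow(ev), n_lags)
  for (k in seq_len(nrow(ev))) {
    i0 <- run_offsets[ev$run[k]] + round(ev$onset_s[k] / tr) + 1
    idx <- i0 + 0:(n_lags - 1)
    run_end <- run_offsets[ev$run[k] + 1]
    if (max(idx) > run_end) stop("trial epoch exceeds run end")
    per_trial[k, ] <- g[idx]
  }
  m <- colMeans(per_trial)
  structure(list(timepoints_s = (0:(n_lags - 1)) * tr,
                 mean_response = m - m[1],
                 per_trial = per_trial, n_trials = nrow(ev)),
            class = "resp_irf")
}
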
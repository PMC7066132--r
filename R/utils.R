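#' Canonical double-gamma hemodynamic response function
#'
#' The SPM-style canonical HRF: a gamma density peaking near 5 s minus a
#' 1/6-scaled undershoot gamma peaking near 15 s, normalized to unit peak.
#' The same kernel is used by the synthetic generator and the design-matrix
#' builder, so parameter-recovery tests isolate estimation error rather than
#' model mismatch.
#'
#' @param t numeric vector of times in seconds (values < 0 return 0).
#' @param peak_delay delay of the response gamma in seconds (default 6).
#' @param undershoot_delay delay of the undershoot gamma (default 16).
#' @param undershoot_ratio relative amplitude of the undershoot (default 1/6).
#' @return numeric vector of HRF values, unit peak.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 1 / 6) {
  h <- rep(0, length(t))
  pos <- t >= 0
  tp <- t[pos]
  h[pos] <- stats::dgamma(tp, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(tp, shape = undershoot_delay, rate = 1)
  # normalize on a dense grid so the peak is 1 regardless of sampling
  tg <- seq(0, 32, by = 0.01)
  hg <- stats::dgamma(tg, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(tg, shape = undershoot_delay, rate = 1)
  h / max(hg)
}

#' Legendre polynomial drift basis
#'
#' Legendre polynomials P0..Pk evaluated on n equally spaced points of
#' \[-1, 1\], the standard slow-drift nuisance basis for fMRI runs.
#'
#' @param n number of time points.
#' @param order maximum polynomial order (k).
#' @return n x (order + 1) matrix, column j holds P_{j-1}.
#' @export
legendre_basis <- function(n, order) {
  stopifnot(n >= 1, order >= 0)
  x <- if (n == 1) 0 else seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  P
}

#' HRF-convolved trial regressor on the TR grid
#'
#' Convolves a boxcar of `duration_s` seconds at each onset with the
#' double-gamma HRF on a dense (0.1 s) grid, then samples at volume
#' acquisition times 0, TR, 2 TR, ...
#'
#' @param onsets_s trial onsets in seconds relative to run start.
#' @param n_vol number of volumes in the run.
#' @param tr_s repetition time in seconds.
#' @param duration_s boxcar duration per trial (default 6 s: three
#'   utterances separated by one TR).
#' @param hrf_fun HRF function of time in seconds.
#' @return numeric vector of length `n_vol`, unit peak for an isolated trial.
#' @export
hrf_regressor <- function(onsets_s, n_vol, tr_s, duration_s = 6,
                          hrf_fun = hrf_double_gamma) {
  dt <- 0.1
  t_end <- n_vol * tr_s + 32
  tg <- seq(0, t_end, by = dt)
  stim <- rep(0, length(tg))
  for (on in onsets_s) {
    stim[tg >= on & tg < on + duration_s] <- 1
  }
  h <- hrf_fun(seq(0, 32, by = dt))
  conv_full <- stats::convolve(stim, rev(h), type = "open")[seq_along(tg)] * dt
  # unit-peak response for a single isolated trial
  single <- stats::convolve(
    as.numeric(tg < duration_s), rev(h), type = "open"
  )[seq_along(tg)] * dt
  conv_full <- conv_full / max(single)
  vol_t <- (seq_len(n_vol) - 1) * tr_s
  conv_full[round(vol_t / dt) + 1]
}

# Vectorized one-sample t-test over columns: returns t, two-sided p, df.
.col_one_sample_t <- function(X) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 observations for a t-test")
  m <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2, m)^2) / (n - 1))
  se <- s / sqrt(n)
  # a zero-variance column with a mean that is numerically zero relative to
  # the data scale is a true zero, not an infinite t
  scale <- colMeans(abs(X))
  zero_mean <- abs(m) <= 1e-12 * pmax(1, scale)
  t <- ifelse(se == 0, ifelse(zero_mean, 0, sign(m) * Inf), m / se)
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  p[is.infinite(t)] <- 0
  p[t == 0 & se == 0] <- 1
  list(t = t, p = p, df = n - 1, mean = m)
}

# linear voxel index <-> integer coordinates on a 3D grid
.coord_to_index <- function(coords, dim3) {
  coords[, 1] + (coords[, 2] - 1) * dim3[1] +
    (coords[, 3] - 1) * dim3[1] * dim3[2]
}

.index_to_coord <- function(idx, dim3) {
  idx0 <- idx - 1
  x <- idx0 %% dim3[1]
  y <- (idx0 %/% dim3[1]) %% dim3[2]
  z <- idx0 %/% (dim3[1] * dim3[2])
  cbind(x + 1, y + 1, z + 1)
}

.stop_if_not_binary <- function(labels) {
  u <- unique(labels)
  if (length(u) != 2) {
    stop("labels must contain exactly 2 classes, got ", length(u))
  }
  invisible(u)
}
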
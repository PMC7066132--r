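# shared fixtures, built once per test session

.fx <- new.env(parent = emptyenv())

# small planted-pattern dataset used across modules
small_dataset <- function() {
  if (is.null(.fx$ds)) {
    .fx$ds <- generate_experiment(experiment_config(
      n_trials_per_run = 10, grid_shape = c(16, 16, 16),
      roi_size = c(3, 3, 3), gray_margin = 2,
      effect_size = 1.5, n_pattern_voxels = 20, seed = 7))
  }
  .fx$ds
}

# nuisance-regressed beta series of the small dataset
small_betas <- function() {
  if (is.null(.fx$bs)) {
    ds <- small_dataset()
    dm <- dataset_matrix(ds)
    des <- build_design(dm$events, dm$motion, ds$n_vol_per_run, dm$tr_s,
                        include_interest = FALSE)
    fit <- fit_glm(dm$Y, des)
    .fx$dm <- dm
    .fx$des <- des
    .fx$bs <- extract_trial_features(fit$residuals, dm$events, dm$runs,
                                     dm$tr_s, censored = des$censored)
  }
  list(ds = small_dataset(), dm = .fx$dm, des = .fx$des, bs = .fx$bs)
}

# independent step-up FDR oracle: enumerate every k directly
brute_force_bh <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= (seq_len(m)) * q / m)
  rejected <- rep(FALSE, m)
  if (length(ks)) rejected[p <= ps[max(ks)]] <- TRUE
  rejected
}

# expected RFE survivor-count schedule under the ceil convention
elimination_schedule <- function(n0, frac, iters) {
  out <- integer(0)
  n <- n0
  for (i in seq_len(iters)) {
    n <- n - ceiling(frac * n)
    if (n < 1) break
    out <- c(out, n)
  }
  out
}

# two-resonator synthesis used as the formant-recovery oracle
synth_two_pole <- function(freqs, bws, fs, n = 8000) {
  y <- stats::rnorm(n)
  for (i in 1:2) {
    r <- exp(-pi * bws[i] / fs)
    th <- 2 * pi * freqs[i] / fs
    y <- as.numeric(stats::filter(y, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  y
}

# balanced 2-class label/run layout helpers for decoder tests
null_labels <- function(n_runs = 4, per_run = 8) {
  list(labels = rep(rep(c("a", "b"), per_run / 2), n_runs),
       runs = rep(seq_len(n_runs), each = per_run))
}
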
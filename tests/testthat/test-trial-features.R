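test_that("motion censoring applies a strict 0.4 mm derivative threshold", {
  m <- matrix(0, 10, 6)
  expect_false(any(censor_frames(m)))

  m[5, 1] <- 0.5                       # jump of 0.5 into volume 5
  flags <- censor_frames(m)
  expect_true(flags[5])
  expect_true(flags[6])                # and 0.5 back out again
  expect_equal(sum(flags), 2L)

  m2 <- matrix(0, 10, 6)
  m2[5:10, 1] <- 0.4                   # exactly 0.4: strict inequality
  expect_false(any(censor_frames(m2)))
  expect_false(censor_frames(matrix(rnorm(60), 10, 6))[1])

  expect_error(censor_frames(matrix(0, 5, 5)), "6 columns")
  m3 <- matrix(0, 5, 6); m3[2, 2] <- NA
  expect_error(censor_frames(m3), "non-finite")
})

test_that("design matrix has the documented column structure", {
  fx <- small_betas()
  dm <- fx$dm
  ds <- fx$ds
  des <- build_design(dm$events, dm$motion, ds$n_vol_per_run, dm$tr_s,
                      include_interest = TRUE)
  n_cens <- sum(des$censored)
  expect_equal(ncol(des$X), 10 + 6 * 4 + 6 + n_cens)
  expect_equal(sum(grepl("^legendre", colnames(des$X))), 24L)
  # interest regressors are zero outside their condition's trials
  reg <- des$X[, "cond_voiced_bb"]
  ev <- dm$events[dm$events$task == "voiced" & dm$events$item == "bb", ]
  run_off <- c(0, cumsum(rep(ds$n_vol_per_run, 3)))
  live <- unlist(lapply(seq_len(nrow(ev)), function(k) {
    i0 <- run_off[ev$run[k]] + round(ev$onset_s[k] / dm$tr_s) + 1
    i0:(i0 + 16)
  }))
  expect_lt(max(abs(reg[-live])), 0.05)
  expect_error(build_design(dm$events, NULL, ds$n_vol_per_run, dm$tr_s),
               "required")
})

test_that("the HRF-convolved regressor peaks where dense convolution says", {
  n_vol <- 40
  reg <- hrf_regressor(10, n_vol, tr_s = 2, duration_s = 6)
  # independent dense-grid oracle
  dt <- 0.01
  tg <- seq(0, n_vol * 2 + 32, by = dt)
  stim <- as.numeric(tg >= 10 & tg < 16)
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  dense <- stats::convolve(stim, rev(h), type = "open")[seq_along(tg)]
  peak_dense <- tg[which.max(dense)]
  peak_reg <- (which.max(reg) - 1) * 2
  expect_lt(abs(peak_reg - peak_dense), 2)
  expect_lt(abs(peak_dense - (10 + 8)), 1.5)   # ~HRF peak + mid-boxcar
})

test_that("OLS recovers noiseless planted amplitudes exactly", {
  cfg <- experiment_config(n_trials_per_run = 10, n_runs = 2,
                           grid_shape = c(10, 10, 10), roi_size = c(2, 2, 2),
                           gray_margin = 2, noise_sd = 0, evoked_amp = 1.7,
                           resp_amp = 0, motion_spike_frac = 0,
                           physio_fs_hz = 100, seed = 17)
  ds <- generate_experiment(cfg)
  dm <- dataset_matrix(ds, mask = ds$roi_labels > 0)
  des <- build_design(dm$events, dm$motion, ds$n_vol_per_run, dm$tr_s)
  fit <- fit_glm(dm$Y, des)
  betas <- fit$beta[grepl("^cond_", rownames(fit$beta)), ]
  expect_lt(max(abs(betas - 1.7)), 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-6)
})

test_that("residuals are orthogonal to every design column", {
  fx <- small_betas()
  fit <- fit_glm(fx$dm$Y[, 1:50], fx$des)
  dots <- crossprod(fx$des$X, fit$residuals)
  norms <- outer(sqrt(colSums(fx$des$X^2)),
                 sqrt(colSums(fit$residuals^2) + 1e-300))
  expect_lt(max(abs(dots) / norms), 1e-8)
})

test_that("rank deficiency is an error naming the collinear columns", {
  fx <- small_betas()
  des <- fx$des
  des$X <- cbind(des$X, dup_col = des$X[, "motion1"])
  expect_error(fit_glm(fx$dm$Y[, 1:2], des), "dup_col|motion1")
})

test_that("beta estimates are unbiased under noise (Monte-Carlo oracle)", {
  set.seed(8)
  n_vol <- 60
  reg <- hrf_regressor(c(8, 24, 40, 56, 72, 88), n_vol, 2)
  X <- cbind(intercept = 1, cond = reg,
             legendre_basis(n_vol, 2)[, -1])
  betas <- replicate(200, {
    y <- 2.5 * reg + rnorm(n_vol)
    qr.coef(qr(X), y)[2]
  })
  expect_lt(abs(mean(betas) - 2.5), 2 * sd(betas) / sqrt(200))
})

test_that("epoch detrending annihilates linear trends", {
  n_vol <- 44
  trend <- matrix(seq_len(n_vol) * 3.3 + 5, n_vol, 4)
  tt <- data.frame(onset_s = c(8, 24, 40), run = 1,
                   task = "voiced", item = "bb")
  bs <- extract_trial_features(trend, tt, rep(1, n_vol), 2)
  expect_lt(max(abs(bs$values)), 1e-10)
})

test_that("the trial feature grows monotonically with response amplitude", {
  op <- speechmvpa:::.epoch_operator(2)
  template <- speechmvpa:::.trial_template(2, 3, 6)
  s_epoch <- template(op$lags_s)
  amps <- seq(0, 2, by = 0.25)
  feats <- vapply(amps, function(a) sum(op$phi * (a * s_epoch)), numeric(1))
  expect_true(all(diff(feats) > 0))
})

test_that("beta series are invariant to added linear-in-time trends", {
  fx <- small_betas()
  dm <- fx$dm
  Y2 <- fx$dm$Y[, 1:30]
  run_len <- tabulate(dm$runs)
  tvec <- unlist(lapply(run_len, seq_len))
  Y2 <- Y2 + tvec * 0.37
  des <- fx$des
  bs1 <- extract_trial_features(fit_glm(fx$dm$Y[, 1:30], des)$residuals,
                                dm$events, dm$runs, dm$tr_s)
  bs2 <- extract_trial_features(fit_glm(Y2, des)$residuals,
                                dm$events, dm$runs, dm$tr_s)
  expect_equal(bs1$values, bs2$values, tolerance = 1e-8)
})

test_that("trials with heavily censored epochs are dropped and reported", {
  n_vol <- 44
  resid <- matrix(rnorm(n_vol * 3), n_vol, 3)
  tt <- data.frame(onset_s = c(8, 24), run = 1, task = "voiced", item = "bb")
  cens <- rep(FALSE, n_vol)
  cens[(8 / 2 + 1) + 0:4] <- TRUE      # 5 of 9 epoch volumes of trial 1
  bs <- extract_trial_features(resid, tt, rep(1, n_vol), 2, censored = cens)
  expect_equal(bs$dropped, 1L)
  expect_equal(nrow(bs$values), 1L)
  # an epoch running past the run end is dropped with a warning
  tt2 <- data.frame(onset_s = c(8, 80), run = 1, task = "voiced", item = "bb")
  expect_warning(bs2 <- extract_trial_features(resid, tt2, rep(1, n_vol), 2),
                 "exceeds run end")
  expect_equal(bs2$dropped, 2L)
})

test_that("group contrasts validate input and find planted amplitude effects", {
  conds <- as.vector(t(outer(c("voiced", "whispered"),
                             c("bb", "dd", "mm", "nn", "schwa"),
                             paste, sep = "_")))
  contrast <- setNames(ifelse(grepl("^voiced", conds), 0.2, -0.2), conds)
  # betas identical across the contrasted conditions: t = 0 everywhere
  b_eq <- matrix(rnorm(5 * 20), 5, 20)
  mk <- function() rbind(b_eq, b_eq)   # voiced rows == whispered rows
  b <- mk(); rownames(b) <- conds
  same <- group_contrast(list(b, b, b), contrast)
  expect_true(all(same$t_map == 0))

  expect_error(group_contrast(list(b, b, b),
                              setNames(rep(0.1, 10), conds)), "sum to zero")
  expect_error(group_contrast(list(b, b), contrast), "3 subjects")

  # planted voiced > whispered region is localized
  set.seed(30)
  subs <- lapply(1:12, function(s) {
    bb <- matrix(rnorm(10 * 100), 10, 100, dimnames = list(conds, NULL))
    bb[grepl("^voiced", rownames(bb)), 11:25] <-
      bb[grepl("^voiced", rownames(bb)), 11:25] + 1
    bb
  })
  g <- group_contrast(subs, contrast)
  hits <- which(g$p_map < 0.05 & g$t_map > 0)
  expect_gte(length(intersect(hits, 11:25)) / 15, 0.9)
  expect_lt(length(setdiff(hits, 11:25)), 10)
})
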
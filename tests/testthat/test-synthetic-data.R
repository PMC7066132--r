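test_that("config invariants are enforced", {
  expect_error(experiment_config(iti_s = 15), "multiple of tr_s")
  expect_error(experiment_config(n_trials_per_run = 12), "multiple of 10")
  expect_error(generate_experiment(experiment_config(
    grid_shape = c(8, 8, 8), roi_size = c(5, 5, 5), gray_margin = 2)),
    "too small")
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- experiment_config(n_trials_per_run = 10, grid_shape = c(12, 12, 12),
                           roi_size = c(2, 2, 2), gray_margin = 2,
                           physio_fs_hz = 100, seed = 5)
  expect_identical(generate_experiment(cfg), generate_experiment(cfg))
})

test_that("condition types are balanced within every run", {
  ds <- small_dataset()
  ev <- ds$subjects[[1]]$events
  tab <- table(ev$run, paste(ev$task, ev$item))
  expect_true(all(tab == tab[1, 1]))
  expect_equal(ncol(tab), 10L)
})

test_that("zero noise and zero signal leave only baseline plus drift", {
  cfg <- experiment_config(n_trials_per_run = 10, n_runs = 1,
                           grid_shape = c(10, 10, 10), roi_size = c(2, 2, 2),
                           gray_margin = 2, noise_sd = 0, evoked_amp = 0,
                           resp_amp = 0, effect_size = 0,
                           motion_spike_frac = 0, physio_fs_hz = 100,
                           seed = 3)
  ds <- generate_experiment(cfg)
  dm <- dataset_matrix(ds, mask = array(TRUE, c(10, 10, 10)))
  n_vol <- nrow(dm$Y)
  L <- cbind(1, legendre_basis(n_vol, cfg$drift_order)[, -1])
  resid <- qr.resid(qr(L), dm$Y)
  expect_lt(max(abs(resid)), 1e-8)
  # and with drift_sd = 0 the volumes are exactly constant 100
  cfg0 <- experiment_config(n_trials_per_run = 10, n_runs = 1,
                            grid_shape = c(10, 10, 10), roi_size = c(2, 2, 2),
                            gray_margin = 2, noise_sd = 0, evoked_amp = 0,
                            resp_amp = 0, drift_sd = 0,
                            motion_spike_frac = 0, physio_fs_hz = 100,
                            seed = 3)
  ds0 <- generate_experiment(cfg0)
  expect_equal(max(abs(ds0$subjects[[1]]$volumes[[1]] - 100)), 0)
})

test_that("planted pattern is confined to its ground-truth voxels", {
  fx <- small_betas()
  ds <- fx$ds
  bs <- fx$bs
  cc <- contrast_classes(bs$trials, "voiced-vs-whispered")
  v <- bs$values[cc$subset, , drop = FALSE]
  g <- cc$classes
  pooled_d <- function(cols) {
    a <- v[g == levels(g)[1], cols, drop = FALSE]
    b <- v[g == levels(g)[2], cols, drop = FALSE]
    (colMeans(a) - colMeans(b)) /
      sqrt((apply(a, 2, var) + apply(b, 2, var)) / 2)
  }
  planted_cols <- match(ds$ground_truth$pattern_voxels, fx$dm$voxel_index)
  w <- ds$ground_truth$pattern_maps[[1]][ds$ground_truth$pattern_voxels]
  d_planted <- pooled_d(planted_cols) * sign(w)
  # realized per-voxel d matches the requested effect size
  expect_lt(abs(mean(d_planted) - ds$ground_truth$effect_size), 0.35)
  # signal-free voxels show no class effect on average; the shared
  # respiratory/drift components induce a small common offset across all
  # voxels of one dataset, so the tolerance is above pure sampling error
  free_cols <- setdiff(seq_along(fx$dm$voxel_index), planted_cols)
  d_free <- pooled_d(free_cols)
  expect_lt(abs(mean(d_free)), 0.15)
  expect_lt(mean(abs(d_free) > 1), 0.01)
})

test_that("plant_pattern at zero effect size is a no-op and validates input", {
  ds <- generate_experiment(experiment_config(
    n_trials_per_run = 10, n_runs = 2, grid_shape = c(12, 12, 12),
    roi_size = c(2, 2, 2), gray_margin = 2, physio_fs_hz = 100, seed = 9))
  expect_identical(plant_pattern(ds, "lip_M1", "voiced-vs-whispered", 0), ds)
  expect_error(plant_pattern(ds, integer(0), "voiced-vs-whispered", 1),
               "nonempty")
  expect_error(plant_pattern(ds, "nowhere", "voiced-vs-whispered", 1),
               "unknown ROI")
})

test_that("patterns in disjoint ROIs decode independently", {
  cfg <- experiment_config(n_trials_per_run = 10, grid_shape = c(16, 16, 16),
                           roi_size = c(3, 3, 3), gray_margin = 2,
                           physio_fs_hz = 100, seed = 21)
  ds <- generate_experiment(cfg)
  ds <- plant_pattern(ds, "lip_M1", "voiced-vs-whispered", 1.5, seed = 1)
  voxA <- which(ds$roi_labels == 1)
  voxB <- which(ds$roi_labels == 5)
  dm <- dataset_matrix(ds)
  des <- build_design(dm$events, dm$motion, ds$n_vol_per_run, dm$tr_s,
                      include_interest = FALSE)
  bs <- extract_trial_features(fit_glm(dm$Y, des)$residuals, dm$events,
                               dm$runs, dm$tr_s, censored = des$censored)
  cc <- contrast_classes(bs$trials, "voiced-vs-whispered")
  folds <- leave_run_out_folds(cc$classes, bs$trials$run[cc$subset])
  accA <- lda_accuracy(bs$values[cc$subset, match(voxA, dm$voxel_index)],
                       cc$classes, folds)
  # zero ROI B everywhere: ROI A decoding must be unaffected
  for (r in seq_along(ds$subjects[[1]]$volumes)) {
    vol <- ds$subjects[[1]]$volumes[[r]]
    m <- matrix(vol, prod(cfg$grid_shape), dim(vol)[4])
    m[voxB, ] <- 0
    ds$subjects[[1]]$volumes[[r]] <- array(m, dim(vol))
  }
  dm2 <- dataset_matrix(ds)
  bs2 <- extract_trial_features(fit_glm(dm2$Y, des)$residuals, dm2$events,
                                dm2$runs, dm2$tr_s, censored = des$censored)
  accA2 <- lda_accuracy(bs2$values[cc$subset, match(voxA, dm2$voxel_index)],
                        cc$classes, folds)
  expect_equal(accA, accA2)
  expect_gt(accA, 0.7)
})

test_that("physio traces carry trial-locked structure with matched tasks", {
  cfg <- experiment_config(n_trials_per_run = 10, n_runs = 2,
                           grid_shape = c(10, 10, 10), roi_size = c(2, 2, 2),
                           gray_margin = 2, physio_fs_hz = 200, seed = 13)
  ds <- generate_experiment(cfg)
  p <- ds$subjects[[1]]$physio[[1]]
  fs <- p$fs_hz
  expect_equal(length(p$respiration), length(p$chin_pressure))
  expect_equal(unique(diff(p$tr_triggers)), cfg$tr_s * fs)
  # inhalation peak precedes the first chin-pressure deflection, per trial
  ev <- ds$subjects[[1]]$events
  ev <- ev[ev$run == 1, ]
  precede <- vapply(ev$onset_s, function(on) {
    w <- (round((on - 2) * fs):round((on + 6) * fs)) + 1
    which.max(p$respiration[w]) < which(p$chin_pressure[w] > 0.5)[1]
  }, logical(1))
  expect_true(all(precede))
})

test_that("voiced and whispered respiration are exchangeable at defaults", {
  tr_a <- list(); tr_b <- list()
  for (s in 1:6) {
    cfg <- experiment_config(n_trials_per_run = 10, n_runs = 2,
                             grid_shape = c(10, 10, 10), roi_size = c(2, 2, 2),
                             gray_margin = 2, physio_fs_hz = 200,
                             seed = 200 + s)
    ds <- generate_experiment(cfg)
    tt <- physio_trial_traces(ds$subjects[[1]]$physio,
                              ds$subjects[[1]]$events, decimate = 40)
    tr_a[[s]] <- colMeans(tt$voiced)
    tr_b[[s]] <- colMeans(tt$whispered)
  }
  res <- compare_traces(do.call(rbind, tr_a), do.call(rbind, tr_b))
  expect_equal(sum(res$sig_fdr), 0L)
})

test_that("a zero-trial table yields traces without trial-locked deflections", {
  cfg <- experiment_config(n_trials_per_run = 10, n_runs = 1,
                           grid_shape = c(10, 10, 10), roi_size = c(2, 2, 2),
                           gray_margin = 2, physio_fs_hz = 200, seed = 1)
  empty <- data.frame(onset_s = numeric(0), run = integer(0),
                      task = character(0), item = character(0))
  p <- withr::with_seed(1, generate_physio(empty, cfg, n_vol = 20))[[1]]
  expect_lt(max(abs(p$chin_pressure)), 0.5)
  expect_lt(diff(range(p$respiration)), 1.5)   # quiet breathing only
})

test_that("utterance audio has the designed loudness and source contrasts", {
  v <- generate_utterance_audio("bb", "voiced", seed = 2)
  w <- generate_utterance_audio("bb", "whispered", seed = 2)
  fs <- attr(v, "fs_hz")
  expect_gt(compute_loudness(v, fs_hz = fs), compute_loudness(w, fs_hz = fs))
  expect_error(generate_utterance_audio("xx", "voiced"), "unknown item")
  expect_error(generate_utterance_audio("bb", "sung"), "unknown task")
  # silence has zero loudness
  expect_equal(compute_loudness(rep(0, length(v)),
                                envelope = rep(0, length(v)), fs_hz = fs), 0)
  # ground-truth resonance is recoverable from the waveform
  est <- estimate_formants(v[2000:14000], fs)
  expect_lt(abs(est$f1_hz - attr(v, "formants_hz")[1]) /
              attr(v, "formants_hz")[1], 0.1)
})
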
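#' Configuration of a synthetic sparse-sampled speech-production experiment
#'
#' Bundles all generator parameters. Defaults reproduce the modeled study
#' design: 4 runs, TR 2 s with a 900 ms silent production gap, slow
#' event-related trials every 16 s with 3 utterances per trial, 2 mm voxels,
#' and 10 condition types (2 tasks x 5 items) balanced within run.
#'
#' @param n_subjects number of subjects to simulate.
#' @param n_runs functional runs per subject.
#' @param n_trials_per_run trials per run; must be a multiple of 10 so every
#'   task x item condition type occurs equally often in every run.
#' @param tr_s repetition time in seconds.
#' @param silent_gap_s silent production gap inside each TR, seconds.
#' @param iti_s inter-trial interval in seconds; must be a multiple of `tr_s`.
#' @param utterances_per_trial utterances per trial (>= 1).
#' @param grid_shape integer 3-vector of voxel counts per axis.
#' @param voxel_mm isotropic voxel size in millimetres.
#' @param noise_sd per-voxel Gaussian noise standard deviation (signal units).
#' @param drift_order maximum Legendre polynomial order of the planted drift.
#' @param drift_sd standard deviation of random drift coefficients.
#' @param evoked_amp amplitude of the task-evoked response in active (ROI)
#'   voxels, in units of the unit-peak trial response.
#' @param resp_amp amplitude of the global respiratory component added to all
#'   gray-matter voxels.
#' @param resp_peak_s peak latency of the respiratory response kernel in
#'   seconds after trial onset (default 8).
#' @param effect_size Cohen's d per planted voxel of the multivoxel condition
#'   pattern (0 = no pattern planted).
#' @param pattern_roi name of the ROI receiving the planted pattern.
#' @param pattern_contrast contrast name defining the binary trial classes of
#'   the planted pattern (see [contrast_classes()]).
#' @param n_pattern_voxels number of ROI voxels carrying the pattern.
#' @param pattern_type `"multivoxel"` (random +/- voxel weights, mean zero:
#'   decodable but univariately silent) or `"uniform"` (all-positive weights:
#'   decodable and visible to univariate contrasts).
#' @param coupling_strength amplitude of the shared trial-level gain linking
#'   the coupling seed and target ROIs (0 = none).
#' @param coupling_seed_roi,coupling_target_roi ROI names sharing the gain.
#' @param coupling_conditions optional character vector of task names whose
#'   trials carry the coupling (default: all trials).
#' @param motion_spike_frac fraction of volumes receiving a motion spike with
#'   derivative norm above the 0.4 mm censoring threshold.
#' @param roi_size integer 3-vector, extent of each box-shaped ROI.
#' @param gray_margin margin (voxels) between grid boundary and gray matter.
#' @param physio_fs_hz physiological sampling rate in Hz.
#' @param hrf_peak_delay HRF peak-delay parameter; change it to synthesize
#'   with a latency-mismatched HRF for robustness checks.
#' @param seed integer RNG seed; identical configs and seeds give
#'   bit-identical datasets.
#' @return object of class `experiment_config` (a validated list).
#' @export
experiment_config <- function(n_subjects = 1, n_runs = 4, n_trials_per_run = 30,
                              tr_s = 2, silent_gap_s = 0.9, iti_s = 16,
                              utterances_per_trial = 3,
                              grid_shape = c(24, 24, 24), voxel_mm = 2,
                              noise_sd = 1, drift_order = 5, drift_sd = 2,
                              evoked_amp = 1, resp_amp = 1.5, resp_peak_s = 8,
                              effect_size = 0, pattern_roi = "lip_M1",
                              pattern_contrast = "voiced-vs-whispered",
                              n_pattern_voxels = 50,
                              pattern_type = c("multivoxel", "uniform"),
                              coupling_strength = 0,
                              coupling_seed_roi = "lip_M1",
                              coupling_target_roi = "cerebellum_L",
                              coupling_conditions = NULL,
                              motion_spike_frac = 0.02,
                              roi_size = c(5, 5, 4), gray_margin = 3,
                              physio_fs_hz = 1000, hrf_peak_delay = 6,
                              seed = 1) {
  pattern_type <- match.arg(pattern_type)
  cfg <- list(n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
              n_trials_per_run = as.integer(n_trials_per_run), tr_s = tr_s,
              silent_gap_s = silent_gap_s, iti_s = iti_s,
              utterances_per_trial = as.integer(utterances_per_trial),
              grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
              noise_sd = noise_sd, drift_order = as.integer(drift_order),
              drift_sd = drift_sd, evoked_amp = evoked_amp,
              resp_amp = resp_amp, resp_peak_s = resp_peak_s,
              effect_size = effect_size, pattern_roi = pattern_roi,
              pattern_contrast = pattern_contrast,
              n_pattern_voxels = as.integer(n_pattern_voxels),
              pattern_type = pattern_type,
              coupling_strength = coupling_strength,
              coupling_seed_roi = coupling_seed_roi,
              coupling_target_roi = coupling_target_roi,
              coupling_conditions = coupling_conditions,
              motion_spike_frac = motion_spike_frac,
              roi_size = as.integer(roi_size),
              gray_margin = as.integer(gray_margin),
              physio_fs_hz = physio_fs_hz, hrf_peak_delay = hrf_peak_delay,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_runs >= 1, cfg$n_trials_per_run >= 1,
            cfg$tr_s > 0, cfg$iti_s > 0, cfg$utterances_per_trial >= 1,
            length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 1),
            cfg$voxel_mm > 0, cfg$noise_sd >= 0, cfg$drift_order >= 0)
  if (abs(cfg$iti_s / cfg$tr_s - round(cfg$iti_s / cfg$tr_s)) > 1e-9) {
    stop("iti_s must be an integer multiple of tr_s")
  }
  if (cfg$n_trials_per_run %% 10 != 0) {
    stop("n_trials_per_run must be a multiple of 10 so that each of the ",
         "10 task x item condition types is balanced within run")
  }
  invisible(cfg)
}

# the 2 x 5 condition inventory
.tasks <- c("voiced", "whispered")
.items <- c("bb", "dd", "mm", "nn", "schwa")

#' Binary class labels for a named condition contrast
#'
#' Maps a contrast name to the trial subset and binary class labels used by
#' the decoders. Supported names: `"voiced-vs-whispered"` (task),
#' `"bilabial-vs-alveolar"` (bb+mm vs dd+nn, both tasks),
#' `"oral-vs-nasal"` (bb+dd vs mm+nn, voiced task only),
#' `"bilabial-vs-schwa"` (bb+mm vs schwa, voiced task only).
#'
#' @param trial_table data frame with columns `task` and `item`.
#' @param contrast contrast name.
#' @return list: `subset` (integer row indices of trials in the contrast)
#'   and `classes` (factor of length `length(subset)` with 2 levels).
#' @export
contrast_classes <- function(trial_table, contrast) {
  task <- trial_table$task
  item <- trial_table$item
  res <- switch(contrast,
    "voiced-vs-whispered" = list(
      subset = seq_len(nrow(trial_table)),
      classes = factor(task, levels = .tasks)),
    "bilabial-vs-alveolar" = {
      keep <- which(item %in% c("bb", "mm", "dd", "nn"))
      list(subset = keep,
           classes = factor(ifelse(item[keep] %in% c("bb", "mm"),
                                   "bilabial", "alveolar"),
                            levels = c("bilabial", "alveolar")))
    },
    "oral-vs-nasal" = {
      keep <- which(task == "voiced" & item %in% c("bb", "dd", "mm", "nn"))
      list(subset = keep,
           classes = factor(ifelse(item[keep] %in% c("bb", "dd"),
                                   "oral", "nasal"),
                            levels = c("oral", "nasal")))
    },
    "bilabial-vs-schwa" = {
      keep <- which(task == "voiced" & item %in% c("bb", "mm", "schwa"))
      list(subset = keep,
           classes = factor(ifelse(item[keep] == "schwa",
                                   "schwa", "bilabial"),
                            levels = c("bilabial", "schwa")))
    },
    stop("unknown contrast: ", contrast)
  )
  res
}

# default box-shaped ROI layout: 8 ROIs centered in the octants of the
# gray-matter interior.
.default_roi_names <- c("lip_M1", "tongue_M1", "larynx_M1", "sma",
                        "cerebellum_L", "cerebellum_R", "putamen", "stg")

.build_rois <- function(grid_shape, gray_margin, roi_size) {
  lo <- rep(gray_margin + 1, 3)
  hi <- grid_shape - gray_margin
  if (any(hi - lo + 1 < 2)) stop("grid too small for the gray-matter mask")
  half <- function(a, b) {
    mid <- (a + b) / 2
    list(c(a, floor(mid)), c(floor(mid) + 1, b))
  }
  octs <- list()
  hx <- half(lo[1], hi[1]); hy <- half(lo[2], hi[2]); hz <- half(lo[3], hi[3])
  for (ix in 1:2) for (iy in 1:2) for (iz in 1:2) {
    octs[[length(octs) + 1]] <- list(x = hx[[ix]], y = hy[[iy]], z = hz[[iz]])
  }
  labels <- array(0L, grid_shape)
  for (k in seq_along(octs)) {
    o <- octs[[k]]
    ext <- c(diff(o$x), diff(o$y), diff(o$z)) + 1
    if (any(roi_size > ext)) {
      stop("grid too small to contain the requested ROIs: roi_size ",
           paste(roi_size, collapse = "x"), " exceeds octant ",
           paste(ext, collapse = "x"))
    }
    start <- c(o$x[1], o$y[1], o$z[1]) + floor((ext - roi_size) / 2)
    labels[start[1]:(start[1] + roi_size[1] - 1),
           start[2]:(start[2] + roi_size[2] - 1),
           start[3]:(start[3] + roi_size[3] - 1)] <- k
  }
  labels
}

# dense single-trial response template (unit peak); returns a lookup
# function of time-since-onset in seconds.
.trial_template <- function(tr_s, utterances_per_trial, hrf_peak_delay) {
  dt <- 0.1
  dur <- (utterances_per_trial - 1) * tr_s + 2  # 3 utterances 1 TR apart: 6 s
  tg <- seq(0, dur + 32, by = dt)
  stim <- as.numeric(tg < dur)
  h <- hrf_double_gamma(seq(0, 32, by = dt), peak_delay = hrf_peak_delay)
  resp <- stats::convolve(stim, rev(h), type = "open")[seq_along(tg)] * dt
  resp <- resp / max(resp)
  function(t_s) {
    out <- rep(0, length(t_s))
    ok <- t_s >= 0 & t_s <= max(tg)
    out[ok] <- resp[pmin(length(resp), round(t_s[ok] / dt) + 1)]
    out
  }
}

# respiratory response kernel: gamma bump with configurable peak latency and
# a shallow late undershoot (the post-inhalation dip), unit peak.
.resp_kernel <- function(t_s, peak_s = 8) {
  scale <- 2
  shape <- peak_s / scale + 1
  k <- stats::dgamma(t_s, shape = shape, scale = scale) -
    0.25 * stats::dgamma(t_s, shape = 11, scale = 2.4)
  tg <- seq(0, 40, by = 0.05)
  kg <- stats::dgamma(tg, shape = shape, scale = scale) -
    0.25 * stats::dgamma(tg, shape = 11, scale = 2.4)
  k / max(kg)
}

# per-trial regressor matrix (n_vol x n_trials) for one run
.trial_regressors <- function(onsets_s, n_vol, tr_s, template) {
  vol_t <- (seq_len(n_vol) - 1) * tr_s
  vapply(onsets_s, function(on) template(vol_t - on), numeric(n_vol))
}

#' Generate a synthetic speech-production fMRI experiment
#'
#' Builds per-subject, per-run 4D volumes on the configured grid containing:
#' a constant baseline (100), per-voxel random Legendre drift, a global
#' respiratory response in gray matter (kernel peaking at
#' `config$resp_peak_s`), HRF-convolved task-evoked responses in all ROI
#' voxels, optional planted multivoxel condition patterns and trial-gain
#' couplings with known ground truth, Gaussian noise, motion traces with
#' occasional spikes, and synchronized physiological traces. Condition
#' labels are balanced within run by blocked shuffling, so leave-run-out
#' folds never lose a class.
#'
#' @param config an [experiment_config()].
#' @return object of class `speech_dataset`: `config`, `gray_mask` (logical
#'   3D array), `roi_labels` (integer 3D array with ROI names in
#'   `attr(,"roi_names")`), `subjects` (list; each with `volumes` (list of
#'   4D arrays per run), `motion` (list of n_vol x 6 matrices), `events`
#'   (trial table), `physio`), and `ground_truth` (pattern maps, planted
#'   voxel sets, effect size, coupling, respiratory peak).
#' @export
generate_experiment <- function(config) {
  validate_config(config)
  withr::with_seed(config$seed, .generate_experiment_impl(config))
}

.generate_experiment_impl <- function(cfg) {
  dim3 <- cfg$grid_shape
  n_vox <- prod(dim3)
  gray <- array(FALSE, dim3)
  m <- cfg$gray_margin
  gray[(m + 1):(dim3[1] - m), (m + 1):(dim3[2] - m),
       (m + 1):(dim3[3] - m)] <- TRUE
  roi_labels <- .build_rois(dim3, cfg$gray_margin, cfg$roi_size)
  attr(roi_labels, "roi_names") <- .default_roi_names
  gray_idx <- which(gray)
  active_idx <- which(roi_labels > 0)

  n_trials <- cfg$n_trials_per_run
  pre_s <- 2 * cfg$tr_s
  n_vol <- as.integer((pre_s + n_trials * cfg$iti_s) / cfg$tr_s + 1)
  template <- .trial_template(cfg$tr_s, cfg$utterances_per_trial,
                              cfg$hrf_peak_delay)

  # planted pattern bookkeeping (weights fixed across subjects and runs)
  gt <- list(effect_size = cfg$effect_size, resp_irf_peak_s = cfg$resp_peak_s,
             pattern_maps = list(), seed_regions = list(),
             coupled_regions = list())
  pattern <- NULL
  if (cfg$effect_size > 0) {
    roi_k <- match(cfg$pattern_roi, .default_roi_names)
    if (is.na(roi_k)) stop("unknown pattern_roi: ", cfg$pattern_roi)
    roi_idx <- which(roi_labels == roi_k)
    nv <- min(cfg$n_pattern_voxels, length(roi_idx))
    vox <- sort(sample(roi_idx, nv))
    signs <- if (cfg$pattern_type == "uniform") rep(1, nv)
             else sample(c(-1, 1), nv, replace = TRUE)
    amp <- .pattern_amplitude(cfg, template)
    pattern <- list(vox = vox, w = signs * amp, contrast = cfg$pattern_contrast)
    pm <- rep(0, n_vox)
    pm[vox] <- signs * amp
    gt$pattern_maps[[cfg$pattern_contrast]] <- pm
    gt$pattern_voxels <- vox
    gt$pattern_roi <- cfg$pattern_roi
  }
  coupling <- NULL
  if (cfg$coupling_strength > 0) {
    sk <- match(cfg$coupling_seed_roi, .default_roi_names)
    tk <- match(cfg$coupling_target_roi, .default_roi_names)
    coupling <- list(seed = which(roi_labels == sk),
                     target = which(roi_labels == tk))
    gt$seed_regions[[cfg$coupling_seed_roi]] <- coupling$seed
    gt$coupled_regions[[cfg$coupling_target_roi]] <- coupling$target
  }

  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    events <- list()
    volumes <- vector("list", cfg$n_runs)
    motion <- vector("list", cfg$n_runs)
    for (r in seq_len(cfg$n_runs)) {
      # balanced blocked shuffle of the 10 condition types
      conds <- expand.grid(task = .tasks, item = .items,
                           stringsAsFactors = FALSE)
      conds <- conds[rep(seq_len(10), n_trials / 10), ]
      conds <- conds[sample(nrow(conds)), ]
      onsets <- pre_s + (seq_len(n_trials) - 1) * cfg$iti_s
      ev <- data.frame(onset_s = onsets, run = r, task = conds$task,
                       item = conds$item, stringsAsFactors = FALSE)
      events[[r]] <- ev

      S <- .trial_regressors(onsets, n_vol, cfg$tr_s, template)   # n_vol x n_trials
      Y <- matrix(stats::rnorm(n_vol * n_vox, sd = cfg$noise_sd), n_vol, n_vox)
      Y <- Y + 100
      # drift: random Legendre coefficients per voxel, orders 1..drift_order
      if (cfg$drift_order >= 1 && cfg$drift_sd > 0) {
        L <- legendre_basis(n_vol, cfg$drift_order)[, -1, drop = FALSE]
        B <- matrix(stats::rnorm(ncol(L) * n_vox, sd = cfg$drift_sd),
                    ncol(L), n_vox)
        Y <- Y + L %*% B
      }
      # global respiratory component over gray matter
      if (cfg$resp_amp != 0) {
        vol_t <- (seq_len(n_vol) - 1) * cfg$tr_s
        rr <- rowSums(vapply(onsets, function(on) {
          tt <- vol_t - on
          out <- rep(0, n_vol)
          ok <- tt >= 0
          out[ok] <- .resp_kernel(tt[ok], cfg$resp_peak_s)
          out
        }, numeric(n_vol)))
        Y[, gray_idx] <- Y[, gray_idx] + cfg$resp_amp * rr
      }
      # task-evoked response in all ROI voxels
      if (cfg$evoked_amp != 0 && length(active_idx)) {
        Y[, active_idx] <- Y[, active_idx] + cfg$evoked_amp * rowSums(S)
      }
      # planted multivoxel pattern
      if (!is.null(pattern)) {
        cc <- contrast_classes(ev, pattern$contrast)
        csign <- rep(0, n_trials)
        csign[cc$subset] <- ifelse(as.integer(cc$classes) == 1, 1, -1)
        Y[, pattern$vox] <- Y[, pattern$vox] +
          outer(drop(S %*% csign), pattern$w)
      }
      # shared trial-level gain coupling
      if (!is.null(coupling)) {
        gain <- stats::rnorm(n_trials)
        if (!is.null(cfg$coupling_conditions)) {
          gain[!(ev$task %in% cfg$coupling_conditions)] <- 0
        }
        add <- drop(S %*% gain) * cfg$coupling_strength
        both <- union(coupling$seed, coupling$target)
        Y[, both] <- Y[, both] + add
      }
      volumes[[r]] <- array(t(Y), dim = c(dim3, n_vol))
      motion[[r]] <- .generate_motion(n_vol, cfg$motion_spike_frac)
    }
    ev_all <- do.call(rbind, events)
    physio <- generate_physio(ev_all, cfg, n_vol = n_vol)
    subjects[[s]] <- list(volumes = volumes, motion = motion,
                          events = ev_all, physio = physio)
  }
  structure(list(config = cfg, gray_mask = gray, roi_labels = roi_labels,
                 subjects = subjects, ground_truth = gt,
                 n_vol_per_run = n_vol),
            class = "speech_dataset")
}

# Pattern amplitude for a requested per-voxel Cohen's d of the single-trial
# feature: the feature is a fixed linear functional phi of the 9-lag epoch,
# so its noise SD is noise_sd * ||phi|| and its class-mean separation is
# 2 * amp * (phi . unit-trial-response epoch).
.pattern_amplitude <- function(cfg, template) {
  op <- .epoch_operator(cfg$tr_s)
  s_epoch <- template(op$lags_s)
  proj <- sum(op$phi * s_epoch)
  cfg$effect_size * cfg$noise_sd * sqrt(sum(op$phi^2)) / (2 * proj)
}

.generate_motion <- function(n_vol, spike_frac) {
  mp <- apply(matrix(stats::rnorm(n_vol * 6, sd = 0.01), n_vol, 6), 2, cumsum)
  n_spk <- floor(spike_frac * n_vol)
  if (n_spk > 0) {
    at <- sample(2:n_vol, n_spk)
    ax <- sample(1:3, n_spk, replace = TRUE)
    for (i in seq_len(n_spk)) {
      mp[at[i], ax[i]] <- mp[at[i], ax[i]] + stats::runif(1, 0.5, 0.8)
    }
  }
  colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  mp
}

#' Plant a multivoxel condition pattern into an existing dataset
#'
#' Adds to each trial's HRF-convolved response a fixed voxel-weight vector
#' whose sign follows the trial's class under `contrast`. The amplitude is
#' calibrated so the realized per-voxel Cohen's d of the downstream
#' single-trial feature equals `effect_size` up to Monte-Carlo error.
#'
#' @param dataset a `speech_dataset`.
#' @param roi_voxels integer linear voxel indices receiving the pattern
#'   (nonempty), or an ROI name from the dataset's label map.
#' @param contrast contrast name understood by [contrast_classes()].
#' @param effect_size per-voxel Cohen's d; 0 returns the dataset unchanged.
#' @param seed integer seed for the voxel-weight signs.
#' @param pattern_type `"multivoxel"` or `"uniform"` (see
#'   [experiment_config()]).
#' @return the modified dataset with `ground_truth$pattern_maps` extended.
#' @export
plant_pattern <- function(dataset, roi_voxels, contrast, effect_size,
                          seed = 1, pattern_type = "multivoxel") {
  stopifnot(inherits(dataset, "speech_dataset"))
  if (is.character(roi_voxels)) {
    k <- match(roi_voxels, attr(dataset$roi_labels, "roi_names"))
    if (is.na(k)) stop("unknown ROI name: ", roi_voxels)
    roi_voxels <- which(dataset$roi_labels == k)
  }
  if (length(roi_voxels) == 0) stop("roi_voxels must be nonempty")
  if (effect_size == 0) return(dataset)
  cfg <- dataset$config
  template <- .trial_template(cfg$tr_s, cfg$utterances_per_trial,
                              cfg$hrf_peak_delay)
  amp <- .pattern_amplitude(
    utils::modifyList(cfg, list(effect_size = effect_size)), template)
  w <- withr::with_seed(seed, {
    signs <- if (pattern_type == "uniform") rep(1, length(roi_voxels))
             else sample(c(-1, 1), length(roi_voxels), replace = TRUE)
    signs * amp
  })
  dim3 <- cfg$grid_shape
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    for (r in seq_len(cfg$n_runs)) {
      ev <- sub$events[sub$events$run == r, ]
      cc <- contrast_classes(ev, contrast)
      if (length(unique(cc$classes)) < 2) {
        stop("contrast has an empty class in run ", r)
      }
      csign <- rep(0, nrow(ev))
      csign[cc$subset] <- ifelse(as.integer(cc$classes) == 1, 1, -1)
      n_vol <- dim(sub$volumes[[r]])[4]
      S <- .trial_regressors(ev$onset_s, n_vol, cfg$tr_s, template)
      addition <- outer(drop(S %*% csign), w)   # n_vol x n_roi
      vol <- matrix(sub$volumes[[r]], prod(dim3), n_vol)
      vol[roi_voxels, ] <- vol[roi_voxels, ] + t(addition)
      dataset$subjects[[s]]$volumes[[r]] <- array(vol, c(dim3, n_vol))
    }
  }
  pm <- rep(0, prod(dim3))
  pm[roi_voxels] <- w
  dataset$ground_truth$pattern_maps[[contrast]] <- pm
  dataset$ground_truth$pattern_voxels <- roi_voxels
  dataset$ground_truth$effect_size <- effect_size
  dataset
}

#' Extract the concatenated time-by-voxel data matrix of one subject
#'
#' @param dataset a `speech_dataset`.
#' @param subject subject index.
#' @param mask logical 3D array selecting voxels (default: gray matter).
#' @return list: `Y` (time x voxels, runs concatenated), `runs` (run id per
#'   volume), `voxel_index` (linear grid indices of the columns), `coords`
#'   (voxel integer coordinates), `events`, `motion` (list), `tr_s`.
#' @export
dataset_matrix <- function(dataset, subject = 1, mask = dataset$gray_mask) {
  sub <- dataset$subjects[[subject]]
  idx <- which(mask)
  dim3 <- dataset$config$grid_shape
  Ys <- lapply(sub$volumes, function(v) {
    n_vol <- dim(v)[4]
    t(matrix(v, prod(dim3), n_vol)[idx, , drop = FALSE])
  })
  runs <- rep(seq_along(Ys), vapply(Ys, nrow, integer(1)))
  list(Y = do.call(rbind, Ys), runs = runs, voxel_index = idx,
       coords = .index_to_coord(idx, dim3), events = sub$events,
       motion = sub$motion, tr_s = dataset$config$tr_s)
}
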
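#' Configuration of the recursive feature elimination decoder
#'
#' Defaults follow the modeled procedure: 10 elimination iterations, 30%
#' of surviving voxels removed per iteration, 40 nested resampling splits
#' (class-stratified draws of 90% of the training trials with replacement),
#' weights averaged and smoothed every fourth split, a 3x3x3 box smoothing
#' kernel masked to the surviving voxels, a 5% margin-violation budget for
#' the linear classifier, and 100 label permutations for the chance level.
#'
#' @param n_iterations number of eliminations.
#' @param elim_fraction fraction of surviving voxels removed each iteration
#'   (count = `ceiling(n * elim_fraction)`).
#' @param n_nested_splits number of nested resampling splits; must equal
#'   `n_iterations * splits_per_elimination`.
#' @param nested_ratio resampling ratio (draws with replacement).
#' @param splits_per_elimination splits per weight-averaging window.
#' @param smooth_kernel box kernel edge in voxels (3 = 3x3x3).
#' @param slack_fraction allowed fraction of margin-violating training
#'   trials (the nu parameter of the nu-SVM).
#' @param n_permutations label permutations for the chance level.
#' @param rng_seed integer seed governing resampling and permutations.
#' @return list of class `rfe_config`.
#' @export
rfe_config <- function(n_iterations = 10, elim_fraction = 0.3,
                       n_nested_splits = 40, nested_ratio = 0.9,
                       splits_per_elimination = 4, smooth_kernel = 3,
                       slack_fraction = 0.05, n_permutations = 100,
                       rng_seed = 1) {
  stopifnot(elim_fraction >= 0, elim_fraction < 1,
            nested_ratio > 0, nested_ratio <= 1,
            n_iterations >= 1, splits_per_elimination >= 1)
  if (n_nested_splits != n_iterations * splits_per_elimination) {
    stop("n_nested_splits must equal n_iterations * splits_per_elimination")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 elim_fraction = elim_fraction,
                 n_nested_splits = as.integer(n_nested_splits),
                 nested_ratio = nested_ratio,
                 splits_per_elimination = as.integer(splits_per_elimination),
                 smooth_kernel = as.integer(smooth_kernel),
                 slack_fraction = slack_fraction,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed)),
            class = "rfe_config")
}

#' Leave-run-out cross-validation folds
#'
#' One fold per run: the run is the test set, all other runs train. Every
#' run must contain both classes.
#'
#' @param labels binary label vector.
#' @param runs run identifier per trial.
#' @return list of folds, each with `run`, `train`, `test` index vectors.
#' @export
leave_run_out_folds <- function(labels, runs) {
  .stop_if_not_binary(labels)
  run_ids <- sort(unique(runs))
  if (length(run_ids) < 2) stop("need at least 2 runs")
  for (r in run_ids) {
    if (length(unique(labels[runs == r])) < 2) {
      stop("run ", r, " does not contain both classes")
    }
  }
  lapply(run_ids, function(r) {
    list(run = r, train = which(runs != r), test = which(runs == r))
  })
}

#' Train a linear maximum-margin classifier
#'
#' Linear nu-SVM (libsvm via \pkg{e1071}): `nu = slack_fraction` bounds the
#' fraction of training trials allowed to violate the margin, the
#' margin-violation budget of the modeled procedure. Features are not
#' rescaled, so the signed weight vector lives in voxel space and is usable
#' for feature ranking.
#'
#' @param x trials x features matrix.
#' @param labels binary labels (>= 2 samples per class).
#' @param slack_fraction margin-violation budget in (0, 1).
#' @return list of class `linear_margin_fit`: `weights`, `bias`, `levels`
#'   (positive decision values predict `levels[1]`), `model`.
#' @export
train_linear_margin <- function(x, labels, slack_fraction = 0.05) {
  x <- as.matrix(x)
  u <- .stop_if_not_binary(labels)
  y <- factor(labels, levels = sort(as.character(u)))
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  cm <- colMeans(x)
  if (all(colSums(x * x) / nrow(x) - cm^2 <= 1e-24)) {
    stop("degenerate features: all columns are constant")
  }
  nu <- max(min(slack_fraction, 2 * min(table(y)) / length(y) - 1e-6), 1e-4)
  model <- e1071::svm(x, y, type = "nu-classification", kernel = "linear",
                      nu = nu, scale = FALSE, fitted = FALSE,
                      na.action = stats::na.pass)
  w <- drop(crossprod(model$coefs, model$SV))
  b <- -model$rho
  # libsvm orients decision values so positive predicts the class of the
  # first training example; model$labels records that internal order
  dec_levels <- model$levels[model$labels]
  # canonical orientation: positive weights point toward the first sorted
  # level, so flipping all labels flips the weight sign
  if (dec_levels[1] != levels(y)[1]) {
    w <- -w; b <- -b
    dec_levels <- rev(dec_levels)
  }
  structure(list(weights = w, bias = b, levels = dec_levels, model = model),
            class = "linear_margin_fit")
}

#' @export
predict.linear_margin_fit <- function(object, newdata, ...) {
  s <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  factor(ifelse(s > 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' Mask-restricted box smoothing of a voxel weight map
#'
#' Each voxel's value becomes the mean of the weights over its k x k x k
#' neighborhood intersected with the current surviving-voxel mask. An
#' isolated voxel keeps its own value.
#'
#' @param weights numeric vector over surviving voxels.
#' @param voxel_coords matrix of integer 3D coordinates, one row per
#'   surviving voxel (these coordinates ARE the mask).
#' @param kernel box edge length (odd, default 3).
#' @return smoothed weights, same length/order as `weights`.
#' @export
smooth_weight_map <- function(weights, voxel_coords, kernel = 3) {
  voxel_coords <- as.matrix(voxel_coords)
  n <- length(weights)
  if (nrow(voxel_coords) != n) stop("weights and coordinates differ in length")
  half <- (kernel - 1) %/% 2
  # hash coordinates into a compact lookup box with a guard margin
  mins <- c(min(voxel_coords[, 1]), min(voxel_coords[, 2]),
            min(voxel_coords[, 3])) - half - 1L
  cx <- voxel_coords[, 1] - mins[1]
  cy <- voxel_coords[, 2] - mins[2]
  cz <- voxel_coords[, 3] - mins[3]
  dims <- c(max(cx), max(cy), max(cz)) + half + 1L
  key <- cx + (cy - 1L) * dims[1] + (cz - 1L) * dims[1] * dims[2]
  lut <- rep(NA_integer_, prod(dims))
  lut[key] <- seq_len(n)
  acc <- rep(0, n)
  cnt <- rep(0L, n)
  for (dx in -half:half) for (dy in -half:half) for (dz in -half:half) {
    hit <- lut[key + dx + dy * dims[1] + dz * dims[1] * dims[2]]
    ok <- which(!is.na(hit))
    acc[ok] <- acc[ok] + weights[hit[ok]]
    cnt[ok] <- cnt[ok] + 1L
  }
  acc / cnt
}

#' Nested recursive feature elimination on a training set
#'
#' Loops over `n_nested_splits` class-stratified resamples (ratio
#' `nested_ratio`, drawn with replacement) of the training trials, training
#' the linear margin classifier on each. After every
#' `splits_per_elimination` splits the signed weights of that window are
#' averaged, box-smoothed within the surviving mask, and the voxels with
#' the smallest `ceiling(n * elim_fraction)` absolute smoothed weights are
#' removed (ties broken by voxel index for determinism). This repeats for
#' `n_iterations` eliminations; if elimination would empty the set the
#' current set is recorded and iteration stops early.
#'
#' @param x training trials x ROI voxels.
#' @param labels binary training labels.
#' @param coords integer 3D coordinates of the ROI voxels (rows of `x`'s
#'   columns).
#' @param config an [rfe_config()].
#' @return list: `survivors` (list of voxel-index vectors, one per
#'   iteration), `weight_maps` (list of smoothed window-average weights on
#'   the pre-elimination set), `n_iterations_done`.
#' @export
rfe_iterate <- function(x, labels, coords, config = rfe_config()) {
  x <- as.matrix(x)
  y <- factor(labels)
  n <- nrow(x)
  idx_by_class <- split(seq_len(n), y)
  active <- seq_len(ncol(x))
  survivors <- list()
  weight_maps <- list()
  wsum <- rep(0, ncol(x))
  for (split in seq_len(config$n_nested_splits)) {
    take <- unlist(lapply(idx_by_class, function(ii) {
      sample(ii, size = max(2, round(config$nested_ratio * length(ii))),
             replace = TRUE)
    }), use.names = FALSE)
    fit <- train_linear_margin(x[take, active, drop = FALSE], y[take],
                               config$slack_fraction)
    wsum[active] <- wsum[active] + fit$weights
    if (split %% config$splits_per_elimination == 0) {
      wavg <- wsum[active] / config$splits_per_elimination
      sm <- smooth_weight_map(wavg, coords[active, , drop = FALSE],
                              config$smooth_kernel)
      wm <- rep(NA_real_, ncol(x)); wm[active] <- sm
      weight_maps[[length(weight_maps) + 1]] <- wm
      k <- if (config$elim_fraction > 0) {
        as.integer(ceiling(config$elim_fraction * length(active)))
      } else 0L
      if (length(active) - k < 1) {
        # elimination impossible: record the current set and stop early
        survivors[[length(survivors) + 1]] <- active
        break
      }
      if (k > 0) {
        ord <- order(abs(sm), seq_along(active))
        active <- sort(active[-ord[seq_len(k)]])
      }
      survivors[[length(survivors) + 1]] <- active
      wsum <- rep(0, ncol(x))
    }
  }
  list(survivors = survivors, weight_maps = weight_maps,
       n_iterations_done = length(survivors))
}

#' ROI decoding with nested RFE and leave-run-out cross-validation
#'
#' For each leave-run-out fold, runs [rfe_iterate()] on the training runs;
#' at every iteration's surviving voxel set the classifier is retrained on
#' the full training data (the nested splits serve only for ranking) and
#' scored on the held-out run. Per-iteration cross-validated accuracy is
#' the mean over folds, and the final accuracy is the maximum over
#' iterations — the max-statistic that inflates naive chance and motivates
#' the permutation-derived chance level of [permutation_null()].
#'
#' @param beta_values trials x voxels beta-series matrix.
#' @param labels binary labels per trial.
#' @param runs run id per trial.
#' @param roi_cols column indices of the ROI voxels.
#' @param coords integer 3D coordinates of ALL columns of `beta_values`.
#' @param config an [rfe_config()].
#' @return list of class `rfe_result`: `accuracy` (folds x iterations,
#'   NA-padded on early stop), `iteration_accuracy` (mean over folds),
#'   `final_accuracy` (max over iterations), `survivors` (per fold),
#'   `weight_maps` (per fold), `config`.
#' @export
decode_roi <- function(beta_values, labels, runs, roi_cols, coords,
                       config = rfe_config()) {
  if (length(roi_cols) == 0) stop("ROI is empty")
  x <- as.matrix(beta_values)[, roi_cols, drop = FALSE]
  rcoords <- coords[roi_cols, , drop = FALSE]
  y <- factor(labels)
  folds <- leave_run_out_folds(y, runs)
  withr::with_seed(config$rng_seed, {
    acc <- matrix(NA_real_, length(folds), config$n_iterations)
    surv_all <- list(); wm_all <- list()
    for (fi in seq_along(folds)) {
      f <- folds[[fi]]
      rfe <- rfe_iterate(x[f$train, , drop = FALSE], y[f$train], rcoords,
                         config)
      for (it in seq_len(rfe$n_iterations_done)) {
        set <- rfe$survivors[[it]]
        fit <- train_linear_margin(x[f$train, set, drop = FALSE],
                                   y[f$train], config$slack_fraction)
        pred <- predict(fit, x[f$test, set, drop = FALSE])
        acc[fi, it] <- mean(pred == y[f$test])
      }
      surv_all[[fi]] <- rfe$survivors
      wm_all[[fi]] <- rfe$weight_maps
    }
    iter_acc <- colMeans(acc, na.rm = TRUE)
    iter_acc[is.nan(iter_acc)] <- NA_real_
    structure(list(accuracy = acc, iteration_accuracy = iter_acc,
                   final_accuracy = max(iter_acc, na.rm = TRUE),
                   survivors = surv_all, weight_maps = wm_all,
                   config = config),
              class = "rfe_result")
  })
}

#' Permutation-derived chance level for ROI decoding
#'
#' Repeats the complete RFE decoding procedure under label permutations
#' (shuffled within run, preserving leave-run-out exchangeability). The
#' chance level is the mean of the permuted final accuracies; because the
#' final accuracy is a maximum over iterations, this chance level exceeds
#' the theoretical 0.5.
#'
#' @inheritParams decode_roi
#' @return list of class `permutation_null`: `accuracies` (one final
#'   accuracy per permutation), `chance_level` (their mean).
#' @export
permutation_null <- function(beta_values, labels, runs, roi_cols, coords,
                             config = rfe_config()) {
  accs <- vapply(seq_len(config$n_permutations), function(b) {
    labs_b <- permute_labels(labels, runs, seed = config$rng_seed + 104729L + b)
    cfg_b <- config
    cfg_b$rng_seed <- config$rng_seed + 7919L * b
    decode_roi(beta_values, labs_b, runs, roi_cols, coords,
               cfg_b)$final_accuracy
  }, numeric(1))
  structure(list(accuracies = accs, chance_level = mean(accs)),
            class = "permutation_null")
}

#' Group statistics of ROI decoding accuracies against chance
#'
#' Per ROI, a paired two-tailed t-test of subject accuracies against their
#' permutation chance levels, with Benjamini-Hochberg FDR across ROIs.
#'
#' @param roi_table data frame with columns `roi`, `subject`,
#'   `final_accuracy`, `chance` (>= 3 subjects, identical subject sets per
#'   ROI).
#' @param q FDR level (default 0.05).
#' @return data frame: `roi`, `mean_accuracy`, `mean_chance`, `t`, `p`,
#'   `q_value`, `significant`.
#' @export
group_roi_stats <- function(roi_table, q = 0.05) {
  rois <- unique(roi_table$roi)
  subj_sets <- lapply(rois, function(r)
    sort(roi_table$subject[roi_table$roi == r]))
  if (length(unique(vapply(subj_sets, paste, character(1),
                           collapse = ","))) != 1) {
    stop("subject sets differ across ROIs")
  }
  if (length(subj_sets[[1]]) < 3) stop("need at least 3 subjects")
  rows <- lapply(rois, function(r) {
    d <- roi_table[roi_table$roi == r, ]
    d <- d[order(d$subject), ]
    tt <- paired_t(d$final_accuracy, d$chance)
    data.frame(roi = r, mean_accuracy = mean(d$final_accuracy),
               mean_chance = mean(d$chance), t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, q = q)
  out$q_value <- fdr$q_values
  out$significant <- fdr$rejected
  out
}
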
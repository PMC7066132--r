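#' Flag volumes with excessive motion
#'
#' A volume is censored when the Euclidean norm of the backward difference
#' of its 6 realignment parameters strictly exceeds 0.4 mm. The first
#' volume of a run has no predecessor and is never flagged; a derivative
#' norm of exactly 0.4 is not flagged.
#'
#' @param motion n_vol x 6 matrix of realignment parameters for one run.
#' @param threshold_mm censoring threshold (default 0.4).
#' @return logical vector of length n_vol.
#' @export
censor_frames <- function(motion, threshold_mm = 0.4) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  if (any(!is.finite(motion))) stop("non-finite motion values")
  d <- diff(motion)
  c(FALSE, sqrt(rowSums(d^2)) > threshold_mm)
}

#' Build the first-level design matrix
#'
#' Regressors of interest: one per task x item condition type, a 6 s boxcar
#' per trial (three utterances separated by one TR) convolved with the
#' double-gamma HRF on the TR grid. Nuisance regressors: Legendre
#' polynomials of order 0..`drift_order` per run (block diagonal), the 6
#' motion parameters, and one indicator column per censored volume (the
#' censoring style that keeps the residual grid aligned to the TR grid).
#'
#' @param trial_table data frame (onset_s, run, task, item).
#' @param motion list with one n_vol x 6 matrix per run (required; a
#'   missing table is an error, never a silent omission).
#' @param n_vol_per_run volumes per run (scalar or vector over runs).
#' @param tr_s repetition time in seconds.
#' @param drift_order maximum Legendre order (default 5).
#' @param censor optional logical vector over concatenated volumes; when
#'   NULL it is computed from `motion` via [censor_frames()].
#' @param include_interest include the 10 condition regressors (set FALSE
#'   for the nuisance-only model whose residuals feed single-trial feature
#'   estimation).
#' @param duration_s boxcar duration (default 6).
#' @return list of class `design_matrix`: `X` (named columns), `interest`
#'   (column indices of condition regressors), `runs` (run id per row),
#'   `censored` (logical per row), `tr_s`, `conditions`.
#' @export
build_design <- function(trial_table, motion, n_vol_per_run, tr_s,
                         drift_order = 5, censor = NULL,
                         include_interest = TRUE, duration_s = 6) {
  if (is.null(motion)) stop("motion parameters are required")
  run_ids <- sort(unique(trial_table$run))
  n_runs <- length(run_ids)
  if (length(n_vol_per_run) == 1) n_vol_per_run <- rep(n_vol_per_run, n_runs)
  if (length(motion) != n_runs) stop("motion must have one table per run")
  for (r in seq_len(n_runs)) {
    if (nrow(as.matrix(motion[[r]])) != n_vol_per_run[r]) {
      stop("motion rows must equal the volume count in run ", run_ids[r])
    }
  }
  n_total <- sum(n_vol_per_run)
  runs_row <- rep(run_ids, n_vol_per_run)
  offsets <- c(0, cumsum(n_vol_per_run))

  conditions <- as.vector(t(outer(.tasks, .items, paste, sep = "_")))
  X_int <- NULL
  if (include_interest) {
    X_int <- matrix(0, n_total, length(conditions),
                    dimnames = list(NULL, paste0("cond_", conditions)))
    for (ci in seq_along(conditions)) {
      tk <- sub("_.*", "", conditions[ci])
      it <- sub(".*_", "", conditions[ci])
      for (r in seq_len(n_runs)) {
        ev <- trial_table[trial_table$run == run_ids[r] &
                            trial_table$task == tk & trial_table$item == it, ]
        if (nrow(ev) == 0) next
        if (any(ev$onset_s > n_vol_per_run[r] * tr_s)) {
          stop("trial onset beyond run end in run ", run_ids[r])
        }
        rows <- offsets[r] + seq_len(n_vol_per_run[r])
        X_int[rows, ci] <- X_int[rows, ci] +
          hrf_regressor(ev$onset_s, n_vol_per_run[r], tr_s, duration_s)
      }
    }
  }

  X_drift <- matrix(0, n_total, (drift_order + 1) * n_runs)
  dn <- character(0)
  for (r in seq_len(n_runs)) {
    L <- legendre_basis(n_vol_per_run[r], drift_order)
    cols <- (r - 1) * (drift_order + 1) + seq_len(drift_order + 1)
    X_drift[offsets[r] + seq_len(n_vol_per_run[r]), cols] <- L
    dn <- c(dn, paste0("legendre_r", run_ids[r], "_p", 0:drift_order))
  }
  colnames(X_drift) <- dn

  X_mot <- do.call(rbind, lapply(motion, as.matrix))
  colnames(X_mot) <- paste0("motion", 1:6)

  if (is.null(censor)) {
    censor <- unlist(lapply(motion, censor_frames))
  }
  stopifnot(length(censor) == n_total)
  X_cens <- NULL
  if (any(censor)) {
    w <- which(censor)
    X_cens <- matrix(0, n_total, length(w),
                     dimnames = list(NULL, paste0("censor_", w)))
    X_cens[cbind(w, seq_along(w))] <- 1
  }
  X <- cbind(X_int, X_drift, X_mot, X_cens)
  structure(list(X = X,
                 interest = if (include_interest) seq_along(conditions)
                            else integer(0),
                 runs = runs_row, censored = censor, tr_s = tr_s,
                 conditions = conditions),
            class = "design_matrix")
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares per voxel. The design must be full column rank;
#' rank deficiency is an error naming the collinear columns. Residuals are
#' the data minus all fitted columns (interest and nuisance alike), hence
#' orthogonal to every design column.
#'
#' @param Y time x voxels data matrix (runs concatenated).
#' @param design a `design_matrix`.
#' @return list of class `glm_fit`: `beta` (named coefficients x voxels),
#'   `residuals` (time x voxels), `design`.
#' @export
fit_glm <- function(Y, design) {
  X <- design$X
  if (nrow(X) != nrow(Y)) stop("design rows must match data rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  rownames(beta) <- colnames(X)
  res <- qr.resid(qrX, Y)
  structure(list(beta = beta, residuals = res, design = design),
            class = "glm_fit")
}

# fixed epoch-to-scalar operator: 9 lags (0..16 s at TR 2), demean +
# linear detrend projection, then mean over the HRF peak window
# (lags 2..5 TRs = 4..10 s). phi is the combined linear functional.
.epoch_operator <- function(tr_s, epoch_s = 16, peak_lo_s = 4, peak_hi_s = 10) {
  lags <- 0:as.integer(epoch_s / tr_s)
  Q <- cbind(1, lags)
  P <- diag(length(lags)) - Q %*% solve(crossprod(Q), t(Q))
  u <- as.numeric(lags * tr_s >= peak_lo_s & lags * tr_s <= peak_hi_s)
  u <- u / sum(u)
  list(phi = drop(P %*% u), lags = lags, lags_s = lags * tr_s, P = P, u = u)
}

#' Single-trial feature estimation (beta series)
#'
#' For every trial and voxel, takes the 9-point epoch on the TR grid
#' (lags 0, 2, ..., 16 s from trial onset) from the nuisance-regressed
#' residuals, removes its mean and best-fit line, and summarizes it to one
#' scalar: the mean over the HRF peak window (lags 4-10 s). Trials whose
#' epoch contains more than 1/3 censored volumes, or extends past the run
#' end, are dropped and reported. With `feature = "vector"` the full
#' detrended 9-lag epoch is returned instead of the scalar.
#'
#' @param residuals time x voxels residual matrix from the nuisance-only
#'   GLM (runs concatenated).
#' @param trial_table trial table (onset_s, run, task, item).
#' @param runs run id per residual row.
#' @param tr_s repetition time in seconds.
#' @param censored optional logical per row (for the censoring drop rule).
#' @param feature `"scalar"` (default) or `"vector"`.
#' @return list of class `beta_series`: `values` (kept trials x voxels, or
#'   trials x (9 * voxels) for vector features), `trials` (trial table rows
#'   kept), `kept` (logical over input trials), `dropped` (indices),
#'   `tr_s`, `feature`.
#' @export
extract_trial_features <- function(residuals, trial_table, runs, tr_s,
                                   censored = NULL,
                                   feature = c("scalar", "vector")) {
  feature <- match.arg(feature)
  op <- .epoch_operator(tr_s)
  n_lag <- length(op$lags)
  run_ids <- sort(unique(runs))
  offsets <- c(0, cumsum(vapply(run_ids, function(r) sum(runs == r),
                                integer(1))))
  n_trials <- nrow(trial_table)
  kept <- rep(TRUE, n_trials)
  rows_list <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    r <- match(trial_table$run[k], run_ids)
    i0 <- offsets[r] + round(trial_table$onset_s[k] / tr_s) + 1
    idx <- i0 + op$lags
    if (max(idx) > offsets[r + 1]) {
      warning("trial ", k, " epoch exceeds run end; dropped")
      kept[k] <- FALSE
      next
    }
    if (!is.null(censored) && sum(censored[idx]) / n_lag > 1 / 3) {
      kept[k] <- FALSE
      next
    }
    rows_list[[k]] <- idx
  }
  keep_idx <- which(kept)
  if (feature == "scalar") {
    values <- matrix(NA_real_, length(keep_idx), ncol(residuals))
    for (j in seq_along(keep_idx)) {
      values[j, ] <- drop(op$phi %*% residuals[rows_list[[keep_idx[j]]], ,
                                               drop = FALSE])
    }
  } else {
    values <- array(NA_real_, c(length(keep_idx), n_lag, ncol(residuals)))
    for (j in seq_along(keep_idx)) {
      values[j, , ] <- op$P %*% residuals[rows_list[[keep_idx[j]]], ,
                                          drop = FALSE]
    }
  }
  structure(list(values = values, trials = trial_table[keep_idx, , drop = FALSE],
                 kept = kept, dropped = which(!kept), tr_s = tr_s,
                 feature = feature),
            class = "beta_series")
}

#' Group-level univariate contrast map
#'
#' Per-voxel one-sample two-tailed t-test across subjects of the contrast
#' of condition betas (equivalently a paired t across the contrasted
#' conditions). The contrast weights must sum to zero. P-values are
#' uncorrected.
#'
#' @param beta_list list with one conditions x voxels beta matrix per
#'   subject (row names are condition names; all on a common grid).
#' @param contrast named numeric vector of weights over conditions, summing
#'   to zero.
#' @return list: `t_map`, `p_map` (vectors over voxels), `n_subjects`,
#'   `contrast_values` (subjects x voxels).
#' @export
group_contrast <- function(beta_list, contrast) {
  if (length(beta_list) < 3) stop("need at least 3 subjects")
  if (abs(sum(contrast)) > 1e-12) stop("contrast weights must sum to zero")
  p <- ncol(beta_list[[1]])
  vals <- t(vapply(beta_list, function(b) {
    if (ncol(b) != p) stop("subjects are not on a common grid")
    miss <- setdiff(names(contrast), rownames(b))
    if (length(miss)) stop("conditions missing from betas: ",
                           paste(miss, collapse = ", "))
    drop(contrast %*% b[names(contrast), , drop = FALSE])
  }, numeric(p)))
  res <- .col_one_sample_t(vals)
  list(t_map = res$t, p_map = res$p, n_subjects = length(beta_list),
       contrast_values = vals)
}
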
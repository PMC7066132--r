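#' Localize a subject-level seed region from a thresholded contrast map
#'
#' Thresholds the subject's contrast t-map at uncorrected p < `threshold_p`
#' (positive tail) inside an anatomical search mask and returns the largest
#' 26-connected suprathreshold cluster. Subjects without any suprathreshold
#' voxel are flagged and should be excluded from seed analyses.
#'
#' @param t_map 3D array of subject-level t statistics.
#' @param anatomical_mask logical 3D array, same grid.
#' @param threshold_p uncorrected p threshold (default 0.05, two-tailed
#'   quantile, positive direction).
#' @param df degrees of freedom of the t-map.
#' @return list of class `seed_region`: `voxels` (linear indices),
#'   `coords`, `n_voxels`, `peak` (coordinate of the maximal t),
#'   `empty` (TRUE when no suprathreshold voxel exists).
#' @export
localize_seed <- function(t_map, anatomical_mask, threshold_p = 0.05, df) {
  if (!all(dim(t_map) == dim(anatomical_mask))) {
    stop("t-map and mask are not on the same grid")
  }
  thr <- if (threshold_p >= 1) -Inf else stats::qt(1 - threshold_p / 2, df)
  supra <- which(anatomical_mask & t_map > thr)
  if (length(supra) == 0) {
    return(structure(list(voxels = integer(0), coords = NULL, n_voxels = 0L,
                          peak = NULL, empty = TRUE), class = "seed_region"))
  }
  dim3 <- dim(t_map)
  coords <- .index_to_coord(supra, dim3)
  comp <- .label_components_26(coords)
  sizes <- tabulate(comp)
  best <- which.max(sizes)      # ties: first (lowest label = first seen)
  keep <- comp == best
  vox <- supra[keep]
  pk <- coords[keep, , drop = FALSE][which.max(t_map[vox]), ]
  structure(list(voxels = vox, coords = coords[keep, , drop = FALSE],
                 n_voxels = sum(keep), peak = pk, empty = FALSE),
            class = "seed_region")
}

# label 26-connected components of a voxel coordinate set
.label_components_26 <- function(coords) {
  n <- nrow(coords)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    frontier <- s
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      cand <- which(comp == 0L)
      if (!length(cand)) break
      reach <- vapply(cand, function(i) {
        any(abs(fc[, 1] - coords[i, 1]) <= 1 &
              abs(fc[, 2] - coords[i, 2]) <= 1 &
              abs(fc[, 3] - coords[i, 3]) <= 1)
      }, logical(1))
      frontier <- cand[reach]
      comp[frontier] <- cur
    }
  }
  comp
}

#' Seed-based beta-series correlation map
#'
#' The seed series is the mean beta series over the seed voxels (within
#' the requested trial subset); Pearson correlations against every voxel's
#' beta series are Fisher-transformed (z = atanh(r), with |r| clipped at
#' 1 - 1e-7). Zero-variance voxels yield NA. Computing within a condition
#' subset uses only that condition's trials, making the map immune to
#' signal modulations across conditions.
#'
#' @param beta_values trials x voxels beta-series matrix.
#' @param seed_cols column indices of the seed voxels (or a `seed_region`
#'   plus `voxel_index` mapping via `cols_of_seed()`).
#' @param trial_subset optional integer subset of trials (>= 10 after
#'   subsetting).
#' @return list of class `connectivity_map`: `r`, `z` (vectors over
#'   voxels), `n_trials`, `seed_cols`.
#' @export
seed_correlation <- function(beta_values, seed_cols, trial_subset = NULL) {
  beta_values <- as.matrix(beta_values)
  if (length(seed_cols) == 0) stop("seed region is empty")
  if (!is.null(trial_subset)) {
    beta_values <- beta_values[trial_subset, , drop = FALSE]
  }
  if (nrow(beta_values) < 10) stop("need at least 10 trials")
  seed_series <- rowMeans(beta_values[, seed_cols, drop = FALSE])
  sds <- apply(beta_values, 2, stats::sd)
  r <- rep(NA_real_, ncol(beta_values))
  ok <- sds > 0 & stats::sd(seed_series) > 0
  if (any(ok)) {
    r[ok] <- drop(stats::cor(seed_series, beta_values[, ok, drop = FALSE]))
  }
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  structure(list(r = r, z = z, n_trials = nrow(beta_values),
                 seed_cols = seed_cols),
            class = "connectivity_map")
}

#' Group-level seed connectivity
#'
#' Per-voxel one-sample two-sided t-test of subject Fisher-z maps against
#' zero (the null of no correlation).
#'
#' @param z_maps subjects x voxels matrix of Fisher-z values.
#' @return list: `t_map`, `p_map`, `mean_z`, `n_subjects`.
#' @export
group_connectivity <- function(z_maps) {
  z_maps <- as.matrix(z_maps)
  if (nrow(z_maps) < 3) stop("need at least 3 subjects")
  res <- .col_one_sample_t(z_maps)
  list(t_map = res$t, p_map = res$p, mean_z = res$mean,
       n_subjects = nrow(z_maps))
}

#' Condition contrast of seed connectivity
#'
#' Per-voxel paired two-sided t-test of z_A - z_B across subjects, probing
#' condition-specific (articulatory- or phonatory-specific) connectivity.
#'
#' @param z_maps_a,z_maps_b subjects x voxels Fisher-z matrices for the two
#'   conditions, same subjects in the same order.
#' @return list: `t_map`, `p_map`, `mean_diff`, `n_subjects`.
#' @export
contrast_connectivity <- function(z_maps_a, z_maps_b) {
  z_maps_a <- as.matrix(z_maps_a); z_maps_b <- as.matrix(z_maps_b)
  if (!all(dim(z_maps_a) == dim(z_maps_b))) {
    stop("condition z-maps must come from the same subjects")
  }
  if (!is.null(rownames(z_maps_a)) && !is.null(rownames(z_maps_b)) &&
      !identical(rownames(z_maps_a), rownames(z_maps_b))) {
    stop("subject sets differ between conditions")
  }
  res <- .col_one_sample_t(z_maps_a - z_maps_b)
  list(t_map = res$t, p_map = res$p, mean_diff = res$mean,
       n_subjects = nrow(z_maps_a))
}

#' Map seed-region voxels to beta-matrix columns
#'
#' @param seed a `seed_region`.
#' @param voxel_index linear grid indices of the beta-matrix columns.
#' @return integer column indices (voxels outside the matrix are dropped).
#' @export
cols_of_seed <- function(seed, voxel_index) {
  m <- match(seed$voxels, voxel_index)
  m[!is.na(m)]
}
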
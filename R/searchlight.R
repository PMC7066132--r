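#' Searchlight sphere offsets
#'
#' All integer voxel offsets within the sphere radius. The millimetre
#' radius is converted to voxel units as `floor(radius_mm / voxel_mm)` —
#' at the 7 mm / 2 mm settings the sphere spans 3 voxels in every direction
#' plus its centroid, 123 voxels in all — and membership uses an inclusive
#' Euclidean bound in voxel units.
#'
#' @param radius_mm sphere radius in millimetres (>= `voxel_mm`).
#' @param voxel_mm isotropic voxel size in millimetres.
#' @return list of class `sphere_spec`: `offsets` (n x 3 integer matrix,
#'   contains (0,0,0), symmetric under sign flips), `radius_mm`,
#'   `voxel_mm`, `radius_vox`.
#' @export
build_sphere <- function(radius_mm = 7, voxel_mm = 2) {
  if (radius_mm < voxel_mm) stop("radius_mm must be at least voxel_mm")
  r <- floor(radius_mm / voxel_mm)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  keep <- rowSums(g^2) <= r^2
  structure(list(offsets = g[keep, , drop = FALSE], radius_mm = radius_mm,
                 voxel_mm = voxel_mm, radius_vox = r),
            class = "sphere_spec")
}

#' Keep only the sphere voxels contiguous with the centroid
#'
#' Computes 26-connectivity connected components within the gray-masked
#' sphere and retains only the component containing the centroid, removing
#' voxels from topographically distant tissue that merely falls inside the
#' sphere volumetrically. Diagonal-only contact counts as connected.
#'
#' @param voxel_coords n x 3 integer coordinates of the masked sphere.
#' @param centroid length-3 integer coordinate of the sphere center; must
#'   be one of the rows.
#' @return logical vector over rows: TRUE for retained voxels.
#' @export
contiguity_filter <- function(voxel_coords, centroid) {
  voxel_coords <- as.matrix(voxel_coords)
  n <- nrow(voxel_coords)
  start <- which(voxel_coords[, 1] == centroid[1] &
                   voxel_coords[, 2] == centroid[2] &
                   voxel_coords[, 3] == centroid[3])
  if (length(start) == 0) stop("centroid is not inside the masked sphere")
  in_comp <- rep(FALSE, n)
  in_comp[start[1]] <- TRUE
  frontier <- start[1]
  while (length(frontier) > 0) {
    fc <- voxel_coords[frontier, , drop = FALSE]
    # Chebyshev distance <= 1 to any frontier voxel = 26-neighborhood
    cand <- which(!in_comp)
    if (length(cand) == 0) break
    reach <- vapply(cand, function(i) {
      any(abs(fc[, 1] - voxel_coords[i, 1]) <= 1 &
            abs(fc[, 2] - voxel_coords[i, 2]) <= 1 &
            abs(fc[, 3] - voxel_coords[i, 3]) <= 1)
    }, logical(1))
    frontier <- cand[reach]
    in_comp[frontier] <- TRUE
  }
  in_comp
}

# train a shrinkage-regularized linear discriminant: pooled covariance
# shrunk toward a scaled identity with a Ledoit-Wolf-style intensity, so
# spheres with more voxels than trials never produce a singular system.
.lda_train <- function(x, y) {
  lev <- levels(y)
  x1 <- x[y == lev[1], , drop = FALSE]
  x2 <- x[y == lev[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  C <- rbind(sweep(x1, 2, m1), sweep(x2, 2, m2))
  n <- nrow(C); p <- ncol(C)
  S <- crossprod(C) / max(n - 2, 1)
  mu <- mean(diag(S))
  if (mu == 0) {
    w <- m1 - m2
  } else {
    d2 <- sum((S - diag(mu, p))^2) / p
    if (d2 == 0) {
      w <- (m1 - m2) / mu
    } else {
      sq <- rowSums(C^2)
      b2bar <- (sum(sq^2) - 2 * max(n - 2, 1) * sum(S^2) + n * sum(S^2)) /
        (n^2 * p)
      rho <- min(1, max(0, b2bar / d2))
      S_sh <- (1 - rho) * S + diag(rho * mu, p)
      w <- solve(S_sh, m1 - m2)
    }
  }
  list(w = w, threshold = sum(w * (m1 + m2)) / 2, levels = lev)
}

.lda_predict <- function(fit, x) {
  s <- drop(as.matrix(x) %*% fit$w) - fit$threshold
  ifelse(s > 0, fit$levels[1], fit$levels[2])
}

#' Cross-validated linear discriminant accuracy
#'
#' Pooled-covariance linear discriminant with Ledoit-Wolf-style shrinkage
#' regularization toward a scaled identity (required because searchlight
#' spheres can hold more voxels than trials); mean held-out accuracy over
#' the supplied folds.
#'
#' @param x trials x features matrix.
#' @param labels binary labels.
#' @param folds folds as from [leave_run_out_folds()].
#' @return mean held-out accuracy in \[0, 1\].
#' @export
lda_accuracy <- function(x, labels, folds) {
  x <- as.matrix(x)
  y <- factor(labels)
  accs <- vapply(folds, function(f) {
    fit <- .lda_train(x[f$train, , drop = FALSE], y[f$train])
    mean(.lda_predict(fit, x[f$test, , drop = FALSE]) ==
           as.character(y[f$test]))
  }, numeric(1))
  mean(accs)
}

#' Volumetric searchlight decoding over a gray-matter mask
#'
#' For every centroid voxel: select the sphere, intersect with the gray
#' mask, apply the centroid-contiguity filter, and compute leave-run-out
#' linear-discriminant accuracy. Permutation p-values come from within-run
#' label shuffles (shared across centroids), and Benjamini-Hochberg FDR is
#' applied across centroids. Edge spheres are truncated by the mask, never
#' padded; spheres with fewer than 2 voxels are skipped with a flag.
#'
#' @param beta_values trials x voxels matrix (columns = gray-mask voxels).
#' @param voxel_index linear grid indices of the columns.
#' @param gray_mask logical 3D array.
#' @param labels binary labels per trial.
#' @param runs run id per trial.
#' @param sphere a `sphere_spec` from [build_sphere()].
#' @param centroids optional vector of linear grid indices to visit
#'   (default: every gray-mask voxel).
#' @param n_permutations within-run label permutations (0 disables p-values).
#' @param q FDR level across centroids.
#' @param seed RNG seed for the permutations.
#' @return data frame of class `searchlight_map`: `voxel` (linear index),
#'   `x`, `y`, `z`, `n_voxels` (sphere size after filtering), `accuracy`,
#'   `p`, `q_value`, `significant`, `skipped`.
#' @export
run_searchlight <- function(beta_values, voxel_index, gray_mask, labels,
                            runs, sphere = build_sphere(),
                            centroids = NULL, n_permutations = 100,
                            q = 0.05, seed = 1) {
  beta_values <- as.matrix(beta_values)
  dim3 <- dim(gray_mask)
  y <- factor(labels)
  folds <- leave_run_out_folds(y, runs)
  col_of <- rep(NA_integer_, prod(dim3))
  col_of[voxel_index] <- seq_along(voxel_index)
  if (is.null(centroids)) centroids <- voxel_index
  perm_labels <- if (n_permutations > 0) {
    lapply(seq_len(n_permutations), function(b) {
      permute_labels(y, runs, seed = seed + b)
    })
  } else list()
  cents <- .index_to_coord(centroids, dim3)
  n_c <- length(centroids)
  acc <- rep(NA_real_, n_c); nv <- rep(NA_integer_, n_c)
  pv <- rep(NA_real_, n_c); skip <- rep(FALSE, n_c)
  for (i in seq_len(n_c)) {
    cc <- cents[i, ]
    if (is.na(col_of[centroids[i]]) || !gray_mask[cc[1], cc[2], cc[3]]) {
      skip[i] <- TRUE
      next
    }
    vox <- sweep(sphere$offsets, 2, -cc)
    ok <- vox[, 1] >= 1 & vox[, 1] <= dim3[1] &
      vox[, 2] >= 1 & vox[, 2] <= dim3[2] &
      vox[, 3] >= 1 & vox[, 3] <= dim3[3]
    vox <- vox[ok, , drop = FALSE]
    cols <- col_of[.coord_to_index(vox, dim3)]
    inmask <- !is.na(cols)
    vox <- vox[inmask, , drop = FALSE]
    cols <- cols[inmask]
    keep <- contiguity_filter(vox, cc)
    cols <- cols[keep]
    if (length(cols) < 2) {
      skip[i] <- TRUE
      next
    }
    xs <- beta_values[, cols, drop = FALSE]
    acc[i] <- lda_accuracy(xs, y, folds)
    nv[i] <- length(cols)
    if (n_permutations > 0) {
      pacc <- vapply(perm_labels, function(pl) lda_accuracy(xs, pl, folds),
                     numeric(1))
      pv[i] <- (1 + sum(pacc >= acc[i])) / (n_permutations + 1)
    }
  }
  out <- data.frame(voxel = centroids, x = cents[, 1], y = cents[, 2],
                    z = cents[, 3], n_voxels = nv, accuracy = acc, p = pv,
                    q_value = NA_real_, significant = NA, skipped = skip)
  valid <- which(!is.na(pv))
  if (length(valid)) {
    fdr <- fdr_bh(pv[valid], q = q)
    out$q_value[valid] <- fdr$q_values
    out$significant[valid] <- fdr$rejected
  }
  class(out) <- c("searchlight_map", "data.frame")
  out
}

#' Group-level searchlight statistics
#'
#' Per centroid, a paired two-tailed t-test of subject accuracies against
#' subject chance levels (a scalar 0.5 or per-subject permutation means),
#' with Benjamini-Hochberg FDR across centroids.
#'
#' @param accuracy_mat subjects x centroids accuracy matrix.
#' @param chance scalar chance level, or a matrix matching `accuracy_mat`.
#' @param q FDR level.
#' @return data frame: `t`, `p`, `q_value`, `significant` per centroid.
#' @export
group_searchlight <- function(accuracy_mat, chance = 0.5, q = 0.05) {
  accuracy_mat <- as.matrix(accuracy_mat)
  if (length(chance) == 1) {
    chance <- matrix(chance, nrow(accuracy_mat), ncol(accuracy_mat))
  }
  res <- .col_one_sample_t(accuracy_mat - chance)
  fdr <- fdr_bh(res$p, q = q)
  data.frame(t = res$t, p = res$p, q_value = fdr$q_values,
             significant = fdr$rejected)
}
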
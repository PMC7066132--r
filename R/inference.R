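#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR: reject all hypotheses with p <= p_(k*) where
#' k* = max\{k : p_(k) <= k q / m\}. Implemented through
#' [stats::p.adjust()] with method "BH"; the rejected set equals the
#' step-up definition exactly.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q target false discovery rate (default 0.05).
#' @return list of class `fdr_result`: `p_values`, `q`, `rejected`
#'   (logical), `q_values` (BH-adjusted p), `n_rejected`,
#'   `largest_rejected_rank` (k*, 0 if none).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(structure(list(p_values = numeric(0), q = q,
                          rejected = logical(0), q_values = numeric(0),
                          n_rejected = 0L, largest_rejected_rank = 0L),
                     class = "fdr_result"))
  }
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be finite and within [0, 1]")
  }
  qv <- stats::p.adjust(p_values, method = "BH")
  rejected <- qv <= q
  structure(list(p_values = p_values, q = q, rejected = rejected,
                 q_values = qv, n_rejected = sum(rejected),
                 largest_rejected_rank = sum(rejected)),
            class = "fdr_result")
}

#' Paired two-tailed t-test
#'
#' Classical paired t with n - 1 degrees of freedom. Zero variance of the
#' paired differences with a nonzero mean is flagged (`infinite = TRUE`)
#' rather than producing NaN.
#'
#' @param x,y matched numeric samples of equal length (n >= 2).
#' @return list: `t`, `p` (two-tailed), `df`, `mean_diff`, `infinite`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("samples must have equal length")
  if (length(x) < 2) stop("need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0,
                df = length(d) - 1, mean_diff = m, infinite = m != 0))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), infinite = FALSE)
}

#' Shuffle condition labels within runs
#'
#' Uniform permutation of the label vector within each run, preserving
#' per-run class counts. This respects leave-run-out cross-validation
#' structure: run-level exchangeability is maintained under the null.
#'
#' @param labels label vector (any type).
#' @param runs run identifier per trial, same length as `labels`.
#' @param seed optional integer; if given, the shuffle is reproducible and
#'   the caller's RNG state is untouched.
#' @return permuted label vector.
#' @export
permute_labels <- function(labels, runs, seed = NULL) {
  if (length(labels) != length(runs)) stop("labels and runs lengths differ")
  shuffle <- function() {
    out <- labels
    for (r in unique(runs)) {
      i <- which(runs == r)
      if (length(i) > 1) out[i] <- labels[sample(i)]
    }
    out
  }
  if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
}
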
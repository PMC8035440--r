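#' Per-subject mean map values over a cluster
#'
#' @param maps_a,maps_b lists of smoothed [fcd_map()]s (or 3D arrays), one
#'   per subject in each group.
#' @param voxels integer vector of linear voxel indices of the cluster.
#' @param cluster_id identifier string.
#' @return A `cluster_values` object: list(cluster_id, values_a, values_b).
#' @export
cluster_mean_values <- function(maps_a, maps_b, voxels, cluster_id = "cl") {
  stopifnot(length(voxels) >= 1)
  mv <- function(maps) vapply(maps, function(m) {
    v <- map_values(m)[voxels]
    if (any(!is.finite(v))) stop("subject map contains non-finite values")
    mean(v)
  }, numeric(1))
  structure(list(cluster_id = cluster_id, values_a = mv(maps_a),
                 values_b = mv(maps_b)),
            class = "cluster_values")
}

# Exhaustive pairwise AUC of x (positive class) against y, ties = 0.5.
pairwise_auc <- function(x, y) {
  ps <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(ps)
}

# Rank-based AUC (Mann-Whitney U / (n*m)), identical to pairwise counting.
rank_auc <- function(x, y) {
  r <- rank(c(x, y))
  m <- length(x)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(y))
}

# DeLong variance of the AUC via placement values.
delong_se <- function(x, y) {
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

#' ROC analysis of a cluster's group discrimination
#'
#' AUC computed as the Mann-Whitney U statistic divided by nA*nB (ties
#' counted 0.5), oriented so that AUC >= 0.5; the group with the higher
#' mean is recorded as `positive_group`. The 95% confidence interval uses
#' DeLong's method by default (a seeded percentile bootstrap is available),
#' the p-value tests AUC = 0.5 by the normal approximation, and the
#' accuracy band follows [accuracy_band()].
#'
#' Note: when clusters were selected by the same group contrast the ROC
#' evaluates, AUC estimates are optimistically biased (circular analysis).
#'
#' @param values a [cluster_mean_values()] result.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @return A `roc_result`: list(cluster_id, auc, ci_low, ci_high, p_value,
#'   band, positive_group, degenerate).
#' @export
roc_auc <- function(values, ci_method = c("delong", "bootstrap"),
                    n_boot = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  a <- values$values_a
  b <- values$values_b
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  pos <- if (mean(a) >= mean(b)) "A" else "B"
  x <- if (pos == "A") a else b
  y <- if (pos == "A") b else a
  auc <- rank_auc(x, y)
  if (auc < 0.5) {  # mean-based orientation disagrees with rank order
    pos <- setdiff(c("A", "B"), pos)
    tmp <- x; x <- y; y <- tmp
    auc <- 1 - auc
  }
  degenerate <- length(unique(c(x, y))) == 1L
  if (degenerate) {
    return(structure(list(cluster_id = values$cluster_id, auc = 0.5,
                          ci_low = 0.5, ci_high = 0.5, p_value = 1,
                          band = accuracy_band(0.5), positive_group = pos,
                          degenerate = TRUE), class = "roc_result"))
  }
  if (ci_method == "delong") {
    se <- delong_se(x, y)
    if (se > 0) {
      ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))
      p <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
    } else {
      ci <- c(auc, auc)
      p <- if (auc == 0.5) 1 else 0
    }
  } else {
    bs <- with_seed(seed, vapply(seq_len(n_boot), function(i)
      rank_auc(sample(x, replace = TRUE), sample(y, replace = TRUE)),
      numeric(1)))
    ci <- unname(stats::quantile(bs, c(0.025, 0.975), type = 7))
    p <- 2 * min(mean(bs <= 0.5), mean(bs >= 0.5))
  }
  structure(list(cluster_id = values$cluster_id, auc = auc,
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 band = accuracy_band(auc), positive_group = pos,
                 degenerate = FALSE),
            class = "roc_result")
}

#' Diagnostic accuracy band of an AUC
#'
#' AUC in [0.5, 0.7) is labelled `"low"`, at or above 0.7 `"excellent"`
#' (values above 0.9 keep the `"excellent"` label).
#'
#' @param auc area under the ROC curve, must be >= 0.5 after orientation.
#' @return `"low"` or `"excellent"`.
#' @export
accuracy_band <- function(auc) {
  if (!is.finite(auc) || auc < 0.5 || auc > 1)
    stop("AUC must lie in [0.5, 1] after orientation; got ", auc)
  if (auc < 0.7) "low" else "excellent"
}

#' ROC curve points for a cluster
#'
#' False/true positive rates at every distinct threshold, positive class =
#' the oriented positive group.
#'
#' @param values a [cluster_mean_values()] result.
#' @param positive_group `"A"` or `"B"`.
#' @return data.frame(threshold, fpr, tpr), threshold decreasing.
#' @export
roc_curve <- function(values, positive_group = "A") {
  x <- if (positive_group == "A") values$values_a else values$values_b
  y <- if (positive_group == "A") values$values_b else values$values_a
  th <- sort(unique(c(x, y, Inf)), decreasing = TRUE)
  data.frame(threshold = th,
             fpr = vapply(th, function(t) mean(y >= t), numeric(1)),
             tpr = vapply(th, function(t) mean(x >= t), numeric(1)))
}
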
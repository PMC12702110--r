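#' Wrapped angular difference
#'
#' Minimal-magnitude representative of `a - b` modulo 180 degrees, sign
#' preserved, in `(-90, 90]`. Axial angles (helix, sheetlet) are equivalent
#' modulo 180, so 89 vs -89 differ by 2, not 178.
#'
#' @param a,b angles in degrees.
#' @return wrapped differences in degrees.
#' @export
wrap_angle_diff <- function(a, b) {
  wrap_halfcircle(a - b)
}

metric_is_angular <- function(metric_kind) {
  if (!metric_kind %in% c("md", "fa", "ha", "e2a", "abs_e2a")) {
    stop(sprintf("unknown metric kind '%s'", metric_kind))
  }
  metric_kind %in% c("ha", "e2a")
}

#' Per-voxel RMSD of bootstrap samples against a reference
#'
#' Accuracy measure: root mean squared difference between each voxel's
#' bootstrap sample values and the reference value computed from the fully
#' sampled dataset. Angular metrics use the wrapped (modulo-180) difference.
#'
#' @param samples V x S matrix of per-sample metric values.
#' @param reference_map length-V reference values.
#' @param metric_kind one of `"md"`, `"fa"`, `"ha"`, `"e2a"`, `"abs_e2a"`.
#' @return length-V RMSD vector.
#' @export
rmsd_map <- function(samples, reference_map, metric_kind) {
  samples <- rbind(samples)
  stopifnot(length(reference_map) == nrow(samples))
  d <- if (metric_is_angular(metric_kind)) {
    wrap_angle_diff(samples, matrix(reference_map, nrow(samples), ncol(samples)))
  } else {
    samples - reference_map
  }
  sqrt(rowMeans(d^2))
}

## axial (modulo-180) mean via the double-angle method
axial_mean <- function(x) {
  t2 <- x * pi / 90 # 2 * theta in radians
  atan2(mean(sin(t2)), mean(cos(t2))) * 90 / pi
}

#' Per-voxel SD across bootstrap samples
#'
#' Precision measure: sample standard deviation (n - 1 denominator) across
#' bootstrap samples; `precision = SD^-2`. Angular metrics use wrapped
#' deviations about the axial (modulo-180) mean.
#'
#' @inheritParams rmsd_map
#' @return length-V SD vector.
#' @export
sd_map <- function(samples, metric_kind) {
  samples <- rbind(samples)
  if (ncol(samples) < 2L) stop("need at least 2 samples for an SD")
  if (metric_is_angular(metric_kind)) {
    apply(samples, 1, function(x) {
      d <- wrap_angle_diff(x, axial_mean(x))
      stats::sd(d)
    })
  } else {
    apply(samples, 1, stats::sd)
  }
}

#' ROI aggregation with sector exclusion
#'
#' Averages a per-voxel map over the mask after removing excluded angular
#' sectors. Sectors are equal azimuth wedges about the LV center (sector 1
#' starts at azimuth -pi); a septal-style ROI is obtained by excluding all
#' but a contiguous pair of wedges.
#'
#' @param values length-V per-voxel values (matching `voxels` rows).
#' @param voxels V x 2 voxel coordinates.
#' @param center LV center, e.g. from [center_of_mass()].
#' @param excluded_sectors integer sector indices to drop (1..n_sectors).
#' @param n_sectors number of equal azimuth wedges.
#' @return list with `mean`, `n` (voxels used) and `sector` (per-voxel
#'   sector index).
#' @export
roi_summary <- function(values, voxels, center, excluded_sectors = integer(0),
                        n_sectors = 12L) {
  stopifnot(length(values) == nrow(voxels))
  az <- atan2(voxels[, 2] - center[2], voxels[, 1] - center[1])
  sector <- floor((az + pi) / (2 * pi / n_sectors)) + 1L
  sector[sector > n_sectors] <- n_sectors # az == +pi edge
  keep <- !(sector %in% excluded_sectors) & !is.na(values)
  if (!any(keep)) stop("no voxels left after sector exclusion")
  list(mean = mean(values[keep]), n = sum(keep), sector = sector)
}

#' Holm step-down adjustment of p-values
#'
#' Bonferroni-Holm correction: sort ascending, multiply the i-th smallest by
#' `m - i + 1`, enforce monotonicity, cap at 1. Delegates to
#' [stats::p.adjust()] after validation.
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Pairwise paired comparisons between acquisition schemes
#'
#' Paired t-tests between every pair of schemes across replicates (rows),
#' for one statistic (e.g. ROI RMSD of MD). P-values are Holm-adjusted over
#' the matrix's lower triangle. A scheme compared with itself has p = 1 by
#' convention. 95% confidence intervals of each scheme's mean use the
#' normal approximation.
#'
#' @param values replicates x schemes numeric matrix (column names label
#'   the schemes); replicate r must refer to the same underlying dataset in
#'   every column.
#' @return object of class `comparison_report`: symmetric matrices `p` and
#'   `p_adjusted` (unit diagonal), `mean`, `ci_lower`, `ci_upper` per
#'   scheme, `n_replicates`.
#' @export
paired_comparison_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3L) stop("need at least 3 paired replicates")
  if (any(is.na(values))) stop("replicates must be complete (no NA)")
  k <- ncol(values)
  nm <- colnames(values) %||% paste0("scheme", seq_len(k))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- values[, i] - values[, j]
      p[i, j] <- p[j, i] <- if (stats::sd(d) == 0) {
        if (all(d == 0)) 1 else 0
      } else {
        stats::t.test(values[, i], values[, j], paired = TRUE)$p.value
      }
    }
  }
  lower <- p[lower.tri(p)]
  adj <- holm_adjust(lower)
  p_adj <- matrix(1, k, k, dimnames = dimnames(p))
  p_adj[lower.tri(p_adj)] <- adj
  p_adj <- pmin(p_adj, t(p_adj))
  diag(p_adj) <- 1
  m <- colMeans(values)
  se <- apply(values, 2, stats::sd) / sqrt(nrow(values))
  structure(
    list(
      p = p, p_adjusted = p_adj,
      mean = m, ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
      n_replicates = nrow(values)
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d schemes, %d paired replicates\n",
              ncol(x$p), x$n_replicates))
  cat("Holm-adjusted p-values:\n")
  print(round(x$p_adjusted, 4))
  invisible(x)
}

#' Percent change between two scheme groups
#'
#' `100 * (a - b) / b`, elementwise then averaged: the relative difference
#' of group A's statistic with respect to group B's (negative = A lower).
#'
#' @param group_a,group_b numeric vectors of matched statistics (e.g. ROI
#'   RMSD at the same acquisition-time bands).
#' @return scalar mean percent change.
#' @export
percent_change <- function(group_a, group_b) {
  stopifnot(length(group_a) == length(group_b))
  if (any(group_b == 0)) stop("zero denominator in percent change")
  mean(100 * (group_a - group_b) / group_b)
}

#' Summarize a bootstrap run against a reference
#'
#' Convenience wrapper producing the per-metric ROI-aggregated mean, RMSD
#' and SD for one bootstrap run.
#'
#' @param run a [run_bootstrap()] result.
#' @param reference named list of reference metric vectors (from
#'   [metric_maps()] of the full reference fit).
#' @param voxels,center,excluded_sectors,n_sectors passed to [roi_summary()].
#' @return data frame with columns `scheme`, `metric`, `statistic`, `value`.
#' @export
summarize_bootstrap <- function(run, reference, voxels, center,
                                excluded_sectors = integer(0),
                                n_sectors = 12L) {
  rows <- list()
  for (m in names(run$samples)) {
    smp <- run$samples[[m]]
    ok <- rowSums(is.na(smp)) == 0 & !is.na(reference[[m]])
    agg <- function(v) {
      roi_summary(ifelse(ok, v, NA), voxels, center,
                  excluded_sectors, n_sectors)$mean
    }
    mean_v <- rowMeans(smp)
    rows[[length(rows) + 1L]] <- data.frame(
      scheme = run$plan$name, metric = m,
      statistic = c("mean", "rmsd", "sd"),
      value = c(
        agg(mean_v),
        agg(rmsd_map(smp, reference[[m]], m)),
        agg(sd_map(smp, m))
      )
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
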
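#' Match segmentation centroids to ground truth
#'
#' Greedy one-pass matcher: ground-truth centroids are visited in ascending
#' index order; for each, the unmatched segmentation centroids within the
#' spherical neighbourhood of `radius` voxels are candidates and the nearest
#' one becomes a true positive and leaves the pool (ties at equal distance
#' go to the lower segmentation index). False positives are unmatched
#' segmentation centroids (`FP = N_SC - TP`), false negatives unmatched
#' ground-truth centroids (`FN = N_GT - TP`).
#'
#' @param gt ground-truth centroids (matrix or data frame with x/y/z),
#'   voxel coordinates in the downscaled space.
#' @param seg segmentation centroids, same space.
#' @param radius matching radius in voxels.
#' @return A `match_result`: counts `tp`, `fp`, `fn`, `n_gt`, `n_sc`,
#'   matched index `pairs` (tibble `gt`, `seg`, `distance`) and
#'   `match_radius`.
#' @export
#' @examples
#' gt <- rbind(c(0, 0, 0), c(30, 0, 0))
#' seg <- rbind(c(2, 0, 0), c(30, 11, 0), c(90, 0, 0))
#' match_centroids(gt, seg)$tp
match_centroids <- function(gt, seg, radius = 12) {
  if (radius <= 0) stop("radius must be positive")
  gt_m <- if (length(gt) == 0 || NROW(gt) == 0) matrix(0, 0, 3) else .as_points(gt)
  seg_m <- if (length(seg) == 0 || NROW(seg) == 0) matrix(0, 0, 3) else .as_points(seg)
  n_gt <- nrow(gt_m); n_sc <- nrow(seg_m)
  pairs <- list()
  if (n_gt > 0 && n_sc > 0) {
    available <- rep(TRUE, n_sc)
    for (i in seq_len(n_gt)) {
      d <- sqrt(colSums((t(seg_m) - gt_m[i, ])^2))
      d[!available] <- Inf
      j <- which.min(d) # ties resolved to the lowest index by which.min
      if (is.finite(d[j]) && d[j] <= radius) {
        available[j] <- FALSE
        pairs[[length(pairs) + 1]] <- c(i, j, d[j])
      }
    }
  }
  pairs <- if (length(pairs) > 0) {
    m <- do.call(rbind, pairs)
    tibble::tibble(gt = as.integer(m[, 1]), seg = as.integer(m[, 2]),
                   distance = m[, 3])
  } else {
    tibble::tibble(gt = integer(0), seg = integer(0), distance = numeric(0))
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = n_sc - tp, fn = n_gt - tp,
                 n_gt = n_gt, n_sc = n_sc, pairs = pairs,
                 match_radius = radius),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FP %d, FN %d (GT %d, seg %d, radius %g voxels)\n",
    x$tp, x$fp, x$fn, x$n_gt, x$n_sc, x$match_radius))
  m <- compute_metrics(x)
  cat(sprintf("  recall %.2f, precision %.2f, F score %.2f\n",
              m$recall, m$precision, m$f_score))
  invisible(x)
}

#' Recall, precision and F score of a match result
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, and the F score
#' is their harmonic mean. Undefined ratios (zero denominator) are returned
#' as `NA`, not 0. Values are unrounded; round only for reporting.
#'
#' @param m a `match_result`, or a list/row with `tp`, `fp`, `fn`.
#' @return A tibble with `recall`, `precision`, `f_score`.
#' @export
#' @examples
#' compute_metrics(list(tp = 216, fp = 9, fn = 36))
compute_metrics <- function(m) {
  tp <- m$tp; fp <- m$fp; fn <- m$fn
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f_score <- if (!is.na(recall) && !is.na(precision) &&
                 (recall + precision) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(recall = recall, precision = precision, f_score = f_score)
}

#' Evaluate a segmentation against ground-truth centroids
#'
#' Convenience wrapper accepting a [label_image()] (its centroids are
#' computed internally) or a centroid table.
#'
#' @param gt ground-truth centroid table.
#' @param seg a [label_image()] or centroid table.
#' @param radius matching radius in voxels.
#' @return A `match_result`.
#' @export
evaluate_segmentation <- function(gt, seg, radius = 12) {
  if (inherits(seg, "label_image")) seg <- label_centroids(seg)
  match_centroids(gt, seg, radius = radius)
}
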
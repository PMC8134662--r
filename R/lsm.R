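# Voxel-wise lesion-symptom mapping: Brunner-Munzel test per voxel,
# Benjamini-Hochberg FDR across tested voxels, |W| weight map, atlas ROIs.

# Core statistic on two numeric vectors; no validation, shared by bm_test
# and bm_map. Returns c(W, df, p, degenerate).
bm_core <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  ri1 <- rank(x, ties.method = "average")
  ri2 <- rank(y, ties.method = "average")
  s1 <- sum((r1 - ri1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  s2 <- sum((r2 - ri2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  vv <- n1 * s1 + n2 * s2
  if (vv <= 0) return(c(W = 0, df = NA_real_, p = NA_real_, degenerate = 1))
  W <- n1 * n2 * (m2 - m1) / ((n1 + n2) * sqrt(vv))
  df <- vv^2 / ((n1 * s1)^2 / (n1 - 1) + (n2 * s2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(W), df = df)
  c(W = W, df = df, p = min(p, 1), degenerate = 0)
}

#' Brunner-Munzel rank test
#'
#' Nonparametric test for stochastic equality of two samples, robust to ties
#' and unequal variances. Mid-ranks are assigned over the pooled sample; the
#' statistic uses separate rank-variance estimates per group and a
#' Satterthwaite-type t approximation for the degrees of freedom. Two-sided.
#'
#' @param scores_lesioned,scores_intact Numeric vectors, each of length >= 2.
#' @return List with `statistic` (W), `df`, `p.value`, and `degenerate`
#'   (`TRUE` when both within-group rank variances are zero, e.g. complete
#'   separation, in which case `df` and `p.value` are `NA`).
#' @examples
#' bm_test(c(12, 18, 20, 25, 31), c(4, 8, 9, 14, 22))
#' @export
bm_test <- function(scores_lesioned, scores_intact) {
  x <- as.numeric(scores_lesioned); y <- as.numeric(scores_intact)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("scores must not contain NA")
  z <- bm_core(x, y)
  list(statistic = unname(z["W"]), df = unname(z["df"]),
       p.value = unname(z["p"]), degenerate = unname(z["degenerate"]) == 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m p_(j) / j`, clipped at
#' 1 and order-preserving.
#'
#' @param p Numeric vector of p-values in \[0,1\] (NAs propagate).
#' @return Vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Voxel-wise Brunner-Munzel lesion-symptom map
#'
#' At every voxel that passes the lesion-coverage filter and the minimum
#' group-size rule, patients are split into lesioned vs. intact at that
#' voxel and their outcome scores compared with [bm_test()]. P-values of the
#' non-degenerate tested voxels are FDR-adjusted together.
#'
#' @param masks List of 3D lesion masks, n-x-V matrix, or `stroke_cohort`.
#' @param scores Numeric outcome per patient (e.g. 48-hour NIHSS).
#' @param coverage_threshold Minimum fraction of patients lesioned at a
#'   voxel for it to be tested (inclusive); default 0.10.
#' @param min_group_size Minimum patients per side (lesioned and intact);
#'   default 2, required by the rank-variance estimators.
#' @return Object of class `voxel_stat_map`: 3D arrays `tested`, `statistic`,
#'   `p`, `q`, `degenerate` (arrays are `NA` outside tested voxels) plus
#'   `n_patients` and filter settings.
#' @export
bm_map <- function(masks, scores, coverage_threshold = 0.10,
                   min_group_size = 2L) {
  mm <- as_mask_matrix(masks)
  d <- attr(mm, "grid_dim")
  n <- nrow(mm)
  scores <- as.numeric(scores)
  if (length(scores) != n) stop("one score per patient required")
  if (n < 4L) stop("need at least 4 patients")

  counts <- colSums(mm)
  tested_v <- counts / n >= coverage_threshold &
    counts >= min_group_size & (n - counts) >= min_group_size
  idx <- which(tested_v)

  W <- p <- array(NA_real_, dim = d)
  degen <- array(FALSE, dim = d)

  if (length(idx)) {
    pat <- mm[, idx, drop = FALSE]
    # voxels sharing a lesioned-patient set share the test result
    keys <- apply(pat, 2L, function(col) paste(which(col), collapse = ","))
    uk <- !duplicated(keys)
    ures <- t(vapply(which(uk), function(j) {
      les <- pat[, j]
      bm_core(scores[les], scores[!les])
    }, numeric(4)))
    res <- ures[match(keys, keys[uk]), , drop = FALSE]
    W[idx] <- res[, 1]
    p[idx] <- res[, 3]
    degen[idx] <- res[, 4] == 1
  }

  q <- array(NA_real_, dim = d)
  test_ok <- which(tested_v & !degen)
  if (length(test_ok)) q[test_ok] <- fdr_adjust(p[test_ok])

  structure(list(tested = array(tested_v, dim = d), statistic = W, p = p,
                 q = q, degenerate = degen, n_patients = n,
                 coverage_threshold = coverage_threshold,
                 min_group_size = min_group_size),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  nt <- sum(x$tested)
  cat(sprintf("Voxel-wise Brunner-Munzel map: %d tested voxels (%d patients)\n",
              nt, x$n_patients))
  if (nt) cat(sprintf("  %d degenerate; min q = %.4g\n",
                      sum(x$degenerate), suppressWarnings(min(x$q, na.rm = TRUE))))
  invisible(x)
}

#' Threshold a statistic map into a voxel weight map
#'
#' Voxels whose FDR-adjusted q-value is at most `alpha` receive weight
#' `|W|`; everything else is zero. Degenerate voxels (zero rank variance)
#' are excluded from the FDR and therefore weightless unless
#' `include_degenerate = TRUE`.
#'
#' @param stat_map A `voxel_stat_map`.
#' @param alpha Significance level on q-values; default 0.05.
#' @param include_degenerate Give degenerate voxels a nominal weight of 1.
#' @return 3D numeric weight array.
#' @export
threshold_to_weights <- function(stat_map, alpha = 0.05,
                                 include_degenerate = FALSE) {
  w <- array(0, dim = dim(stat_map$statistic))
  hit <- !is.na(stat_map$q) & stat_map$q <= alpha
  w[hit] <- abs(stat_map$statistic[hit])
  if (include_degenerate) w[stat_map$degenerate] <- 1
  w
}

#' Atlas regions touched by surviving voxels
#'
#' @param weight_map 3D weight array on the atlas lattice.
#' @param atlas A `toy_atlas`.
#' @return Sorted integer vector of region ids containing at least one
#'   nonzero-weight voxel.
#' @export
lsm_rois <- function(weight_map, atlas) {
  if (!identical(dim(weight_map), dim(atlas$labels)))
    stop("weight map and atlas are on different lattices")
  sort(unique(atlas$labels[weight_map != 0 & atlas$labels > 0L]))
}

#' Full LSM pipeline: map, threshold, regions
#'
#' @inheritParams bm_map
#' @param atlas A `toy_atlas`.
#' @param alpha FDR-adjusted significance threshold.
#' @return Object of class `lsm_result`: `stat_map`, `weight_map`, `roi_ids`.
#' @export
run_lsm <- function(masks, scores, atlas, alpha = 0.05,
                    coverage_threshold = 0.10, min_group_size = 2L) {
  sm <- bm_map(masks, scores, coverage_threshold, min_group_size)
  wm <- threshold_to_weights(sm, alpha = alpha)
  structure(list(stat_map = sm, weight_map = wm,
                 roi_ids = lsm_rois(wm, atlas), alpha = alpha),
            class = "lsm_result")
}

#' @export
print.lsm_result <- function(x, ...) {
  cat(sprintf("LSM result: %d voxels survive q <= %g; %d ROI(s)\n",
              sum(x$weight_map != 0), x$alpha, length(x$roi_ids)))
  if (length(x$roi_ids)) cat("  ROIs:", paste(x$roi_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Write LSM outputs (NIfTI maps + ROI JSON)
#'
#' @param result An `lsm_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_lsm <- function(result, dir) {
  tryCatch({
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sm <- result$stat_map
    na0 <- function(a) { a[is.na(a)] <- 0; a }
    RNifti::writeNifti(na0(sm$statistic), file.path(dir, "lsm_statistic.nii.gz"))
    RNifti::writeNifti(na0(sm$p), file.path(dir, "lsm_p.nii.gz"))
    RNifti::writeNifti(na0(sm$q), file.path(dir, "lsm_q.nii.gz"))
    RNifti::writeNifti(result$weight_map, file.path(dir, "lsm_weights.nii.gz"))
    jsonlite::write_json(list(alpha = result$alpha, roi_ids = result$roi_ids),
                         file.path(dir, "lsm_rois.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) stop_io("LSM write failed: ", conditionMessage(e)))
  invisible(dir)
}
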
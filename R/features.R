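#' Relative lesion overlap of a region
#'
#' Fraction of the region's voxels covered by the lesion,
#' `|lesion ∩ region| / |region|`.
#'
#' @param lesion_mask 3D 0/1 array (or logical).
#' @param region_vox Integer vector of linear voxel indices of the region.
#' @return Fraction in \[0,1\].
#' @export
overlap_fraction <- function(lesion_mask, region_vox) {
  if (length(region_vox) == 0L)
    stop("overlap undefined for an empty region")
  sum(lesion_mask[region_vox] > 0) / length(region_vox)
}

#' White-matter tract integrity after a lesion
#'
#' The tract is sliced along its declared axis; each slice's spared fraction
#' is `1 - |lesion ∩ tract ∩ slice| / |tract ∩ slice|`. Integrity is the
#' summary of those per-slice fractions — by default the minimum, because a
#' single fully lesioned cross-section disconnects the tract (1 = untouched,
#' 0 = transected somewhere).
#'
#' @param lesion_mask 3D 0/1 array.
#' @param tract_vox Linear voxel indices of the tract.
#' @param axis Tract axis: `"x"`, `"y"`, `"z"` or 1:3.
#' @param summary `"min"` (default) or `"mean"` over slices.
#' @param grid_dim Dimensions of the lattice (defaults to `dim(lesion_mask)`).
#' @return Fraction in \[0,1\].
#' @export
tract_integrity <- function(lesion_mask, tract_vox, axis, summary = c("min", "mean"),
                            grid_dim = dim(lesion_mask)) {
  if (length(tract_vox) == 0L) stop("integrity undefined for an empty tract")
  summary <- match.arg(summary)
  ax <- axis_index(axis)
  coords <- arrayInd(tract_vox, grid_dim)[, ax]
  hit <- lesion_mask[tract_vox] > 0
  tot <- tabulate(coords, nbins = grid_dim[ax])
  les <- tabulate(coords[hit], nbins = grid_dim[ax])
  nonempty <- tot > 0L
  spared <- 1 - les[nonempty] / tot[nonempty]
  if (summary == "min") min(spared) else mean(spared)
}

#' Lesion-coverage filter
#'
#' Retains a voxel (or atlas region) iff the fraction of patients with at
#' least one lesioned voxel in it is at least `threshold` (inclusive).
#'
#' @param masks List of 3D lesion masks, an n-x-V logical matrix, or a
#'   `stroke_cohort`.
#' @param unit `"voxel"` or `"region"`.
#' @param atlas Required for `unit = "region"`.
#' @param threshold Coverage fraction in (0,1); default 0.10.
#' @return For `unit = "voxel"`, a 3D logical array of retained voxels; for
#'   `unit = "region"`, a sorted integer vector of retained region ids.
#' @export
coverage_filter <- function(masks, unit = c("voxel", "region"), atlas = NULL,
                            threshold = 0.10) {
  unit <- match.arg(unit)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  mm <- as_mask_matrix(masks)
  n <- nrow(mm)
  if (n < 1L) stop("need at least one mask")
  counts <- colSums(mm)
  if (unit == "voxel") {
    d <- attr(mm, "grid_dim") %||% dim(if (is.list(masks)) masks[[1]] else masks$masks[[1]])
    return(array(counts / n >= threshold, dim = d))
  }
  if (is.null(atlas)) stop("atlas required for region-level filtering")
  labs <- as.vector(atlas$labels)
  ids <- sort(atlas$regions$region_id)
  keep <- vapply(ids, function(id) {
    vox <- which(labs == id)
    # a patient "affects" the region if any of its voxels is lesioned
    affected <- rowSums(mm[, vox, drop = FALSE]) > 0
    sum(affected) / n >= threshold
  }, logical(1))
  ids[keep]
}

# canonical feature-kind order within a region
feature_kinds <- c("gm_overlap", "wm_overlap", "wm_integrity")

#' Build the imaging feature matrix
#'
#' One `gm_overlap` column per GM region and one `wm_overlap` plus one
#' `wm_integrity` column per WM region in `region_set`; values come from
#' [overlap_fraction()] and [tract_integrity()]. Columns are ordered by
#' region id, then kind, so the layout is reproducible.
#'
#' @param cohort A `stroke_cohort` (or list of masks with patient names).
#' @param atlas A `toy_atlas`.
#' @param region_set Integer vector of region ids (subset of the atlas);
#'   empty gives a zero-column matrix.
#' @param integrity_summary Passed to [tract_integrity()].
#' @return Object of class `feature_matrix`: list with `values` (numeric
#'   matrix, rownames = patient ids) and `manifest` (data frame `name`,
#'   `region_id`, `kind`, `provenance`).
#' @export
build_feature_matrix <- function(cohort, atlas, region_set,
                                 integrity_summary = "min") {
  masks <- if (inherits(cohort, "stroke_cohort")) cohort$masks else cohort
  region_set <- sort(unique(as.integer(region_set)))
  unknown <- setdiff(region_set, atlas$regions$region_id)
  if (length(unknown))
    stop("unknown region id(s): ", paste(unknown, collapse = ", "))

  cols <- list()
  manifest <- list()
  d <- dim(atlas$labels)
  for (id in region_set) {
    tissue <- atlas$regions$tissue[atlas$regions$region_id == id]
    vox <- region_voxels(atlas, id)
    if (tissue == "GM") {
      kinds <- "gm_overlap"
    } else {
      kinds <- c("wm_overlap", "wm_integrity")
      axis <- atlas$regions$axis[atlas$regions$region_id == id]
    }
    for (kind in kinds) {
      nm <- sprintf("r%03d_%s", id, kind)
      vals <- vapply(masks, function(m) {
        if (kind == "wm_integrity")
          tract_integrity(m, vox, axis, summary = integrity_summary, grid_dim = d)
        else
          overlap_fraction(m, vox)
      }, numeric(1))
      cols[[nm]] <- vals
      manifest[[nm]] <- data.frame(name = nm, region_id = id, kind = kind,
                                   provenance = "imaging")
    }
  }
  values <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(masks), ncol = 0)
  rownames(values) <- names(masks)
  structure(list(values = values,
                 manifest = if (length(manifest)) do.call(rbind, manifest) else
                   data.frame(name = character(0), region_id = integer(0),
                              kind = character(0), provenance = character(0))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d patients x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (nrow(x$manifest))
    cat("  kinds:", paste(sprintf("%s (%d)", names(table(x$manifest$kind)),
                                  table(x$manifest$kind)), collapse = ", "), "\n")
  invisible(x)
}

# Candidate clinical covariates, in the order they enter models.
clinical_candidates <- c("age", "sex", "nihss_baseline", "glucose",
                         "hematocrit", "sbp", "afib", "htn", "hld", "dm",
                         "smoker", "treatment", "onset_to_admission_min")

#' Clinical feature matrix of a cohort
#'
#' Encodes the candidate clinical covariates numerically (sex as male = 1,
#' binary risk factors as 0/1) into a `feature_matrix` with clinical
#' provenance. Outcome scores are never included.
#'
#' @param cohort A `stroke_cohort` or its `clinical` data frame.
#' @return A `feature_matrix`.
#' @export
clinical_features <- function(cohort) {
  cl <- if (inherits(cohort, "stroke_cohort")) cohort$clinical else cohort
  present <- intersect(clinical_candidates, names(cl))
  values <- sapply(present, function(nm) {
    v <- cl[[nm]]
    if (nm == "sex") as.numeric(v == "M" | v == 1) else as.numeric(v)
  })
  values <- matrix(values, nrow = nrow(cl),
                   dimnames = list(cl$patient_id, present))
  structure(list(values = values,
                 manifest = data.frame(name = present, region_id = NA_integer_,
                                       kind = "clinical",
                                       provenance = "clinical")),
            class = "feature_matrix")
}

#' Write a feature matrix as CSV plus a JSON manifest
#'
#' @param fm A `feature_matrix`.
#' @param path CSV output path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = rownames(fm$values), fm$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(fm$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
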
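#' Generate a toy parcellation atlas
#'
#' Builds a small labelled 3D volume standing in for a fused grey-matter /
#' white-matter parcellation. `n_wm_tracts` white-matter (WM) tracts are
#' axis-aligned bundles, each contiguous along its declared axis; the
#' remaining volume is partitioned exhaustively into `n_gm_regions`
#' grey-matter (GM) parcels as the Voronoi cells of randomly placed seed
#' points — like a real parcellation, every brain voxel belongs to exactly
#' one region, so any lesion overlaps some parcel. Region voxel sets are
#' pairwise disjoint. Placement is random but fully determined by `seed`.
#'
#' @param grid_shape Integer vector of length 3, each entry at least 16.
#' @param n_gm_regions Number of GM parcels (at least 2).
#' @param n_wm_tracts Number of WM tracts (0 allowed).
#' @param seed Integer seed controlling placement.
#' @param min_region_size Minimum expected voxels per GM parcel; requesting
#'   more parcels than the grid can hold at this granularity is a sizing
#'   error.
#' @param wm_section Cross-section half-width of WM tracts (voxels); the
#'   tract occupies a `(2*wm_section+1)^2` square in the plane orthogonal to
#'   its axis.
#' @return An object of class `toy_atlas`: a list with `labels` (3D integer
#'   array) and `regions` (data frame with columns `region_id`, `name`,
#'   `tissue`, `axis`; `axis` is `NA` for GM regions).
#' @examples
#' atl <- make_toy_atlas(c(32, 32, 32), n_gm_regions = 6, n_wm_tracts = 2, seed = 1)
#' atl
#' @export
make_toy_atlas <- function(grid_shape = c(32L, 32L, 32L), n_gm_regions = 20L,
                           n_wm_tracts = 4L, seed = 1L,
                           min_region_size = 32L, wm_section = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be three integers, each >= 16")
  n_gm_regions <- as.integer(n_gm_regions)
  n_wm_tracts <- as.integer(n_wm_tracts)
  if (n_gm_regions < 2L) stop("n_gm_regions must be >= 2")
  if (n_wm_tracts < 0L) stop("n_wm_tracts must be >= 0")
  if (n_gm_regions * min_region_size > prod(grid_shape))
    stop_sim("cannot pack ", n_gm_regions, " GM regions of >= ",
             min_region_size, " voxels into a ",
             paste(grid_shape, collapse = "x"), " grid")

  with_seed(seed, {
    labels <- array(0L, dim = grid_shape)
    regions <- list()
    max_tries <- 400L

    # WM tracts first: axis-aligned boxes, disjoint from each other
    for (w in seq_len(n_wm_tracts)) {
      rid <- n_gm_regions + as.integer(w)
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ax <- sample(1:3, 1L)
        len <- sample(seq(round(grid_shape[ax] * 0.4), round(grid_shape[ax] * 0.7)), 1L)
        start <- sample(seq_len(grid_shape[ax] - len + 1L), 1L)
        other <- setdiff(1:3, ax)
        lo <- vapply(other, function(d)
          sample(seq_len(grid_shape[d] - 2L * wm_section), 1L), numeric(1))
        rng <- vector("list", 3L)
        rng[[ax]] <- start:(start + len - 1L)
        rng[[other[1]]] <- lo[1]:(lo[1] + 2L * wm_section)
        rng[[other[2]]] <- lo[2]:(lo[2] + 2L * wm_section)
        coords <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
        idx <- coords[, 1] + (coords[, 2] - 1L) * grid_shape[1] +
          (coords[, 3] - 1L) * grid_shape[1] * grid_shape[2]
        if (all(labels[idx] == 0L)) {
          labels[idx] <- rid
          regions[[rid]] <- data.frame(region_id = rid,
                                       name = sprintf("wm_%02d", w),
                                       tissue = "WM",
                                       axis = c("x", "y", "z")[ax])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_sim("cannot pack ", n_wm_tracts, " WM tracts into the grid")
    }

    # GM: Voronoi cells of random seed voxels over the remaining volume
    free <- which(labels == 0L)
    seeds <- free[sample.int(length(free), n_gm_regions)]
    seed_xyz <- arrayInd(seeds, grid_shape)
    free_xyz <- arrayInd(free, grid_shape)
    nearest <- max.col(-(outer(free_xyz[, 1], seed_xyz[, 1], "-")^2 +
                           outer(free_xyz[, 2], seed_xyz[, 2], "-")^2 +
                           outer(free_xyz[, 3], seed_xyz[, 3], "-")^2),
                       ties.method = "first")
    labels[free] <- as.integer(nearest)
    storage.mode(labels) <- "integer"
    for (g in seq_len(n_gm_regions))
      regions[[g]] <- data.frame(region_id = g,
                                 name = sprintf("gm_%02d", g),
                                 tissue = "GM", axis = NA_character_)

    structure(list(labels = labels,
                   regions = do.call(rbind, regions[order(vapply(regions, function(r)
                     r$region_id, numeric(1)))])),
              class = "toy_atlas")
  })
}

#' @export
print.toy_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat("Toy parcellation atlas:", paste(d, collapse = " x "), "voxels\n")
  cat(sprintf("  %d regions (%d GM, %d WM), %d labelled voxels\n",
              nrow(x$regions), sum(x$regions$tissue == "GM"),
              sum(x$regions$tissue == "WM"), sum(x$labels > 0L)))
  invisible(x)
}

#' Linear voxel indices of one atlas region
#'
#' @param atlas A `toy_atlas`.
#' @param region_id A single region id present in the atlas.
#' @return Integer vector of linear indices into the label volume.
#' @export
region_voxels <- function(atlas, region_id) {
  if (!region_id %in% atlas$regions$region_id)
    stop("unknown region id: ", region_id)
  which(atlas$labels == as.integer(region_id))
}

# Voxels of an axis-aligned ellipsoid, ordered by normalized distance from
# the centre. Coordinates outside the grid are flagged, not dropped, so
# callers can count pre-clipping size.
ellipsoid_voxels <- function(center, radii, grid_shape) {
  lo <- floor(center - radii)
  hi <- ceiling(center + radii)
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  dist2 <- ((g$x - center[1]) / radii[1])^2 +
    ((g$y - center[2]) / radii[2])^2 +
    ((g$z - center[3]) / radii[3])^2
  keep <- dist2 <= 1
  g <- g[keep, , drop = FALSE]
  dist2 <- dist2[keep]
  ord <- order(dist2, g$x, g$y, g$z)
  g <- g[ord, , drop = FALSE]
  inside <- g$x >= 1 & g$x <= grid_shape[1] &
    g$y >= 1 & g$y <= grid_shape[2] &
    g$z >= 1 & g$z <= grid_shape[3]
  index <- rep(NA_integer_, nrow(g))
  index[inside] <- g$x[inside] + (g$y[inside] - 1L) * grid_shape[1] +
    (g$z[inside] - 1L) * grid_shape[1] * grid_shape[2]
  list(coords = as.matrix(g), inside = inside, index = index[inside])
}

#' Write / read a toy atlas on disk
#'
#' The label volume is stored as NIfTI-1 (identity affine, 1 mm isotropic)
#' and the region table as CSV with columns `region_id,name,tissue,axis`.
#'
#' @param atlas A `toy_atlas`.
#' @param dir Output directory (created if missing).
#' @return `write_atlas` returns `dir` invisibly; `read_atlas` returns a
#'   `toy_atlas`.
#' @export
write_atlas <- function(atlas, dir) {
  tryCatch({
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    RNifti::writeNifti(atlas$labels, file.path(dir, "atlas_labels.nii.gz"))
    utils::write.csv(atlas$regions, file.path(dir, "atlas_regions.csv"),
                     row.names = FALSE)
  }, error = function(e) stop_io("atlas write failed: ", conditionMessage(e)))
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  lab_file <- file.path(dir, "atlas_labels.nii.gz")
  reg_file <- file.path(dir, "atlas_regions.csv")
  if (!file.exists(lab_file) || !file.exists(reg_file))
    stop_io("atlas files not found under ", dir)
  vol <- RNifti::readNifti(lab_file)
  labels <- array(as.integer(vol), dim = dim(vol))
  regions <- utils::read.csv(reg_file, stringsAsFactors = FALSE)
  regions$axis <- as.character(regions$axis)
  structure(list(labels = labels, regions = regions), class = "toy_atlas")
}
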
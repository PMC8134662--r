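# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG state
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG stream so
#' that seeded helpers do not perturb surrounding randomness.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-unit sub-seed so adding patients to a cohort never
# reshuffles earlier patients. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# NIHSS is an integer clinical score bounded by its maximum attainable value.
NIHSS_MIN <- 0L
NIHSS_MAX <- 42L

clamp_nihss <- function(x) as.integer(clamp(round(x), NIHSS_MIN, NIHSS_MAX))

stop_sim <- function(...) {
  stop(errorCondition(paste0(...), class = c("strokenest_sim_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("strokenest_io_error", "error")))
}

# Resolve an axis given as "x"/"y"/"z" or 1:3 to a dimension index.
axis_index <- function(axis) {
  if (is.character(axis)) {
    i <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(i)) stop("axis must be one of 'x', 'y', 'z'")
    return(i)
  }
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  axis
}

# Stack per-patient 3D masks into an n x V logical matrix (V = prod(dim)).
as_mask_matrix <- function(masks) {
  if (is.matrix(masks)) return(masks)
  if (inherits(masks, "stroke_cohort")) masks <- masks$masks
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1L]])
  out <- matrix(FALSE, nrow = length(masks), ncol = prod(d))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!identical(dim(m), d)) stop("all lesion masks must share one lattice")
    out[i, ] <- as.vector(m) > 0
  }
  attr(out, "grid_dim") <- d
  out
}
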
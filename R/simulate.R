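#' Configuration for a synthetic stroke cohort
#'
#' Collects every generative parameter of the simulator in one validated
#' object. The outcome model is a causal chain: lesion load in "eloquent"
#' regions (plus baseline severity) drives the 48-hour NIHSS, and the
#' 48-hour NIHSS (plus clinical covariates) drives the 30-day NIHSS:
#'
#' \deqn{NIHSS_{48h} = clip_{0..42}(round(\alpha_0 + \alpha_1 b +
#'   \sum_r \beta_r o_r + \sum_t \gamma_t (1 - i_t) + \epsilon_1))}
#' \deqn{NIHSS_{30d} = clip_{0..42}(round(\delta_0 + \delta_{48} NIHSS_{48h} +
#'   \sum_c \delta_c x_c + \epsilon_2))}
#'
#' where \eqn{b} is baseline NIHSS, \eqn{o_r} the relative lesion overlap of
#' region r, \eqn{i_t} the integrity of tract t, and \eqn{\epsilon ~ N(0,
#' noise\_sd)}. Continuous covariates enter centred at their population
#' typical value (age 69 y, glucose 7 mmol/L, hematocrit 0.42, systolic
#' blood pressure 150 mmHg, onset-to-admission 150 min).
#'
#' @param n_patients Cohort size (>= 10).
#' @param seed Integer master seed; per-patient sub-streams are derived from
#'   it so growing the cohort never reshuffles earlier patients.
#' @param eloquent_effects Named numeric vector, `names` = atlas region ids,
#'   values = beta (NIHSS points per unit lesion overlap), all >= 0.
#' @param tract_effects Named numeric vector, `names` = WM tract region ids,
#'   values = gamma (NIHSS points per unit integrity loss), all >= 0.
#' @param baseline_intercept,baseline_coef Alpha0 and alpha1 of the 48-hour
#'   model.
#' @param baseline_mean,baseline_lesion_coef,baseline_noise_sd Generative
#'   model of baseline NIHSS: the presenting deficit is caused by the same
#'   infarct, so baseline = clip(round(mean + coef * eloquent lesion load +
#'   noise)), clipped to \[2,30\]. Defaults keep the marginal distribution
#'   near median 15, SD 6 while correlating baseline severity with lesion
#'   load as observed clinically.
#' @param outcome_coefs Named numeric vector for the 30-day model; recognised
#'   names: `intercept`, `nihss_48h`, `age`, `sex`, `glucose`, `hematocrit`,
#'   `sbp`, `afib`, `htn`, `hld`, `dm`, `smoker`, `treatment`,
#'   `onset_to_admission_min`.
#' @param noise_sd_48,noise_sd_30 Gaussian noise SDs (NIHSS points), >= 0.
#' @param lesion_size_range Two integers: min/max lesion size in voxels
#'   before clipping at the grid boundary.
#' @param territory_center Voxel coordinates (length 3, 1-based) of the
#'   centre of the high-incidence arterial territory; `NULL` resolves, at
#'   simulation time, to a lateralised default mimicking a middle-cerebral-
#'   artery territory.
#' @param territory_radius Radius (voxels) of that territory.
#' @param territory_prob Probability that a lesion centre is drawn inside
#'   the territory (the remainder is uniform over the grid).
#' @param prevalence Named list of Bernoulli prevalences for the binary risk
#'   factors (`afib`, `htn`, `hld`, `dm`, `smoker`, `treatment`) and the
#'   probability of male sex (`male`).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 200L,
                              seed = 1L,
                              eloquent_effects = numeric(0),
                              tract_effects = numeric(0),
                              baseline_intercept = 0,
                              baseline_coef = 0.9,
                              baseline_mean = 12,
                              baseline_lesion_coef = 0.5,
                              baseline_noise_sd = 5.5,
                              outcome_coefs = c(intercept = -1.5,
                                                nihss_48h = 0.85,
                                                age = 0.05,
                                                sex = 0.5,
                                                glucose = 0.3,
                                                afib = 1.0,
                                                treatment = -1.5),
                              noise_sd_48 = 3,
                              noise_sd_30 = 3,
                              lesion_size_range = c(100L, 2000L),
                              territory_center = NULL,
                              territory_radius = 7,
                              territory_prob = 0.8,
                              prevalence = list(afib = 0.35, htn = 0.65,
                                                hld = 0.40, dm = 0.25,
                                                smoker = 0.30,
                                                treatment = 0.50,
                                                male = 0.52)) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 10L) stop("n_patients must be >= 10")
  if (any(noise_sd_48 < 0, noise_sd_30 < 0)) stop("noise SDs must be >= 0")
  if (length(eloquent_effects) && (is.null(names(eloquent_effects)) ||
                                   any(eloquent_effects < 0)))
    stop("eloquent_effects must be a named non-negative vector")
  if (length(tract_effects) && (is.null(names(tract_effects)) ||
                                any(tract_effects < 0)))
    stop("tract_effects must be a named non-negative vector")
  lesion_size_range <- as.integer(lesion_size_range)
  if (length(lesion_size_range) != 2L || lesion_size_range[1] < 1L ||
      lesion_size_range[2] < lesion_size_range[1])
    stop("lesion_size_range must be increasing positive integers")
  if (territory_prob < 0 || territory_prob > 1)
    stop("territory_prob must be in [0,1]")
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 eloquent_effects = eloquent_effects,
                 tract_effects = tract_effects,
                 baseline_intercept = baseline_intercept,
                 baseline_coef = baseline_coef,
                 baseline_mean = baseline_mean,
                 baseline_lesion_coef = baseline_lesion_coef,
                 baseline_noise_sd = baseline_noise_sd,
                 outcome_coefs = outcome_coefs,
                 noise_sd_48 = noise_sd_48, noise_sd_30 = noise_sd_30,
                 lesion_size_range = lesion_size_range,
                 territory_center = territory_center,
                 territory_radius = territory_radius,
                 territory_prob = territory_prob,
                 prevalence = prevalence),
            class = "sim_config")
}

# Centres used when covariates enter the 30-day linear predictor.
covariate_centers <- c(age = 69, glucose = 7, hematocrit = 0.42, sbp = 150,
                       onset_to_admission_min = 150)

resolve_territory <- function(config, grid_shape) {
  ctr <- config$territory_center %||% round(grid_shape * c(0.30, 0.50, 0.55))
  if (any(ctr < 1) || any(ctr > grid_shape))
    stop("territory_center lies outside the grid")
  ctr
}

#' Sample one ellipsoid lesion mask
#'
#' Lesion centres fall inside the configured arterial territory with
#' probability `territory_prob` (uniform in the territory ball) and uniformly
#' over the grid otherwise, reproducing the territorial clustering of stroke
#' incidence. The lesion is an axis-aligned ellipsoid with jittered radii,
#' trimmed/grown to an exact target voxel count drawn from
#' `lesion_size_range`, then clipped at the grid boundary.
#'
#' @param atlas A `toy_atlas` providing the lattice.
#' @param config A `sim_config`.
#' @param max_retries Resampling attempts when clipping empties the mask.
#' @return 3D integer array of 0/1 on the atlas lattice.
#' @export
sample_lesion <- function(atlas, config, max_retries = 20L) {
  d <- dim(atlas$labels)
  ctr0 <- resolve_territory(config, d)
  for (try in seq_len(max_retries)) {
    if (stats::runif(1) < config$territory_prob) {
      # uniform draw in the territory ball
      u <- stats::rnorm(3)
      u <- u / max(sqrt(sum(u^2)), 1e-12)
      r <- config$territory_radius * stats::runif(1)^(1 / 3)
      center <- ctr0 + u * r
    } else {
      center <- stats::runif(3, 1, d)
    }
    target <- if (config$lesion_size_range[1] == config$lesion_size_range[2])
      config$lesion_size_range[1]
    else
      sample(seq(config$lesion_size_range[1], config$lesion_size_range[2]), 1L)
    r0 <- (3 * target / (4 * pi))^(1 / 3)
    jit <- exp(stats::rnorm(3, 0, 0.25))
    radii <- r0 * jit / prod(jit)^(1 / 3)
    # enumerate a generous ellipsoid, keep the `target` voxels nearest the
    # centre: exact pre-clipping size regardless of discretisation
    vox <- ellipsoid_voxels(center, radii * 1.35, d)
    if (nrow(vox$coords) < target) vox <- ellipsoid_voxels(center, radii * 2, d)
    n_take <- min(target, nrow(vox$coords))
    inside <- vox$inside[seq_len(n_take)]
    idx <- vox$coords[seq_len(n_take), , drop = FALSE][inside, , drop = FALSE]
    if (nrow(idx) == 0L) next
    mask <- array(0L, dim = d)
    lin <- idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
    mask[lin] <- 1L
    attr(mask, "pre_clip_size") <- n_take
    return(mask)
  }
  stop_sim("could not draw a non-empty lesion after ", max_retries, " tries")
}

#' Simulate the NIHSS outcome chain for one patient
#'
#' Applies the generative model documented in [simulation_config()] to
#' already-computed lesion features and covariates. Noise is drawn from the
#' current RNG stream.
#'
#' @param lesion_features List with `overlaps` (named by region id, in
#'   \[0,1\]) and `integrities` (named by tract id, in \[0,1\]).
#' @param covariates One-row data frame (or named list) with
#'   `nihss_baseline` and any covariates named in `outcome_coefs`.
#' @param config A `sim_config`.
#' @return Named integer vector `nihss_baseline`, `nihss_48h`, `nihss_30d`,
#'   each in \[0,42\].
#' @export
simulate_outcomes <- function(lesion_features, covariates, config) {
  ov <- lesion_features$overlaps %||% numeric(0)
  it <- lesion_features$integrities %||% numeric(0)
  if (length(ov) && (any(ov < 0) || any(ov > 1))) stop("overlaps must be in [0,1]")
  if (length(it) && (any(it < 0) || any(it > 1))) stop("integrities must be in [0,1]")
  covariates <- as.list(covariates)

  eff48 <- 0
  if (length(config$eloquent_effects)) {
    o <- ov[names(config$eloquent_effects)]
    o[is.na(o)] <- 0
    eff48 <- eff48 + sum(config$eloquent_effects * o)
  }
  if (length(config$tract_effects)) {
    i <- it[names(config$tract_effects)]
    i[is.na(i)] <- 1
    eff48 <- eff48 + sum(config$tract_effects * (1 - i))
  }

  # presenting severity is caused by the same infarct: couple baseline to
  # the eloquent lesion load unless a baseline score is supplied
  baseline <- if (!is.null(covariates$nihss_baseline)) {
    clamp_nihss(covariates$nihss_baseline)
  } else {
    as.integer(clamp(round(config$baseline_mean +
                             config$baseline_lesion_coef * eff48 +
                             stats::rnorm(1, 0, config$baseline_noise_sd)),
                     2, 30))
  }

  raw48 <- config$baseline_intercept + config$baseline_coef * baseline + eff48 +
    stats::rnorm(1, 0, config$noise_sd_48)
  nihss_48h <- clamp_nihss(raw48)

  dc <- config$outcome_coefs
  raw30 <- coef0(dc["intercept"]) + coef0(dc["nihss_48h"]) * nihss_48h
  for (nm in setdiff(names(dc), c("intercept", "nihss_48h"))) {
    val <- covariates[[nm]]
    if (is.null(val)) next
    if (nm == "sex") val <- as.numeric(val == "M" | val == 1)
    if (nm %in% names(covariate_centers)) val <- val - covariate_centers[[nm]]
    raw30 <- raw30 + dc[[nm]] * as.numeric(val)
  }
  raw30 <- raw30 + stats::rnorm(1, 0, config$noise_sd_30)
  c(nihss_baseline = baseline, nihss_48h = nihss_48h,
    nihss_30d = clamp_nihss(raw30))
}

# missing coefficient treated as zero
coef0 <- function(x) if (length(x) == 0 || anyNA(x)) 0 else unname(x)

draw_covariates <- function(config) {
  pv <- config$prevalence
  age <- 0
  while (age < 30 || age > 95) age <- stats::rnorm(1, 69, 14)
  glucose <- max(stats::rnorm(1, 7, 2), 3)
  data.frame(
    age = round(age, 1),
    sex = if (stats::runif(1) < pv$male) "M" else "F",
    glucose = round(glucose, 2),
    hematocrit = round(clamp(stats::rnorm(1, 0.42, 0.05), 0.2, 0.6), 3),
    sbp = as.integer(round(clamp(stats::rnorm(1, 150, 20), 90, 230))),
    afib = as.integer(stats::runif(1) < pv$afib),
    htn = as.integer(stats::runif(1) < pv$htn),
    hld = as.integer(stats::runif(1) < pv$hld),
    dm = as.integer(stats::runif(1) < pv$dm),
    smoker = as.integer(stats::runif(1) < pv$smoker),
    treatment = as.integer(stats::runif(1) < pv$treatment),
    onset_to_admission_min = as.integer(round(exp(stats::rnorm(1, log(150), 0.5)))),
    stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Draws `n_patients` lesions, covariates and NIHSS outcomes under the
#' generative model of [simulation_config()]. Each patient uses a seed
#' sub-stream derived from the master seed, so two cohorts sharing a seed
#' are identical patient-by-patient even if their sizes differ.
#'
#' @param config A `sim_config`.
#' @param atlas A `toy_atlas`; every region referenced by the effect maps
#'   must exist in it.
#' @return An object of class `stroke_cohort`: list with `clinical` (one row
#'   per patient), `masks` (list of 3D 0/1 arrays), `ground_truth` (the
#'   generative parameters and the eloquent region set), and `grid_dim`.
#' @export
simulate_cohort <- function(config, atlas) {
  stopifnot(inherits(config, "sim_config"), inherits(atlas, "toy_atlas"))
  eff_ids <- unique(c(names(config$eloquent_effects), names(config$tract_effects)))
  unknown <- setdiff(as.integer(eff_ids), atlas$regions$region_id)
  if (length(unknown))
    stop_sim("effect map references unknown region id(s): ",
             paste(unknown, collapse = ", "))
  wm_ids <- atlas$regions$region_id[atlas$regions$tissue == "WM"]
  bad_tract <- setdiff(as.integer(names(config$tract_effects)), wm_ids)
  if (length(bad_tract))
    stop_sim("tract_effects references non-WM region(s): ",
             paste(bad_tract, collapse = ", "))

  reg_idx <- lapply(as.integer(names(config$eloquent_effects)),
                    function(id) region_voxels(atlas, id))
  names(reg_idx) <- names(config$eloquent_effects)
  tract_info <- lapply(as.integer(names(config$tract_effects)), function(id) {
    list(idx = region_voxels(atlas, id),
         axis = atlas$regions$axis[atlas$regions$region_id == id])
  })
  names(tract_info) <- names(config$tract_effects)

  n <- config$n_patients
  masks <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- with_seed(substream_seed(config$seed, i), {
      mask <- sample_lesion(atlas, config)
      cov <- draw_covariates(config)
      ov <- vapply(reg_idx, function(vx) overlap_fraction(mask, vx), numeric(1))
      it <- vapply(tract_info, function(tr)
        tract_integrity(mask, tr$idx, tr$axis, grid_dim = dim(mask)), numeric(1))
      sc <- simulate_outcomes(list(overlaps = ov, integrities = it), cov, config)
      list(mask = mask, cov = cov, sc = sc)
    })
    masks[[i]] <- res$mask
    rows[[i]] <- cbind(data.frame(patient_id = sprintf("p%04d", i)),
                       res$cov[, c("age", "sex")],
                       data.frame(nihss_baseline = res$sc[["nihss_baseline"]],
                                  nihss_48h = res$sc[["nihss_48h"]],
                                  nihss_30d = res$sc[["nihss_30d"]]),
                       res$cov[, setdiff(names(res$cov), c("age", "sex"))])
  }
  clinical <- do.call(rbind, rows)
  rownames(clinical) <- clinical$patient_id
  names(masks) <- clinical$patient_id

  eloquent <- sort(unique(as.integer(c(
    names(config$eloquent_effects)[config$eloquent_effects > 0],
    names(config$tract_effects)[config$tract_effects > 0]))))
  structure(list(clinical = clinical, masks = masks,
                 ground_truth = list(
                   eloquent_regions = eloquent,
                   eloquent_effects = as.list(config$eloquent_effects),
                   tract_effects = as.list(config$tract_effects),
                   baseline_intercept = config$baseline_intercept,
                   baseline_coef = config$baseline_coef,
                   baseline_mean = config$baseline_mean,
                   baseline_lesion_coef = config$baseline_lesion_coef,
                   baseline_noise_sd = config$baseline_noise_sd,
                   outcome_coefs = as.list(config$outcome_coefs),
                   noise_sd_48 = config$noise_sd_48,
                   noise_sd_30 = config$noise_sd_30,
                   seed = config$seed),
                 grid_dim = dim(atlas$labels)),
            class = "stroke_cohort")
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat(sprintf("Synthetic stroke cohort: %d patients on a %s grid\n",
              nrow(x$clinical), paste(x$grid_dim, collapse = " x ")))
  cat(sprintf("  median baseline NIHSS %s, 48h %s, 30d %s\n",
              stats::median(x$clinical$nihss_baseline),
              stats::median(x$clinical$nihss_48h),
              stats::median(x$clinical$nihss_30d)))
  cat("  eloquent regions:",
      if (length(x$ground_truth$eloquent_regions))
        paste(x$ground_truth$eloquent_regions, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Write / read a cohort on disk
#'
#' Layout: `clinical.csv` (header `patient_id,age,sex,nihss_baseline,
#' nihss_48h,nihss_30d,glucose,hematocrit,sbp,afib,htn,hld,dm,smoker,
#' treatment,onset_to_admission_min`), `ground_truth.json`, and one
#' `masks/<patient_id>_lesion.nii.gz` per patient. Output is byte-identical
#' across runs for a fixed seed.
#'
#' @param cohort A `stroke_cohort`.
#' @param dir Output directory.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `stroke_cohort` (with `ground_truth` if the JSON is present).
#' @export
write_cohort <- function(cohort, dir) {
  tryCatch({
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (pid in names(cohort$masks))
      RNifti::writeNifti(cohort$masks[[pid]],
                         file.path(dir, "masks", paste0(pid, "_lesion.nii.gz")))
  }, error = function(e) {
    if (inherits(e, "strokenest_io_error")) stop(e)
    stop_io("cohort write failed: ", conditionMessage(e))
  })
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "clinical.csv")
  if (!file.exists(csv)) stop_io("clinical.csv not found under ", dir)
  clinical <- utils::read.csv(csv, stringsAsFactors = FALSE)
  rownames(clinical) <- clinical$patient_id
  masks <- lapply(clinical$patient_id, function(pid) {
    f <- file.path(dir, "masks", paste0(pid, "_lesion.nii.gz"))
    if (!file.exists(f)) stop_io("missing lesion mask: ", f)
    vol <- RNifti::readNifti(f)
    array(as.integer(vol), dim = dim(vol))
  })
  names(masks) <- clinical$patient_id
  gt_file <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_file)) jsonlite::read_json(gt_file, simplifyVector = TRUE)
  structure(list(clinical = clinical, masks = masks, ground_truth = gt,
                 grid_dim = dim(masks[[1]])),
            class = "stroke_cohort")
}

#' Default eloquent-effect map and matching arterial territory
#'
#' Convenience for simulation studies: picks a compact cluster of `n_gm` GM
#' regions (seeded at the region nearest a lateralised anchor, then grown
#' by centroid proximity), assigns each effect weight `beta`, assigns
#' `gamma` to the nearest WM tract, and centres the high-incidence arterial
#' territory on the cluster — mirroring the fact that the regions supplied
#' by an artery are both where infarcts concentrate and where the deficit
#' arises.
#'
#' @param atlas A `toy_atlas`.
#' @param n_gm Number of eloquent GM regions.
#' @param beta Effect per unit overlap (NIHSS points).
#' @param gamma Effect per unit tract-integrity loss; 0 disables.
#' @return List with `eloquent_effects`, `tract_effects`,
#'   `territory_center`, and `territory_radius`, ready to splice into
#'   [simulation_config()].
#' @export
eloquent_defaults <- function(atlas, n_gm = 3L, beta = 8, gamma = 6) {
  d <- dim(atlas$labels)
  anchor <- d * c(0.30, 0.50, 0.55)
  centroids <- t(vapply(atlas$regions$region_id, function(id) {
    colMeans(arrayInd(region_voxels(atlas, id), d))
  }, numeric(3)))
  rownames(centroids) <- atlas$regions$region_id

  gm <- atlas$regions$region_id[atlas$regions$tissue == "GM"]
  gm_c <- centroids[as.character(gm), , drop = FALSE]
  seed_i <- which.min(colSums((t(gm_c) - anchor)^2))
  picked <- seed_i
  while (length(picked) < min(n_gm, length(gm))) {
    ctr <- colMeans(gm_c[picked, , drop = FALSE])
    rest <- setdiff(seq_along(gm), picked)
    picked <- c(picked, rest[which.min(colSums((t(gm_c[rest, , drop = FALSE]) - ctr)^2))])
  }
  gm_pick <- gm[picked]
  el <- stats::setNames(rep(beta, length(gm_pick)), gm_pick)

  ctr <- colMeans(gm_c[picked, , drop = FALSE])
  spread <- sqrt(max(colSums((t(gm_c[picked, , drop = FALSE]) - ctr)^2)))

  tr <- numeric(0)
  wm <- atlas$regions$region_id[atlas$regions$tissue == "WM"]
  if (gamma > 0 && length(wm)) {
    wm_c <- centroids[as.character(wm), , drop = FALSE]
    wm_pick <- wm[which.min(colSums((t(wm_c) - ctr)^2))]
    tr <- stats::setNames(gamma, wm_pick)
  }
  list(eloquent_effects = el, tract_effects = tr,
       territory_center = round(ctr),
       territory_radius = max(6, ceiling(spread)))
}

#' One-call study configuration
#'
#' Builds the default simulation setup used throughout the package's
#' simulation studies: a toy atlas effect map from [eloquent_defaults()]
#' spliced into a [simulation_config()].
#'
#' @param atlas A `toy_atlas`.
#' @param n_patients,seed Passed to [simulation_config()].
#' @param n_gm,beta,gamma Passed to [eloquent_defaults()].
#' @param ... Further overrides for [simulation_config()].
#' @return A `sim_config`.
#' @export
default_study_config <- function(atlas, n_patients = 200L, seed = 1L,
                                 n_gm = 3L, beta = 8, gamma = 6, ...) {
  eff <- eloquent_defaults(atlas, n_gm = n_gm, beta = beta, gamma = gamma)
  simulation_config(n_patients = n_patients, seed = seed,
                    eloquent_effects = eff$eloquent_effects,
                    tract_effects = eff$tract_effects,
                    territory_center = eff$territory_center,
                    territory_radius = eff$territory_radius, ...)
}
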
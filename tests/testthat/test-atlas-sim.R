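test_that("toy atlas satisfies its structural invariants", {
  atl <- make_toy_atlas(c(32, 32, 32), n_gm_regions = 6, n_wm_tracts = 2, seed = 1)
  expect_s3_class(atl, "toy_atlas")
  expect_equal(nrow(atl$regions), 8)

  labs <- sort(unique(as.vector(atl$labels)))
  expect_equal(setdiff(labs, 0L), sort(atl$regions$region_id))

  # disjointness is implied by a single label volume; check label counts > 0
  for (id in atl$regions$region_id)
    expect_gt(length(region_voxels(atl, id)), 0)

  # WM tracts contiguous along their axis: every spanned slice non-empty
  for (i in which(atl$regions$tissue == "WM")) {
    id <- atl$regions$region_id[i]
    ax <- match(atl$regions$axis[i], c("x", "y", "z"))
    co <- arrayInd(region_voxels(atl, id), dim(atl$labels))[, ax]
    expect_equal(sort(unique(co)), seq(min(co), max(co)))
  }

  expect_identical(atl$labels,
                   make_toy_atlas(c(32, 32, 32), 6, 2, seed = 1)$labels)
  expect_error(make_toy_atlas(c(16, 16, 16), n_gm_regions = 500, n_wm_tracts = 0),
               class = "strokenest_sim_error")
})

test_that("lesion sampling respects territory, size, and retry contracts", {
  atl <- fixture_atlas()
  # degenerate point territory with certain in-territory draws pins centres
  cfg <- simulation_config(n_patients = 10, seed = 1, territory_center = c(16, 16, 16),
                           territory_radius = 0, territory_prob = 1,
                           lesion_size_range = c(30, 30))
  set.seed(7)
  for (i in 1:5) {
    m <- sample_lesion(atl, cfg)
    expect_equal(attr(m, "pre_clip_size"), 30)
    expect_equal(sum(m), 30)           # interior centre: no clipping
    expect_true(m[16, 16, 16] == 1L)   # centre voxel always lesioned
  }

  # lesions cluster in the territory more than in its mirror image
  cfg2 <- simulation_config(n_patients = 10, seed = 1,
                            territory_center = c(10, 16, 16), territory_radius = 6)
  d <- dim(atl$labels)
  ball <- function(ctr, r) {
    g <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
    which(colSums((t(g) - ctr)^2) <= r^2)
  }
  terr <- ball(c(10, 16, 16), 6)
  mirror <- ball(c(23, 16, 16), 6)
  set.seed(11)
  ov_t <- ov_m <- 0
  for (i in 1:200) {
    m <- sample_lesion(atl, cfg2)
    ov_t <- ov_t + sum(m[terr]); ov_m <- ov_m + sum(m[mirror])
  }
  expect_gt(ov_t, ov_m)
})

test_that("outcome chain follows the generative arithmetic and clips", {
  atl <- fixture_atlas()
  id1 <- atl$regions$region_id[1]
  mk_cfg <- function(...) simulation_config(
    n_patients = 10, seed = 1, baseline_intercept = 0, baseline_coef = 1,
    outcome_coefs = c(intercept = 0, nihss_48h = 1),
    noise_sd_48 = 0, noise_sd_30 = 0, ...)

  # identity chain: all effects zero
  sc <- simulate_outcomes(list(), list(nihss_baseline = 15), mk_cfg())
  expect_identical(unname(sc), c(15L, 15L, 15L))

  # linear arithmetic: beta 10 on overlap 0.5 adds 5 points
  cfg <- mk_cfg(eloquent_effects = stats::setNames(10, id1))
  sc2 <- simulate_outcomes(list(overlaps = stats::setNames(0.5, id1)),
                           list(nihss_baseline = 15), cfg)
  expect_equal(unname(sc2[["nihss_48h"]]), 20L)

  # clip floor at 0: negative raw score
  cfg3 <- simulation_config(n_patients = 10, seed = 1, baseline_intercept = -10,
                            baseline_coef = 1,
                            outcome_coefs = c(intercept = -99, nihss_48h = 1),
                            noise_sd_48 = 0, noise_sd_30 = 0)
  sc3 <- simulate_outcomes(list(), list(nihss_baseline = 6), cfg3)
  expect_equal(unname(sc3[["nihss_48h"]]), 0L)
  expect_equal(unname(sc3[["nihss_30d"]]), 0L)

  expect_error(simulate_outcomes(list(overlaps = stats::setNames(1.5, id1)),
                                 list(nihss_baseline = 10), cfg),
               "overlaps")
})

test_that("cohorts are deterministic, valid, and stable under growth", {
  atl <- fixture_atlas()
  cfg <- default_study_config(atl, n_patients = 20, seed = 7)
  co1 <- simulate_cohort(cfg, atl)
  co2 <- simulate_cohort(cfg, atl)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(co1$masks, co2$masks)

  for (col in c("nihss_baseline", "nihss_48h", "nihss_30d")) {
    v <- co1$clinical[[col]]
    expect_true(all(v == round(v) & v >= 0 & v <= 42))
  }
  expect_true(all(vapply(co1$masks, sum, numeric(1)) > 0))

  # per-patient sub-streams: enlarging the cohort keeps earlier patients
  cfg_big <- default_study_config(atl, n_patients = 25, seed = 7)
  co_big <- simulate_cohort(cfg_big, atl)
  expect_identical(co_big$clinical[1:20, ], co1$clinical)
  expect_identical(co_big$masks[1:20], co1$masks)

  # unknown effect region rejected
  bad <- simulation_config(n_patients = 10, seed = 1,
                           eloquent_effects = c("999" = 5))
  expect_error(simulate_cohort(bad, atl), class = "strokenest_sim_error")

  # ground truth lists exactly the regions with positive effects
  expect_setequal(co1$ground_truth$eloquent_regions,
                  as.integer(c(names(cfg$eloquent_effects)[cfg$eloquent_effects > 0],
                               names(cfg$tract_effects)[cfg$tract_effects > 0])))
})

test_that("zero-effect zero-noise cohorts tie 48h NIHSS to baseline only", {
  atl <- fixture_atlas()
  cfg <- simulation_config(n_patients = 120, seed = 3, noise_sd_48 = 0,
                           territory_center = c(10, 16, 18), territory_radius = 8)
  co <- simulate_cohort(cfg, atl)
  cl <- co$clinical
  resid <- cl$nihss_48h - cfg$baseline_coef * cl$nihss_baseline
  # the residual is pure rounding noise: one SD of any overlap feature
  # shifts the fitted residual by less than the rounding half-step
  expect_lte(max(abs(resid)), 0.5)
  fm <- build_feature_matrix(co, atl, atl$regions$region_id[1:4])
  for (j in seq_len(ncol(fm$values))) {
    x <- fm$values[, j]
    if (stats::sd(x) > 0)
      expect_lt(abs(stats::coef(stats::lm(resid ~ x))[2]) * stats::sd(x), 0.5)
  }
})

test_that("least squares on a noise-free cohort recovers the generative betas", {
  atl <- fixture_atlas()
  eff <- eloquent_defaults(atl)
  cfg <- simulation_config(n_patients = 200, seed = 5,
                           eloquent_effects = eff$eloquent_effects,
                           tract_effects = numeric(0),
                           territory_center = eff$territory_center,
                           territory_radius = eff$territory_radius,
                           noise_sd_48 = 0, noise_sd_30 = 0)
  co <- simulate_cohort(cfg, atl)
  ids <- as.integer(names(cfg$eloquent_effects))
  fm <- build_feature_matrix(co, atl, ids)
  ov <- fm$values[, sprintf("r%03d_gm_overlap", ids), drop = FALSE]
  y <- co$clinical$nihss_48h - cfg$baseline_coef * co$clinical$nihss_baseline
  beta_hat <- stats::coef(stats::lm(y ~ ov))[-1]
  expect_true(all(abs(beta_hat - cfg$eloquent_effects) <= 0.5))
})

test_that("cohort and atlas round-trip through disk byte-identically", {
  atl <- make_toy_atlas(c(32, 32, 32), n_gm_regions = 4, n_wm_tracts = 1, seed = 2)
  cfg <- default_study_config(atl, n_patients = 12, seed = 9)
  co <- simulate_cohort(cfg, atl)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(co, d1); write_cohort(co, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))

  co_rt <- read_cohort(d1)
  expect_identical(co_rt$clinical, co$clinical)
  expect_identical(lapply(co_rt$masks, as.integer), lapply(co$masks, as.integer))

  da <- file.path(tempdir(), "atl1")
  write_atlas(atl, da)
  atl_rt <- read_atlas(da)
  expect_identical(atl_rt$labels, atl$labels)
  expect_identical(atl_rt$regions$region_id, atl$regions$region_id)
  expect_error(read_cohort(file.path(tempdir(), "nope")),
               class = "strokenest_io_error")
  unlink(c(d1, d2, da), recursive = TRUE)
})
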
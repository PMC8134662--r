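test_that("bm_test reproduces hand-derived and oracle values", {
  # symmetry: identical samples give W = 0, p = 1
  r <- bm_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # frozen values from the mid-rank formulas evaluated by hand
  r2 <- bm_test(c(1, 2, 4, 5, 8), c(3, 6, 7, 9, 10))
  expect_equal(r2$statistic, 1.9364916731037, tolerance = 1e-10)
  expect_equal(r2$df, 8, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.0888261521115, tolerance = 1e-9)

  # complete separation: zero rank variance on both sides
  r3 <- bm_test(c(1, 2, 3), c(10, 11, 12))
  expect_true(r3$degenerate)

  expect_error(bm_test(1, c(1, 2, 3)), "at least 2")
})

test_that("bm_test matches the brute-force mid-rank oracle on random inputs", {
  set.seed(8)
  for (i in 1:300) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    tie <- runif(1) < 0.5
    x <- if (tie) sample(0:8, n1, replace = TRUE) else rnorm(n1)
    y <- if (tie) sample(0:8, n2, replace = TRUE) else rnorm(n2)
    o <- oracle_bm(x, y)
    r <- bm_test(x, y)
    expect_identical(r$degenerate, o$degenerate)
    if (!o$degenerate) {
      expect_equal(r$statistic, o$W, tolerance = 1e-10)
      expect_equal(r$df, o$df, tolerance = 1e-10)
      expect_equal(r$p.value, o$p, tolerance = 1e-10)
      # swapping groups negates W, preserves p
      rs <- bm_test(y, x)
      expect_equal(rs$statistic, -r$statistic, tolerance = 1e-12)
      expect_equal(rs$p.value, r$p.value, tolerance = 1e-12)
    }
  }
})

test_that("fdr_adjust is BH step-up, order-preserving, and bounded by p", {
  expect_equal(fdr_adjust(0.05), 0.05)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(12)
  for (i in 1:100) {
    p <- runif(sample(1:100, 1))
    q <- fdr_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # order preservation
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("bm_map groups patients per voxel and applies the filters", {
  d <- c(8L, 8L, 8L)
  # identical lesion in all patients: nothing testable (no intact group
  # inside lesion, no lesioned group outside)
  same <- blank_mask(d); same[1:40] <- 1L
  masks <- lapply(1:10, function(i) same)
  sm <- bm_map(masks, rnorm(10))
  expect_equal(sum(sm$tested), 0)

  # voxel lesioned in 1 of 20 patients fails the 10% coverage rule
  masks2 <- lapply(1:20, function(i) blank_mask(d))
  masks2[[1]][1] <- 1L
  for (i in 1:20) masks2[[i]][2] <- as.integer(i <= 10)
  sm2 <- bm_map(masks2, rnorm(20))
  expect_false(sm2$tested[1])
  expect_true(sm2$tested[2])

  # the tested voxel's statistic equals a direct bm_test on its grouping
  scores <- c(rnorm(10, 5), rnorm(10, 0))
  sm3 <- bm_map(masks2, scores)
  direct <- bm_test(scores[1:10], scores[11:20])
  expect_equal(sm3$statistic[2], direct$statistic, tolerance = 1e-12)
  expect_equal(sm3$p[2], direct$p.value, tolerance = 1e-12)

  expect_error(bm_map(masks2[1:3], rnorm(3)), "at least 4")
})

test_that("label swapping leaves the LSM maps unchanged", {
  co <- fixture_cohort(n = 40, seed = 31)
  scores <- co$clinical$nihss_48h
  sm <- bm_map(co$masks, scores)
  # swapping lesioned/intact at every voxel = flipping all masks
  flipped <- lapply(co$masks, function(m) 1L - m)
  # flipped masks change coverage; restrict to voxels tested in both
  sm_f <- bm_map(flipped, scores, coverage_threshold = 1e-9)
  both <- sm$tested & sm_f$tested
  expect_gt(sum(both), 0)
  expect_equal(abs(sm$statistic[both]), abs(sm_f$statistic[both]),
               tolerance = 1e-12)
  expect_equal(sm$p[both], sm_f$p[both], tolerance = 1e-12)
})

test_that("thresholding and ROI mapping follow the weight rules", {
  d <- c(8L, 8L, 8L)
  sm <- structure(list(
    tested = array(FALSE, d), statistic = array(NA_real_, d),
    p = array(NA_real_, d), q = array(NA_real_, d),
    degenerate = array(FALSE, d), n_patients = 20), class = "voxel_stat_map")
  sm$tested[1:4] <- TRUE
  sm$statistic[1:4] <- c(-3.2, 1.0, 2.0, 0.5)
  sm$q[1:4] <- c(0.01, 0.20, 0.80, 0.99)

  w <- threshold_to_weights(sm, alpha = 0.05)
  expect_equal(w[1], 3.2)        # absolute value of a negative statistic
  expect_equal(sum(w != 0), 1)

  w1 <- threshold_to_weights(sm, alpha = 1)
  expect_equal(sum(w1 != 0), 4)  # all non-degenerate tested voxels

  sm$q[1:4] <- 0.5
  expect_equal(sum(threshold_to_weights(sm, alpha = 0.05)), 0)

  atl <- list(labels = array(0L, d),
              regions = data.frame(region_id = c(3L, 5L, 7L),
                                   name = c("a", "b", "c"), tissue = "GM",
                                   axis = NA))
  class(atl) <- "toy_atlas"
  atl$labels[1:2] <- 3L; atl$labels[3] <- 7L; atl$labels[10] <- 5L
  wz <- array(0, d)
  expect_identical(lsm_rois(wz, atl), integer(0))
  wz[1] <- 2
  expect_identical(lsm_rois(wz, atl), 3L)
  wz[3] <- 1
  expect_identical(lsm_rois(wz, atl), c(3L, 7L))
})

test_that("null cohorts keep the tested-voxel false-positive rate near alpha", {
  # permuted outcomes sever any lesion-outcome link; check raw p calibration
  atl <- fixture_atlas()
  cfg <- default_study_config(atl, n_patients = 100, seed = 77)
  co <- simulate_cohort(cfg, atl)
  fp <- q_hits <- 0; n_tested <- 0
  set.seed(123)
  for (i in 1:10) {
    scores <- sample(co$clinical$nihss_48h)
    sm <- bm_map(co$masks, scores)
    ok <- sm$tested & !sm$degenerate
    fp <- fp + sum(sm$p[ok] < 0.05)
    q_hits <- q_hits + sum(sm$q[ok] <= 0.05)
    n_tested <- n_tested + sum(ok)
  }
  expect_lt(fp / n_tested, 0.08)   # ~0.05 within Monte-Carlo slack
  expect_gt(fp / n_tested, 0.02)
  expect_lte(q_hits / n_tested, 0.01)  # FDR strongly controls the null
})
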
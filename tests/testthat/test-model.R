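test_that("stratified split preserves severity representation and counts", {
  set.seed(1)
  y <- sample(0:42, 100, replace = TRUE)
  sp <- stratified_split(y, seed = 5)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$test), 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))

  # per-stratum train fraction within one patient of 80%
  for (s in unique(sp$strata)) {
    members <- which(sp$strata == s)
    n_tr <- sum(members %in% sp$train)
    expect_lte(abs(n_tr - 0.8 * length(members)), 1)
  }

  expect_identical(stratified_split(y, seed = 5), sp)
  expect_false(identical(stratified_split(y, seed = 6)$train, sp$train))

  # n = 221 gives the documented 177/44 partition
  y2 <- sample(0:42, 221, replace = TRUE)
  sp2 <- stratified_split(y2, seed = 2)
  expect_equal(length(sp2$test), 44)
  expect_equal(length(sp2$train), 177)

  # named outcomes propagate ids
  names(y) <- sprintf("p%03d", seq_along(y))
  sp3 <- stratified_split(y, seed = 5)
  expect_true(all(grepl("^p", sp3$train)))
})

test_that("undersized strata are merged with a warning", {
  # heavy ties collapse the quartile breaks so the top bin holds 1 patient
  y <- c(rep(0, 20), rep(10, 9), 20)
  expect_warning(sp <- stratified_split(y, n_bins = 4, seed = 1), "merging")
  expect_equal(length(sp$train) + length(sp$test), 30)
})

test_that("fit_svr standardizes, drops constants, and is reproducible", {
  set.seed(3)
  n <- 50
  X <- cbind(x1 = runif(n), flat = rep(2, n))
  y <- 2 * X[, "x1"]
  expect_warning(fit <- fit_svr(X, y), "zero-variance")
  expect_identical(fit$features, "x1")

  # easy function: training MAE well inside the epsilon tube scale
  pred <- predict(fit, X)
  expect_lt(mean(abs(pred - y)), 0.2)

  fit2 <- suppressWarnings(fit_svr(X, y))
  expect_identical(predict(fit2, X), pred)

  # duplicated rows predict identically
  Xd <- X[c(1, 1, 2:n), ]; yd <- y[c(1, 1, 2:n)]
  fd <- suppressWarnings(fit_svr(Xd, yd))
  pd <- predict(fd, Xd)
  expect_identical(pd[1], pd[2])

  expect_error(fit_svr(X, rep(1, n)), "constant")
  expect_error(predict(fit, matrix(1, 2, 1, dimnames = list(NULL, "other"))),
               "missing feature")
})

test_that("nested fit wires inner predictions into the outer model", {
  co <- fixture_cohort(n = 80, seed = 55)
  atl <- fixture_atlas()
  cl <- co$clinical
  y48 <- stats::setNames(as.numeric(cl$nihss_48h), cl$patient_id)
  y30 <- stats::setNames(as.numeric(cl$nihss_30d), cl$patient_id)
  clinX <- clinical_features(co)$values
  sp <- stratified_split(y30, seed = 9)

  fm <- build_feature_matrix(co, atl, co$ground_truth$eloquent_regions)
  fit <- fit_nested(clinX, fm$values, y48, y30, sp$train)
  expect_s3_class(fit, "nested_svr")
  # outer input dimension = clinical features + 1
  expect_equal(length(fit$outer$features),
               length(fit$clinical_features) + 1)
  expect_true("nihss_48h_pred" %in% fit$outer$features)

  pr <- predict(fit, clinX, fm$values, ids = sp$test)
  expect_equal(nrow(pr), length(sp$test))
  expect_true(all(pr$predicted >= 0 & pr$predicted <= 42))
  expect_identical(predict(fit, clinX, fm$values, ids = sp$test), pr)

  # all-zero imaging features collapse to the clinical-plus-constant model
  z <- matrix(0, nrow(clinX), 3,
              dimnames = list(rownames(clinX), c("za", "zb", "zc")))
  fit0 <- suppressWarnings(fit_nested(clinX, z, y48, y30, sp$train,
                                      inner_oof = FALSE))
  const_col <- matrix(mean(y48[sp$train]), nrow(clinX), 1,
                      dimnames = list(rownames(clinX), "nihss_48h_pred"))
  ref <- suppressWarnings(
    fit_svr(cbind(clinX[sp$train, ], const_col[sp$train, , drop = FALSE]),
            y30[sp$train]))
  pr0 <- predict(fit0, clinX, z, ids = sp$test)
  pr_ref <- pmin(pmax(predict(
    ref, cbind(clinX[sp$test, ], const_col[sp$test, , drop = FALSE])), 0), 42)
  expect_equal(pr0$predicted, pr_ref, tolerance = 1e-6)

  expect_error(fit_nested(clinX, fm$values, y48, y30, train_ids = "p0001"),
               "at least 2")

  # empty imaging set warns and degenerates to a training-mean inner model
  e <- matrix(numeric(0), nrow(clinX), 0, dimnames = list(rownames(clinX), NULL))
  # the constant inner prediction is then dropped by the outer fit, too
  expect_warning(
    expect_warning(fit_e <- fit_nested(clinX, e, y48, y30, sp$train),
                   "empty imaging"),
    "zero-variance")
  expect_equal(length(fit_e$inner$features), 0)
})

test_that("nested model beats the mean predictor on a noise-free cohort", {
  atl <- fixture_atlas()
  cfg <- default_study_config(atl, n_patients = 60, seed = 91,
                              noise_sd_48 = 0, noise_sd_30 = 0)
  co <- simulate_cohort(cfg, atl)
  cl <- co$clinical
  y48 <- stats::setNames(as.numeric(cl$nihss_48h), cl$patient_id)
  y30 <- stats::setNames(as.numeric(cl$nihss_30d), cl$patient_id)
  clinX <- clinical_features(co)$values
  fm <- build_feature_matrix(co, atl, co$ground_truth$eloquent_regions)
  ids <- cl$patient_id
  fit <- fit_nested(clinX, fm$values, y48, y30, ids)
  pr <- predict(fit, clinX, fm$values, ids = ids)
  mae_fit <- mean(abs(pr$predicted - y30))
  mae_mean <- mean(abs(mean(y30) - y30))
  expect_lt(mae_fit, mae_mean)
})

test_that("clinical-only arm respects the selected feature subset", {
  co <- fixture_cohort(n = 60, seed = 65)
  cl <- co$clinical
  y30 <- stats::setNames(as.numeric(cl$nihss_30d), cl$patient_id)
  clinX <- clinical_features(co)$values
  sel <- c("age", "nihss_baseline", "glucose")
  fit <- fit_clinical_only(clinX, y30, cl$patient_id[1:48], features = sel)
  expect_true(all(fit$features %in% sel))
  expect_error(fit_clinical_only(clinX, y30, cl$patient_id[1:48],
                                 features = "not_a_column"),
               "missing clinical")
})
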
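# Metrics, between-model comparison, and the end-to-end experiment driver
# comparing the clinical-only, RReliefF-selected, and LSM-selected arms.

#' Prediction error metrics
#'
#' `mae` is the mean absolute error, `rmse` the root mean squared error,
#' and `r2` the coefficient of determination `1 - SSres/SStot` computed on
#' the evaluation set (it can be negative; it is not a squared
#' correlation). Jensen's inequality guarantees `mae <= rmse`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single number.
#' @export
mae <- function(observed, predicted) {
  check_pair(observed, predicted)
  mean(abs(observed - predicted))
}

#' @rdname mae
#' @export
rmse <- function(observed, predicted) {
  check_pair(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname mae
#' @export
r2 <- function(observed, predicted) {
  check_pair(observed, predicted)
  if (length(unique(observed)) < 2L)
    stop("R^2 undefined for constant observed values")
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

check_pair <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 observations")
  invisible(TRUE)
}

#' Significance of the predicted-observed association
#'
#' Two-sided test of zero linear (Pearson) association between predictions
#' and observations on the evaluation set. Constant predictions carry no
#' association and return p = 1 with a warning.
#'
#' @param observed,predicted Numeric vectors, length >= 3.
#' @return p-value in (0,1\].
#' @export
model_pvalue <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3L) stop("need at least 3 observations")
  if (length(unique(predicted)) < 2L) {
    warning("constant predictions: association test degenerate, p = 1")
    return(1)
  }
  if (length(unique(observed)) < 2L) {
    warning("constant observations: association test degenerate, p = 1")
    return(1)
  }
  stats::cor.test(observed, predicted, method = "pearson",
                  alternative = "two.sided")$p.value
}

#' Paired comparison of per-patient absolute errors
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-patient absolute
#' errors of two models evaluated on the same patients (normal
#' approximation with continuity correction, robust to the ties that
#' integer NIHSS errors produce). All-zero differences give p = 1.
#'
#' @param abs_errors_a,abs_errors_b Paired numeric vectors.
#' @return p-value in (0,1\].
#' @export
compare_mae <- function(abs_errors_a, abs_errors_b) {
  if (length(abs_errors_a) != length(abs_errors_b)) stop("length mismatch")
  d <- abs_errors_a - abs_errors_b
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(abs_errors_a, abs_errors_b, paired = TRUE,
                       exact = FALSE, correct = TRUE)$p.value)
}

#' Run the three-arm outcome-prediction experiment
#'
#' End-to-end driver: severity-stratified 80/20 split; clinical feature
#' selection by RReliefF against the 30-day NIHSS on training rows;
#' imaging region selection per arm on training rows only — RReliefF on
#' region-level features or voxel-wise LSM, both targeting the 48-hour
#' NIHSS (never the 30-day outcome, so selected structure-function
#' relationships reflect the primary deficit); nested fits; test-set
#' metrics and pairwise MAE comparisons.
#'
#' @param cohort A `stroke_cohort`.
#' @param atlas The `toy_atlas` the cohort was simulated on.
#' @param seed Integer seed driving the split and RReliefF sampling.
#' @param arms Arms to run, subset of `c("clinical", "relief", "lsm")`.
#' @param alpha FDR threshold of the LSM arm.
#' @param coverage Lesion-coverage threshold (both arms); default 0.10.
#' @param relieff_m,relieff_k RReliefF sample size and neighbor count
#'   (defaults 10 and 5).
#' @param relieff_exhaustive Use the deterministic full pass over all
#'   training instances instead of sampling `relieff_m` of them. The
#'   sampled default is faithful to small-sample practice but high-variance;
#'   exhaustive mode is the reproducible choice for simulation studies.
#' @param train_frac,n_bins Split parameters.
#' @param split Optional pre-computed `split_spec` (then `train_frac`,
#'   `n_bins` and the split part of `seed` are ignored).
#' @param inner_oof Passed to [fit_nested()].
#' @param cost,epsilon,gamma SVR hyperparameters shared by all arms.
#' @return Object of class `evaluation_report`: `metrics` (one row per arm:
#'   `model`, `n_rois`, `n_features`, `mae`, `rmse`, `r2`, `p_value`),
#'   `comparisons` (pairwise MAE-difference p-values), `predictions`
#'   (per-arm test-set data frames), `meta`.
#' @export
run_experiment <- function(cohort, atlas, seed = 1L,
                           arms = c("clinical", "relief", "lsm"),
                           alpha = 0.05, coverage = 0.10,
                           relieff_m = 10L, relieff_k = 5L,
                           relieff_exhaustive = FALSE,
                           train_frac = 0.8, n_bins = 4L, split = NULL,
                           inner_oof = TRUE,
                           cost = 1, epsilon = 0.1, gamma = NULL) {
  arms <- match.arg(arms, several.ok = TRUE)
  cl <- cohort$clinical
  y30 <- stats::setNames(as.numeric(cl$nihss_30d), cl$patient_id)
  y48 <- stats::setNames(as.numeric(cl$nihss_48h), cl$patient_id)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  split <- split %||% stage("split",
    stratified_split(y30, train_frac = train_frac, n_bins = n_bins, seed = seed))
  tr <- split$train
  te <- split$test

  clin_fm <- stage("clinical_features", clinical_features(cohort))
  clinX <- clin_fm$values

  # clinical feature selection on training rows (targets the 30-day score
  # it will be asked to predict)
  clin_sel <- stage("clinical_selection", {
    w <- rrelieff(clinX[tr, , drop = FALSE], y30[tr], m = relieff_m,
                  k = relieff_k, seed = substream_seed(seed, 101),
                  exhaustive = relieff_exhaustive)
    s <- select_features(w, rule = "positive")
    if (!length(s)) {
      warning("RReliefF selected no clinical features; keeping all")
      s <- colnames(clinX)
    }
    s
  })

  train_masks <- cohort$masks[tr]
  fits <- list(); preds <- list(); rois <- list()

  if ("clinical" %in% arms) {
    fits$clinical <- stage("fit_clinical",
      fit_clinical_only(clinX, y30, tr, features = clin_sel,
                        cost = cost, epsilon = epsilon, gamma = gamma))
    p <- clamp(predict(fits$clinical, clinX[te, clin_sel, drop = FALSE]),
               NIHSS_MIN, NIHSS_MAX)
    preds$clinical <- data.frame(patient_id = te, observed = y30[te],
                                 predicted = p, row.names = NULL)
    rois$clinical <- integer(0)
  }

  nested_arm <- function(region_ids, label) {
    fm <- stage(paste0(label, "_features"),
                build_feature_matrix(cohort, atlas, region_ids))
    fit <- stage(paste0(label, "_fit"), suppressWarnings(
      fit_nested(clinX[, clin_sel, drop = FALSE], fm$values, y48, y30, tr,
                 inner_oof = inner_oof, cost = cost, epsilon = epsilon,
                 gamma = gamma)))
    pr <- predict(fit, clinX[, clin_sel, drop = FALSE], fm$values, ids = te)
    pr$observed <- y30[te]
    list(fit = fit, pred = pr)
  }

  if ("relief" %in% arms) {
    rois$relief <- stage("relief_selection", {
      cand <- coverage_filter(train_masks, unit = "region", atlas = atlas,
                              threshold = coverage)
      if (!length(cand)) integer(0) else {
        fm_tr <- build_feature_matrix(train_masks, atlas, cand)
        w <- rrelieff(fm_tr$values, y48[tr], m = relieff_m, k = relieff_k,
                      seed = substream_seed(seed, 202),
                      exhaustive = relieff_exhaustive)
        sel_cols <- select_features(w, rule = "positive")
        sort(unique(fm_tr$manifest$region_id[fm_tr$manifest$name %in% sel_cols]))
      }
    })
    res <- nested_arm(rois$relief, "relief")
    fits$relief <- res$fit; preds$relief <- res$pred
  }

  if ("lsm" %in% arms) {
    rois$lsm <- stage("lsm_selection",
      run_lsm(train_masks, y48[tr], atlas, alpha = alpha,
              coverage_threshold = coverage)$roi_ids)
    res <- nested_arm(rois$lsm, "lsm")
    fits$lsm <- res$fit; preds$lsm <- res$pred
  }

  metrics <- do.call(rbind, lapply(names(preds), function(a) {
    pr <- preds[[a]]
    data.frame(model = model_label(a),
               n_rois = length(rois[[a]]),
               n_features = if (a == "clinical") length(clin_sel) else
                 length(fits[[a]]$imaging_features),
               mae = mae(pr$observed, pr$predicted),
               rmse = rmse(pr$observed, pr$predicted),
               r2 = r2(pr$observed, pr$predicted),
               p_value = suppressWarnings(model_pvalue(pr$observed, pr$predicted)))
  }))

  combos <- utils::combn(names(preds), 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(combos, function(ab) {
    ea <- abs(preds[[ab[1]]]$observed - preds[[ab[1]]]$predicted)
    eb <- abs(preds[[ab[2]]]$observed - preds[[ab[2]]]$predicted)
    data.frame(model_a = model_label(ab[1]), model_b = model_label(ab[2]),
               p_value = compare_mae(ea, eb))
  }))

  structure(list(metrics = metrics, comparisons = comparisons,
                 predictions = preds,
                 roi_ids = rois,
                 meta = list(n = nrow(cl), n_train = length(tr),
                             n_test = length(te), seed = seed,
                             alpha = alpha, coverage = coverage,
                             relieff_m = relieff_m, relieff_k = relieff_k,
                             clinical_features = clin_sel)),
            class = "evaluation_report")
}

model_label <- function(a) {
  c(clinical = "M_CLINICAL", relief = "M_RELIEF", lsm = "M_LSM")[[a]]
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Stroke outcome prediction report (n = %d, test n = %d, seed %d)\n\n",
              x$meta$n, x$meta$n_test, x$meta$seed))
  m <- x$metrics
  tab <- data.frame(Model = m$model, ROIs = m$n_rois,
                    MAE = round(m$mae, digits), RMSE = round(m$rmse, digits),
                    `R2` = round(m$r2, digits),
                    `p-value` = signif(m$p_value, 3), check.names = FALSE)
  print(tab, row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\nPaired MAE comparisons (Wilcoxon signed-rank):\n")
    cmp <- x$comparisons
    cmp$p_value <- signif(cmp$p_value, 3)
    print(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(metrics = report$metrics, comparisons = report$comparisons,
              roi_ids = report$roi_ids, meta = report$meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
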
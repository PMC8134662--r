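# Nested two-stage epsilon-SVR: inner model maps imaging features to the
# 48-hour NIHSS; the outer model maps clinical features plus the inner
# prediction to the 30-day NIHSS. Standardization constants always come
# from training rows only.

#' Severity-stratified train/test split
#'
#' Patients are binned into quantile strata of the outcome (default
#' quartiles of 30-day NIHSS) so that both subsets preserve the
#' representation of stroke severity; sampling is without replacement
#' within strata. Per-stratum train counts use nearest-integer allocation
#' with largest-remainder correction so the global train size is exactly
#' `round(train_frac * n)`.
#'
#' @param y Outcome values (names, if present, become the returned ids).
#' @param train_frac Training fraction in (0,1); default 0.8.
#' @param n_bins Number of quantile strata; default 4. Strata with fewer
#'   than 2 patients are merged into their lower neighbor with a warning.
#' @param seed Integer seed.
#' @return Object of class `split_spec`: `train`, `test` (ids or indices),
#'   `strata` (per patient), `seed`.
#' @export
stratified_split <- function(y, train_frac = 0.8, n_bins = 4L, seed = 1L) {
  n <- length(y)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  if (n < 2L * n_bins) stop("need at least 2 patients per stratum")
  ids <- names(y) %||% seq_len(n)

  breaks <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
  strata <- if (length(breaks) < 2L) rep(1L, n) else
    as.integer(cut(y, breaks, include.lowest = TRUE, labels = FALSE))

  # merge undersized strata downward
  repeat {
    sizes <- table(factor(strata, levels = sort(unique(strata))))
    small <- as.integer(names(sizes))[sizes < 2L]
    if (!length(small)) break
    s <- small[1]
    lv <- sort(unique(strata))
    tgt <- if (s == min(lv)) lv[which(lv == s) + 1L] else lv[which(lv == s) - 1L]
    warning("merging undersized severity stratum ", s, " into ", tgt)
    strata[strata == s] <- tgt
  }

  n_train <- round(train_frac * n)
  lv <- sort(unique(strata))
  sizes <- vapply(lv, function(s) sum(strata == s), integer(1))
  target <- train_frac * sizes
  base <- floor(target)
  rem <- n_train - sum(base)
  extra <- integer(length(lv))
  if (rem > 0) {
    ord <- order(-(target - base), lv)
    extra[ord[seq_len(rem)]] <- 1L
  } else if (rem < 0) {
    ord <- order(target - base, lv)
    take <- ord[seq_len(-rem)]
    base[take] <- base[take] - 1L
  }
  counts <- base + extra

  train_idx <- with_seed(seed, {
    picked <- integer(0)
    for (si in seq_along(lv)) {
      members <- which(strata == lv[si])
      picked <- c(picked, members[sample.int(length(members), counts[si])])
    }
    picked
  })
  train_idx <- sort(train_idx)
  structure(list(train = ids[train_idx], test = ids[setdiff(seq_len(n), train_idx)],
                 strata = stats::setNames(strata, ids), seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Stratified split: %d train / %d test (seed %d, %d strata)\n",
              length(x$train), length(x$test), x$seed,
              length(unique(x$strata))))
  invisible(x)
}

#' Fit an epsilon-SVR with radial-basis kernel
#'
#' Thin wrapper around [e1071::svm()] that standardizes inputs with
#' training-set mean/SD, drops zero-variance columns with a warning, and
#' records the manifest needed to apply the model to new rows by column
#' name. With zero usable columns the fit degenerates to a constant
#' training-mean predictor (with a warning).
#'
#' @param X Numeric matrix, rows = patients (rownames kept as ids).
#' @param y Numeric response; needs at least 2 distinct values.
#' @param cost,epsilon SVR hyperparameters (defaults 1 and 0.1).
#' @param gamma RBF kernel width; default `1/ncol(X)` on the standardized
#'   inputs (i.e. 1 / (d * feature variance)).
#' @return Object of class `svr_fit`.
#' @export
fit_svr <- function(X, y, cost = 1, epsilon = 0.1, gamma = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(y)) < 2L) stop("response is constant; nothing to fit")
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (nrow(X) < 2L) stop("need at least 2 training rows")

  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped))
    warning("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
  keep <- sds > 0
  Xk <- X[, keep, drop = FALSE]

  if (ncol(Xk) == 0L) {
    warning("no usable features; fitting a constant mean predictor")
    return(structure(list(model = NULL, constant = mean(y),
                          features = character(0), dropped = dropped,
                          center = numeric(0), scale = numeric(0),
                          hyper = list(cost = cost, epsilon = epsilon,
                                       gamma = NA_real_)),
                     class = "svr_fit"))
  }
  ctr <- colMeans(Xk)
  scl <- apply(Xk, 2, stats::sd)
  Xs <- scale(Xk, center = ctr, scale = scl)
  gamma <- gamma %||% (1 / ncol(Xs))
  model <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                      kernel = "radial", cost = cost, epsilon = epsilon,
                      gamma = gamma, scale = FALSE)
  structure(list(model = model, constant = NULL, features = colnames(Xk),
                 dropped = dropped, center = ctr, scale = scl,
                 hyper = list(cost = cost, epsilon = epsilon, gamma = gamma)),
            class = "svr_fit")
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  if (length(object$features) == 0L)
    return(rep(object$constant, nrow(as.matrix(newdata))))
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$features, colnames(newdata))
  if (length(missing_cols))
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  Xs <- scale(newdata[, object$features, drop = FALSE],
              center = object$center, scale = object$scale)
  as.numeric(stats::predict(object$model, Xs))
}

#' @export
print.svr_fit <- function(x, ...) {
  if (length(x$features) == 0L) {
    cat(sprintf("Degenerate SVR fit: constant predictor %.3f\n", x$constant))
  } else {
    cat(sprintf("epsilon-SVR (RBF): %d features, cost %g, epsilon %g, gamma %.4g\n",
                length(x$features), x$hyper$cost, x$hyper$epsilon, x$hyper$gamma))
  }
  invisible(x)
}

# Deterministic balanced folds over training rows, stratified on the inner
# target so each fold sees the severity range.
make_folds <- function(y, n_folds) {
  ((rank(y, ties.method = "first") - 1L) %% n_folds) + 1L
}

#' Fit the nested two-stage outcome model
#'
#' The inner epsilon-SVR maps imaging features to the 48-hour NIHSS; its
#' predictions then join the clinical features as one extra column for the
#' outer epsilon-SVR predicting the 30-day NIHSS. The inner predictions
#' used for outer *training* are out-of-fold by default (5-fold CV within
#' the training set) so the outer model sees realistic inner errors rather
#' than resubstitution fits; `inner_oof = FALSE` uses in-sample inner
#' predictions instead.
#'
#' @param clinical_X Numeric matrix of clinical features (rownames = ids).
#' @param imaging_X Numeric matrix of imaging features for the selected
#'   regions (rownames = ids); zero columns allowed (degenerate inner).
#' @param y_48h,y_30d Named numeric outcomes.
#' @param train_ids Ids of training patients.
#' @param inner_oof Use out-of-fold inner predictions for outer training.
#' @param n_folds Folds for the out-of-fold scheme; default 5.
#' @param cost,epsilon,gamma Shared SVR hyperparameters.
#' @return Object of class `nested_svr` with components `inner`, `outer`
#'   (both `svr_fit`), `clinical_features`, `imaging_features`, and fitting
#'   metadata.
#' @seealso [predict.nested_svr()]
#' @export
fit_nested <- function(clinical_X, imaging_X, y_48h, y_30d, train_ids,
                       inner_oof = TRUE, n_folds = 5L,
                       cost = 1, epsilon = 0.1, gamma = NULL) {
  clinical_X <- as.matrix(clinical_X)
  imaging_X <- as.matrix(imaging_X)
  if (length(train_ids) < 2L) stop("need at least 2 training patients")
  if (is.null(rownames(clinical_X)) ||
      (ncol(imaging_X) > 0 && is.null(rownames(imaging_X))))
    stop("feature matrices need patient ids as rownames")
  if (!all(train_ids %in% rownames(clinical_X)))
    stop("train_ids missing from clinical_X")

  tr <- as.character(train_ids)
  img_tr <- imaging_X[tr, , drop = FALSE]
  y48_tr <- y_48h[tr]
  y30_tr <- y_30d[tr]

  if (ncol(img_tr) == 0L) {
    warning("empty imaging feature set; inner model predicts the training mean")
    inner <- structure(list(model = NULL, constant = mean(y48_tr),
                            features = character(0), dropped = character(0),
                            center = numeric(0), scale = numeric(0),
                            hyper = list(cost = cost, epsilon = epsilon,
                                         gamma = NA_real_)),
                       class = "svr_fit")
    inner_for_outer <- rep(mean(y48_tr), length(tr))
  } else {
    inner <- fit_svr(img_tr, y48_tr, cost = cost, epsilon = epsilon,
                     gamma = gamma)
    if (inner_oof && length(tr) >= 2L * n_folds) {
      folds <- make_folds(y48_tr, n_folds)
      inner_for_outer <- numeric(length(tr))
      for (f in seq_len(n_folds)) {
        hold <- folds == f
        fit_f <- suppressWarnings(
          fit_svr(img_tr[!hold, , drop = FALSE], y48_tr[!hold],
                  cost = cost, epsilon = epsilon, gamma = gamma))
        inner_for_outer[hold] <- predict(fit_f, img_tr[hold, , drop = FALSE])
      }
    } else {
      inner_for_outer <- predict(inner, img_tr)
    }
  }

  outer_X <- cbind(clinical_X[tr, , drop = FALSE],
                   nihss_48h_pred = inner_for_outer)
  outer <- fit_svr(outer_X, y30_tr, cost = cost, epsilon = epsilon,
                   gamma = gamma)

  structure(list(inner = inner, outer = outer,
                 clinical_features = colnames(clinical_X),
                 imaging_features = colnames(imaging_X),
                 train_ids = tr, inner_oof = inner_oof, n_folds = n_folds,
                 hyper = list(cost = cost, epsilon = epsilon, gamma = gamma)),
            class = "nested_svr")
}

#' Predict 30-day NIHSS from a nested fit
#'
#' Applies the inner model to the imaging rows, appends its output to the
#' clinical features, applies the outer model, and clamps the result to the
#' valid NIHSS range \[0,42\] (no rounding).
#'
#' @param object A `nested_svr`.
#' @param clinical_X,imaging_X Feature matrices with the manifest columns
#'   and patient ids as rownames.
#' @param ids Patients to predict; default all rows of `clinical_X`.
#' @param ... Unused.
#' @return Data frame `patient_id`, `predicted`.
#' @export
predict.nested_svr <- function(object, clinical_X, imaging_X,
                               ids = rownames(as.matrix(clinical_X)), ...) {
  clinical_X <- as.matrix(clinical_X)
  imaging_X <- as.matrix(imaging_X)
  ids <- as.character(ids)
  missing_cl <- setdiff(object$clinical_features, colnames(clinical_X))
  if (length(missing_cl))
    stop("missing clinical column(s): ", paste(missing_cl, collapse = ", "))
  inner_pred <- if (length(object$inner$features) == 0L)
    rep(object$inner$constant, length(ids))
  else
    predict(object$inner, imaging_X[ids, , drop = FALSE])
  outer_X <- cbind(clinical_X[ids, object$clinical_features, drop = FALSE],
                   nihss_48h_pred = inner_pred)
  pred <- clamp(predict(object$outer, outer_X), NIHSS_MIN, NIHSS_MAX)
  data.frame(patient_id = ids, predicted = pred, row.names = NULL)
}

#' @export
print.nested_svr <- function(x, ...) {
  cat("Nested epsilon-SVR outcome model\n")
  cat(sprintf("  inner : %d imaging feature(s) -> 48-hour NIHSS%s\n",
              length(x$inner$features),
              if (length(x$inner$features) == 0L) " (degenerate: constant)" else ""))
  cat(sprintf("  outer : %d clinical feature(s) + inner prediction -> 30-day NIHSS\n",
              length(x$clinical_features)))
  cat(sprintf("  trained on %d patients; inner predictions for outer training: %s\n",
              length(x$train_ids),
              if (x$inner_oof) sprintf("out-of-fold (%d-fold)", x$n_folds)
              else "in-sample"))
  invisible(x)
}

#' @export
summary.nested_svr <- function(object, ...) {
  structure(list(fit = object), class = "summary.nested_svr")
}

#' @export
print.summary.nested_svr <- function(x, ...) {
  print(x$fit)
  cat("  clinical features:", paste(x$fit$clinical_features, collapse = ", "), "\n")
  if (length(x$fit$imaging_features))
    cat("  imaging features :", paste(x$fit$imaging_features, collapse = ", "), "\n")
  cat(sprintf("  hyperparameters  : cost %g, epsilon %g, gamma %s\n",
              x$fit$hyper$cost, x$fit$hyper$epsilon,
              x$fit$hyper$gamma %||% "1/d"))
  invisible(x)
}

#' Clinical-only baseline model
#'
#' Single epsilon-SVR from (selected) clinical features to the 30-day
#' NIHSS, the un-nested comparison arm.
#'
#' @param clinical_X Clinical feature matrix (rownames = ids).
#' @param y_30d Named outcomes.
#' @param train_ids Training patients.
#' @param features Selected feature names (e.g. from [select_features()]);
#'   default all columns.
#' @inheritParams fit_svr
#' @return An `svr_fit`.
#' @export
fit_clinical_only <- function(clinical_X, y_30d, train_ids, features = NULL,
                              cost = 1, epsilon = 0.1, gamma = NULL) {
  clinical_X <- as.matrix(clinical_X)
  features <- features %||% colnames(clinical_X)
  missing_cols <- setdiff(features, colnames(clinical_X))
  if (length(missing_cols))
    stop("missing clinical column(s): ", paste(missing_cols, collapse = ", "))
  tr <- as.character(train_ids)
  fit_svr(clinical_X[tr, features, drop = FALSE], y_30d[tr],
          cost = cost, epsilon = epsilon, gamma = gamma)
}
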
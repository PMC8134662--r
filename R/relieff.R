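# RReliefF: Relief-family feature weighting for a continuous target.
#
# For each sampled instance and its k nearest neighbors (Manhattan distance
# on min-max-normalized features; nominal features contribute an inequality
# indicator), three accumulators are updated with neighbor influence 1/k:
#   N_dC        += diff_y                 (normalized target difference)
#   N_dA[A]     += diff_A                 (feature difference)
#   N_dC&dA[A]  += diff_y * diff_A
# and the final weight of feature A over m sampled instances is
#   W[A] = N_dC&dA[A] / N_dC - (N_dA[A] - N_dC&dA[A]) / (m - N_dC),
# which estimates P(changed target | changed A) minus
# P(unchanged target | changed A) and lies in [-1, 1].

#' RReliefF feature weights for regression
#'
#' Weights each feature by how much its value differences co-occur with
#' target differences among nearest neighbors, which penalises redundant
#' and irrelevant features without assuming linearity.
#'
#' @param X Numeric matrix or data frame (factors treated as nominal with
#'   0/1 inequality differences), instances in rows.
#' @param y Continuous target, one value per row of `X`; must not be
#'   constant.
#' @param m Number of randomly sampled instances (default 10). Ignored when
#'   `exhaustive = TRUE`, which performs one deterministic pass over all
#'   instances in order.
#' @param k Neighbor count (default 5); must satisfy `1 <= k < n`. Distance
#'   ties are broken by lowest instance index.
#' @param seed Integer seed for the instance sampling (sampled mode only).
#' @param exhaustive Use every instance exactly once instead of sampling.
#' @return Object of class `attribute_weights`: data frame `feature`,
#'   `weight` (in \[-1,1\]), with attributes `m`, `k`, `seed`.
#' @examples
#' set.seed(1)
#' X <- cbind(signal = runif(40), noise = runif(40))
#' w <- rrelieff(X, y = X[, "signal"], exhaustive = TRUE, k = 5)
#' w
#' @export
rrelieff <- function(X, y, m = 10L, k = 5L, seed = NULL, exhaustive = FALSE) {
  X <- as.data.frame(X)
  n <- nrow(X)
  p <- ncol(X)
  y <- as.numeric(y)
  if (length(y) != n) stop("y must have one value per instance")
  if (anyNA(y) || any(vapply(X, anyNA, logical(1)))) stop("inputs must be finite")
  if (diff(range(y)) == 0) stop("constant target: target differences undefined")
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  if (!exhaustive && m < 1L) stop("m must be >= 1")

  nominal <- vapply(X, function(col) is.factor(col) || is.character(col),
                    logical(1))
  # normalized difference tables: numeric -> |x_i - x_j| / range (0 if the
  # range is zero), nominal -> inequality indicator
  Xn <- matrix(0, n, p)
  for (j in seq_len(p)) {
    if (nominal[j]) {
      Xn[, j] <- as.numeric(as.factor(X[[j]]))
    } else {
      col <- as.numeric(X[[j]])
      rg <- diff(range(col))
      Xn[, j] <- if (rg > 0) (col - min(col)) / rg else 0
    }
  }
  yn <- (y - min(y)) / diff(range(y))

  feat_diff <- function(i, js) {
    d <- abs(Xn[rep(i, length(js)), , drop = FALSE] - Xn[js, , drop = FALSE])
    if (any(nominal)) d[, nominal] <- (d[, nominal] != 0) * 1
    d
  }

  # pairwise distances: sum over features of diff
  D <- matrix(0, n, n)
  for (j in seq_len(p)) {
    dj <- abs(outer(Xn[, j], Xn[, j], "-"))
    if (nominal[j]) dj <- (dj != 0) * 1
    D <- D + dj
  }

  sampled <- if (exhaustive) seq_len(n) else
    with_seed(seed %||% 0L, sample.int(n, m, replace = TRUE))
  m_used <- length(sampled)

  NdC <- 0
  NdA <- numeric(p)
  NdCdA <- numeric(p)
  for (i in sampled) {
    d <- D[i, ]
    d[i] <- Inf
    # quantize before ordering so mathematically tied distances (which can
    # differ by ~1e-16 depending on summation order) tie exactly and break
    # deterministically by lowest index
    nb <- order(round(d, 10), seq_len(n))[seq_len(k)]
    dy <- abs(yn[i] - yn[nb])
    dA <- feat_diff(i, nb)
    NdC <- NdC + sum(dy) / k
    NdA <- NdA + colSums(dA) / k
    NdCdA <- NdCdA + colSums(dA * dy) / k
  }

  if (NdC == 0) {
    warning("no target variation among sampled neighborhoods; all weights 0")
    w <- numeric(p)
  } else if (m_used - NdC == 0) {
    w <- NdCdA / NdC
  } else {
    w <- NdCdA / NdC - (NdA - NdCdA) / (m_used - NdC)
  }
  structure(data.frame(feature = colnames(X) %||% paste0("V", seq_len(p)),
                       weight = w, stringsAsFactors = FALSE),
            class = c("attribute_weights", "data.frame"),
            m = m_used, k = k, seed = seed, exhaustive = exhaustive)
}

#' @export
print.attribute_weights <- function(x, ...) {
  cat(sprintf("RReliefF weights (m = %d, k = %d%s)\n", attr(x, "m"),
              attr(x, "k"),
              if (isTRUE(attr(x, "exhaustive"))) ", exhaustive" else ""))
  df <- data.frame(feature = x$feature, weight = round(x$weight, 4))
  print.data.frame(df[order(-df$weight), ], row.names = FALSE)
  invisible(x)
}

#' Select features from RReliefF weights
#'
#' @param weights An `attribute_weights` object (or data frame with
#'   `feature` and `weight`).
#' @param rule `"positive"` (default: strictly positive weights),
#'   `"top"` (the `j` largest), or `"threshold"` (weight >= `tau`).
#' @param j,tau Parameters of the non-default rules.
#' @return Character vector of selected feature names, in descending weight
#'   order.
#' @export
select_features <- function(weights, rule = c("positive", "top", "threshold"),
                            j = NULL, tau = NULL) {
  rule <- match.arg(rule)
  ord <- order(-weights$weight, weights$feature)
  w <- weights$weight[ord]
  f <- weights$feature[ord]
  keep <- switch(rule,
                 positive = w > 0,
                 top = seq_along(w) <= (j %||% stop("rule 'top' needs j")),
                 threshold = w >= (tau %||% stop("rule 'threshold' needs tau")))
  f[keep]
}

#' Write attribute weights as CSV
#'
#' @param weights An `attribute_weights`.
#' @param path Output CSV (`feature,weight`).
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(data.frame(feature = weights$feature,
                              weight = weights$weight),
                   path, row.names = FALSE)
  invisible(path)
}
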
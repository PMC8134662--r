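# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no rank(), no p.adjust(), no vectorised updates) so they can
# arbitrate correctness.

# mid-rank of each element of v within pool, by explicit counting
oracle_midranks <- function(v, pool) {
  vapply(v, function(x) sum(pool < x) + (sum(pool == x) + 1) / 2, numeric(1))
}

# Brunner-Munzel statistic evaluated directly from the mid-rank formulas
oracle_bm <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  R1 <- oracle_midranks(x, pool); R2 <- oracle_midranks(y, pool)
  r1 <- oracle_midranks(x, x); r2 <- oracle_midranks(y, y)
  m1 <- mean(R1); m2 <- mean(R2)
  S1 <- sum((R1 - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  S2 <- sum((R2 - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  vv <- n1 * S1 + n2 * S2
  if (vv <= 0) return(list(W = 0, df = NA_real_, p = NA_real_, degenerate = TRUE))
  W <- n1 * n2 * (m2 - m1) / ((n1 + n2) * sqrt(vv))
  df <- vv^2 / ((n1 * S1)^2 / (n1 - 1) + (n2 * S2)^2 / (n2 - 1))
  list(W = W, df = df, p = min(1, 2 * stats::pt(-abs(W), df)), degenerate = FALSE)
}

# Benjamini-Hochberg by the literal step-up definition:
# q_i = min over j with p_(j) >= p_i of m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    js <- which(ps >= pi - 1e-15)
    min(1, min(m * ps[js] / js))
  }, numeric(1))
}

# Straight-loop RReliefF with uniform 1/k neighbor influence, min-max
# normalisation, lowest-index tie-break; instance set given explicitly.
oracle_rrelieff <- function(X, y, sampled, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xn <- X
  for (j in seq_len(p)) {
    rg <- max(X[, j]) - min(X[, j])
    Xn[, j] <- if (rg > 0) (X[, j] - min(X[, j])) / rg else 0
  }
  yn <- (y - min(y)) / (max(y) - min(y))
  NdC <- 0; NdA <- numeric(p); NdCdA <- numeric(p)
  for (i in sampled) {
    d <- numeric(n)
    for (jj in seq_len(n)) d[jj] <- sum(abs(Xn[i, ] - Xn[jj, ]))
    d[i] <- Inf
    nb <- order(round(d, 10), seq_len(n))[seq_len(k)]  # ties by lowest index
    for (b in nb) {
      dy <- abs(yn[i] - yn[b])
      NdC <- NdC + dy / k
      for (a in seq_len(p)) {
        dA <- abs(Xn[i, a] - Xn[b, a])
        NdA[a] <- NdA[a] + dA / k
        NdCdA[a] <- NdCdA[a] + dA * dy / k
      }
    }
  }
  m_used <- length(sampled)
  NdCdA / NdC - (NdA - NdCdA) / (m_used - NdC)
}

# per-slice spared fraction of a tract, enumerated voxel by voxel
oracle_tract_integrity <- function(mask, tract_vox, axis_dim, summary = "min") {
  co <- arrayInd(tract_vox, dim(mask))
  slices <- sort(unique(co[, axis_dim]))
  spared <- vapply(slices, function(s) {
    vox <- tract_vox[co[, axis_dim] == s]
    1 - sum(mask[vox] > 0) / length(vox)
  }, numeric(1))
  if (summary == "min") min(spared) else mean(spared)
}
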
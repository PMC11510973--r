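# Independent brute-force oracles. These deliberately avoid the package's
# implementation path (and igraph): explicit DFT sums, Floyd-Warshall,
# triangle counting, shortest-path counting by dynamic programming.

# O(n^2) DFT-based analytic signal: explicit transform matrices.
oracle_analytic <- function(x) {
  n <- length(x)
  j <- 0:(n - 1)
  Wm <- exp(-2i * pi * outer(j, j) / n)
  X <- as.vector(Wm %*% x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  as.vector(Conj(Wm) %*% (X * h)) / n
}

# Time-loop WPLI with the same edge-trim convention as the package.
oracle_wpli <- function(x, y, trim = 0.05) {
  ax <- oracle_analytic(x)
  ay <- oracle_analytic(y)
  n <- length(x)
  k <- max(1, round(trim * n))
  num <- 0; den <- 0; cnt <- 0
  for (t in (k + 1):(n - k)) {
    im <- Im(ax[t] * Conj(ay[t]))
    num <- num + im
    den <- den + abs(im)
    cnt <- cnt + 1
  }
  if (den / cnt < 1e-12) return(0)
  abs(num / cnt) / (den / cnt)
}

# All-pairs shortest paths by Floyd-Warshall on a binary adjacency.
oracle_distances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(N))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracle_global_eff <- function(A) {
  N <- nrow(A)
  if (N < 2) return(list(per_node = numeric(N), value = 0))
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  per <- rowSums(inv) / (N - 1)
  list(per_node = per, value = mean(per))
}

oracle_clustering <- function(A) {
  N <- nrow(A)
  per <- vapply(seq_len(N), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, 0)
  list(per_node = per, mean = mean(per))
}

oracle_local_eff <- function(A) {
  N <- nrow(A)
  per <- vapply(seq_len(N), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_eff(A[nb, nb, drop = FALSE])$value
  }, 0)
  list(per_node = per, value = mean(per))
}

# Betweenness by exhaustive shortest-path counting: sigma[s, t] from a
# BFS-layer DP, then pair contributions sigma_st(v) / sigma_st.
oracle_betweenness <- function(A) {
  N <- nrow(A)
  D <- oracle_distances(A)
  sigma <- matrix(0, N, N)
  for (s in seq_len(N)) {
    sigma[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (v in which(D[s, ] == d)) {
        pred <- which(A[v, ] == 1 & D[s, ] == d - 1)
        sigma[s, v] <- sum(sigma[s, pred])
      }
    }
  }
  b <- numeric(N)
  for (v in seq_len(N)) {
    tot <- 0
    for (s in seq_len(N)) {
      for (t in seq_len(N)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t])
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    b[v] <- tot
  }
  b / ((N - 1) * (N - 2) / 2)
}

# Random symmetric binary adjacency with zero diagonal.
random_adjacency <- function(N, p = 0.3) {
  A <- matrix(0, N, N)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1, p)
  A + t(A)
}

# Exact two-sided Mann-Whitney p by full enumeration of group
# assignments (tie-free data only), matching the convention
# p = min(1, 2 * min(P(W <= w), P(W >= w))).
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  combos <- utils::combn(nx + ny, nx)
  wobs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(ws <= wobs), mean(ws >= wobs))
  min(1, p)
}

# Frequency response magnitude of an ARMA filter at frequency f (Hz).
filter_gain <- function(flt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  num <- sum(flt$b * z^(seq_along(flt$b) - 1))
  den <- sum(flt$a * z^(seq_along(flt$a) - 1))
  Mod(num / den)
}

# Ranking AUC via the rank-sum identity.
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

permute_sample <- function(s, perm) {
  graph_sample(s$node_feats[perm, , drop = FALSE],
               s$adjacency[perm, perm, drop = FALSE],
               s$node_names[perm], s$label, s$modality,
               modality_mask = s$modality_mask[perm],
               segment_id = s$segment_id)
}
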
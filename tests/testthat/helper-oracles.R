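## Independent oracles: implemented from first principles, never calling
## the code paths they check.

# exact 1-D K-means by dynamic programming over sorted values (optimal
# clusters of sorted 1-D data are contiguous intervals); returns the
# optimal within-cluster sum of squares
dp_kmeans_wcss <- function(x, K) {
  x <- sort(x)
  n <- length(x)
  stopifnot(K >= 1, K <= n)
  S1 <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  ## cost[j, i] = within-ssq of x[j..i] (Inf for j > i)
  jm <- matrix(seq_len(n), n, n)
  im <- t(jm)
  cnt <- im - jm + 1
  sm <- matrix(S1[im + 1] - S1[jm], n, n)
  sq <- matrix(S2[im + 1] - S2[jm], n, n)
  cost <- sq - sm^2 / pmax(cnt, 1)
  cost[cnt < 1] <- Inf
  D <- matrix(Inf, K, n)
  D[1, ] <- cost[1, ]
  if (K > 1) for (k in 2:K) {
    prev <- c(Inf, D[k - 1, -n])       # D[k-1, j-1] indexed by j
    M <- cost + prev                   # recycles down columns (rows = j)
    D[k, ] <- apply(M, 2, min)
  }
  D[K, n]
}

wcss_of_centers <- function(x, centers) {
  d <- abs(outer(x, centers, `-`))
  sum(apply(d, 1, min)^2)
}

# literal double-loop transcription of the grey relation formulas
naive_grey_eta <- function(X, Y) {
  m <- nrow(X)
  n <- ncol(X)
  em <- numeric(m)
  for (k in seq_len(m)) {
    s <- 0
    t <- 0
    for (q in seq_len(n)) {
      s <- s + (X[k, q] - X[k, 1])
      t <- t + (Y[k, q] - Y[k, 1])
    }
    em[k] <- (1 + abs(s) + abs(t)) / (1 + abs(s) + abs(t) + abs(s - t))
  }
  en <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    t <- 0
    for (q in seq_len(m)) {
      s <- s + (X[q, k] - X[1, k])
      t <- t + (Y[q, k] - Y[1, k])
    }
    en[k] <- (1 + abs(s) + abs(t)) / (1 + abs(s) + abs(t) + abs(s - t))
  }
  (mean(em) + mean(en)) / 2
}

# direct per-vertex evaluation of the SGF formula via local_cluster()
brute_sgf <- function(mesh, si_values, boundary, w1 = 0.5, w2 = 0.5,
                      ring_depth = 2L) {
  n <- nrow(mesh$vertices)
  A <- vertex_area(mesh)
  ## strict 1-ring extrema (by the documented 1e-9 margin) on the full mesh
  is_ext <- vapply(seq_len(n), function(j) {
    nb <- setdiff(local_cluster(mesh, j, 1L), j)
    length(nb) > 0 &&
      (all(si_values[j] > si_values[nb] + 1e-9) ||
         all(si_values[j] < si_values[nb] - 1e-9))
  }, logical(1))
  vapply(seq_len(n), function(i) {
    Fi <- local_cluster(mesh, i, ring_depth)
    af <- A[Fi] / sum(A[Fi])
    s <- si_values[Fi]
    w1 * sum(af * s^3) +
      w2 * sum(is_ext[Fi]) * (mean(s^2) - mean(s)^2)
  }, numeric(1))
}
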
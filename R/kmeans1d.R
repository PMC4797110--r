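#' One-dimensional K-means with seeded data-point initialization
#'
#' Values are sorted internally before clustering, so the result depends
#' only on the multiset of values (vertex order is irrelevant). Initial
#' centers are `K` values sampled uniformly without replacement from the
#' data under `cfg$seed`; Lloyd iteration (nearest-center assignment with
#' equidistant points going to the lower cluster, then mean updates) runs
#' until the maximum center shift drops below `cfg$tol` or `cfg$max_iter`
#' is reached, re-seeding any empty cluster with the point farthest from
#' its current center.
#'
#' Plain Lloyd iteration with random initialization is prone to poor
#' local optima in one-dimensional quantization once `K` grows, so each
#' converged solution is polished deterministically: optimal 1-D clusters
#' of sorted data are contiguous intervals, and (a) every cluster
#' boundary is relocated exactly given its neighbors, then (b) a
#' split-merge step removes the least useful center and splits the
#' costliest cluster while that strictly lowers the within-cluster sum
#' of squares. `cfg$n_start` seeded restarts plus one deterministic
#' quantile-spaced start are polished this way and the best solution is
#' returned. The whole procedure is deterministic given `cfg$seed`.
#'
#' @param values numeric vector of length `n >= K`.
#' @param cfg a [descriptor_config()].
#' @return numeric vector of `K` cluster means, ascending.
#' @export
kmeans_1d <- function(values, cfg = descriptor_config()) {
  x <- sort(as.numeric(values))
  n <- length(x)
  K <- cfg$K
  if (n < K)
    stop("kmeans_1d: n = ", n, " values but K = ", K,
         "; choose a smaller K")
  if (K == n) return(x)
  pre <- list(S1 = c(0, cumsum(x)), S2 = c(0, cumsum(x * x)))
  n_start <- cfg$n_start %||% max(4L, as.integer(ceiling(48 / K)))
  best <- NULL
  for (r in seq_len(n_start)) {
    seed_r <- as.integer((cfg$seed + (r - 1) * 7919) %%
                           .Machine$integer.max)
    init <- sort(with_seed(seed_r, function() x[sample.int(n, K)]))
    res <- km1d_run(x, K, init, pre, cfg$max_iter, cfg$tol)
    if (is.null(best) || res$wcss < best$wcss) best <- res
  }
  qidx <- unique(pmax(1L, pmin(n, round((seq_len(K) - 0.5) / K * n))))
  if (length(qidx) == K) {
    res <- km1d_run(x, K, x[qidx], pre, cfg$max_iter, cfg$tol)
    if (res$wcss < best$wcss) best <- res
  }
  best$centers
}

## within-ssq / mean of x[a..b] from prefix sums; vectorized in a and b
seg_cost <- function(pre, a, b) {
  s <- pre$S1[b + 1] - pre$S1[a]
  pmax(pre$S2[b + 1] - pre$S2[a] - s * s / (b - a + 1), 0)
}
seg_mean <- function(pre, a, b) (pre$S1[b + 1] - pre$S1[a]) / (b - a + 1)

## one run on sorted x: Lloyd from `init`, then exact boundary sweeps and
## split-merge moves. Partitions are held as a boundary vector b of length
## K + 1: cluster j owns x[(b[j] + 1)..b[j + 1]].
km1d_run <- function(x, K, init, pre, max_iter, tol) {
  n <- length(x)
  bounds_of <- function(cen)
    c(0L, findInterval((cen[-K] + cen[-1]) / 2, x), n)
  wcss_of <- function(b) {
    cnt <- diff(b)
    ok <- cnt > 0L
    sum(seg_cost(pre, (b[-(K + 1L)] + 1L)[ok], b[-1L][ok]))
  }
  centers_of <- function(b) {
    cnt <- diff(b)
    cen <- numeric(K)
    ok <- cnt > 0L
    cen[ok] <- seg_mean(pre, (b[-(K + 1L)] + 1L)[ok], b[-1L][ok])
    cen[!ok] <- x[pmax(b[-(K + 1L)][!ok], 1L)]
    sort(cen)
  }
  lloyd <- function(cen) {
    for (it in seq_len(max_iter)) {
      b <- bounds_of(cen)
      cnt <- diff(b)
      guard <- 0L
      ## empty clusters: re-seed with the farthest-from-center point;
      ## bounded so duplicate-heavy (or constant) data cannot cycle
      while (any(cnt == 0L) && guard < 2L * K) {
        guard <- guard + 1L
        resid <- abs(x - rep(cen, pmax(cnt, 0L)))
        far <- which.max(resid)
        if (resid[far] <= 0) break
        cen[which(cnt == 0L)[1L]] <- x[far]
        cen <- sort(cen)
        b <- bounds_of(cen)
        cnt <- diff(b)
      }
      newc <- centers_of(b)
      shift <- max(abs(newc - cen))
      cen <- newc
      if (shift < tol) break
    }
    cen
  }
  ## exact relocation of each interior boundary given its neighbors
  sweep_bounds <- function(b) {
    for (pass in seq_len(50L)) {
      changed <- FALSE
      for (j in seq_len(K - 1L)) {
        a <- b[j] + 1L
        e <- b[j + 2L]
        if (e - a < 1L) next
        ss <- a:(e - 1L)
        tot <- seg_cost(pre, a, ss) + seg_cost(pre, ss + 1L, e)
        s_new <- ss[which.min(tot)]
        if (s_new != b[j + 1L]) {
          b[j + 1L] <- s_new
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    b
  }
  b <- sweep_bounds(bounds_of(lloyd(init)))
  if (K > 1L) for (step in seq_len(4L * K)) {
    cnt <- diff(b)
    lo <- b[-(K + 1L)] + 1L
    hi <- b[-1L]
    costs <- ifelse(cnt > 0L, seg_cost(pre, pmin(lo, hi), hi), 0)
    ## best binary split over all clusters
    best_gain <- 0
    best_j <- NA_integer_
    best_s <- NA_integer_
    for (j in seq_len(K)) {
      if (cnt[j] < 2L) next
      ss <- lo[j]:(hi[j] - 1L)
      g <- costs[j] -
        (seg_cost(pre, lo[j], ss) + seg_cost(pre, ss + 1L, hi[j]))
      i2 <- which.max(g)
      if (g[i2] > best_gain) {
        best_gain <- g[i2]
        best_j <- j
        best_s <- ss[i2]
      }
    }
    if (is.na(best_j)) break
    ## cheapest center removal (points folded into the neighbors)
    pen <- rep(Inf, K)
    for (j in seq_len(K)) {
      if (cnt[j] == 0L) {
        pen[j] <- 0
        next
      }
      if (j == 1L) {
        pen[j] <- seg_cost(pre, 1L, b[3L]) - costs[1L] - costs[2L]
      } else if (j == K) {
        pen[j] <- seg_cost(pre, b[K - 1L] + 1L, n) - costs[K] -
          costs[K - 1L]
      } else {
        a0 <- b[j - 1L] + 1L
        e0 <- b[j + 2L]
        ss <- b[j]:b[j + 1L]        # new boundary between j-1 and j+1
        left <- ifelse(ss >= a0, seg_cost(pre, a0, pmax(ss, a0)), 0)
        right <- ifelse(ss < e0, seg_cost(pre, pmin(ss, e0 - 1L) + 1L,
                                          e0), 0)
        pen[j] <- min(left + right) - costs[j - 1L] - costs[j] -
          costs[j + 1L]
      }
    }
    ord <- order(pen)
    rem_j <- if (ord[1L] != best_j) ord[1L] else ord[min(2L, K)]
    if (rem_j == best_j || !is.finite(pen[rem_j]) ||
        best_gain - pen[rem_j] <= 1e-12) break
    keep <- setdiff(seq_len(K), c(rem_j, best_j))
    newcen <- sort(c(centers_of(b)[keep],
                     seg_mean(pre, lo[best_j], best_s),
                     seg_mean(pre, best_s + 1L, hi[best_j])))
    b_new <- sweep_bounds(bounds_of(lloyd(newcen)))
    if (wcss_of(b_new) < wcss_of(b) - 1e-12) b <- b_new else break
  }
  list(centers = centers_of(b), wcss = wcss_of(b))
}
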
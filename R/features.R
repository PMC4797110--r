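#' Shape index field
#'
#' The shape index maps the local surface type to `[-1, 1]`:
#' `SI = -(2/pi) * arctan((k1 + k2) / (k1 - k2))`. Under the package's
#' convex-negative mean-curvature convention a convex cap scores +1, a
#' symmetric saddle 0 (`k1 = -k2`), and a concave cup -1. SI depends only
#' on the ratio of the principal curvatures, so it is invariant under
#' rigid motion and uniform scaling.
#'
#' Near umbilics (`k1` close to `k2`) the quotient is numerically wild, so
#' where `|k1 - k2| <= umbilic_tol * max(|k1|, |k2|, 1)` the limit value
#' of the formula is used instead: +1 when `kM < 0` (convex), -1 when
#' `kM > 0`, and 0 when `|kM| <= umbilic_tol` (flat).
#'
#' @param curv a `curvature_field` from [curvature()].
#' @param umbilic_tol relative near-umbilic threshold; the default 0.25
#'   classifies discretized spheres as umbilic (exact SI = 1) while
#'   leaving genuinely anisotropic vertices (tori, saddles) on the
#'   formula branch.
#' @return an object of class `shape_index_field`: data.frame with
#'   columns `si` and `boundary`.
#' @export
shape_index <- function(curv, umbilic_tol = 0.25) {
  stopifnot(inherits(curv, "curvature_field"), umbilic_tol >= 0)
  k1 <- curv$k1
  k2 <- curv$k2
  diff <- k1 - k2                       # >= 0 by construction
  umb <- diff <= umbilic_tol * pmax(abs(k1), abs(k2), 1)
  si <- numeric(length(k1))
  si[!umb] <- -(2 / pi) * atan((k1[!umb] + k2[!umb]) / diff[!umb])
  si[umb] <- ifelse(abs(curv$kM[umb]) <= umbilic_tol, 0,
                    ifelse(curv$kM[umb] < 0, 1, -1))
  out <- data.frame(si = si, boundary = curv$boundary)
  class(out) <- c("shape_index_field", class(out))
  attr(out, "mesh_name") <- attr(curv, "mesh_name")
  out
}

#' Configuration for the salient geometric feature
#'
#' @param w1 weight of the area-weighted cubed-SI term (default 0.5).
#' @param w2 weight of the extrema-count x variance term (default 0.5).
#' @param ring_depth topological radius (edge hops) of the local cluster
#'   `F(i)` around each vertex (default 2).
#' @param strict_extrema count only strict local extrema of SI over the
#'   1-ring (default `TRUE`); plateaus count zero.
#' @return a list of class `sgf_config`.
#' @export
sgf_config <- function(w1 = 0.5, w2 = 0.5, ring_depth = 2L,
                       strict_extrema = TRUE) {
  stopifnot(w1 >= 0, w2 >= 0, ring_depth >= 0)
  structure(list(w1 = w1, w2 = w2, ring_depth = as.integer(ring_depth),
                 strict_extrema = strict_extrema),
            class = "sgf_config")
}

#' Topological ring neighborhood of a vertex
#'
#' All vertices within `ring_depth` edge hops of `i`, inclusive of `i`.
#'
#' @param mesh a [trimesh].
#' @param i vertex index (1-based).
#' @param ring_depth integer >= 0.
#' @return integer vector of vertex ids (sorted, contains `i`).
#' @export
local_cluster <- function(mesh, i, ring_depth = 2L) {
  stopifnot(i >= 1L, i <= nrow(mesh$vertices), ring_depth >= 0)
  adj <- vertex_adjacency(mesh)
  cur <- as.integer(i)
  seen <- cur
  d <- 0L
  while (d < ring_depth && length(cur)) {
    nxt <- setdiff(unique(unlist(adj[cur], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    cur <- nxt
    d <- d + 1L
  }
  sort(seen)
}

#' Salient geometric feature field
#'
#' For each vertex `i` with local cluster `F = F(i)` (the ring
#' neighborhood of depth `ring_depth`):
#' \deqn{SGF(i) = w1 \sum_{j \in F} AreaFrac(j) SI(j)^3 + w2 N Var}
#' where `AreaFrac(j)` is vertex `j`'s barycentric patch area relative to
#' the cluster's total, `N` is the number of cluster members whose SI is
#' a (strict) local minimum or maximum over their own 1-ring on the full
#' mesh, and `Var` is the population variance of SI over the cluster. A
#' local extremum must clear its neighbors by a 1e-9 margin, so exact
#' plateaus (constant fields, symmetry rings of regular meshes) count
#' zero and the field is stable under rounding-level perturbation. The
#' second term is added once per cluster. High SGF marks regions whose
#' curvature character varies saliently; a constant-SI surface has
#' `SGF = w1 * SI^3` everywhere.
#'
#' @param mesh a [trimesh].
#' @param si a `shape_index_field` computed on the same mesh.
#' @param cfg an [sgf_config()].
#' @return object of class `sgf_field`: data.frame with columns `sgf`,
#'   `cluster_size`, `boundary`.
#' @export
sgf_field <- function(mesh, si, cfg = sgf_config()) {
  stopifnot(inherits(si, "shape_index_field"),
            nrow(si) == nrow(mesh$vertices))
  n <- nrow(mesh$vertices)
  s <- si$si
  A <- vertex_area(mesh)
  e <- mesh_edges(mesh)
  ## reachability within ring_depth hops as a sparse pattern matrix
  B <- Matrix::sparseMatrix(i = c(e$v1, e$v2, seq_len(n)),
                            j = c(e$v2, e$v1, seq_len(n)),
                            x = 1, dims = c(n, n))
  R <- B
  d <- 1L
  while (d < cfg$ring_depth) {
    R <- R %*% B
    d <- d + 1L
  }
  if (cfg$ring_depth == 0L) R <- Matrix::Diagonal(n)
  R <- methods::as(R != 0, "dMatrix") * 1   # 0/1 reach pattern

  ## strict local extrema of SI over each vertex's own 1-ring
  src <- c(e$v1, e$v2)
  dst <- c(e$v2, e$v1)
  ord <- order(src, method = "radix")
  fac <- factor(src[ord], levels = seq_len(n))
  nb_si <- split(s[dst[ord]], fac)
  nmax <- vapply(nb_si, function(x) if (length(x)) max(x) else -Inf, 0)
  nmin <- vapply(nb_si, function(x) if (length(x)) min(x) else Inf, 0)
  ## strict extrema by a 1e-9 margin: SI is dimensionless and O(1), and
  ## exact plateaus (e.g. along symmetry rings of regular meshes) must not
  ## flip in or out of the count under rounding-level jitter
  eps <- 1e-9
  if (cfg$strict_extrema) {
    extremum <- as.numeric(s > nmax + eps | s < nmin - eps)
  } else {
    extremum <- as.numeric(s >= nmax - eps | s <= nmin + eps)
  }

  csize <- as.numeric(R %*% rep(1, n))
  atot <- as.numeric(R %*% A)
  term1 <- cfg$w1 * as.numeric(R %*% (A * s^3)) / atot
  Ncnt <- as.numeric(R %*% extremum)
  mu <- as.numeric(R %*% s) / csize
  varp <- pmax(as.numeric(R %*% s^2) / csize - mu^2, 0)
  sgf <- term1 + cfg$w2 * Ncnt * varp
  out <- data.frame(sgf = sgf, cluster_size = as.integer(csize),
                    boundary = si$boundary)
  class(out) <- c("sgf_field", class(out))
  attr(out, "mesh_name") <- attr(si, "mesh_name")
  attr(out, "config") <- cfg
  out
}
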
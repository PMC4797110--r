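#' Discrete curvature of a triangle mesh
#'
#' Per-vertex Gaussian curvature (angle deficit over the mixed Voronoi
#' vertex area), mean curvature (edge-length-weighted signed dihedral
#' angles), and the principal curvatures recovered from the pair.
#'
#' Sign convention (convex-negative): the mean curvature of a closed
#' convex surface with outward orientation is negative — a unit sphere has
#' `kM = -1`. Under this convention the shape index formula assigns +1 to
#' convex regions and -1 to concave ones. Boundary vertices use the
#' reduced angle-deficit formula (pi instead of 2*pi) and receive no
#' contribution from boundary edges; they are flagged in the result.
#'
#' @param mesh a clean, consistently oriented [trimesh] (see
#'   [clean_mesh()], [orient_outward()]).
#' @return an object of class `curvature_field`: a data.frame with columns
#'   `kG` (1/length^2), `kM` (1/length), `k1`, `k2` (principal, `k1 >=
#'   k2`), `clamped` (discriminant `kM^2 - kG` was negative and clamped to
#'   an umbilic), `boundary`.
#' @export
curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  if (n == 0L || nrow(f) == 0L) stop("curvature needs a non-empty mesh")
  if (any(tabulate(as.vector(f), n) == 0L))
    stop("mesh has unreferenced vertices; run clean_mesh() first")
  A <- mixed_vertex_area(mesh)
  ang <- corner_angles(mesh)
  idx <- as.vector(f)
  angsum <- acc_by_vertex(as.vector(ang), idx, n)
  bnd <- rep(FALSE, n)
  bnd[boundary_vertices(mesh)] <- TRUE
  full <- ifelse(bnd, pi, 2 * pi)
  kG <- (full - angsum) / A

  ## mean curvature from signed dihedral angles over interior edges
  e <- mesh_edges(mesh)
  fa <- face_normals_areas(mesh)
  int <- which(!is.na(e$f2))
  s <- numeric(n)
  if (length(int)) {
    va <- e$v1[int]; vb <- e$v2[int]
    n1 <- fa$normal[e$f1[int], , drop = FALSE]
    n2 <- fa$normal[e$f2[int], , drop = FALSE]
    evec <- v[vb, , drop = FALSE] - v[va, , drop = FALSE]
    elen <- sqrt(rowSums(evec^2))
    ehat <- evec / elen
    ## edge direction as traversed by f1: mesh_edges stores (v1, v2) in
    ## f1's traversal order, so ehat is already f1's direction
    crn <- cbind(n1[, 2L] * n2[, 3L] - n1[, 3L] * n2[, 2L],
                 n1[, 3L] * n2[, 1L] - n1[, 1L] * n2[, 3L],
                 n1[, 1L] * n2[, 2L] - n1[, 2L] * n2[, 1L])
    beta <- atan2(rowSums(crn * ehat), rowSums(n1 * n2))
    contrib <- elen * beta
    s <- acc_by_vertex(c(contrib, contrib), c(va, vb), n)
  }
  kM <- -s / (4 * A)   # leading minus: convex-negative calibration

  pc <- principal_from_gm(kG, kM)
  out <- data.frame(kG = kG, kM = kM, k1 = pc$k1, k2 = pc$k2,
                    clamped = pc$clamped, boundary = bnd)
  class(out) <- c("curvature_field", class(out))
  attr(out, "mesh_name") <- mesh$name
  out
}

#' Principal curvatures from Gaussian and mean curvature
#'
#' `k1 = kM + sqrt(d)`, `k2 = kM - sqrt(d)` with `d = max(kM^2 - kG, 0)`.
#' A negative discriminant is a numerically inconsistent discrete estimate
#' and is clamped to zero (an umbilic); the `clamped` flag records where.
#' Always `k1 >= k2`, `k1 + k2 = 2 kM` exactly, and `k1 * k2 = kG`
#' wherever not clamped.
#'
#' @param kG,kM aligned numeric vectors.
#' @return `list(k1, k2, clamped)`.
#' @export
principal_from_gm <- function(kG, kM) {
  stopifnot(length(kG) == length(kM))
  d <- kM^2 - kG
  clamped <- d < 0
  sq <- sqrt(pmax(d, 0))
  list(k1 = kM + sq, k2 = kM - sq, clamped = clamped)
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("curvature_field (%s): %d vertices, %d boundary, %d clamped\n",
              attr(x, "mesh_name") %||% "?", nrow(x),
              sum(x$boundary), sum(x$clamped)))
  cat(sprintf("  kG in [%.4g, %.4g]; kM in [%.4g, %.4g]\n",
              min(x$kG), max(x$kG), min(x$kM), max(x$kM)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total angle deficit of a mesh
#'
#' Sum over vertices of `2*pi - sum(incident angles)` (`pi - sum` at
#' boundary vertices). For a closed mesh this equals `2*pi* chi` exactly
#' (discrete Gauss-Bonnet): `4*pi` for a sphere, `0` for a torus.
#'
#' @param mesh a [trimesh].
#' @return scalar (radians).
#' @export
total_angle_deficit <- function(mesh) {
  n <- nrow(mesh$vertices)
  angsum <- acc_by_vertex(as.vector(corner_angles(mesh)),
                          as.vector(mesh$faces), n)
  bnd <- rep(FALSE, n)
  bnd[boundary_vertices(mesh)] <- TRUE
  sum(ifelse(bnd, pi, 2 * pi) - angsum)
}

## Mixed Voronoi vertex areas (Meyer et al.): the cotangent Voronoi cell
## clipped for obtuse triangles (area/2 at the obtuse corner, area/4 at
## the others). Partitions the total surface area exactly.
mixed_vertex_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  P <- list(v[f[, 1L], , drop = FALSE],
            v[f[, 2L], , drop = FALSE],
            v[f[, 3L], , drop = FALSE])
  area <- face_normals_areas(mesh)$area
  cot <- vector("list", 3L)
  for (i in 1:3) {
    j <- i %% 3L + 1L
    k <- (i + 1L) %% 3L + 1L
    u <- P[[j]] - P[[i]]
    w <- P[[k]] - P[[i]]
    dotp <- rowSums(u * w)
    cross2 <- pmax(rowSums(u^2) * rowSums(w^2) - dotp^2, 0)
    cot[[i]] <- dotp / sqrt(pmax(cross2, 1e-300))
  }
  obtuse_any <- cot[[1L]] < 0 | cot[[2L]] < 0 | cot[[3L]] < 0
  A <- numeric(n)
  for (i in 1:3) {
    j <- i %% 3L + 1L
    k <- (i + 1L) %% 3L + 1L
    lij2 <- rowSums((P[[j]] - P[[i]])^2)
    lik2 <- rowSums((P[[k]] - P[[i]])^2)
    avor <- (lik2 * cot[[j]] + lij2 * cot[[k]]) / 8
    acontrib <- ifelse(!obtuse_any, avor,
                       ifelse(cot[[i]] < 0, area / 2, area / 4))
    A <- A + acc_by_vertex(acontrib, f[, i], n)
  }
  A
}
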
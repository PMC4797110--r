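#' Construct a triangle mesh
#'
#' A `trimesh` is the container every field in this package lives on: an
#' `n x 3` matrix of vertex coordinates (units arbitrary, typically
#' Angstroms for molecular surfaces) and an `m x 3` integer matrix of
#' 1-based vertex indices, one row per triangular face.
#'
#' @param vertices numeric matrix (or coercible) with 3 columns.
#' @param faces integer matrix (or coercible) with 3 columns of 1-based
#'   vertex indices.
#' @param name free-text model label (e.g. a PDB id such as "1HLB").
#' @param validate check structural invariants (indices in range, three
#'   distinct vertices per face).
#' @return an object of class `trimesh` with elements `vertices`, `faces`,
#'   `name`.
#' @export
trimesh <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(vertices) == 0L) vertices <- matrix(numeric(0), 0L, 3L)
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns, got ", ncol(vertices))
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(faces) != 3L)
    stop("'faces' must have 3 columns, got ", ncol(faces))
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces,
                      name = as.character(name)[1L]),
                 class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

validate_trimesh <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  if (nrow(f) > 0L) {
    if (anyNA(f) || min(f) < 1L || max(f) > n)
      stop("face indices must lie in [1, ", n, "]")
    degen <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
    if (any(degen))
      stop(sum(degen), " face(s) with repeated vertex indices")
  }
  if (anyNA(mesh$vertices) || any(!is.finite(mesh$vertices)))
    stop("vertex coordinates must be finite")
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  nb <- length(boundary_vertices(x))
  cat(sprintf("  euler characteristic %d; %s\n", euler_characteristic(x),
              if (nb == 0L) "closed" else paste0(nb, " boundary vertices")))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

## undirected edge table: one row per distinct edge, columns v1 < v2,
## plus the incident face ids (f2 = NA on boundary edges)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1L, 2L), drop = FALSE],
              f[, c(2L, 3L), drop = FALSE],
              f[, c(3L, 1L), drop = FALSE])
  hface <- rep.int(seq_len(nrow(f)), 3L)
  a <- pmin(he[, 1L], he[, 2L])
  b <- pmax(he[, 1L], he[, 2L])
  key <- (a - 1) * nrow(mesh$vertices) + b  # double; exact below 2^53
  ord <- order(key, method = "radix")
  key <- key[ord]
  grp <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  cnt <- tabulate(grp)
  if (any(cnt > 2L))
    stop("non-manifold mesh: ", sum(cnt > 2L),
         " edge(s) shared by more than 2 faces")
  first <- which(c(TRUE, key[-1L] != key[-length(key)]))
  oa <- ord[first]
  e1 <- he[oa, , drop = FALSE]          # as traversed by face1
  f1 <- hface[oa]
  f2 <- rep(NA_integer_, length(first))
  second <- first + 1L
  has2 <- cnt == 2L
  f2[has2] <- hface[ord[second[has2]]]
  # direction of traversal in face2 (same or opposite to face1's)
  same_dir <- rep(NA, length(first))
  same_dir[has2] <- he[ord[second[has2]], 1L] == e1[has2, 1L]
  list(v1 = e1[, 1L], v2 = e1[, 2L], f1 = f1, f2 = f2, same_dir = same_dir)
}

face_normals_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - p1
  e2 <- v[f[, 3L], , drop = FALSE] - p1
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm2 <- sqrt(rowSums(cr^2))
  area <- nrm2 / 2
  normal <- cr / ifelse(nrm2 > 0, nrm2, 1)
  list(normal = normal, area = area)
}

#' Barycentric per-vertex patch areas
#'
#' Assigns one third of every incident face area to each of its corners, so
#' the patch areas partition the total surface area exactly. These are the
#' `Area(i)` weights used in the salient-geometric-feature field.
#'
#' @param mesh a [trimesh].
#' @return numeric vector of length `n_vertices`, units length^2.
#' @export
vertex_area <- function(mesh) {
  fa <- face_normals_areas(mesh)$area
  acc_by_vertex(rep(fa / 3, 3L), as.vector(mesh$faces), nrow(mesh$vertices))
}

## accumulate values by vertex id into a dense length-n vector
acc_by_vertex <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Signed volume enclosed by a mesh
#'
#' Sum of signed tetrahedron volumes to the origin (divergence theorem);
#' positive for a closed, outward-oriented surface.
#'
#' @param mesh a [trimesh].
#' @return scalar signed volume (length^3).
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  sum(p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
      p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
      p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])) / 6
}

#' Euler characteristic V - E + F
#' @param mesh a [trimesh].
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  as.integer(nrow(mesh$vertices) - length(e$v1) + nrow(mesh$faces))
}

#' Indices of boundary vertices
#'
#' A vertex is on the boundary when it touches an edge with only one
#' incident face.
#'
#' @param mesh a [trimesh].
#' @return sorted integer vector (possibly empty).
#' @export
boundary_vertices <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(integer(0))
  e <- mesh_edges(mesh)
  open <- is.na(e$f2)
  sort(unique(c(e$v1[open], e$v2[open])))
}

## vertex-vertex adjacency as a list of integer vectors
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  src <- c(e$v1, e$v2)
  dst <- c(e$v2, e$v1)
  ord <- order(src, method = "radix")
  unname(split(dst[ord], factor(src[ord], levels = seq_len(n))))
}

## outward (area-weighted) vertex normals; requires oriented mesh
vertex_normals <- function(mesh) {
  fa <- face_normals_areas(mesh)
  n <- nrow(mesh$vertices)
  idx <- as.vector(mesh$faces)
  vn <- vapply(1:3, function(k)
    acc_by_vertex(rep(fa$area, 3L) * rep(fa$normal[, k], 3L), idx, n),
    numeric(n))
  len <- sqrt(rowSums(vn^2))
  vn / ifelse(len > 0, len, 1)
}

## per-corner interior angles, m x 3 (columns follow face columns)
corner_angles <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ang <- matrix(0, nrow(f), 3L)
  for (c0 in 1:3) {
    a <- v[f[, c0], , drop = FALSE]
    b <- v[f[, c0 %% 3L + 1L], , drop = FALSE]
    cc <- v[f[, (c0 + 1L) %% 3L + 1L], , drop = FALSE]
    u <- b - a
    w <- cc - a
    cosang <- rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2))
    ang[, c0] <- acos(pmin(1, pmax(-1, cosang)))
  }
  ang
}

bbox_diagonal <- function(mesh) {
  if (nrow(mesh$vertices) == 0L) return(0)
  rng <- apply(mesh$vertices, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}
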
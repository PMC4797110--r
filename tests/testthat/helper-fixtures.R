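## Small meshes built in code, shared across test files.

# regular tetrahedron with unit edge length, outward winding
unit_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    (2 * sqrt(2))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  m <- trimesh(v, f, "tetra")
  if (signed_volume(m) < 0)
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# axis-aligned unit cube as 12 triangles, outward winding
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(quad(1, 3, 4, 2),   # z = 0, normal -z
             quad(5, 6, 8, 7),   # z = 1, normal +z
             quad(1, 2, 6, 5),   # y = 0
             quad(3, 7, 8, 4),   # y = 1
             quad(1, 5, 7, 3),   # x = 0
             quad(2, 4, 8, 6))   # x = 1
  m <- trimesh(v, f, "cube")
  stopifnot(abs(signed_volume(m) - 1) < 1e-12)
  m
}

# flat n x n grid in the z = 0 plane
planar_grid <- function(n = 7L, extent = 1) {
  xs <- seq(-extent, extent, length.out = n)
  x <- rep(xs, times = n)
  y <- rep(xs, each = n)
  vid <- function(i, j) j * n + i + 1L
  i <- rep(0:(n - 2L), times = n - 1L)
  j <- rep(0:(n - 2L), each = n - 1L)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
             cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  trimesh(cbind(x, y, 0), f, "grid")
}

# Moebius band triangulation (non-orientable)
moebius_strip <- function(n = 12L) {
  u <- 2 * pi * (0:(n - 1L)) / n
  p <- function(u, s) {
    r <- 1 + s * 0.3 * cos(u / 2)
    c(r * cos(u), r * sin(u), s * 0.3 * sin(u / 2))
  }
  v <- do.call(rbind, c(lapply(u, p, s = -1), lapply(u, p, s = 1)))
  f <- NULL
  for (i in 0:(n - 1L)) {
    a <- i + 1L
    b <- i + n + 1L
    if (i < n - 1L) {
      cc <- i + 2L
      d <- i + n + 2L
    } else {      # seam: rails swap (the half twist)
      cc <- n + 1L
      d <- 1L
    }
    f <- rbind(f, c(a, b, cc), c(b, d, cc))
  }
  trimesh(v, f, "moebius")
}

rotation_xyz <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

transform_mesh <- function(mesh, rot = diag(3), shift = c(0, 0, 0),
                           scale = 1) {
  trimesh(scale * (mesh$vertices %*% t(rot)) +
            matrix(shift, nrow(mesh$vertices), 3, byrow = TRUE),
          mesh$faces, mesh$name)
}

# consistent re-indexing of vertices (and faces) by a permutation
permute_mesh <- function(mesh, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  trimesh(mesh$vertices[perm, , drop = FALSE],
          matrix(inv[mesh$faces], ncol = 3L), mesh$name)
}

total_face_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}
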
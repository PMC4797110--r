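#' Synthetic meshes with analytic curvature oracles
#'
#' The generators in this file produce closed (or, for the saddle patch,
#' open) meshes whose exact Gaussian curvature and mean-curvature magnitude
#' are known in closed form, so every downstream stage — curvature
#' estimation, shape index, salient features, descriptors, similarity — can
#' be exercised without any protein data. Each generator returns
#' `list(mesh = <trimesh>, oracle = <data.frame>)`; the oracle rows align
#' 1:1 with mesh vertices and carry `kG` (1/length^2) and `kM_mag`
#' (1/length). The package's mean-curvature sign convention is
#' convex-negative: an outward-oriented convex surface has `kM < 0` (unit
#' sphere -> kM = -1), recorded in `attr(oracle, "sign_convention")`.
#'
#' @name synthetic-meshes
NULL

make_oracle <- function(kG, kM_mag) {
  o <- data.frame(kG = kG, kM_mag = kM_mag)
  attr(o, "sign_convention") <- "convex_negative"
  o
}

icosahedron_vf <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

subdivide_vf <- function(v, f) {
  ## midpoint (1-to-4) subdivision with shared-edge midpoints
  nv <- nrow(v)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
  key <- (a - 1) * nv + b
  uk <- !duplicated(key)
  mid_id <- match(key, key[uk]) + nv
  mids <- (v[a[uk], , drop = FALSE] + v[b[uk], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2L * nf + seq_len(nf)]
  f2 <- rbind(cbind(f[, 1L], m12, m31),
              cbind(m12, f[, 2L], m23),
              cbind(m31, m23, f[, 3L]),
              cbind(m12, m23, m31))
  list(v = rbind(v, mids), f = f2)
}

#' Icosphere with exact sphere-curvature oracle
#'
#' An icosahedron subdivided `subdivisions` times with vertices projected
#' to the sphere after each level; `10 * 4^s + 2` vertices. Closed and
#' outward-oriented by construction.
#'
#' @param radius sphere radius (> 0).
#' @param subdivisions integer >= 0.
#' @return `list(mesh, oracle)`; oracle `kG = 1/radius^2`,
#'   `kM_mag = 1/radius` everywhere.
#' @export
icosphere <- function(radius = 1, subdivisions = 3L) {
  stopifnot(radius > 0, subdivisions >= 0)
  m <- icosahedron_vf()
  if (subdivisions > 0) for (i in seq_len(subdivisions)) {
    m <- subdivide_vf(m$v, m$f)
    m$v <- m$v / sqrt(rowSums(m$v^2))
  }
  mesh <- trimesh(radius * m$v, m$f,
                  sprintf("icosphere_r%g_s%d", radius, subdivisions))
  n <- nrow(mesh$vertices)
  list(mesh = mesh,
       oracle = make_oracle(rep(1 / radius^2, n), rep(1 / radius, n)))
}

#' Torus grid mesh with analytic curvature oracle
#'
#' Standard torus of tube radius `r` about a circle of radius `R`,
#' triangulated on a regular `nu x nv` parameter grid. Euler
#' characteristic 0; closed and outward-oriented.
#'
#' At tube angle `v` (0 at the outer equator): `kG = cos v / (r (R + r cos
#' v))` and `|kM| = (R + 2 r cos v) / (2 r (R + r cos v))`.
#'
#' @param R distance from torus center to tube center (> r).
#' @param r tube radius (> 0).
#' @param nu,nv grid resolution around the main ring and the tube
#'   (both >= 3).
#' @return `list(mesh, oracle)`; the oracle also carries the tube angle
#'   per vertex as column `v_param`.
#' @export
torus_mesh <- function(R = 2, r = 0.5, nu = 48L, nv = 24L) {
  stopifnot(R > r, r > 0, nu >= 3, nv >= 3)
  u <- 2 * pi * (seq_len(nu) - 1L) / nu
  vv <- 2 * pi * (seq_len(nv) - 1L) / nv
  ug <- rep(u, times = nv)
  vg <- rep(vv, each = nu)
  verts <- cbind((R + r * cos(vg)) * cos(ug),
                 (R + r * cos(vg)) * sin(ug),
                 r * sin(vg))
  vid <- function(i, j) (j %% nv) * nu + (i %% nu) + 1L  # 0-based i, j
  i <- rep(0:(nu - 1L), times = nv)
  j <- rep(0:(nv - 1L), each = nu)
  ## outward winding for the (u, v) parameterization used here
  fa <- cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
  fb <- cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  mesh <- trimesh(verts, rbind(fa, fb),
                  sprintf("torus_R%g_r%g_%dx%d", R, r, nu, nv))
  den <- R + r * cos(vg)
  oracle <- make_oracle(cos(vg) / (r * den),
                        abs(R + 2 * r * cos(vg)) / (2 * r * den))
  oracle$v_param <- vg
  list(mesh = mesh, oracle = oracle)
}

#' Saddle patch z = x^2 - y^2 with analytic oracle
#'
#' Open regular-grid triangulation of the graph surface over
#' `[-extent, extent]^2` with `n x n` vertices. The center vertex is a
#' perfectly symmetric saddle: `kM = 0`, `kG = -4`. Boundary vertices are
#' flagged downstream by the curvature estimator.
#'
#' @param extent half-width of the square domain.
#' @param n vertices per side (>= 2).
#' @return `list(mesh, oracle)`.
#' @export
saddle_patch <- function(extent = 1, n = 21L) {
  stopifnot(n >= 2, extent > 0)
  xs <- seq(-extent, extent, length.out = n)
  x <- rep(xs, times = n)
  y <- rep(xs, each = n)
  verts <- cbind(x, y, x^2 - y^2)
  vid <- function(i, j) j * n + i + 1L   # 0-based grid indices
  i <- rep(0:(n - 2L), times = n - 1L)
  j <- rep(0:(n - 2L), each = n - 1L)
  fa <- cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
  fb <- cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  mesh <- trimesh(verts, rbind(fa, fb), sprintf("saddle_e%g_n%d", extent, n))
  ## graph-surface curvature: f = x^2 - y^2
  w <- 1 + 4 * x^2 + 4 * y^2        # 1 + fx^2 + fy^2
  kG <- -4 / w^2
  kM_mag <- abs((1 + 4 * y^2) * 2 + (1 + 4 * x^2) * (-2)) / (2 * w^1.5)
  list(mesh = mesh, oracle = make_oracle(kG, kM_mag))
}

## run fn with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  fn()
}

#' Displace vertices along their normals with Gaussian noise
#'
#' Perturbation is along per-vertex outward normals (not isotropic) so
#' small `sigma` preserves topology. Deterministic under `seed`.
#'
#' @param mesh an oriented [trimesh].
#' @param sigma non-negative standard deviation of the displacement, in
#'   length units.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return a perturbed [trimesh].
#' @export
add_vertex_noise <- function(mesh, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mesh)
  vn <- vertex_normals(mesh)
  d <- with_seed(seed, function() stats::rnorm(nrow(mesh$vertices), 0, sigma))
  trimesh(mesh$vertices + vn * d, mesh$faces,
          paste0(mesh$name, "_noise"))
}

#' Smooth random radial deformation of a closed mesh
#'
#' Multiplies each vertex's radius (about the centroid) by
#' `1 + amplitude * g(direction)` where `g` is a random trigonometric
#' polynomial of angular order `frequency`, normalized to `max |g| = 1`.
#' Different seeds give distinct smooth "lumpy" shapes, useful as
#' protein-like decoys in retrieval tests. Deterministic under `seed`.
#'
#' @param mesh a closed [trimesh].
#' @param amplitude relative bump height (dimensionless; 0 = identity).
#' @param frequency integer angular order (>= 1).
#' @param seed integer seed.
#' @return a deformed [trimesh].
#' @export
blobby_deform <- function(mesh, amplitude, frequency = 3L, seed = 1L) {
  stopifnot(amplitude >= 0, frequency >= 1)
  if (amplitude == 0) return(mesh)
  ctr <- colMeans(mesh$vertices)
  p <- sweep(mesh$vertices, 2L, ctr)
  rad <- sqrt(rowSums(p^2))
  dirs <- p / ifelse(rad > 0, rad, 1)
  co <- with_seed(seed, function() stats::rnorm(3L * frequency))
  g <- numeric(nrow(p))
  for (l in seq_len(frequency)) {
    ph <- atan2(dirs[, 2L], dirs[, 1L])
    th <- acos(pmin(1, pmax(-1, dirs[, 3L])))
    g <- g + co[3L * l - 2L] * cos(l * ph) * sin(th)^l +
             co[3L * l - 1L] * sin(l * ph) * sin(th)^l +
             co[3L * l] * cos(l * th)
  }
  g <- g / max(abs(g))
  newv <- sweep(dirs * (rad * (1 + amplitude * g)), 2L, ctr, `+`)
  trimesh(newv, mesh$faces, paste0(mesh$name, "_blob"))
}
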
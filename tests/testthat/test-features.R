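fake_curv <- function(k1, k2, boundary = FALSE) {
  out <- data.frame(kG = k1 * k2, kM = (k1 + k2) / 2, k1 = k1, k2 = k2,
                    clamped = FALSE,
                    boundary = rep_len(boundary, length(k1)))
  class(out) <- c("curvature_field", class(out))
  out
}

test_that("shape index hits its closed-form anchor values", {
  # symmetric saddle k1 = -k2 -> exactly 0
  expect_identical(shape_index(fake_curv(1, -1))$si, 0)
  # k1 = 2, k2 = 1 -> -(2/pi) arctan(3)
  expect_equal(shape_index(fake_curv(2, 1))$si, -(2 / pi) * atan(3),
               tolerance = 1e-12)
  expect_equal(shape_index(fake_curv(2, 1))$si, -0.7952, tolerance = 1e-4)
  # convex umbilic (k1 = k2 < 0) -> limit value +1; concave -> -1
  expect_identical(shape_index(fake_curv(-1, -1))$si, 1)
  expect_identical(shape_index(fake_curv(1, 1))$si, -1)
  # flat umbilic -> 0
  expect_identical(shape_index(fake_curv(0, 0))$si, 0)
})

test_that("shape index stays in [-1, 1] and is +1 on discrete spheres", {
  for (s in 2:3) {
    si <- shape_index(curvature(icosphere(1, s)$mesh))
    expect_identical(si$si, rep(1, nrow(si)))
  }
  tor <- shape_index(curvature(torus_mesh(2, 0.5, 48, 24)$mesh))
  expect_true(all(tor$si >= -1 & tor$si <= 1))
  # the outer equator is strongly convex; the inner band is much less so
  # (analytic SI at the equators: (2/pi) atan(1.5) ~ 0.63 outer,
  #  (2/pi) atan(0.5) ~ 0.30 inner)
  expect_equal(max(tor$si), (2 / pi) * atan(1.5), tolerance = 0.02)
  expect_equal(min(tor$si), (2 / pi) * atan(0.5), tolerance = 0.02)
})

test_that("saddle-patch center has |SI| < 0.05", {
  sad <- saddle_patch(1, 41)
  si <- shape_index(curvature(sad$mesh))
  ctr <- which(sad$mesh$vertices[, 1] == 0 & sad$mesh$vertices[, 2] == 0)
  expect_lt(abs(si$si[ctr]), 0.05)
})

test_that("SI and SGF are invariant under rigid motion and scaling", {
  tor <- torus_mesh(2, 0.5, 24, 12)$mesh
  si <- shape_index(curvature(tor))
  sg <- sgf_field(tor, si)
  moved <- transform_mesh(tor, rotation_xyz(1, 2, 3), c(-5, 1, 2),
                          scale = 2)
  si2 <- shape_index(curvature(moved))
  sg2 <- sgf_field(moved, si2)
  expect_equal(si2$si, si$si, tolerance = 1e-9)
  expect_equal(sg2$sgf, sg$sgf, tolerance = 1e-9)
})

test_that("flipping face orientation negates SI; SGF flips only its first term", {
  tor <- torus_mesh(2, 0.5, 24, 12)$mesh
  flipped <- trimesh(tor$vertices, tor$faces[, c(1, 3, 2)], tor$name)
  si <- shape_index(curvature(tor))
  si_f <- shape_index(curvature(flipped))
  expect_equal(si_f$si, -si$si, tolerance = 1e-9)
  cfg_area <- sgf_config(w1 = 0.5, w2 = 0)    # first term only
  cfg_var <- sgf_config(w1 = 0, w2 = 0.5)     # second term only
  expect_equal(sgf_field(flipped, si_f, cfg_area)$sgf,
               -sgf_field(tor, si, cfg_area)$sgf, tolerance = 1e-9)
  expect_equal(sgf_field(flipped, si_f, cfg_var)$sgf,
               sgf_field(tor, si, cfg_var)$sgf, tolerance = 1e-9)
})

test_that("local_cluster walks topological rings", {
  ico <- icosphere(1, 0)$mesh    # icosahedron: every vertex has valence 5
  expect_identical(local_cluster(ico, 3L, 0L), 3L)
  expect_identical(length(local_cluster(ico, 3L, 1L)), 6L)
  expect_identical(local_cluster(ico, 1L, 10L), 1:12)   # whole mesh
  g <- planar_grid(5)
  corner <- 1L
  expect_identical(length(local_cluster(g, corner, 1L)), 4L)
})

test_that("constant SI fields give SGF = w1 * c^3 everywhere", {
  m <- icosphere(1, 2)$mesh
  for (cc in c(1, -0.4)) {
    si <- structure(data.frame(si = rep(cc, nrow(m$vertices)),
                               boundary = FALSE),
                    class = c("shape_index_field", "data.frame"))
    sg <- sgf_field(m, si)
    expect_equal(sg$sgf, rep(0.5 * cc^3, nrow(m$vertices)),
                 tolerance = 1e-12)
  }
  # corollary: exact-SI sphere -> SGF = 0.5 everywhere
  sg <- sgf_field(m, shape_index(curvature(m)))
  expect_equal(sg$sgf, rep(0.5, nrow(m$vertices)), tolerance = 1e-12)
})

test_that("sgf_field agrees with a brute-force evaluation of the formula", {
  m <- icosphere(1, 1)$mesh
  # a smooth non-constant synthetic SI field
  sv <- sin(2 * m$vertices[, 1]) * cos(m$vertices[, 2]) * 0.8
  si <- structure(data.frame(si = sv, boundary = FALSE),
                  class = c("shape_index_field", "data.frame"))
  for (rd in 1:2) {
    got <- sgf_field(m, si, sgf_config(ring_depth = rd))$sgf
    want <- brute_sgf(m, sv, ring_depth = rd)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("an SI spike raises SGF nearby through the N and Var terms", {
  g <- planar_grid(9)
  sv <- rep(0, nrow(g$vertices))
  spike <- 41L                      # a central vertex
  sv[spike] <- 1
  si <- structure(data.frame(si = sv, boundary = FALSE),
                  class = c("shape_index_field", "data.frame"))
  sg <- sgf_field(g, si, sgf_config(ring_depth = 2))
  near <- setdiff(local_cluster(g, spike, 1L), spike)[1]
  far <- 1L                         # a corner outside the spike's 2-ring
  expect_gt(sg$sgf[near], sg$sgf[far])
  expect_equal(sg$sgf[far], 0, tolerance = 1e-12)
  # matches the brute-force oracle on the same constructed patch
  expect_equal(sg$sgf, brute_sgf(g, sv), tolerance = 1e-12)
})

test_that("SGF respects its lower bound -w1", {
  tor <- torus_mesh(2, 0.5, 24, 12)$mesh
  si <- shape_index(curvature(tor))
  sg <- sgf_field(tor, si)
  expect_true(all(sg$sgf >= -0.5))
})
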
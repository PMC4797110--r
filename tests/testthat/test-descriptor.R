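test_that("kmeans_1d recovers trivial and degenerate clusterings", {
  cfg3 <- descriptor_config(K = 3, seed = 1)
  expect_equal(sort(kmeans_1d(c(1, 2, 3), cfg3)), c(1, 2, 3))
  # all values identical: every center collapses to that value
  cfg2 <- descriptor_config(K = 2, seed = 1)
  expect_equal(kmeans_1d(rep(7, 50), cfg2), c(7, 7))
  expect_error(kmeans_1d(1:10, descriptor_config(K = 20)), "smaller K")
})

test_that("kmeans_1d separates two tight blobs", {
  x <- withr::with_seed(99, c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)))
  got <- sort(kmeans_1d(x, descriptor_config(K = 2, seed = 5)))
  expect_lt(abs(got[1] - 0), 0.5)
  expect_lt(abs(got[2] - 10), 0.5)
  # and the solution matches the exact DP optimum on this easy instance
  expect_equal(wcss_of_centers(x, got), dp_kmeans_wcss(x, 2),
               tolerance = 1e-8)
})

test_that("kmeans_1d stays near the exact DP optimum across instances", {
  ratios <- vapply(1:12, function(i) {
    x <- withr::with_seed(1000 + i, {
      ncl <- sample(2:6, 1)
      unlist(lapply(seq_len(ncl), function(j)
        rnorm(sample(20:60, 1), mean = runif(1, -5, 5),
              sd = runif(1, 0.05, 0.8))))
    })
    K <- min(2L + (i %% 7L), length(x) - 1L)
    centers <- kmeans_1d(x, descriptor_config(K = K, seed = i))
    wcss_of_centers(x, centers) / max(dp_kmeans_wcss(x, K), 1e-12)
  }, numeric(1))
  expect_true(all(ratios >= 1 - 1e-9))   # DP is a true lower bound
  expect_lt(max(ratios), 1.05)
})

test_that("kmeans_1d is deterministic under seed and order-independent", {
  x <- withr::with_seed(7, runif(300))
  cfg <- descriptor_config(K = 10, seed = 42)
  a <- kmeans_1d(x, cfg)
  b <- kmeans_1d(x, cfg)
  expect_identical(a, b)
  expect_identical(kmeans_1d(rev(x), cfg), a)    # order-free
  expect_identical(kmeans_1d(sample(x), cfg), a)
})

test_that("feature_vector sorts, labels, and bounds its output", {
  x <- withr::with_seed(3, runif(200, -1, 1))
  fv <- feature_vector(x, "SI", descriptor_config(K = 8, seed = 2))
  expect_length(fv, 8)
  expect_false(is.unsorted(fv))
  expect_true(all(fv >= -1 & fv <= 1))
  expect_identical(attr(fv, "channel"), "SI")
  fv2 <- feature_vector(x, "SI", descriptor_config(K = 8, seed = 2))
  expect_identical(as.numeric(fv), as.numeric(fv2))
})

test_that("the feature matrix is the sum of the two outer products", {
  M <- build_feature_matrix(c(1, 0), c(0, 1))
  expect_equal(unclass(M), diag(2), ignore_attr = TRUE)
  # P = 0 -> rank-1 outer product of T
  M1 <- build_feature_matrix(c(1, 2, 3), c(0, 0, 0))
  expect_equal(unclass(M1), outer(1:3, 1:3), ignore_attr = TRUE)
  expect_error(build_feature_matrix(1:3, 1:4), "length")
  # symmetric, PSD, rank <= 2 for arbitrary vectors
  set.seed(11)
  Tv <- rnorm(16)
  Pv <- rnorm(16)
  M2 <- unclass(build_feature_matrix(Tv, Pv))
  expect_equal(M2, t(M2))
  ev <- eigen(M2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_lt(sum(ev > 1e-10), 3)
})

test_that("the sphere descriptor is the constant 1.25 matrix", {
  d <- compute_descriptor(icosphere(1, 3)$mesh,
                          cfg = descriptor_config(seed = 9))
  expect_equal(as.numeric(d$T), rep(1, 48))
  expect_equal(as.numeric(d$P), rep(0.5, 48), tolerance = 1e-12)
  expect_equal(unclass(d$M), matrix(1.25, 48, 48), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("descriptors are invariant to rigid motion, scale and reindexing", {
  # a lumpy deformed sphere: generic fields with no exact duplicate
  # values, as on real protein surfaces (exact-tie fields make the
  # K-means optimum non-unique, so invariance is only meaningful here)
  m <- blobby_deform(icosphere(1, 2)$mesh, 0.3, 3, seed = 6)
  cfg <- descriptor_config(K = 24, seed = 13)
  d0 <- compute_descriptor(m, cfg = cfg)
  moved <- transform_mesh(m, rotation_xyz(0.5, 1.2, -0.7), c(9, -4, 2))
  expect_equal(unclass(compute_descriptor(moved, cfg = cfg)$M),
               unclass(d0$M), tolerance = 1e-9)
  # scale down so all curvature magnitudes stay above 1: there the
  # near-umbilic guard max(|k1|, |k2|, 1) is exactly scale-free (its
  # absolute floor of 1 can otherwise switch branches for borderline
  # vertices)
  scaled <- transform_mesh(m, scale = 0.5)
  expect_equal(unclass(compute_descriptor(scaled, cfg = cfg)$M),
               unclass(d0$M), tolerance = 1e-9)
  perm <- withr::with_seed(5, sample(nrow(m$vertices)))
  expect_equal(unclass(compute_descriptor(permute_mesh(m, perm),
                                          cfg = cfg)$M),
               unclass(d0$M), tolerance = 1e-9)
})

test_that("optional min-max normalization maps the SGF channel to [0, 1]", {
  m <- blobby_deform(icosphere(1, 2)$mesh, 0.3, 3, seed = 6)
  d <- compute_descriptor(m, cfg = descriptor_config(K = 16, seed = 3,
                                                     normalize_sgf = TRUE))
  expect_true(all(d$P >= 0 & d$P <= 1))
  d0 <- compute_descriptor(m, cfg = descriptor_config(K = 16, seed = 3))
  expect_identical(as.numeric(d$T), as.numeric(d0$T))  # SI untouched
  expect_false(identical(as.numeric(d$P), as.numeric(d0$P)))
})

test_that("descriptor computation needs at least K usable vertices", {
  expect_error(compute_descriptor(unit_tetrahedron(),
                                  cfg = descriptor_config(K = 48)),
               "usable vertices")
})

test_that("descriptor JSON cache round-trips", {
  d <- compute_descriptor(icosphere(1, 2)$mesh,
                          cfg = descriptor_config(K = 16, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_descriptor(d, path)
  back <- read_descriptor(path)
  expect_equal(as.numeric(back$T), as.numeric(d$T), tolerance = 1e-12)
  expect_equal(as.numeric(back$P), as.numeric(d$P), tolerance = 1e-12)
  expect_equal(unclass(back$M), unclass(d$M), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$name, d$name)
})
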
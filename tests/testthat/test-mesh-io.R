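test_that("OFF read/write round-trips a tetrahedron and checks its header", {
  tet <- unit_tetrahedron()
  path <- withr::local_tempfile(fileext = ".off")
  write_mesh(tet, path)
  txt <- readLines(path)
  expect_identical(txt[1], "OFF")
  expect_match(txt[2], "^4 4 ")
  back <- read_mesh(path)
  expect_equal(back$vertices, tet$vertices)
  expect_identical(back$faces, tet$faces)
})

test_that("round-trips preserve connectivity exactly in all three formats", {
  m <- icosphere(1, 2)$mesh
  for (ext in c(".off", ".ply", ".obj")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(m, path)
    back <- read_mesh(path)
    expect_identical(back$faces, m$faces, label = ext)
    expect_equal(back$vertices, m$vertices, tolerance = 1e-12, label = ext)
  }
})

test_that("binary little-endian PLY is read", {
  m <- unit_cube()
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 8",
               "property float x", "property float y", "property float z",
               "element face 12",
               "property list uchar int vertex_indices",
               "end_header"), con)
  for (i in seq_len(8))
    writeBin(as.numeric(m$vertices[i, ]), con, size = 4, endian = "little")
  for (i in seq_len(12)) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  close(con)
  back <- read_mesh(path)
  expect_identical(back$faces, m$faces)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
})

test_that("quads in input files are fan-triangulated", {
  path <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), path)
  m <- read_mesh(path)
  expect_identical(nrow(m$faces), 2L)
  expect_identical(m$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
})

test_that("malformed OFF files raise parse errors", {
  p1 <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "5 4 0", "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 1 2"), p1)     # header promises 5 vertices, body has 4
  expect_error(read_mesh(p1), "parse error")
  p2 <- withr::local_tempfile(fileext = ".off")
  writeLines(c("0 0 0", "1 1 1"), p2)
  expect_error(read_mesh(p2), "OFF header")
  expect_error(read_mesh(tempfile()), "no such file")
})

test_that("writing an empty mesh errors", {
  empty <- trimesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_mesh(empty, tempfile(fileext = ".off")), "empty mesh")
})

test_that("clean_mesh merges duplicates, drops slivers, and is idempotent", {
  tet <- unit_tetrahedron()
  # duplicate vertex 1 exactly and reference the copy from one face
  v <- rbind(tet$vertices, tet$vertices[1, ])
  f <- tet$faces
  f[f[, 1] == 1L & seq_len(nrow(f)) == 1L, 1] <- 5L
  dirty <- trimesh(v, f, "dirty")
  cleaned <- clean_mesh(dirty)
  expect_identical(nrow(cleaned$vertices), 4L)
  expect_identical(nrow(cleaned$faces), 4L)
  expect_identical(euler_characteristic(cleaned), 2L)

  # zero-area sliver: a face whose third vertex lies on the edge
  v2 <- rbind(tet$vertices, (tet$vertices[1, ] + tet$vertices[2, ]) / 2)
  f2 <- rbind(tet$faces, c(1L, 2L, 5L))
  sliver <- clean_mesh(trimesh(v2, f2, "sliver"))
  expect_identical(nrow(sliver$faces), 4L)
  expect_identical(nrow(sliver$vertices), 4L)  # orphan midpoint dropped

  # duplicate face dropped
  dupf <- clean_mesh(trimesh(tet$vertices, rbind(tet$faces, tet$faces[1, ])))
  expect_identical(nrow(dupf$faces), 4L)

  # idempotence on an already-clean mesh
  again <- clean_mesh(cleaned)
  expect_identical(again$vertices, cleaned$vertices)
  expect_identical(again$faces, cleaned$faces)
})

test_that("orient_outward repairs windings and yields positive volume", {
  cube <- unit_cube()
  broken <- cube
  broken$faces[5, ] <- broken$faces[5, c(1, 3, 2)]  # flip one face
  fixed <- orient_outward(broken)
  expect_equal(signed_volume(fixed), 1, tolerance = 1e-12)

  # fully inverted mesh gets flipped back
  inverted <- cube
  inverted$faces <- inverted$faces[, c(1, 3, 2)]
  expect_equal(signed_volume(orient_outward(inverted)), 1,
               tolerance = 1e-12)

  # idempotence on a consistently outward mesh
  ico <- icosphere(1, 2)$mesh
  expect_identical(orient_outward(ico)$faces, ico$faces)
})

test_that("non-orientable surfaces are rejected", {
  expect_error(orient_outward(moebius_strip()), "non-orientable")
})

test_that("open meshes orient with a warning about outwardness", {
  sad <- saddle_patch(1, 5)$mesh
  expect_warning(orient_outward(sad), "open")
})

test_that("barycentric vertex areas partition the surface area", {
  tet <- unit_tetrahedron()
  A <- vertex_area(tet)
  # each vertex touches 3 unit-edge equilateral faces: A_i = sqrt(3)/4
  expect_equal(A, rep(sqrt(3) / 4, 4), tolerance = 1e-12)
  for (m in list(tet, unit_cube(), torus_mesh(2, 0.5, 16, 8)$mesh)) {
    expect_equal(sum(vertex_area(m)), total_face_area(m),
                 tolerance = 1e-12)
  }
})

test_that("meshes with more than two faces per edge are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(euler_characteristic(trimesh(v, f)), "non-manifold")
})
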
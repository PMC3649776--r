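test_that("mesh validation rejects malformed inputs", {
  v <- matrix(rnorm(9), 3, 3)
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  v[1, 1] <- NA
  expect_error(surface_mesh(v, rbind(c(1, 2, 3))), "non-finite")
  expect_error(point_cloud(matrix(1, 2, 3), normals = matrix(2, 2, 3)),
               "unit length")
})

test_that("STL round-trips preserve geometry (both flavors)", {
  mesh <- generate_sphere(10, subdivisions = 2)
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_mesh(mesh, path, binary = binary)
    back <- read_mesh(path)
    expect_equal(nrow(back$faces), nrow(mesh$faces))
    # STL is a triangle soup: vertex order may change, per-face corners
    # must survive within float32 precision
    orig <- cbind(mesh$vertices[mesh$faces[, 1], ],
                  mesh$vertices[mesh$faces[, 2], ],
                  mesh$vertices[mesh$faces[, 3], ])
    got <- cbind(back$vertices[back$faces[, 1], ],
                 back$vertices[back$faces[, 2], ],
                 back$vertices[back$faces[, 3], ])
    expect_lt(max(abs(orig - got)), 1e-5)
    expect_true(is_closed_mesh(back))
  }
})

test_that("single-triangle STL reads back as 3 vertices, 1 face", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tri, path)
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 3L)
  expect_equal(nrow(back$faces), 1L)
})

test_that("PLY round-trips preserve vertices exactly and colors byte-wise", {
  mesh <- generate_sphere(8, subdivisions = 1)
  cols <- matrix(as.integer((seq_len(3 * nrow(mesh$vertices)) * 37) %% 256),
                 ncol = 3)
  mesh <- surface_mesh(mesh$vertices, mesh$faces, colors = cols)
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_mesh(mesh, path, binary = binary)
    back <- read_mesh(path)
    expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
    expect_identical(back$faces, mesh$faces)
    expect_identical(back$colors, cols)
  }
})

test_that("corrupt mesh files raise format errors", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(1:100), path)
  expect_error(read_mesh(path), "corrupt|truncated")
  path2 <- withr::local_tempfile(fileext = ".ply")
  writeLines("not a ply", path2)
  expect_error(read_mesh(path2), "PLY")
})

test_that("mirroring is an involution and matches the reflection formula", {
  expect_equal(reflect_points(rbind(c(3, 1, 2)), mirror_plane()),
               rbind(c(-3, 1, 2)))
  mesh <- test_femur()$mesh
  plane <- mirror_plane(c(2, -1, 5), c(1, 2, -0.5))
  twice <- mirror_mesh(mirror_mesh(mesh, plane), plane)
  expect_lt(max(abs(twice$vertices - mesh$vertices)), 1e-12)
  expect_identical(twice$faces, mesh$faces)
})

test_that("mirroring preserves outward orientation via winding reversal", {
  mesh <- generate_sphere(5, subdivisions = 2)
  expect_gt(mesh_volume(mesh), 0)
  # vertex reflection alone flips the signed volume...
  reflected_only <- mesh
  reflected_only$vertices <- reflect_points(mesh$vertices, mirror_plane())
  expect_lt(mesh_volume(reflected_only), 0)
  # ...mirror_mesh additionally reverses winding, restoring outwardness
  expect_equal(mesh_volume(mirror_mesh(mesh)), mesh_volume(mesh),
               tolerance = 1e-12)
})

test_that("rigid transforms preserve pairwise distances and reject reflections", {
  pts <- matrix(rnorm(60), 20, 3)
  tr <- random_rigid_transform(11)
  moved <- apply_transform(pts, tr)
  expect_lt(max(abs(dist(moved) - dist(pts))), 1e-9)
  expect_equal(apply_transform(pts, rigid_transform()), pts)
  expect_equal(as.numeric(apply_transform(rbind(c(1, 0, 0)),
                                          rigid_transform(rotation_about(c(0, 0, 1), pi / 2)))),
               c(0, 1, 0), tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "determinant")
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3)), "orthonormal")
})

test_that("transform JSON round-trips and composition/inversion are exact", {
  tr <- random_rigid_transform(5)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tr$translation, tolerance = 1e-12)
  ident <- compose_transforms(invert_transform(tr), tr)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(ident$translation)), 1e-12)
})

test_that("surface sampling is area-uniform, on-surface, and deterministic", {
  cube <- unit_cube_mesh()
  k <- 3000
  cloud <- sample_point_cloud(cube, k, seed = 42)
  # per-face-pair counts: each cube face has probability 1/6
  fn <- face_normals(cube)
  areas <- face_areas(cube)
  expect_equal(sum(areas), 6)
  # points lie exactly on a face plane: for the unit cube each point must
  # have at least one coordinate equal to 0 or 1
  on_plane <- apply(cloud$points, 1, function(p)
    any(abs(p) < 1e-9 | abs(p - 1) < 1e-9))
  expect_true(all(on_plane))
  # face of each sampled point, from its normal + plane
  axis <- apply(cloud$points, 1, function(p) {
    hits <- c(abs(p) < 1e-9, abs(p - 1) < 1e-9)
    which(hits)[1]
  })
  counts <- tabulate(axis, 6)
  p <- 1 / 6
  sigma <- sqrt(k * p * (1 - p))
  expect_true(all(abs(counts - k * p) < 5 * sigma))
  cloud2 <- sample_point_cloud(cube, k, seed = 42)
  expect_identical(cloud$points, cloud2$points)
  expect_false(identical(sample_point_cloud(cube, k, seed = 43)$points,
                         cloud$points))
})

test_that("sampling leaves the caller's RNG state untouched", {
  set.seed(123)
  expected <- rnorm(3)
  set.seed(123)
  invisible(sample_point_cloud(unit_cube_mesh(), 10, seed = 7))
  expect_identical(rnorm(3), expected)
})
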
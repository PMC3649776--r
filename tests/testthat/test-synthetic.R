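test_that("generator round-trip: ABC of landmarks equals parameters at zero noise", {
  fem <- test_femur(a = 80, b = 60, c = 62)
  expect_equal(as.numeric(compute_abc(fem$landmarks)), c(80, 60, 62))
  expect_true(is_closed_mesh(fem$mesh))
  expect_gt(mesh_volume(fem$mesh), 0) # consistently outward-wound
})

test_that("parameter validation enforces plausibility invariants", {
  expect_error(femur_params(a_mm = -5), "positive")
  expect_error(femur_params(a_mm = 60, b_mm = 65), "exceed")
  expect_error(femur_params(noise_sd_mm = -1), "noise_sd_mm")
  expect_error(femur_params(side = "middle"))
})

test_that("left and right femurs are exact mirror images", {
  right <- test_femur(side = "right")
  left <- test_femur(side = "left")
  mirrored <- mirror_mesh(left$mesh, mirror_plane())
  expect_lt(max(abs(mirrored$vertices - right$mesh$vertices)), 1e-9)
  expect_equal(unclass(mirror_landmarks(left$landmarks))[LANDMARK_NAMES],
               unclass(right$landmarks)[LANDMARK_NAMES], tolerance = 1e-12)
})

test_that("generation is deterministic in the seed, including noise", {
  a <- test_femur(noise = 0.3, seed = 7)
  b <- test_femur(noise = 0.3, seed = 7)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(unclass(a$landmarks), unclass(b$landmarks))
  c <- test_femur(noise = 0.3, seed = 8)
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
})

test_that("noisy landmarks keep ABC within Monte-Carlo bounds", {
  # each measure is calibrated to have sd ~= noise_sd; over seeds, the
  # 3-sigma band should hold for the vast majority of draws
  noise <- 0.3
  dev <- t(vapply(1:60, function(seed) {
    fem <- test_femur(noise = noise, seed = seed, resolution = 4)
    abs(as.numeric(compute_abc(fem$landmarks)) - c(80, 60, 62))
  }, numeric(3)))
  expect_lt(mean(dev > 3 * noise), 0.05)
  expect_lt(max(dev), 5 * noise)
})

test_that("defects remove local geometry and leave an open boundary", {
  mesh <- test_femur()$mesh
  # tiny defect far from any vertex: identity
  same <- apply_defect(mesh, defect_spec(c(500, 500, 500), 0.001))
  expect_identical(same$vertices, mesh$vertices)
  # medial condyle defect: fewer vertices, open boundary
  def <- apply_defect(mesh, defect_spec(c(-40, 0, 0), 10))
  expect_lt(nrow(def$vertices), nrow(mesh$vertices))
  expect_false(is_closed_mesh(def))
  # all removed: degenerate
  expect_error(apply_defect(mesh, defect_spec(c(0, 0, 20), 1000)),
               "degenerate")
})

test_that("sphere rasterization recovers the analytic volume", {
  sph <- generate_sphere(10, subdivisions = 3)
  vol <- rasterize_to_volume(sph, spacing_mm = c(1, 1, 1))
  inside <- sum(vol$intensities > 500)
  expect_equal(inside * 1, 4 / 3 * pi * 1000, tolerance = 0.02)
  # noise-free volume has exactly two intensity values
  expect_identical(sort(unique(as.vector(vol$intensities))), c(0, 1000))
  # halving the spacing multiplies the inside count by ~8
  vol2 <- rasterize_to_volume(sph, spacing_mm = c(0.5, 0.5, 0.5))
  expect_equal(sum(vol2$intensities > 500) / inside, 8, tolerance = 0.03)
})

test_that("rasterization covers the mesh with a margin and needs closed input", {
  sph <- generate_sphere(5, subdivisions = 2, center_mm = c(10, -4, 7))
  vol <- rasterize_to_volume(sph, spacing_mm = c(1, 1, 1))
  bmin <- apply(sph$vertices, 2, min)
  bmax <- apply(sph$vertices, 2, max)
  expect_true(all(vol$origin_mm <= bmin - 2))
  top <- vol$origin_mm + (dim(vol$intensities) - 1) * vol$spacing_mm
  expect_true(all(top >= bmax + 2))
  open_mesh <- apply_defect(sph, defect_spec(c(15, -4, 7), 2))
  expect_error(rasterize_to_volume(open_mesh), "not closed")
})

test_that("bank generation is deterministic, unique, and self-consistent", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  idx1 <- generate_bank(6, dir1, seed = 42, resolution_mm = 4)
  idx2 <- generate_bank(6, dir2, seed = 42, resolution_mm = 4)
  expect_false(any(duplicated(idx1$donor_id)))
  # byte-identical regeneration
  for (f in list.files(dir1)) {
    expect_identical(readBin(file.path(dir1, f), "raw", 2e6),
                     readBin(file.path(dir2, f), "raw", 2e6))
  }
  # stored ABC equals compute_abc of stored landmarks
  for (i in seq_len(nrow(idx1))) {
    lm <- read_landmarks(file.path(dir1, idx1$landmarks_path[i]))
    expect_equal(as.numeric(compute_abc(lm)),
                 as.numeric(idx1[i, c("a_mm", "b_mm", "c_mm")]),
                 tolerance = 1e-12)
  }
})

test_that("single zero-spread donor reproduces the requested ABC", {
  dir <- withr::local_tempdir()
  idx <- generate_bank(1, dir, abc_mean = c(80, 60, 62), abc_sd = c(0, 0, 0),
                       seed = 3, resolution_mm = 4)
  expect_equal(as.numeric(idx[1, c("a_mm", "b_mm", "c_mm")]), c(80, 60, 62))
})

test_that("bank ABC sample means follow the requested distribution (CLT)", {
  dir <- withr::local_tempdir()
  idx <- generate_bank(50, dir, abc_mean = c(80, 60, 62), abc_sd = c(4, 3, 3),
                       seed = 11, resolution_mm = 5)
  means <- colMeans(idx[, c("a_mm", "b_mm", "c_mm")])
  bound <- 3 * c(4, 3, 3) / sqrt(50)
  expect_true(all(abs(means - c(80, 60, 62)) < bound))
})
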
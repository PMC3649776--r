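test_that("parallel-plane distances are exactly the plane separation", {
  target <- plane_mesh(z0 = 0)
  src <- plane_mesh(z0 = 1, half = 5)
  cloud <- sample_point_cloud(src, 500, seed = 1)
  d <- surface_distances(cloud, target)
  expect_true(all(abs(d$distances - 1) < 1e-12))
})

test_that("points sampled on the target itself have zero distance", {
  fem <- test_femur(resolution = 4)
  cloud <- sample_point_cloud(fem$mesh, 1000, seed = 2)
  d <- surface_distances(cloud, fem$mesh)
  expect_lt(max(d$distances), 1e-9)
})

test_that("BVH distances equal the exhaustive brute-force oracle", {
  set.seed(3)
  mesh <- generate_sphere(10, subdivisions = 1) # 80 faces
  pts <- matrix(rnorm(3 * 120, 0, 15), ncol = 3)
  fast <- surface_distances(point_cloud(pts), mesh)$distances
  slow <- brute_surface_distances(pts, mesh)
  expect_lt(max(abs(fast - slow)), 1e-9)
  # a second, irregular target
  fem <- test_femur(resolution = 5)
  pts2 <- matrix(rnorm(3 * 60, 0, 40), ncol = 3)
  fast2 <- surface_distances(point_cloud(pts2), fem$mesh)$distances
  slow2 <- brute_surface_distances(pts2, fem$mesh)
  expect_lt(max(abs(fast2 - slow2)), 1e-9)
})

test_that("distances are invariant under a common rigid transform", {
  fem <- test_femur(resolution = 4)
  cloud <- sample_point_cloud(fem$mesh, 400, seed = 4)
  shifted <- point_cloud(cloud$points + 3)
  base <- surface_distances(shifted, fem$mesh)$distances
  for (seed in c(21, 22, 23)) {
    tr <- random_rigid_transform(seed)
    d <- surface_distances(apply_transform(shifted, tr),
                           apply_transform(fem$mesh, tr))$distances
    expect_lt(max(abs(d - base)), 1e-9)
  }
})

test_that("match_score computes mean, rms, max and interpolated p95", {
  f1 <- structure(list(distances = rep(1, 4), direction = "host_to_donor",
                       signed = FALSE, n = 4), class = "distance_field")
  s1 <- match_score(f1)
  expect_equal(s1$mean_mm, 1)
  expect_equal(s1$rms_mm, 1)
  expect_equal(s1$max_mm, 1)
  f2 <- structure(list(distances = c(0, 2), direction = "host_to_donor",
                       signed = FALSE, n = 2), class = "distance_field")
  s2 <- match_score(f2)
  expect_equal(s2$mean_mm, 1)
  expect_equal(s2$rms_mm, sqrt(2))
  expect_equal(s2$max_mm, 2)
  expect_equal(s2$p95_mm, 0.95 * 2) # linear interpolation between 0 and 2
})

test_that("score ordering invariants hold on random fields", {
  for (seed in 1:20) {
    set.seed(seed)
    d <- abs(rnorm(200, 1, 0.8))
    s <- match_score(structure(list(distances = d, direction = "x",
                                    signed = FALSE, n = length(d)),
                               class = "distance_field"))
    expect_lte(s$mean_mm, s$rms_mm + 1e-12)
    expect_lte(s$rms_mm, s$max_mm + 1e-12)
    expect_lte(s$p95_mm, s$max_mm + 1e-12)
  }
})

test_that("colorimetric export clamps, colors, and round-trips exactly", {
  mesh <- generate_sphere(5, subdivisions = 1)
  n <- nrow(mesh$vertices)
  spec <- color_map_spec(0, 5)
  low_field <- structure(list(distances = rep(0, n), direction = "x",
                              signed = FALSE, n = n),
                         class = "distance_field")
  path <- withr::local_tempfile(fileext = ".ply")
  colorimetric_export(mesh, low_field, spec, path)
  back <- read_mesh(path)
  expect_equal(nrow(unique(back$colors)), 1L) # all colormap(0)
  big_field <- low_field
  big_field$distances <- c(rep(10, n - 1), 5) # above upper: clamped
  path2 <- withr::local_tempfile(fileext = ".ply")
  colorimetric_export(mesh, big_field, spec, path2)
  back2 <- read_mesh(path2)
  expect_equal(nrow(unique(back2$colors)), 1L) # clamp(10) == colormap(1)
  legend <- jsonlite::read_json(paste0(path2, ".legend.json"))
  expect_equal(legend$upper_mm, 5)
  # colors survive a write/read cycle byte-identically
  path3 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(back2, path3)
  expect_identical(read_mesh(path3)$colors, back2$colors)
  bad <- low_field
  bad$n <- 3
  bad$distances <- rep(1, 3)
  expect_error(colorimetric_export(mesh, bad, spec, path), "match")
})

test_that("rank_candidates puts an exact copy first and reports all scores", {
  fem <- test_femur()
  dir <- withr::local_tempdir()
  write_mesh(fem$mesh, file.path(dir, "copy.stl"))
  scaled <- fem$mesh
  scaled$vertices <- scaled$vertices * 1.1
  write_mesh(scaled, file.path(dir, "scaled.stl"))
  cand <- data.frame(donor_id = c("copy", "scaled"),
                     mesh_path = c(file.path(dir, "copy.stl"),
                                   file.path(dir, "scaled.stl")),
                     stringsAsFactors = FALSE)
  rep <- rank_candidates(fem$mesh, fem$landmarks, cand,
                         config = registration_config(sample_size = 1500,
                                                      seed = 3),
                         score_points = 1500)
  expect_equal(rep$table$donor_id[1], "copy")
  expect_lt(rep$table$mean_mm[1], 0.01) # self-match, limited only by ICP tol
  expect_gt(rep$table$mean_mm[2], rep$table$mean_mm[1])
  expect_setequal(names(rep$details), c("copy", "scaled"))
})

test_that("ranking follows surface distance even when ABC screening disagrees", {
  # donor X: same ABC as host but a much shorter shaft -> host shaft points
  # have nothing to land on -> bad surface match
  # donor Y: slightly off ABC but otherwise identical shape -> good match
  host <- test_femur(a = 80, b = 60, c = 62)
  x <- generate_femur(femur_params(80, 60, 62, shaft_length_mm = 35),
                      resolution_mm = 2.5)
  y <- test_femur(a = 81.5, b = 61, c = 63)
  dir <- withr::local_tempdir()
  write_mesh(x$mesh, file.path(dir, "X.stl"))
  write_mesh(y$mesh, file.path(dir, "Y.stl"))
  write_landmarks(x$landmarks, file.path(dir, "X.json"))
  write_landmarks(y$landmarks, file.path(dir, "Y.json"))
  recs <- data.frame(donor_id = c("X", "Y"), side = "right",
                     bone = "distal_femur",
                     a_mm = c(80, 81.5), b_mm = c(60, 61), c_mm = c(62, 63),
                     mesh_path = c(file.path(dir, "X.stl"),
                                   file.path(dir, "Y.stl")),
                     landmarks_path = c(file.path(dir, "X.json"),
                                        file.path(dir, "Y.json")),
                     stringsAsFactors = FALSE)
  idx <- build_index(recs)
  scr <- screen_bank(idx, compute_abc(host$landmarks), k = 2)
  expect_equal(scr$donor_id[1], "X") # ABC prefers X...
  rep <- rank_candidates(host$mesh, host$landmarks, scr,
                         config = registration_config(sample_size = 1500,
                                                      seed = 5),
                         score_points = 1500)
  expect_equal(rep$table$donor_id[1], "Y") # ...surface match prefers Y
})

test_that("unreadable candidates are skipped with a warning, not an error", {
  fem <- test_femur(resolution = 4)
  dir <- withr::local_tempdir()
  write_mesh(fem$mesh, file.path(dir, "ok.stl"))
  cand <- data.frame(donor_id = c("bad", "ok"),
                     mesh_path = c(file.path(dir, "missing.stl"),
                                   file.path(dir, "ok.stl")),
                     stringsAsFactors = FALSE)
  expect_warning(
    rep <- rank_candidates(fem$mesh, fem$landmarks, cand,
                           config = registration_config(sample_size = 1000,
                                                        seed = 2),
                           score_points = 800),
    "skipped")
  expect_equal(rep$table$donor_id, "ok")
})
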
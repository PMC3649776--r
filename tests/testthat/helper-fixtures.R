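# Shared fixtures and independent oracles, built in code at test time.

# Unit cube: 8 vertices, 12 outward-oriented triangles, 2 per face.
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # z = 0
             c(5, 6, 7), c(5, 7, 8),   # z = 1
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 4, 8), c(3, 8, 7),   # y = 1
             c(1, 5, 8), c(1, 8, 4),   # x = 0
             c(2, 3, 7), c(2, 7, 6))   # x = 1
  surface_mesh(v, f)
}

# Flat square in the z = z0 plane, two triangles.
plane_mesh <- function(z0 = 0, half = 10) {
  v <- rbind(c(-half, -half, z0), c(half, -half, z0),
             c(half, half, z0), c(-half, half, z0))
  surface_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
}

# Independent point-to-triangle distance: solve the unconstrained 2x2
# normal equations for the barycentric projection; if outside the triangle
# domain, fall back to the minimum over the three clamped edge segments.
# Deliberately a different algorithm from the package's Voronoi-region walk.
brute_point_triangle_dist <- function(p, a, b, c) {
  e1 <- b - a
  e2 <- c - a
  d <- p - a
  g11 <- sum(e1 * e1); g12 <- sum(e1 * e2); g22 <- sum(e2 * e2)
  r1 <- sum(e1 * d); r2 <- sum(e2 * d)
  det <- g11 * g22 - g12 * g12
  if (det > 0) {
    u <- (g22 * r1 - g12 * r2) / det
    v <- (g11 * r2 - g12 * r1) / det
    if (u >= 0 && v >= 0 && u + v <= 1)
      return(sqrt(sum((a + u * e1 + v * e2 - p)^2)))
  }
  seg <- function(q0, q1) {
    L2 <- sum((q1 - q0)^2)
    if (L2 < 1e-30) return(sqrt(sum((q0 - p)^2)))
    t <- min(1, max(0, sum((p - q0) * (q1 - q0)) / L2))
    sqrt(sum((q0 + t * (q1 - q0) - p)^2))
  }
  min(seg(a, b), seg(b, c), seg(c, a))
}

# Exhaustive point-to-every-triangle oracle over a whole mesh.
brute_surface_distances <- function(points, mesh) {
  fc <- list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
             b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
             c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    min(vapply(seq_len(nrow(mesh$faces)), function(f)
      brute_point_triangle_dist(p, fc$a[f, ], fc$b[f, ], fc$c[f, ]),
      numeric(1)))
  }, numeric(1))
}

# Rotation matrix about a (normalized) axis by angle radians (Rodrigues).
rotation_about <- function(axis, angle) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rigid_transform <- function(seed) {
  set.seed(seed)
  axis <- rnorm(3)
  rigid_transform(rotation_about(axis, runif(1, 0, pi)),
                  rnorm(3, 0, 20))
}

rotation_error_deg <- function(Ra, Rb) {
  ct <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Build a small synthetic case: a bank with one donor generated from the
# host's own parameters ("planted"), plus decoys.
make_case <- function(dir, host_abc = c(81, 59.5, 61), n_decoys = 4,
                      seed = 1, noise = 0.2, resolution = 2.5) {
  bank_dir <- file.path(dir, "bank")
  generate_bank(n_decoys, bank_dir, seed = seed, noise_sd_mm = noise,
                side = "right", resolution_mm = resolution)
  host <- generate_femur(femur_params(host_abc[1], host_abc[2], host_abc[3],
                                      side = "left", noise_sd_mm = noise,
                                      seed = seed + 500),
                         resolution_mm = resolution)
  planted <- generate_femur(femur_params(host_abc[1], host_abc[2],
                                         host_abc[3], side = "right",
                                         noise_sd_mm = noise,
                                         seed = seed + 900),
                            resolution_mm = resolution)
  write_mesh(planted$mesh, file.path(bank_dir, "PLANT.stl"))
  write_landmarks(planted$landmarks,
                  file.path(bank_dir, "PLANT.landmarks.json"))
  abc <- compute_abc(planted$landmarks)
  tab <- read.csv(file.path(bank_dir, "bank.csv"), stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(donor_id = "PLANT", side = "right",
                               bone = "distal_femur", a_mm = abc[[1]],
                               b_mm = abc[[2]], c_mm = abc[[3]],
                               mesh_path = "PLANT.stl",
                               landmarks_path = "PLANT.landmarks.json"))
  write.csv(tab, file.path(bank_dir, "bank.csv"), row.names = FALSE,
            quote = FALSE)
  write_mesh(host$mesh, file.path(dir, "host.stl"))
  write_landmarks(host$landmarks, file.path(dir, "host.landmarks.json"))
  list(bank_csv = file.path(bank_dir, "bank.csv"),
       host_mesh = file.path(dir, "host.stl"),
       host_landmarks = file.path(dir, "host.landmarks.json"))
}

fast_config <- function(case, out, seed = 7) {
  list(host_mesh = case$host_mesh, host_landmarks = case$host_landmarks,
       healthy_side = "left", bank = case$bank_csv, output_dir = out,
       seed = seed,
       registration = list(sample_size = 2000),
       scoring = list(score_points = 1500))
}

# Small femur used by many tests (coarse grid keeps the suite fast).
test_femur <- function(a = 80, b = 60, c = 62, side = "right", noise = 0,
                       seed = 1, resolution = 2.5) {
  generate_femur(femur_params(a_mm = a, b_mm = b, c_mm = c, side = side,
                              noise_sd_mm = noise, seed = seed),
                 resolution_mm = resolution)
}
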
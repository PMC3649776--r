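#' Parameters of the synthetic distal femur
#'
#' The generator builds a distal-femur-like shape — two condylar ellipsoids
#' smoothly blended with a shaft capsule — in a fixed synthetic frame:
#' x = medial-lateral, y = anterior-posterior, z = proximal-distal (condyles
#' around z = 0, shaft toward +z), sagittal plane at x = 0. The three ABC
#' parameters are generative ground truth: at `noise_sd_mm = 0`,
#' [compute_abc()] of the returned landmarks reproduces them exactly.
#'
#' @param a_mm transepicondylar width (measure A), mm.
#' @param b_mm medial condyle anterior-posterior depth (measure B), mm.
#' @param c_mm lateral condyle anterior-posterior depth (measure C), mm.
#' @param shaft_length_mm,shaft_radius_mm shaft capsule dimensions, mm.
#' @param side `"left"` or `"right"`; sides are exact mirror images at
#'   zero noise.
#' @param noise_sd_mm standard deviation of surface perturbation along
#'   outward vertex normals, mm. Landmark placement uncertainty is
#'   calibrated so each ABC measure has standard deviation about
#'   `noise_sd_mm`.
#' @param seed integer seed for the noise draw.
#' @return an object of class `femur_params`.
#' @export
femur_params <- function(a_mm = 80, b_mm = 60, c_mm = 62,
                         shaft_length_mm = 60, shaft_radius_mm = 16,
                         side = c("right", "left"), noise_sd_mm = 0,
                         seed = 1L) {
  side <- match.arg(side)
  p <- list(a_mm = a_mm, b_mm = b_mm, c_mm = c_mm,
            shaft_length_mm = shaft_length_mm,
            shaft_radius_mm = shaft_radius_mm, side = side,
            noise_sd_mm = noise_sd_mm, seed = as.integer(seed))
  lens <- c(p$a_mm, p$b_mm, p$c_mm, p$shaft_length_mm, p$shaft_radius_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all femur dimensions must be positive and finite", call. = FALSE)
  if (p$b_mm > p$a_mm || p$c_mm > p$a_mm)
    stop("condylar depths b_mm and c_mm must not exceed the width a_mm",
         call. = FALSE)
  if (!is.finite(p$noise_sd_mm) || p$noise_sd_mm < 0)
    stop("noise_sd_mm must be >= 0", call. = FALSE)
  structure(p, class = "femur_params")
}

# approximate signed distance to an axis-aligned ellipsoid (negative inside)
ellipsoid_sdf <- function(pts, center, radii) {
  q <- sweep(pts, 2, center)
  k0 <- sqrt(rowSums(sweep(q, 2, radii, "/")^2))
  k1 <- sqrt(rowSums(sweep(q, 2, radii^2, "/")^2))
  out <- k0 * (k0 - 1) / pmax(k1, 1e-12)
  out[k1 < 1e-12] <- -min(radii)
  out
}

# signed distance to a z-aligned capsule from (0,0,z0) to (0,0,z1)
capsule_sdf <- function(pts, z0, z1, radius) {
  zc <- pmin(pmax(pts[, 3], z0), z1)
  sqrt(pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] - zc)^2) - radius
}

# polynomial smooth minimum with blending radius k (mm)
smin <- function(d1, d2, k = 8) {
  h <- pmax(k - abs(d1 - d2), 0) / k
  pmin(d1, d2) - h * h * k * 0.25
}

femur_sdf <- function(pts, p) {
  # canonical right side: medial condyle toward -x
  hm <- 0.40 * p$b_mm  # condyle proximal-distal semi-axis
  hl <- 0.40 * p$c_mm
  dm <- ellipsoid_sdf(pts, c(-p$a_mm / 4, 0, 0), c(p$a_mm / 4, p$b_mm / 2, hm))
  dl <- ellipsoid_sdf(pts, c(p$a_mm / 4, 0, 0), c(p$a_mm / 4, p$c_mm / 2, hl))
  ds <- capsule_sdf(pts, 0.4 * min(hm, hl), p$shaft_length_mm,
                    p$shaft_radius_mm)
  smin(smin(dm, dl), ds)
}

canonical_landmarks <- function(p) {
  landmark_set(ME = c(-p$a_mm / 2, 0, 0),
               LE = c(p$a_mm / 2, 0, 0),
               MA = c(-p$a_mm / 4, p$b_mm / 2, 0),
               MP = c(-p$a_mm / 4, -p$b_mm / 2, 0),
               LA = c(p$a_mm / 4, p$c_mm / 2, 0),
               LP = c(p$a_mm / 4, -p$c_mm / 2, 0))
}

#' Generate a synthetic distal femur with ground-truth landmarks
#'
#' Evaluates the implicit femur shape on a regular grid and extracts the
#' zero isosurface, yielding a closed, consistently outward-oriented
#' triangle mesh, plus the six ABC landmarks placed by construction.
#' `side = "left"` output is the exact sagittal mirror (about x = 0) of the
#' `side = "right"` output at zero noise.
#'
#' @param params a [femur_params()].
#' @param resolution_mm isosurface grid spacing, mm; smaller is smoother
#'   and slower.
#' @return list with elements `mesh` ([surface_mesh()]), `landmarks`
#'   ([landmark_set()]), and `params`.
#' @export
generate_femur <- function(params, resolution_mm = 2) {
  if (!inherits(params, "femur_params"))
    params <- do.call(femur_params, as.list(params))
  p <- params
  hm <- 0.40 * p$b_mm
  hl <- 0.40 * p$c_mm
  pad <- 3 * resolution_mm
  lo <- c(-p$a_mm / 2 - pad, -max(p$b_mm, p$c_mm) / 2 - pad,
          -max(hm, hl) - pad)
  hi <- c(p$a_mm / 2 + pad,
          max(max(p$b_mm, p$c_mm) / 2, p$shaft_radius_mm) + pad,
          p$shaft_length_mm + p$shaft_radius_mm + pad)
  dims <- as.integer(ceiling((hi - lo) / resolution_mm)) + 1L
  gx <- lo[1] + (seq_len(dims[1]) - 1) * resolution_mm
  gy <- lo[2] + (seq_len(dims[2]) - 1) * resolution_mm
  gz <- lo[3] + (seq_len(dims[3]) - 1) * resolution_mm
  pts <- cbind(rep(gx, times = dims[2] * dims[3]),
               rep(rep(gy, each = dims[1]), times = dims[3]),
               rep(gz, each = dims[1] * dims[2]))
  field <- -femur_sdf(pts, p) # interior positive for extraction at iso = 0
  surf <- cpp_marching_tetra(field, dims, 0, lo,
                             rep(resolution_mm, 3))
  mesh <- surface_mesh(surf$vertices, surf$faces)
  landmarks <- canonical_landmarks(p)
  if (p$side == "left") {
    mesh <- mirror_mesh(mesh, mirror_plane())
    landmarks <- mirror_landmarks(landmarks, mirror_plane())
  }
  if (p$noise_sd_mm > 0) {
    vn <- vertex_normals(mesh)
    with_seed(p$seed, {
      disp <- stats::rnorm(nrow(mesh$vertices), 0, p$noise_sd_mm)
      lm_jitter <- matrix(stats::rnorm(18, 0, p$noise_sd_mm / sqrt(2)), 6, 3)
    })
    mesh$vertices <- mesh$vertices + vn * disp
    landmarks <- matrix_landmarks(landmarks_matrix(landmarks) + lm_jitter)
  }
  list(mesh = mesh, landmarks = landmarks, params = p)
}

#' Generate a triangulated sphere (subdivided icosahedron)
#'
#' A closed, outward-oriented sphere mesh used as the analytic fixture for
#' rasterization and reconstruction checks (its enclosed volume converges
#' to 4/3 pi r^3 with subdivision).
#'
#' @param radius_mm sphere radius, mm.
#' @param center_mm length-3 center, mm.
#' @param subdivisions icosahedron subdivision depth (faces = 20 * 4^n).
#' @return a [surface_mesh()].
#' @export
generate_sphere <- function(radius_mm = 20, center_mm = c(0, 0, 0),
                            subdivisions = 4) {
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uniq <- !duplicated(key)
    mid_of <- nrow(v) + match(key, key[uniq])
    mids <- (v[edges[uniq, 1], , drop = FALSE] +
               v[edges[uniq, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_of[seq_len(nf)]
    m23 <- mid_of[nf + seq_len(nf)]
    m31 <- mid_of[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius_mm
  mesh <- surface_mesh(v, f)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh$vertices <- sweep(mesh$vertices, 2, center_mm, "+")
  mesh
}

#' Tumor-like surface defect
#'
#' @param center_mm length-3 numeric, defect center in mm (on or near the
#'   surface).
#' @param radius_mm defect radius, mm (> 0).
#' @return an object of class `defect_spec`.
#' @export
defect_spec <- function(center_mm, radius_mm) {
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L || anyNA(center_mm))
    stop("center_mm must be a finite 3-vector", call. = FALSE)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("radius_mm must be > 0", call. = FALSE)
  structure(list(center_mm = center_mm, radius_mm = radius_mm),
            class = "defect_spec")
}

#' Erode a tumor-like defect into a mesh
#'
#' Removes every vertex within `radius_mm` of the defect center together
#' with its incident faces, leaving an open boundary. This emulates the
#' incomplete bone models of tumoral hosts, where disease erases the
#' anatomy locally; no hole filling is attempted.
#'
#' @param mesh a [surface_mesh()].
#' @param spec a [defect_spec()].
#' @return the defected (open) [surface_mesh()].
#' @export
apply_defect <- function(mesh, spec) {
  validate_mesh(mesh)
  if (!inherits(spec, "defect_spec"))
    stop("spec must be a defect_spec", call. = FALSE)
  d2 <- rowSums(sweep(mesh$vertices, 2, spec$center_mm)^2)
  drop <- d2 <= spec$radius_mm^2
  if (!any(drop)) return(mesh)
  if (all(drop))
    stop("defect removes the entire mesh (degenerate output)", call. = FALSE)
  keep <- which(!drop)
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  fkeep <- rowSums(matrix(drop[mesh$faces], ncol = 3)) == 0
  faces <- matrix(remap[mesh$faces[fkeep, , drop = FALSE]], ncol = 3)
  if (nrow(faces) == 0L)
    stop("defect removes every face (degenerate output)", call. = FALSE)
  # drop vertices that lost all their faces
  used <- sort(unique(as.vector(faces)))
  remap2 <- integer(length(keep))
  remap2[used] <- seq_along(used)
  surface_mesh(mesh$vertices[keep[used], , drop = FALSE],
               matrix(remap2[faces], ncol = 3),
               colors = if (!is.null(mesh$colors))
                 mesh$colors[keep[used], , drop = FALSE])
}

#' Rasterize a closed mesh into a CT-like voxel volume
#'
#' Emulates CT acquisition of a bone: voxel centers inside the mesh receive
#' `inside_value`, the rest `outside_value`, plus optional Gaussian noise.
#' The default spacing of 0.5 mm matches thin-slice clinical acquisitions.
#' The volume bounding box covers the mesh with at least a 2-voxel margin.
#'
#' @param mesh a closed [surface_mesh()].
#' @param spacing_mm voxel spacing, length-3 (mm).
#' @param inside_value,outside_value intensities (HU-like; cortical bone is
#'   high, soft tissue near 0).
#' @param noise_sd intensity noise standard deviation.
#' @param seed integer seed for the noise draw.
#' @return a [voxel_volume()].
#' @export
rasterize_to_volume <- function(mesh, spacing_mm = c(0.5, 0.5, 0.5),
                                inside_value = 1000, outside_value = 0,
                                noise_sd = 0, seed = 1L) {
  validate_mesh(mesh)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (!is_closed_mesh(mesh))
    stop("mesh is not closed: inside/outside is undefined for open meshes",
         call. = FALSE)
  bmin <- apply(mesh$vertices, 2, min)
  bmax <- apply(mesh$vertices, 2, max)
  origin <- bmin - 2 * spacing_mm
  dims <- as.integer(ceiling((bmax + 2 * spacing_mm - origin) / spacing_mm)) + 1L
  mask <- cpp_rasterize_mask(mesh$vertices, mesh$faces - 1L, dims, origin,
                             spacing_mm)
  intensities <- rep(as.numeric(outside_value), length(mask))
  intensities[mask] <- inside_value
  if (noise_sd > 0)
    intensities <- intensities +
      with_seed(seed, stats::rnorm(length(intensities), 0, noise_sd))
  voxel_volume(array(intensities, dim = dims), spacing_mm = spacing_mm,
               origin_mm = origin)
}

#' Generate a synthetic donor bank
#'
#' Draws `n` donors with ABC dimensions from independent normal
#' distributions (rejection-sampled to keep each donor anatomically
#' plausible: positive sizes, condylar depths not exceeding the width),
#' writes each donor's mesh (binary STL) and landmarks (JSON) under `dir`,
#' and writes `bank.csv` — the measured bank table used for screening.
#' Stored ABC values are re-measured from the stored landmarks via
#' [compute_abc()], so the table always agrees with its annotation files.
#' Regeneration with the same seed is byte-identical.
#'
#' @param n number of donors (>= 1).
#' @param dir output directory (created if needed).
#' @param abc_mean,abc_sd length-3 mean and standard deviation of the
#'   A, B, C dimensions in mm. Defaults (80, 60, 62) +/- (4, 3, 3) describe
#'   an adult distal femur population.
#' @param side `"both"` (random 50/50), `"left"`, or `"right"`.
#' @param noise_sd_mm surface noise passed to [generate_femur()].
#' @param seed integer master seed; each donor derives its own sub-seed.
#' @param resolution_mm mesh grid resolution passed to [generate_femur()].
#' @return invisibly, the bank index (see [build_index()]); the CSV path is
#'   in `attr(, "path")`.
#' @export
generate_bank <- function(n, dir, abc_mean = c(80, 60, 62),
                          abc_sd = c(4, 3, 3), side = "both",
                          noise_sd_mm = 0, seed = 1L, resolution_mm = 2) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(abc_sd < 0)) stop("abc_sd must be >= 0", call. = FALSE)
  side <- match.arg(side, c("both", "left", "right"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir))
      stop("cannot create bank directory: ", dir, call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- as.integer((as.double(seed) * 1009 + i) %% 2147483629)
    abc <- with_seed(sub_seed, {
      repeat {
        cand <- stats::rnorm(3, abc_mean, abc_sd)
        if (all(cand > 0) && cand[2] <= cand[1] && cand[3] <= cand[1]) break
      }
      donor_side <- if (side == "both")
        c("left", "right")[1 + (stats::runif(1) > 0.5)] else side
      list(abc = cand, side = donor_side)
    })
    fp <- femur_params(a_mm = abc$abc[1], b_mm = abc$abc[2],
                       c_mm = abc$abc[3], side = abc$side,
                       noise_sd_mm = noise_sd_mm, seed = sub_seed)
    fem <- generate_femur(fp, resolution_mm = resolution_mm)
    donor_id <- sprintf("D%03d", i)
    mesh_path <- file.path(dir, paste0(donor_id, ".stl"))
    lm_path <- file.path(dir, paste0(donor_id, ".landmarks.json"))
    write_mesh(fem$mesh, mesh_path)
    write_landmarks(fem$landmarks, lm_path)
    abc_meas <- compute_abc(fem$landmarks)
    rows[[i]] <- data.frame(donor_id = donor_id, side = abc$side,
                            bone = "distal_femur",
                            a_mm = abc_meas[["a_mm"]],
                            b_mm = abc_meas[["b_mm"]],
                            c_mm = abc_meas[["c_mm"]],
                            mesh_path = basename(mesh_path),
                            landmarks_path = basename(lm_path),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  csv_path <- file.path(dir, "bank.csv")
  write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  idx <- build_index(tab, root = dir)
  attr(idx, "path") <- csv_path
  invisible(idx)
}
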
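#' Triangle surface mesh
#'
#' The central geometric container: a triangle mesh with vertices in
#' millimetres. Bone models of host, mirror and donor are all
#' `surface_mesh` objects, whether they come from isosurface extraction of a
#' CT volume ([extract_surface()]), from an STL/PLY file ([read_mesh()]), or
#' from the synthetic femur generator ([generate_femur()]).
#'
#' @param vertices numeric matrix, N x 3, coordinates in mm.
#' @param faces integer matrix, M x 3, 1-based vertex indices.
#' @param colors optional N x 3 integer matrix of per-vertex RGB in 0..255.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces, colors = colors),
                    class = "surface_mesh")
  validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L)
    stop("mesh vertices must be an N x 3 matrix", call. = FALSE)
  if (!is.matrix(f) || ncol(f) != 3L)
    stop("mesh faces must be an M x 3 matrix", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v)))
    stop("mesh vertices contain non-finite coordinates", call. = FALSE)
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, nrow(vertices)]", call. = FALSE)
    degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(degen))
      stop(sum(degen), " degenerate face(s) with repeated vertex indices",
           call. = FALSE)
  }
  if (!is.null(mesh$colors)) {
    if (nrow(mesh$colors) != nrow(v) || ncol(mesh$colors) != 3L)
      stop("vertex colors must be an N x 3 matrix matching the vertices",
           call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$colors)) ", vertex colors" else ""))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Oriented point cloud
#'
#' Surface samples used by registration and match scoring; normals, when
#' present, are unit vectors inherited from the faces the points were drawn
#' from.
#'
#' @param points numeric matrix, K x 3, mm.
#' @param normals optional K x 3 matrix of unit normals.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!is.matrix(points) || ncol(points) != 3L)
    stop("points must be a K x 3 matrix", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("points contain non-finite coordinates", call. = FALSE)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(points)))
      stop("normals must match the points matrix in shape", call. = FALSE)
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must be unit length (within 1e-6)", call. = FALSE)
  }
  structure(list(points = points, normals = normals), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", nrow(x$points),
              if (!is.null(x$normals)) " with normals" else ""))
  invisible(x)
}

# ---- mesh geometry helpers -------------------------------------------------

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas, normals and vertex normals
#'
#' @param mesh a [surface_mesh()].
#' @return `face_areas`: numeric vector (mm^2). `face_normals`: M x 3 unit
#'   normals. `vertex_normals`: N x 3 area-weighted unit vertex normals.
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  cr / len
}

#' @rdname face_areas
#' @export
vertex_normals <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a) # area-weighted face normals
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    agg <- rowsum(cr, group = mesh$faces[, j])
    at <- as.integer(rownames(agg))
    vn[at, ] <- vn[at, ] + agg
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes against the origin.
#' Positive for consistently outward-oriented closed meshes.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

#' Test whether a mesh is closed (watertight)
#'
#' A mesh is closed when every undirected edge is shared by exactly two
#' faces. Tumor-defected host models are deliberately open; rasterization
#' requires a closed mesh.
#'
#' @param mesh a [surface_mesh()].
#' @return logical scalar.
#' @export
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Area-uniform surface sampling
#'
#' Draws `k` points uniformly by area over the mesh surface: faces are
#' chosen multinomially with probability proportional to area, then points
#' are placed by uniform barycentric coordinates. Normals are inherited from
#' the sampled faces. Deterministic for a fixed `seed`.
#'
#' @param mesh a [surface_mesh()] with at least one face.
#' @param k number of points to draw.
#' @param seed integer seed controlling the draw.
#' @return a [point_cloud()] with `k` points and unit normals.
#' @export
sample_point_cloud <- function(mesh, k, seed = 1L) {
  validate_mesh(mesh)
  if (nrow(mesh$faces) < 1L) stop("mesh has no faces to sample", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  areas <- face_areas(mesh)
  fn <- face_normals(mesh)
  fc <- face_corners(mesh)
  with_seed(seed, {
    fidx <- sample.int(nrow(mesh$faces), k, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(k))
    r2 <- stats::runif(k)
  })
  # uniform barycentric point on each chosen face
  u <- 1 - r1
  v <- r1 * (1 - r2)
  w <- r1 * r2
  pts <- fc$a[fidx, , drop = FALSE] * u +
    fc$b[fidx, , drop = FALSE] * v +
    fc$c[fidx, , drop = FALSE] * w
  point_cloud(pts, fn[fidx, , drop = FALSE])
}

# Run code with a temporary RNG state; restores the caller's state after.
# `expr` is a promise evaluated in the caller's frame after set.seed().
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
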
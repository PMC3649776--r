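#' Rigid transform (rotation + translation)
#'
#' Proper rigid motions only: the rotation must be orthonormal with
#' determinant +1. Reflections are deliberately not representable here —
#' chirality changes happen only through [mirror_mesh()] /
#' [mirror_landmarks()], so registration can never silently flip a bone's
#' handedness.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)))
    stop("rotation must be a 3 x 3 matrix", call. = FALSE)
  if (length(translation) != 3L)
    stop("translation must have length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (within 1e-9)", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation has determinant -1: reflections are not rigid transforms; ",
         "use mirror_mesh() for chirality changes", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first,
#' then `a` (i.e. `x -> a(b(x))`).
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

# rotation angle in degrees from a rotation matrix
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Apply a rigid transform to a mesh, point cloud, or coordinate matrix
#'
#' Points map as `x -> R x + t`; normals are rotated only. Pairwise
#' distances are preserved exactly (up to floating point).
#'
#' @param x a [surface_mesh()], [point_cloud()], or N x 3 matrix.
#' @param transform a [rigid_transform()].
#' @return the transformed object, same class as `x`.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform"))
    stop("transform must be a rigid_transform", call. = FALSE)
  UseMethod("apply_transform")
}

#' @export
apply_transform.matrix <- function(x, transform) {
  sweep(x %*% t(transform$rotation), 2, -transform$translation)
}

#' @export
apply_transform.surface_mesh <- function(x, transform) {
  x$vertices <- apply_transform(x$vertices, transform)
  x
}

#' @export
apply_transform.point_cloud <- function(x, transform) {
  x$points <- apply_transform(x$points, transform)
  if (!is.null(x$normals)) x$normals <- x$normals %*% t(transform$rotation)
  x
}

#' Mirror plane
#'
#' A plane given by a point on it and a unit normal. The default is the
#' sagittal plane of the synthetic frame, `x = 0` with normal (1, 0, 0);
#' for clinical data the plane is a user input — no automatic
#' symmetry-plane estimation is attempted.
#'
#' @param point_mm length-3 numeric, a point on the plane (mm).
#' @param normal length-3 numeric, plane normal (normalized internally).
#' @return an object of class `mirror_plane`.
#' @export
mirror_plane <- function(point_mm = c(0, 0, 0), normal = c(1, 0, 0)) {
  point_mm <- as.numeric(point_mm)
  normal <- as.numeric(normal)
  if (length(point_mm) != 3L || length(normal) != 3L)
    stop("point_mm and normal must have length 3", call. = FALSE)
  len <- sqrt(sum(normal^2))
  if (len == 0) stop("plane normal must be nonzero", call. = FALSE)
  structure(list(point_mm = point_mm, normal = normal / len),
            class = "mirror_plane")
}

reflect_points <- function(pts, plane) {
  n <- plane$normal
  d <- (sweep(pts, 2, plane$point_mm) %*% n)[, 1]
  pts - 2 * outer(d, n)
}

#' Mirror a mesh across a plane
#'
#' Reflects every vertex (`v -> v - 2((v - p) . n) n`) and reverses face
#' winding so the outward orientation is preserved. This is the virtual
#' bone bank's mirror-model step: the patient's healthy contralateral bone
#' is reflected across the sagittal plane to stand in for the tumor-eroded
#' side.
#'
#' @param mesh a [surface_mesh()].
#' @param plane a [mirror_plane()]; default sagittal plane x = 0.
#' @return the mirrored [surface_mesh()].
#' @export
mirror_mesh <- function(mesh, plane = mirror_plane()) {
  validate_mesh(mesh)
  if (!inherits(plane, "mirror_plane"))
    stop("plane must be a mirror_plane", call. = FALSE)
  mesh$vertices <- reflect_points(mesh$vertices, plane)
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Read and write rigid transforms as JSON
#'
#' Serialized as a 4 x 4 row-major homogeneous matrix.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @return `read_transform` returns a [rigid_transform()];
#'   `write_transform` returns `path` invisibly.
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$matrix
  if (is.null(m) || !all(dim(m) == c(4, 4)))
    stop("transform JSON must contain a 4 x 4 'matrix'", call. = FALSE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}
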
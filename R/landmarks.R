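#' The six distal-femur landmarks
#'
#' Size screening uses three distances derived from six operator-placed
#' anatomical landmarks on the distal femur:
#' * `ME`, `LE` — medial and lateral epicondyles (their distance is the
#'   transepicondylar width, measure A);
#' * `MA`, `MP` — anterior and posterior extremes of the medial condyle
#'   (measure B, medial anterior-posterior condylar depth);
#' * `LA`, `LP` — anterior and posterior extremes of the lateral condyle
#'   (measure C, lateral anterior-posterior condylar depth).
#'
#' Landmark names are anatomical, not geometric: mirroring a landmark set
#' keeps `ME` called `ME` — reflection converts left-side geometry into
#' right-side geometry without relabeling.
#'
#' @param ME,LE,MA,MP,LA,LP length-3 numeric coordinates in mm.
#' @return an object of class `landmark_set`: a named list of 3-vectors.
#' @export
landmark_set <- function(ME, LE, MA, MP, LA, LP) {
  pts <- list(ME = ME, LE = LE, MA = MA, MP = MP, LA = LA, LP = LP)
  pts <- lapply(pts, as.numeric)
  bad <- names(pts)[!vapply(pts, function(p)
    length(p) == 3L && all(is.finite(p)), TRUE)]
  if (length(bad))
    stop("landmark(s) not finite length-3 coordinates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(pts, class = "landmark_set")
}

LANDMARK_NAMES <- c("ME", "LE", "MA", "MP", "LA", "LP")

validate_landmarks <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set"))
    stop("expected a landmark_set", call. = FALSE)
  missing <- setdiff(LANDMARK_NAMES, names(landmarks))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(landmarks)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  for (nm in LANDMARK_NAMES)
    cat(sprintf("  %s: (%.3f, %.3f, %.3f) mm\n", nm, x[[nm]][1], x[[nm]][2],
                x[[nm]][3]))
  invisible(x)
}

landmarks_matrix <- function(landmarks) {
  do.call(rbind, lapply(LANDMARK_NAMES, function(nm) landmarks[[nm]]))
}

matrix_landmarks <- function(m) {
  landmark_set(m[1, ], m[2, ], m[3, ], m[4, ], m[5, ], m[6, ])
}

#' Compute the ABC size measures
#'
#' Three-dimensional Euclidean distances between landmark pairs:
#' A = ||ME - LE|| (transepicondylar width), B = ||MA - MP|| (medial
#' condylar anterior-posterior depth), C = ||LA - LP|| (lateral condylar
#' anterior-posterior depth). Being distances, they are invariant under any
#' rigid transform and under mirroring.
#'
#' @param landmarks a [landmark_set()].
#' @return an `abc_measurement`: named numeric `c(a_mm, b_mm, c_mm)`.
#' @export
compute_abc <- function(landmarks) {
  validate_landmarks(landmarks)
  d <- function(p, q) sqrt(sum((p - q)^2))
  abc_measurement(d(landmarks$ME, landmarks$LE),
                  d(landmarks$MA, landmarks$MP),
                  d(landmarks$LA, landmarks$LP))
}

#' ABC measurement triple
#'
#' @param a_mm,b_mm,c_mm non-negative distances in mm.
#' @return named numeric vector of class `abc_measurement`.
#' @export
abc_measurement <- function(a_mm, b_mm, c_mm) {
  v <- c(a_mm = as.numeric(a_mm), b_mm = as.numeric(b_mm),
         c_mm = as.numeric(c_mm))
  if (anyNA(v) || any(v < 0))
    stop("ABC measures must be non-negative numbers", call. = FALSE)
  structure(v, class = "abc_measurement")
}

#' @export
print.abc_measurement <- function(x, ...) {
  cat(sprintf("ABC [mm]: A = %.2f, B = %.2f, C = %.2f\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Mirror a landmark set across a plane
#'
#' Reflects each point; names are unchanged (see [landmark_set()] for why).
#' ABC measures are preserved exactly, since reflection is an isometry.
#'
#' @param landmarks a [landmark_set()].
#' @param plane a [mirror_plane()].
#' @return the mirrored [landmark_set()].
#' @export
mirror_landmarks <- function(landmarks, plane = mirror_plane()) {
  validate_landmarks(landmarks)
  matrix_landmarks(reflect_points(landmarks_matrix(landmarks), plane))
}

#' @rdname mirror_landmarks
#' @param transform a [rigid_transform()].
#' @export
transform_landmarks <- function(landmarks, transform) {
  validate_landmarks(landmarks)
  matrix_landmarks(apply_transform(landmarks_matrix(landmarks), transform))
}

#' Read and write landmark JSON files
#'
#' The schema is a JSON object mapping each of the six landmark names to a
#' `[x, y, z]` array in mm, e.g. `{"ME": [-40, 0, 0], ...}`. Files with
#' missing or unknown names are rejected, naming the offending keys.
#'
#' @param path file path.
#' @param landmarks a [landmark_set()].
#' @return `read_landmarks` returns a [landmark_set()]; `write_landmarks`
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(LANDMARK_NAMES, names(obj))
  if (length(missing))
    stop("landmark file ", path, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(obj), LANDMARK_NAMES)
  if (length(extra))
    stop("landmark file ", path, " has unknown key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  do.call(landmark_set, obj[LANDMARK_NAMES])
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  validate_landmarks(landmarks)
  jsonlite::write_json(lapply(unclass(landmarks)[LANDMARK_NAMES], as.numeric),
                       path, digits = NA)
  invisible(path)
}
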
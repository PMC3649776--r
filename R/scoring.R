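#' Per-point surface distances (host to donor)
#'
#' For every source point, the Euclidean distance to the nearest point on
#' any target triangle (exact point-to-triangle, not point-to-vertex).
#' Inputs are assumed already registered. The default clinical direction is
#' host-mirror points against the donor surface: the question is how well
#' the donor covers the host's required geometry.
#'
#' @param source a [point_cloud()] (or [surface_mesh()], whose vertices are
#'   used).
#' @param target a [surface_mesh()].
#' @param direction tag recorded on the result (default `"host_to_donor"`).
#' @return a `distance_field`: list with `distances` (mm, unsigned),
#'   `direction`, `signed = FALSE`, and `n = length(distances)`.
#' @export
surface_distances <- function(source, target, direction = "host_to_donor") {
  pts <- if (inherits(source, "point_cloud")) source$points
         else if (inherits(source, "surface_mesh")) source$vertices
         else stop("source must be a point_cloud or surface_mesh",
                   call. = FALSE)
  if (nrow(pts) < 1L) stop("source is empty", call. = FALSE)
  validate_mesh(target)
  if (nrow(target$faces) < 1L) stop("target mesh has no faces", call. = FALSE)
  bvh <- cpp_bvh_build(target$vertices, target$faces - 1L)
  d <- cpp_bvh_query(bvh, pts)$distance
  structure(list(distances = d, direction = direction, signed = FALSE,
                 n = length(d)), class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> %d distances (%s), mean %.4g mm, max %.4g mm\n",
              x$n, x$direction, mean(x$distances), max(x$distances)))
  invisible(x)
}

#' Goodness-of-match summary of a distance field
#'
#' The headline allograft-match score is the mean surface distance; the
#' root-mean-square, one-directional maximum (Hausdorff), and the
#' 95th percentile (linear interpolation between order statistics) are
#' reported alongside. Internal ordering `mean <= rms <= max` and
#' `p95 <= max` always holds.
#'
#' @param field a `distance_field` from [surface_distances()].
#' @return a `match_score`: list with `mean_mm`, `rms_mm`, `max_mm`,
#'   `p95_mm`, `n_points`.
#' @export
match_score <- function(field) {
  if (!inherits(field, "distance_field"))
    stop("expected a distance_field", call. = FALSE)
  d <- field$distances
  if (length(d) == 0L) stop("distance field is empty", call. = FALSE)
  structure(list(mean_mm = mean(d),
                 rms_mm = sqrt(mean(d^2)),
                 max_mm = max(d),
                 p95_mm = unname(quantile(d, 0.95, type = 7)),
                 n_points = length(d)),
            class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("<match_score> mean %.3f | rms %.3f | p95 %.3f | max %.3f mm (n = %d)\n",
              x$mean_mm, x$rms_mm, x$p95_mm, x$max_mm, x$n_points))
  invisible(x)
}

#' Color-scale specification for distance maps
#'
#' @param lower_mm,upper_mm distance range mapped onto the colormap;
#'   distances outside are clamped to the end colors. The 0-5 mm default
#'   suits whole-bone allograft comparisons.
#' @param colormap an `hcl.colors()` palette name (default the diverging
#'   `"Blue-Red 3"`: blue = close, red = far).
#' @return an object of class `color_map_spec`.
#' @export
color_map_spec <- function(lower_mm = 0, upper_mm = 5,
                           colormap = "Blue-Red 3") {
  if (!is.finite(lower_mm) || !is.finite(upper_mm) || lower_mm >= upper_mm)
    stop("need lower_mm < upper_mm", call. = FALSE)
  structure(list(lower_mm = lower_mm, upper_mm = upper_mm,
                 colormap = colormap), class = "color_map_spec")
}

distance_colors <- function(distances, spec) {
  t <- (pmin(pmax(distances, spec$lower_mm), spec$upper_mm) - spec$lower_mm) /
    (spec$upper_mm - spec$lower_mm)
  ramp <- colorRamp(hcl.colors(256, palette = spec$colormap))
  rgb <- ramp(t)
  storage.mode(rgb) <- "integer"
  rgb
}

#' Export a colorimetric distance map as a colored PLY
#'
#' Writes the geometry with per-vertex RGB colors encoding the local
#' host-donor distance: `color = colormap((clamp(d) - lower) / (upper -
#' lower))`. A JSON legend (`<path>.legend.json`) records the scale so the
#' colors stay interpretable.
#'
#' @param geometry a [surface_mesh()] or [point_cloud()]; the field must
#'   have one distance per vertex/point.
#' @param field a `distance_field` aligned to `geometry`.
#' @param spec a [color_map_spec()].
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
colorimetric_export <- function(geometry, field, spec = color_map_spec(),
                                path) {
  if (!inherits(field, "distance_field"))
    stop("expected a distance_field", call. = FALSE)
  n <- if (inherits(geometry, "surface_mesh")) nrow(geometry$vertices)
       else if (inherits(geometry, "point_cloud")) nrow(geometry$points)
       else stop("geometry must be a surface_mesh or point_cloud",
                 call. = FALSE)
  if (field$n != n)
    stop("distance field length (", field$n,
         ") does not match geometry size (", n, ")", call. = FALSE)
  cols <- distance_colors(field$distances, spec)
  mesh <- if (inherits(geometry, "surface_mesh"))
    surface_mesh(geometry$vertices, geometry$faces, colors = cols)
  else surface_mesh(geometry$points,
                    matrix(integer(0), 0, 3), colors = cols)
  write_ply(mesh, path, binary = TRUE)
  legend <- list(lower_mm = spec$lower_mm, upper_mm = spec$upper_mm,
                 colormap = spec$colormap, direction = field$direction,
                 clamped = TRUE, units = "mm")
  jsonlite::write_json(legend, paste0(path, ".legend.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Register, score and rank screened donor candidates
#'
#' For each candidate: load its mesh (and landmarks when available),
#' register the host mirror onto it (landmark initialization when donor
#' landmarks exist, principal axes otherwise), compute host-to-donor
#' surface distances, and summarize. Candidates are ranked ascending by
#' mean distance — the match score — with ties broken by `donor_id`.
#' Unreadable candidates are skipped with a warning rather than failing
#' the run.
#'
#' @param host_mesh host-mirror [surface_mesh()] (already mirrored to the
#'   resected side's chirality).
#' @param host_landmarks optional [landmark_set()] of the host mirror.
#' @param candidates a `screening_result` or `bank_index` with `mesh_path`
#'   (and optionally `landmarks_path`) columns.
#' @param config a [registration_config()].
#' @param score_points number of host surface points scored per candidate.
#' @return a `match_report`: list with `table` (ranked data frame:
#'   donor_id, mean/rms/p95/max mm, iterations, converged) and `details`
#'   (per-donor list with the fitted transform, the registration result and
#'   the [match_score()]).
#' @export
rank_candidates <- function(host_mesh, host_landmarks = NULL, candidates,
                            config = registration_config(),
                            score_points = 4000) {
  validate_mesh(host_mesh)
  cand <- as.data.frame(candidates)
  if (nrow(cand) < 1L) stop("no candidates to rank", call. = FALSE)
  if (is.null(cand$mesh_path))
    stop("candidates need a mesh_path column", call. = FALSE)
  details <- list()
  rows <- list()
  cloud <- sample_point_cloud(host_mesh, k = score_points,
                              seed = config$seed)
  for (i in seq_len(nrow(cand))) {
    id <- cand$donor_id[i]
    res <- tryCatch({
      mesh_path <- bank_file(candidates, cand$mesh_path[i])
      donor_mesh <- read_mesh(mesh_path)
      donor_lm <- NULL
      if (!is.null(cand$landmarks_path) && !is.na(cand$landmarks_path[i]) &&
          nzchar(cand$landmarks_path[i])) {
        lm_path <- bank_file(candidates, cand$landmarks_path[i])
        if (file.exists(lm_path)) donor_lm <- read_landmarks(lm_path)
      }
      reg <- register_surfaces(host_mesh, donor_mesh,
                               source_landmarks = host_landmarks,
                               target_landmarks = donor_lm,
                               config = config)
      moved <- apply_transform(cloud, reg$transform)
      field <- surface_distances(moved, donor_mesh)
      score <- match_score(field)
      list(registration = reg, score = score, field = field,
           donor_mesh = donor_mesh)
    }, error = function(e) {
      warning("candidate ", id, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    details[[id]] <- res
    rows[[id]] <- data.frame(donor_id = id,
                             mean_mm = res$score$mean_mm,
                             rms_mm = res$score$rms_mm,
                             p95_mm = res$score$p95_mm,
                             max_mm = res$score$max_mm,
                             n_points = res$score$n_points,
                             iterations = res$registration$iterations_used,
                             converged = res$registration$converged,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no candidate could be registered and scored", call. = FALSE)
  table <- do.call(rbind, rows)
  table <- table[order(table$mean_mm, table$donor_id), , drop = FALSE]
  rownames(table) <- NULL
  structure(list(table = table, details = details[table$donor_id]),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> candidates ranked by mean surface distance:\n")
  print(x$table, digits = 4)
  invisible(x)
}
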
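#' End-to-end allograft selection
#'
#' Runs the full virtual bone bank workflow: (optionally) segment the host
#' CT volume and reconstruct the bone surface, mirror the healthy side
#' across the sagittal plane, measure the host ABC sizes, screen the donor
#' bank for the closest ABC candidates, register each candidate with
#' trimmed ICP, score host-to-donor surface distances, and rank by mean
#' distance. All artifacts (mirrored mesh, ABC row, screening table,
#' per-candidate transforms, colored donor surfaces, ranked JSON report,
#' run manifest) are written under `output_dir`. Fully deterministic for a
#' fixed seed.
#'
#' @param config a list (or path to a JSON file) with entries:
#' \describe{
#'   \item{host_mesh / host_volume}{path to the healthy-side surface mesh
#'     (STL/PLY), or to a CT-like volume (NIfTI/NRRD) to segment first.}
#'   \item{host_landmarks}{path to the healthy-side landmark JSON
#'     (optional; enables landmark-initialized registration and ABC
#'     screening by measurement).}
#'   \item{mirror}{logical, default `TRUE`: reflect the healthy side to
#'     obtain resected-side geometry.}
#'   \item{mirror_plane}{list with `point` and `normal` (default sagittal
#'     plane x = 0).}
#'   \item{healthy_side}{`"left"` or `"right"`; after mirroring, screening
#'     keeps donors of the opposite (resected) side unless
#'     `allow_contralateral` is set.}
#'   \item{bank}{path to the bank CSV.}
#'   \item{screening}{list: `k` (default 5), `weights`, `metric`,
#'     `allow_contralateral` (default `FALSE`).}
#'   \item{segmentation}{list: `low` (default 300), `high`, `connectivity`.}
#'   \item{registration}{list of [registration_config()] arguments.}
#'   \item{scoring}{list: `score_points`, `color_lower_mm`,
#'     `color_upper_mm`, `colormap`, `export_colors` (default `TRUE`).}
#'   \item{output_dir}{output directory.}
#'   \item{seed}{integer seed propagated to all stochastic stages.}
#' }
#' @return a `match_report` (see [rank_candidates()]), invisibly; the
#'   ranked report JSON is at `file.path(output_dir, "report.json")`.
#' @export
select_best_allograft <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("[config] file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- config
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$output_dir %||% stop("[config] output_dir is required",
                                      call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(cfg$bank)) stop("[config] bank CSV path is required",
                              call. = FALSE)
  if (!file.exists(cfg$bank))
    stop("[config] bank CSV not found: ", cfg$bank, call. = FALSE)

  # --- host geometry -------------------------------------------------------
  host_mesh <- if (!is.null(cfg$host_mesh)) {
    if (!file.exists(cfg$host_mesh))
      stop("[segment] host mesh not found: ", cfg$host_mesh, call. = FALSE)
    read_mesh(cfg$host_mesh)
  } else if (!is.null(cfg$host_volume)) {
    if (!file.exists(cfg$host_volume))
      stop("[segment] host volume not found: ", cfg$host_volume,
           call. = FALSE)
    seg <- cfg$segmentation %||% list()
    reconstruct_bone(read_volume(cfg$host_volume),
                     low = seg$low %||% 300, high = seg$high %||% Inf,
                     connectivity = seg$connectivity %||% 26)
  } else stop("[config] either host_mesh or host_volume is required",
              call. = FALSE)
  host_lm <- if (!is.null(cfg$host_landmarks))
    read_landmarks(cfg$host_landmarks) else NULL

  # --- mirror --------------------------------------------------------------
  do_mirror <- cfg$mirror %||% TRUE
  plane <- if (!is.null(cfg$mirror_plane))
    mirror_plane(cfg$mirror_plane$point %||% c(0, 0, 0),
                 cfg$mirror_plane$normal %||% c(1, 0, 0))
  else mirror_plane()
  if (do_mirror) {
    host_mesh <- mirror_mesh(host_mesh, plane)
    if (!is.null(host_lm)) host_lm <- mirror_landmarks(host_lm, plane)
  }
  write_mesh(host_mesh, file.path(out_dir, "host_mirror.stl"))

  # --- measure -------------------------------------------------------------
  host_abc <- if (!is.null(host_lm)) compute_abc(host_lm) else NULL
  if (!is.null(host_abc)) {
    write.csv(data.frame(case = "host_mirror", a_mm = host_abc[["a_mm"]],
                         b_mm = host_abc[["b_mm"]], c_mm = host_abc[["c_mm"]]),
              file.path(out_dir, "host_abc.csv"), row.names = FALSE)
  }

  # --- screen --------------------------------------------------------------
  bank <- read_bank(cfg$bank)
  scr <- cfg$screening %||% list()
  k <- scr$k %||% 5
  resected_side <- if (!is.null(cfg$healthy_side) && do_mirror)
    setdiff(c("left", "right"), cfg$healthy_side) else NULL
  side_filter <- if (isTRUE(scr$allow_contralateral)) NULL else resected_side
  candidates <- if (!is.null(host_abc)) {
    screen_bank(bank, host_abc, k = k,
                weights = scr$weights %||% c(1, 1, 1),
                side = side_filter,
                metric = scr$metric %||% "euclidean")
  } else {
    # no landmarks: no ABC screening possible; forward the whole bank
    # (filtered by side) to surface matching
    sub <- if (is.null(side_filter)) bank
           else build_index(as.data.frame(bank)[bank$side == side_filter, ,
                                                drop = FALSE],
                            root = attr(bank, "root"))
    structure(as.data.frame(sub), root = attr(bank, "root"),
              class = c("screening_result", "data.frame"))
  }
  if (nrow(candidates) == 0L)
    stop("[screen] no donors available after filtering", call. = FALSE)
  write.csv(as.data.frame(candidates),
            file.path(out_dir, "screening.csv"), row.names = FALSE)

  # --- register + score + rank --------------------------------------------
  regcfg_args <- cfg$registration %||% list()
  regcfg_args$seed <- seed
  regcfg <- do.call(registration_config, regcfg_args)
  sc <- cfg$scoring %||% list()
  report <- rank_candidates(host_mesh, host_landmarks = host_lm,
                            candidates = candidates, config = regcfg,
                            score_points = sc$score_points %||% 4000)

  # --- artifacts -----------------------------------------------------------
  cspec <- color_map_spec(sc$color_lower_mm %||% 0, sc$color_upper_mm %||% 5,
                          sc$colormap %||% "Blue-Red 3")
  for (id in names(report$details)) {
    det <- report$details[[id]]
    write_transform(det$registration$transform,
                    file.path(out_dir, paste0(id, ".transform.json")))
    if (!isFALSE(sc$export_colors)) {
      # visualization on the donor surface: donor vertices colored by
      # distance to the registered host mirror (the match score itself
      # remains host-to-donor)
      host_reg <- apply_transform(host_mesh, det$registration$transform)
      dfield <- surface_distances(det$donor_mesh, host_reg,
                                  direction = "donor_vertex_to_host")
      colorimetric_export(det$donor_mesh, dfield, cspec,
                          file.path(out_dir, paste0(id, ".distance.ply")))
    }
  }

  ranked <- report$table
  report_json <- list(
    tool = "vbbank", version = as.character(utils::packageVersion("vbbank")),
    seed = seed,
    host_abc = if (!is.null(host_abc)) as.list(unclass(host_abc)),
    screening = as.data.frame(candidates)[,
      intersect(c("donor_id", "abc_distance_mm", "delta_a_mm", "delta_b_mm",
                  "delta_c_mm"), names(candidates)), drop = FALSE],
    ranking = ranked,
    best_donor = ranked$donor_id[1],
    transforms = lapply(report$details, function(d) {
      m <- d$registration$transform
      rbind(cbind(m$rotation, m$translation), c(0, 0, 0, 1))
    }),
    parameters = list(registration = unclass(regcfg),
                      screening = list(k = k, side = side_filter),
                      scoring = list(color_lower_mm = cspec$lower_mm,
                                     color_upper_mm = cspec$upper_mm,
                                     colormap = cspec$colormap)))
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  manifest <- list(seed = seed, config = cfg,
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
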
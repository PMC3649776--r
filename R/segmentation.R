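#' Binary segmentation mask
#'
#' Boolean voxel grid sharing the geometry of its source volume.
#'
#' @param mask 3D logical array.
#' @param spacing_mm,origin_mm geometry, as in [voxel_volume()].
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(mask, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D logical array", call. = FALSE)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing_mm = rep_len(as.numeric(spacing_mm), 3L),
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d set (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Dual-threshold intensity segmentation
#'
#' Classifies voxels as bone when `low <= intensity <= high`. This is the
#' intensity-based pixel classification step of the bone-model workflow:
#' cortical bone is high-attenuation, so a lower threshold around 300
#' HU-equivalent isolates it from soft tissue in CT-like volumes.
#'
#' @param volume a [voxel_volume()].
#' @param low,high inclusive intensity bounds; `low < high` required.
#' @return a [binary_mask()]. An all-false result triggers a warning, not
#'   an error.
#' @export
threshold_segment <- function(volume, low = 300, high = Inf) {
  if (!inherits(volume, "voxel_volume"))
    stop("expected a voxel_volume", call. = FALSE)
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stop("need low < high", call. = FALSE)
  m <- volume$intensities >= low & volume$intensities <= high
  if (!any(m))
    warning("threshold [", low, ", ", high, "] selected no voxels")
  binary_mask(m, volume$spacing_mm, volume$origin_mm)
}

#' Keep the largest connected component
#'
#' Isolates the bone of interest from disconnected structures (other bones,
#' table, artifacts) by retaining only the component with the most voxels.
#' Ties are broken in favor of the component containing the smallest linear
#' voxel index. Idempotent.
#'
#' @param mask a [binary_mask()] with at least one set voxel.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners, default).
#' @return a [binary_mask()] containing exactly one component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  if (!inherits(mask, "binary_mask"))
    stop("expected a binary_mask", call. = FALSE)
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (!any(mask$mask)) stop("mask is empty", call. = FALSE)
  labels <- cpp_label_components(as.vector(mask$mask), dim(mask$mask),
                                 as.integer(connectivity))
  counts <- tabulate(labels)
  best <- which(counts == max(counts))[1] # labels follow scan order: smallest
                                          # first-voxel index wins ties
  out <- array(labels == best, dim = dim(mask$mask))
  binary_mask(out, mask$spacing_mm, mask$origin_mm)
}

# separable Gaussian smoothing by direct shifted sums (clamped borders)
gaussian_smooth_3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  d <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, d)
    for (t in -r:r) {
      idx <- pmin(pmax(seq_len(d[axis]) + t, 1L), d[axis])
      shifted <- switch(axis,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[t + r + 1] * shifted
    }
    arr <- out
  }
  arr
}

#' Extract an isosurface mesh from a volume or mask
#'
#' Marching-tetrahedra isosurface extraction with linear interpolation,
#' producing a triangle mesh in world millimetres (`origin + index *
#' spacing`) with consistent outward orientation. For a [binary_mask()] the
#' iso level defaults to 0.5, placing the surface midway between inside and
#' outside voxel centers. Optional Gaussian pre-smoothing (in voxel units)
#' is off by default.
#'
#' @param x a [voxel_volume()] or [binary_mask()].
#' @param iso_level iso value; must lie strictly between the field's min
#'   and max. Default 0.5 for masks.
#' @param smooth_sigma_vox Gaussian pre-smoothing sigma in voxels (0 = off).
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(x, iso_level = NULL, smooth_sigma_vox = 0) {
  if (inherits(x, "binary_mask")) {
    field <- array(as.numeric(x$mask), dim = dim(x$mask))
    if (is.null(iso_level)) iso_level <- 0.5
  } else if (inherits(x, "voxel_volume")) {
    field <- x$intensities
    if (is.null(iso_level))
      stop("iso_level is required for intensity volumes", call. = FALSE)
  } else stop("expected a voxel_volume or binary_mask", call. = FALSE)
  if (iso_level <= min(field) || iso_level >= max(field))
    stop("iso_level must lie strictly between the field minimum (",
         min(field), ") and maximum (", max(field), ")", call. = FALSE)
  if (smooth_sigma_vox > 0) field <- gaussian_smooth_3d(field, smooth_sigma_vox)
  surf <- cpp_marching_tetra(as.vector(field), dim(field), iso_level,
                             x$origin_mm, x$spacing_mm)
  surface_mesh(surf$vertices, surf$faces)
}

#' Segment a CT-like volume and reconstruct the bone surface
#'
#' The full image-to-model chain: dual-threshold segmentation, largest
#' connected component, isosurface extraction. Equivalent to calling
#' [threshold_segment()], [largest_component()] and [extract_surface()] in
#' sequence.
#'
#' @param volume a [voxel_volume()].
#' @inheritParams threshold_segment
#' @inheritParams largest_component
#' @inheritParams extract_surface
#' @return a [surface_mesh()] of the reconstructed bone.
#' @export
reconstruct_bone <- function(volume, low = 300, high = Inf,
                             connectivity = 26, smooth_sigma_vox = 0) {
  mask <- threshold_segment(volume, low = low, high = high)
  mask <- largest_component(mask, connectivity = connectivity)
  extract_surface(mask, smooth_sigma_vox = smooth_sigma_vox)
}
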
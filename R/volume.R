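#' CT-like voxel volume
#'
#' A 3D intensity grid with physical geometry: voxel `(i, j, k)` (0-based)
#' has its center at `origin_mm + c(i, j, k) * spacing_mm`. The array uses
#' R's column-major layout with the first index fastest. Axis order is the
#' file/header order; oblique acquisitions are not supported.
#'
#' @param intensities 3D numeric array.
#' @param spacing_mm length-3 positive voxel spacing, mm.
#' @param origin_mm length-3 world position of voxel (0,0,0)'s center, mm.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array", call. = FALSE)
  if (any(dim(intensities) < 2L))
    stop("each volume dimension must be >= 2", call. = FALSE)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be positive and finite", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, axis_order = "ijk=xyz"),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, intensity range [%.1f, %.1f]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Read and write intensity volumes (NIfTI, NRRD)
#'
#' NIfTI (`.nii`, `.nii.gz`) goes through the RNifti library; spacing and
#' origin are taken from the header. NRRD (`.nrrd`) support is a minimal
#' reader/writer for attached raw/gzip little-endian files with axis-aligned
#' space directions.
#'
#' @param path file path; format chosen by extension.
#' @param volume a [voxel_volume()].
#' @return `read_volume` returns a [voxel_volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) read_volume_nifti(path)
  else if (grepl("\\.nrrd$", lower)) read_volume_nrrd(path)
  else stop("unsupported volume format (use .nii, .nii.gz, or .nrrd): ",
            path, call. = FALSE)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "voxel_volume"))
    stop("expected a voxel_volume", call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) write_volume_nifti(volume, path)
  else if (grepl("\\.nrrd$", lower)) write_volume_nrrd(volume, path)
  else stop("unsupported volume format (use .nii, .nii.gz, or .nrrd): ",
            path, call. = FALSE)
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  aff <- RNifti::xform(img)
  spacing <- abs(RNifti::pixdim(img)[1:3])
  origin <- aff[1:3, 4]
  voxel_volume(array(as.numeric(img), dim = dim(img)), spacing_mm = spacing,
               origin_mm = origin)
}

write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing_mm
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing_mm
  aff[1:3, 4] <- volume$origin_mm
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
}

read_volume_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_con_line(con)
  if (is.null(magic) || !grepl("^NRRD000", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- read_con_line(con)
    if (is.null(line)) stop("truncated NRRD header: ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*", fixed = FALSE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L)
    stop("only 3D NRRD volumes are supported: ", path, call. = FALSE)
  type <- fields$type
  enc <- fields$encoding
  if (!enc %in% c("raw", "gzip", "gz"))
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dm <- t(vapply(dirs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(dm^2))
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  size_of <- switch(type,
                    "double" = 8L, "float" = 4L,
                    "short" = 2L, "int16" = 2L, "unsigned short" = 2L,
                    "uint16" = 2L, "int" = 4L, "int32" = 4L,
                    "uchar" = 1L, "uint8" = 1L,
                    stop("unsupported NRRD type: ", type, call. = FALSE))
  payload <- readBin(con, "raw", file.size(path))
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  if (length(payload) < n * size_of)
    stop("truncated NRRD data block: ", path, call. = FALSE)
  what <- if (type %in% c("double", "float")) "numeric" else "integer"
  signed <- !type %in% c("unsigned short", "uint16", "uchar", "uint8")
  vals <- readBin(payload, what, n = n, size = size_of, signed = signed,
                  endian = "little")
  voxel_volume(array(as.numeric(vals), dim = sizes), spacing_mm = spacing,
               origin_mm = origin)
}

write_volume_nrrd <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(volume$intensities)
  s <- volume$spacing_mm
  o <- volume$origin_mm
  hdr <- c("NRRD0004",
           "# written by vbbank",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           "endian: little",
           "encoding: gzip",
           "space dimension: 3",
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   s[1], s[2], s[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)", o[1], o[2], o[3]),
           "")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  raw <- writeBin(as.numeric(volume$intensities), raw(), size = 8,
                  endian = "little")
  writeBin(memCompress(raw, type = "gzip"), con)
}
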
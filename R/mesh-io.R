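#' Read a triangle mesh from STL or PLY
#'
#' Supports binary and ASCII STL, and ASCII or binary little-endian PLY.
#' STL carries no connectivity, so identical vertex coordinates are merged
#' on read to rebuild shared faces. PLY per-vertex `uchar red/green/blue`
#' colors are preserved. Coordinates are assumed to be millimetres.
#'
#' @param path file path; format chosen by extension (`.stl`, `.ply`).
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format '", ext, "' (use .stl or .ply)",
              call. = FALSE))
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; format chosen by extension.
#' @param binary write the binary flavor (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  validate_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path, binary = binary),
         stop("unsupported mesh format '", ext, "' (use .stl or .ply)",
              call. = FALSE))
  invisible(path)
}

# ---- STL -------------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head5 <- readBin(con, "raw", 5)
  size <- file.size(path)
  if (identical(rawToChar(head5), "solid")) {
    # could still be binary with a header starting "solid"; check size rule
    rest <- readBin(con, "raw", 79)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(ntri) && length(ntri) == 1 && size == 84 + 50 * as.numeric(ntri))
      return(read_stl_binary_body(con, ntri))
    return(read_stl_ascii(path))
  }
  readBin(con, "raw", 75)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(ntri) || size != 84 + 50 * as.numeric(ntri))
    stop("corrupt binary STL: triangle count does not match file size",
         call. = FALSE)
  read_stl_binary_body(con, ntri)
}

read_stl_binary_body <- function(con, ntri) {
  raw <- readBin(con, "raw", 50 * ntri)
  if (length(raw) < 50 * ntri) stop("truncated binary STL", call. = FALSE)
  # each record: 12 float32 then uint16; peel floats record-wise
  idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L + rep(1:48, ntri)
  floats <- readBin(raw[idx], "numeric", n = 12L * ntri, size = 4,
                    endian = "little")
  m <- matrix(floats, ncol = 12, byrow = TRUE)
  tri_soup_to_mesh(m[, 4:12, drop = FALSE])
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0)
    stop("corrupt ASCII STL: vertex count not a multiple of 3", call. = FALSE)
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(nums)) stop("corrupt ASCII STL: non-numeric vertex", call. = FALSE)
  soup <- matrix(t(nums), ncol = 9, byrow = TRUE)
  tri_soup_to_mesh(soup)
}

# rows of 9 numbers (v1 v2 v3) -> mesh with merged identical vertices
tri_soup_to_mesh <- function(soup) {
  ntri <- nrow(soup)
  verts <- rbind(soup[, 1:3, drop = FALSE], soup[, 4:6, drop = FALSE],
                 soup[, 7:9, drop = FALSE])
  # order back to per-face corner layout
  ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
  verts <- verts[ord, , drop = FALSE]
  key <- paste(verts[, 1], verts[, 2], verts[, 3], sep = "_")
  uid <- match(key, unique(key))
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts[!duplicated(uid), , drop = FALSE], faces)
}

write_stl <- function(mesh, path, binary = TRUE) {
  fc <- face_corners(mesh)
  fn <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "vbbank binary STL (units: mm)"))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
    rec <- cbind(fn, fc$a, fc$b, fc$c) # ntri x 12
    floats <- writeBin(as.vector(t(rec)), raw(), size = 4, endian = "little")
    recraw <- matrix(raw(50 * nrow(rec)), nrow = 50)
    recraw[1:48, ] <- matrix(floats, nrow = 48)
    writeBin(as.vector(recraw), con)
  } else {
    lines <- c("solid vbbank")
    tri <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      fn[, 1], fn[, 2], fn[, 3],
      fc$a[, 1], fc$a[, 2], fc$a[, 3],
      fc$b[, 1], fc$b[, 2], fc$b[, 3],
      fc$c[, 1], fc$c[, 2], fc$c[, 3])
    writeLines(c(lines, tri, "endsolid vbbank"), path)
  }
  invisible(path)
}

# ---- PLY -------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read header line-wise
  hdr <- character()
  repeat {
    line <- read_con_line(con)
    if (is.null(line)) stop("corrupt PLY: header not terminated", call. = FALSE)
    hdr <- c(hdr, line)
    if (line == "end_header") break
    if (length(hdr) > 500) stop("corrupt PLY header", call. = FALSE)
  }
  if (hdr[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  fmt <- strsplit(fmt, "\\s+")[[1]][1]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt, call. = FALSE)

  elements <- list()
  cur <- NULL
  for (line in hdr) {
    tk <- strsplit(trimws(line), "\\s+")[[1]]
    if (tk[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tk[2], count = as.integer(tk[3]), props = list())
    } else if (tk[1] == "property" && !is.null(cur)) {
      if (tk[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tk[5], list = TRUE, count_type = tk[3], type = tk[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tk[3], list = FALSE, type = tk[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY must contain vertex and face elements", call. = FALSE)

  if (fmt == "ascii") read_ply_ascii(con, elements)
  else read_ply_binary(con, elements)
}

read_con_line <- function(con) {
  chars <- raw()
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) return(NULL)
    if (b == as.raw(10)) break
    chars <- c(chars, b)
  }
  sub("\r$", "", rawToChar(chars))
}

read_ply_ascii <- function(con, elements) {
  rest <- strsplit(readChar(con, 1e8, useBytes = TRUE), "\r?\n")[[1]]
  ve <- elements$vertex
  fe <- elements$face
  if (length(rest) < ve$count + fe$count)
    stop("truncated PLY body", call. = FALSE)
  vnames <- vapply(ve$props, `[[`, "", "name")
  vdat <- matrix(NA_real_, ve$count, length(vnames),
                 dimnames = list(NULL, vnames))
  vt <- do.call(rbind, lapply(strsplit(trimws(rest[seq_len(ve$count)]),
                                       "\\s+"), as.numeric))
  vdat[] <- vt[, seq_along(vnames), drop = FALSE]
  flines <- strsplit(trimws(rest[ve$count + seq_len(fe$count)]), "\\s+")
  faces <- t(vapply(flines, function(x) {
    n <- as.integer(x[1])
    if (n != 3L) stop("only triangle PLY faces are supported", call. = FALSE)
    as.integer(x[2:4])
  }, integer(3))) + 1L
  ply_assemble(vdat, faces)
}

read_ply_binary <- function(con, elements) {
  ve <- elements$vertex
  types <- vapply(ve$props, `[[`, "", "type")
  if (any(vapply(ve$props, `[[`, TRUE, "list")))
    stop("list properties on PLY vertices are not supported", call. = FALSE)
  sizes <- ply_type_size[types]
  if (anyNA(sizes)) stop("unknown PLY property type", call. = FALSE)
  stride <- sum(sizes)
  raw <- readBin(con, "raw", stride * ve$count)
  if (length(raw) < stride * ve$count) stop("truncated PLY body", call. = FALSE)
  vnames <- vapply(ve$props, `[[`, "", "name")
  vdat <- matrix(NA_real_, ve$count, length(vnames),
                 dimnames = list(NULL, vnames))
  off <- 0L
  for (p in seq_along(ve$props)) {
    sz <- sizes[p]
    sel <- rep((seq_len(ve$count) - 1L) * stride, each = sz) +
      rep(off + seq_len(sz), ve$count)
    bytes <- raw[sel]
    ty <- types[p]
    vdat[, p] <- if (ty %in% c("float", "float32", "double", "float64"))
      readBin(bytes, "numeric", ve$count, size = sz, endian = "little")
    else if (ty %in% c("uchar", "uint8"))
      as.integer(bytes[seq(1, length(bytes), by = 1)])
    else
      readBin(bytes, "integer", ve$count, size = sz, endian = "little")
    off <- off + sz
  }
  fe <- elements$face
  fp <- fe$props[[1]]
  if (!fp$list) stop("PLY face element must be a list property", call. = FALSE)
  csz <- ply_type_size[fp$count_type]
  isz <- ply_type_size[fp$type]
  faces <- matrix(0L, fe$count, 3)
  for (i in seq_len(fe$count)) {
    n <- readBin(readBin(con, "raw", csz), "integer", 1, size = csz,
                 endian = "little")
    if (n != 3L) stop("only triangle PLY faces are supported", call. = FALSE)
    faces[i, ] <- readBin(readBin(con, "raw", 3 * isz), "integer", 3,
                          size = isz, endian = "little")
  }
  ply_assemble(vdat, faces + 1L)
}

ply_assemble <- function(vdat, faces) {
  cn <- colnames(vdat)
  if (!all(c("x", "y", "z") %in% cn))
    stop("PLY vertex element must have x, y, z", call. = FALSE)
  colors <- NULL
  if (all(c("red", "green", "blue") %in% cn)) {
    colors <- vdat[, c("red", "green", "blue"), drop = FALSE]
    storage.mode(colors) <- "integer"
    dimnames(colors) <- NULL
  }
  surface_mesh(vdat[, c("x", "y", "z"), drop = FALSE], faces, colors = colors)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_col <- !is.null(mesh$colors)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment vbbank surface mesh (units: mm)",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    vraw <- writeBin(as.vector(t(mesh$vertices)), raw(), size = 8,
                     endian = "little")
    if (has_col) {
      vm <- matrix(vraw, nrow = 24)
      craw <- matrix(as.raw(t(mesh$colors)), nrow = 3)
      rec <- rbind(vm, craw)
      writeBin(as.vector(rec), con)
    } else writeBin(vraw, con)
    f0 <- t(mesh$faces) - 1L
    fraw <- matrix(raw(13 * nf), nrow = 13)
    fraw[1, ] <- as.raw(3)
    fraw[2:13, ] <- matrix(writeBin(as.integer(f0), raw(), size = 4,
                                    endian = "little"), nrow = 12)
    writeBin(as.vector(fraw), con)
  } else {
    vl <- if (has_col)
      sprintf("%.17g %.17g %.17g %d %d %d",
              mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
              mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3])
    else
      sprintf("%.17g %.17g %.17g",
              mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
    fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}
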
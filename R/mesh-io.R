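# Mesh file I/O: PLY (ascii + binary little-endian), binary STL, and OBJ.
# Minimal dialects: vertex positions and triangular faces only.

#' Load a meniscus mesh from a PLY, STL or OBJ file
#'
#' The dialect is chosen by file extension. Coordinates are taken as
#' millimetres verbatim. Binary STL vertices are de-duplicated so faces share
#' vertices; PLY and OBJ are read as stored.
#'
#' @param path mesh file (`.ply`, `.stl` or `.obj`).
#' @param patient_id,side,laterality anatomical metadata, see
#'   [meniscus_mesh()].
#' @param root_anterior,root_posterior root landmark coordinates (mm).
#' @param validate check mesh invariants after reading.
#' @return A [meniscus_mesh()].
#' @export
load_mesh <- function(path, patient_id = "unknown", side = "medial",
                      laterality = "right", root_anterior, root_posterior,
                      validate = TRUE) {
  if (!file.exists(path)) stopf("mesh file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  geo <- switch(ext,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    stopf("unsupported mesh format '.%s' (expected ply, stl or obj)", ext))
  meniscus_mesh(geo$vertices, geo$faces, patient_id, side, laterality,
                root_anterior, root_posterior, validate = validate)
}

#' Save a meniscus mesh to a PLY, STL or OBJ file
#'
#' @param mesh a [meniscus_mesh()].
#' @param path output file; format chosen by extension (`.ply` ascii by
#'   default, `.stl` binary, `.obj`).
#' @param binary for PLY: write binary little-endian instead of ascii.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, binary = FALSE) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  if (file.access(dir, 2L) != 0L) stopf("directory is not writable: %s", dir)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh$vertices, mesh$faces, path, binary = binary),
    stl = write_stl(mesh$vertices, mesh$faces, path),
    obj = write_obj(mesh$vertices, mesh$faces, path),
    stopf("unsupported mesh format '.%s' (expected ply, stl or obj)", ext))
  invisible(path)
}

# ---- PLY ------------------------------------------------------------------

# read one newline-terminated line from a binary connection without buffering
# past it (the payload may be binary)
read_line_bin <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (!length(b)) break
    if (b == as.raw(10L)) break
    out <- c(out, b)
  }
  rawToChar(out[out != as.raw(13L)])
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_line_bin(con)
  if (!identical(trimws(magic), "ply")) stopf("not a PLY file: %s", path)
  fmt <- NULL
  nv <- nf <- NA_integer_
  vprops <- character()
  in_vertex <- FALSE
  repeat {
    line <- trimws(read_line_bin(con))
    if (!nzchar(line)) stopf("unexpected end of PLY header")
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.na(nv) || is.na(nf)) stopf("PLY header lacks vertex/face counts")
  if (!all(c("x", "y", "z") %in% vprops))
    stopf("PLY vertex element lacks x/y/z properties")
  np <- length(vprops)
  xyz <- match(c("x", "y", "z"), vprops)
  if (identical(fmt, "ascii")) {
    lines <- readLines(con)
    lines <- lines[nzchar(trimws(lines))]
    vdat <- do.call(rbind, lapply(lines[seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    v <- vdat[, xyz, drop = FALSE]
    f <- do.call(rbind, lapply(lines[nv + seq_len(nf)], function(l) {
      x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (x[1] != 3L) stopf("only triangular PLY faces are supported")
      x[2:4]
    }))
  } else if (identical(fmt, "binary_little_endian")) {
    raw_v <- readBin(con, "numeric", n = nv * np, size = 4L,
                     endian = "little")
    vdat <- matrix(raw_v, ncol = np, byrow = TRUE)
    v <- vdat[, xyz, drop = FALSE]
    f <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
      if (k != 3L) stopf("only triangular PLY faces are supported")
      f[i, ] <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
    }
  } else stopf("unsupported PLY format '%s'", fmt %||% "?")
  list(vertices = v, faces = f + 1L)
}

write_ply <- function(vertices, faces, path, binary = FALSE) {
  nv <- nrow(vertices)
  nf <- nrow(faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(vertices)), con, size = 4L, endian = "little")
    f0 <- faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g",
                       vertices[, 1], vertices[, 2], vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d",
                       faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
  invisible(path)
}

# ---- binary STL -----------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(nf) || nf < 1L) stopf("invalid binary STL: %s", path)
  tri <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) stopf("truncated binary STL: %s", path)
    tri[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  # de-duplicate vertices (STL stores each triangle independently)
  key <- apply(round(tri, 6L), 1L, paste, collapse = "_")
  uk <- !duplicated(key)
  v <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  f <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

write_stl <- function(vertices, faces, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  nf <- nrow(faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  for (i in seq_len(nf)) {
    a <- vertices[faces[i, 1], ]
    b <- vertices[faces[i, 2], ]
    c_ <- vertices[faces[i, 3], ]
    n <- c((b[2]-a[2])*(c_[3]-a[3]) - (b[3]-a[3])*(c_[2]-a[2]),
           (b[3]-a[3])*(c_[1]-a[1]) - (b[1]-a[1])*(c_[3]-a[3]),
           (b[1]-a[1])*(c_[2]-a[2]) - (b[2]-a[2])*(c_[1]-a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, a, b, c_)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines) || !length(flines))
    stopf("OBJ file has no vertices or no faces: %s", path)
  v <- do.call(rbind, lapply(vlines, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4])))
  f <- do.call(rbind, lapply(flines, function(l) {
    tok <- strsplit(l, "\\s+")[[1]][-1]
    if (length(tok) != 3L) stopf("only triangular OBJ faces are supported")
    as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L))
  }))
  list(vertices = v, faces = f)
}

write_obj <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}
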
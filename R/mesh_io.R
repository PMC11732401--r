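#' Read a triangular mesh from PLY, STL or OBJ
#'
#' Format is chosen by file extension. PLY may be ASCII or binary
#' little-endian; STL may be ASCII or binary; OBJ is ASCII (only `v`/`f`
#' records are used, polygonal faces are fan-triangulated). Coordinates are
#' taken to be millimetres.
#'
#' @param path file path.
#' @return a [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         stop("unsupported mesh format: .", ext,
              " (supported: ply, stl, obj)"))
}

#' Write a triangular mesh to PLY, STL or OBJ
#'
#' @param mesh a [surface_mesh].
#' @param path output path; extension selects the format.
#' @param binary for PLY, write binary little-endian instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, binary = binary),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY: premature end of header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 200L) stop("PLY: header too long / malformed")
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY: missing vertex/face elements")
  # vertex property layout (only float/double properties before face element)
  vstart <- grep("^element vertex", header)
  vend <- grep("^element face", header)
  vprops <- grep("^property ", header[vstart:vend], value = TRUE)
  vtypes <- vapply(strsplit(trimws(vprops), "\\s+"), `[`, "", 2L)
  vnames <- vapply(strsplit(trimws(vprops), "\\s+"), `[`, "", 3L)
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) stop("PLY: vertex element lacks x/y/z properties")
  if (identical(fmt, "ascii")) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vdat <- utils::read.table(text = txt[seq_len(nv)])
    v <- as.matrix(vdat[, xyz])
    frows <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    f <- t(vapply(frows, function(r) as.integer(r[2:4]), integer(3)))
    if (any(vapply(frows, function(r) as.integer(r[1]), 1L) != 3L))
      stop("PLY: non-triangular faces not supported")
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
               int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L)
    vsz <- sizes[vtypes]
    if (anyNA(vsz)) stop("PLY: unsupported vertex property type")
    v <- matrix(0, nv, 3)
    off <- cumsum(c(0L, vsz))[xyz]
    rowlen <- sum(vsz)
    raw <- readBin(con, "raw", n = nv * rowlen)
    for (d in 1:3) {
      k <- xyz[d]
      typ <- vtypes[k]
      at <- rep((seq_len(nv) - 1L) * rowlen + off[d], each = vsz[k]) +
        seq_len(vsz[k])
      v[, d] <- readBin(raw[at],
                        what = if (typ %in% c("float", "float32", "double", "float64")) "double" else "integer",
                        size = vsz[k], n = nv, endian = "little")
    }
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", size = 1L, n = 1L, signed = FALSE)
      if (cnt != 3L) stop("PLY: non-triangular faces not supported")
      f[i, ] <- readBin(con, "integer", size = 4L, n = 3L, endian = "little")
    }
  } else stop("PLY: unsupported format ", fmt)
  surface_mesh(v, f + 1L, validate = FALSE)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment units mm",
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    vtxt <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
    ftxt <- apply(f, 1, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c(hdr, vtxt, ftxt), path)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(r) as.numeric(r[2:4]), numeric(3)))
  faces <- list()
  for (r in strsplit(trimws(fl), "\\s+")) {
    idx <- as.integer(sub("/.*", "", r[-1]))
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- c(idx[1], idx[k + 1L], idx[k + 2L])
  }
  surface_mesh(v, do.call(rbind, faces), validate = FALSE)
}

write_obj <- function(mesh, path) {
  v <- apply(mesh$vertices, 1, function(r)
    paste("v", paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " ")))
  f <- apply(mesh$faces, 1, function(r) paste("f", paste(r, collapse = " ")))
  writeLines(c("# units mm", v, f), path)
  invisible(path)
}

read_stl <- function(path) {
  # sniff ASCII vs binary: ASCII files start with "solid" and contain "facet"
  head_raw <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(r) as.numeric(r[2:4]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    nf <- readBin(con, "integer", size = 4L, endian = "little")
    rec <- readBin(con, "raw", n = nf * 50L)
    m <- matrix(rec, nrow = 50L)            # one facet record per column
    coords <- readBin(as.vector(m[13:48, , drop = FALSE]), "double",
                      size = 4L, n = nf * 9L, endian = "little")
    v <- matrix(coords, ncol = 3L, byrow = TRUE)
  }
  # weld exactly coincident vertices
  key <- apply(v, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- v[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, f, validate = FALSE)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  out <- character(2L + nrow(f) * 7L)
  out[1] <- "solid atriamesh"
  k <- 2L
  fmt <- function(r) paste(format(r, digits = 9, trim = TRUE), collapse = " ")
  for (i in seq_len(nrow(f))) {
    out[k] <- paste("facet normal", fmt(n[i, ])); k <- k + 1L
    out[k] <- "  outer loop"; k <- k + 1L
    for (j in 1:3) { out[k] <- paste("    vertex", fmt(v[f[i, j], ])); k <- k + 1L }
    out[k] <- "  endloop"; k <- k + 1L
    out[k] <- "endfacet"; k <- k + 1L
  }
  out[k] <- "endsolid atriamesh"
  writeLines(out[seq_len(k)], path)
  invisible(path)
}
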
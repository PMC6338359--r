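# Triangle-mesh file I/O: PLY (ascii + binary_little_endian), OBJ (ascii)
# and STL (ascii + binary). These are deliberately minimal readers/writers
# for plain triangle geometry; attributes beyond vertex positions and faces
# are ignored on read and not written.

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' The format is chosen by file extension. Polygonal OBJ faces are
#' fan-triangulated; STL facets are welded on exactly coincident vertices.
#'
#' @param path input file path (`.ply`, `.obj` or `.stl`).
#' @return A [triangle_mesh].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path),
         fs_abort(sprintf("unsupported mesh format '%s'", ext),
                  "fastsurf_invalid_input"))
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a [triangle_mesh].
#' @param path output path; the extension selects the format.
#' @param binary for PLY, write `binary_little_endian` instead of ascii
#'   (ignored for OBJ; STL is always written ascii).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, binary),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path),
         fs_abort(sprintf("unsupported mesh format '%s'", ext),
                  "fastsurf_invalid_input"))
  invisible(path)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  fmt <- if (binary) "binary_little_endian 1.0" else "ascii 1.0"
  header <- c("ply", paste("format", fmt),
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(format(v, digits = 17, scientific = FALSE,
                            trim = TRUE), 1, paste, collapse = " "), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 1000)
      fs_abort("malformed PLY header", "fastsurf_invalid_input")
  }
  fmt <- sub("^format ", "", grep("^format ", header, value = TRUE)[1])
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face", header, value = TRUE)[1]))
  # vertex property types (only the leading x/y/z are used)
  vprops <- grep("^property (double|float)", header, value = TRUE)
  vtype <- sub("^property (double|float).*", "\\1", vprops[1])
  vsize <- if (identical(vtype, "double")) 8L else 4L
  nprop <- length(vprops)
  if (startsWith(fmt, "binary_little_endian")) {
    raw_v <- readBin(con, "numeric", n = nv * nprop, size = vsize,
                     endian = "little")
    vm <- matrix(raw_v, ncol = nprop, byrow = TRUE)[, 1:3, drop = FALSE]
    fm <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      if (cnt != 3L)
        fs_abort("only triangle PLY faces are supported",
                 "fastsurf_invalid_input")
      fm[i, ] <- idx + 1L
    }
  } else {
    lines <- readLines(con)
    vm <- matrix(scan(text = lines[seq_len(nv)], quiet = TRUE),
                 ncol = nprop, byrow = TRUE)[, 1:3, drop = FALSE]
    fvals <- lapply(strsplit(trimws(lines[nv + seq_len(nf)]), "\\s+"),
                    as.integer)
    if (any(vapply(fvals, `[`, 1L, i = 1L) != 3L))
      fs_abort("only triangle PLY faces are supported",
               "fastsurf_invalid_input")
    fm <- do.call(rbind, lapply(fvals, function(x) x[2:4] + 1L))
  }
  triangle_mesh(vm, fm)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- format(mesh$vertices, digits = 17, scientific = FALSE, trim = TRUE)
  writeLines(paste("v", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  vm <- matrix(scan(text = gsub("^v\\s+", "", vlines), quiet = TRUE),
               ncol = 3, byrow = TRUE)
  faces <- list()
  for (fl in flines) {
    toks <- strsplit(trimws(sub("^f\\s+", "", fl)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", i = 1L))
    idx[idx < 0] <- nrow(vm) + 1L + idx[idx < 0]
    for (k in seq_len(length(idx) - 2))  # fan triangulation
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  triangle_mesh(vm, do.call(rbind, faces))
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines("solid fastsurf", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
           (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
           (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
                 sprintf("      vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
                 sprintf("      vertex %.17g %.17g %.17g",
                         c_[1], c_[2], c_[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid fastsurf", con)
}

read_stl <- function(path) {
  # sniff: ascii STL starts with "solid" and contains "facet"
  head_raw <- readBin(path, "raw", n = 512)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    coords <- matrix(scan(text = gsub("^\\s*vertex\\s+", "", vlines),
                          quiet = TRUE), ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    coords <- matrix(0, nf * 3, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      coords[(i - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, byrow = TRUE)
      readBin(con, "raw", n = 2)
    }
  }
  # weld exactly coincident vertices
  key <- apply(coords, 1, paste, collapse = "|")
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}
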
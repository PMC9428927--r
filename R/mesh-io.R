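# Readers/writers for Wavefront OBJ, PLY (ascii + binary little-endian) and
# STL (ascii + binary). Units are taken as millimetres as-is; no rescaling.
# STL repeats vertices per facet, so vertices are de-duplicated on load at a
# 1e-8 mm tolerance.

DEDUP_TOL <- 1e-8

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("obj", "ply", "stl")) ext else
    stop("cannot guess mesh format from extension: ", path)
}

#' Load a triangle mesh from OBJ, PLY or STL
#'
#' Non-triangular faces are triangulated fan-wise with a warning. STL input
#' (which stores one vertex record per facet corner) is de-duplicated at
#' 1e-8 mm.
#'
#' @param path file path.
#' @param format "auto" (by extension), "obj", "ply" or "stl".
#' @param name mesh label; defaults to the file name.
#' @return a [tri_mesh()].
#' @export
load_mesh <- function(path, format = "auto", name = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  format <- match.arg(format, c("auto", "obj", "ply", "stl"))
  if (format == "auto") format <- guess_format(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  m <- switch(format,
              obj = read_obj(path),
              ply = read_ply(path),
              stl = read_stl(path))
  if (nrow(m$vertices) == 0L || nrow(m$faces) == 0L)
    stop("empty mesh: ", path)
  tri_mesh(m$vertices, m$faces, name = name)
}

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' @param mesh a [tri_mesh()].
#' @param path output path; the extension picks the format unless `format`
#'   is given.
#' @param format "auto", "obj", "ply" or "stl".
#' @param binary write binary PLY/STL instead of ASCII.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = "auto", binary = FALSE) {
  stopifnot(is_tri_mesh(mesh))
  format <- match.arg(format, c("auto", "obj", "ply", "stl"))
  if (format == "auto") format <- guess_format(path)
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, binary),
         stl = write_stl(mesh, path, binary))
  invisible(path)
}

fan_triangulate <- function(idx_list) {
  # list of integer vectors (length >= 3) -> m x 3 matrix
  out <- lapply(idx_list, function(ix) {
    if (length(ix) == 3L) return(matrix(ix, 1, 3))
    cbind(ix[1], ix[2:(length(ix) - 1)], ix[3:length(ix)])
  })
  do.call(rbind, out)
}

dedup_vertices <- function(v, f, tol = DEDUP_TOL) {
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  # match against the compacted key table gives compact 1-based indices
  remap <- match(key, key[first])
  list(vertices = v[first, , drop = FALSE],
       faces = matrix(remap[f], ncol = 3))
}

# --- OBJ -------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  fidx <- lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    as.integer(vapply(strsplit(x, "/"), `[[`, "", 1))
  })
  sizes <- lengths(fidx)
  if (any(sizes < 3L)) stop("OBJ face with fewer than 3 vertices")
  if (any(sizes > 3L))
    warning("non-triangular OBJ faces triangulated fan-wise")
  list(vertices = v, faces = fan_triangulate(fidx))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", mesh$name), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

# --- PLY -------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("unterminated PLY header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  # element/property layout
  elements <- list()
  cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY without vertex/face elements")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                 ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                 int32 = 4, uint32 = 4, float = 4, float32 = 4, double = 8,
                 float64 = 8)
  read_scalar <- function(type) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", 1, size = sz, endian = "little")
    else
      readBin(con, "integer", 1, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    vprops <- vapply(elements$vertex$props, `[[`, "", "name")
    vdat <- do.call(rbind, lapply(strsplit(trimws(rest[seq_len(nv)]), "\\s+"),
                                  as.numeric))
    xyz <- match(c("x", "y", "z"), vprops)
    v <- vdat[, xyz, drop = FALSE]
    flines <- strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+")
    fidx <- lapply(flines, function(x) as.integer(x[2:(1 + as.integer(x[1]))]) + 1L)
    if (any(lengths(fidx) > 3L))
      warning("non-triangular PLY faces triangulated fan-wise")
    list(vertices = v, faces = fan_triangulate(fidx))
  } else if (fmt == "binary_little_endian") {
    nv <- elements$vertex$count
    vprops <- elements$vertex$props
    v <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      vals <- vapply(vprops, function(p) read_scalar(p$type), 0.0)
      names(vals) <- vapply(vprops, `[[`, "", "name")
      v[i, ] <- vals[c("x", "y", "z")]
    }
    nf <- elements$face$count
    fidx <- vector("list", nf)
    fp <- elements$face$props[[1]]
    for (i in seq_len(nf)) {
      k <- read_scalar(fp$count_type)
      fidx[[i]] <- vapply(seq_len(k), function(j) read_scalar(fp$type), 0) + 1L
    }
    if (any(lengths(fidx) > 3L))
      warning("non-triangular PLY faces triangulated fan-wise")
    list(vertices = v, faces = fan_triangulate(lapply(fidx, as.integer)))
  } else {
    stop("unsupported PLY format: ", fmt)
  }
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("comment %s", mesh$name),
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    for (i in seq_len(nv))
      writeBin(as.double(mesh$vertices[i, ]), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
}

# --- STL -------------------------------------------------------------------

read_stl <- function(path) {
  # binary STL has an 80-byte header then uint32 facet count; sniff it
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  nfac <- tryCatch(readBin(con, "integer", 1, size = 4, endian = "little"),
                   error = function(e) -1L)
  close(con)
  is_binary <- length(nfac) == 1 && !is.na(nfac) && nfac > 0 &&
    (84 + 50 * as.numeric(nfac)) == sz
  tri <- if (is_binary) read_stl_binary(path, nfac) else read_stl_ascii(path)
  nt <- nrow(tri) / 3
  f <- matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE)
  dedup_vertices(tri, f)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: ", path)
  do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                        function(x) as.numeric(x[2:4])))
}

read_stl_binary <- function(path, nfac) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84)
  tri <- matrix(0, 3 * nfac, 3)
  for (i in seq_len(nfac)) {
    rec <- readBin(con, "double", 12, size = 4, endian = "little")
    tri[3 * i - 2, ] <- rec[4:6]
    tri[3 * i - 1, ] <- rec[7:9]
    tri[3 * i, ] <- rec[10:12]
    readBin(con, "raw", 2) # attribute byte count
  }
  tri
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(f)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("romap", mesh$name)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    for (i in seq_len(n)) {
      writeBin(as.double(c(nx[i], ny[i], nz[i]) / len[i]), con, size = 4,
               endian = "little")
      for (k in 1:3)
        writeBin(as.double(v[f[i, k], ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(n)) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", nx[i] / len[i],
                         ny[i] / len[i], nz[i] / len[i]), con)
      writeLines("    outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g", v[f[i, k], 1],
                           v[f[i, k], 2], v[f[i, k], 3]), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
  }
}

# --- vertex masks ----------------------------------------------------------

#' Read a vertex mask (one 0-based index per line)
#' @param path file path.
#' @param mesh_name mesh the mask refers to.
#' @return a [vertex_mask()].
#' @export
load_vertex_mask <- function(path, mesh_name) {
  idx <- scan(path, what = integer(), quiet = TRUE, comment.char = "#")
  vertex_mask(mesh_name, idx + 1L)
}

#' Write a vertex mask (one 0-based index per line)
#' @param mask a [vertex_mask()].
#' @param path output path.
#' @export
save_vertex_mask <- function(mask, path) {
  writeLines(as.character(mask$indices - 1L), path)
  invisible(path)
}
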
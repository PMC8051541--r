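# STL (binary + ASCII) and OBJ readers/writers. STL stores every facet
# independently, so reading welds coincident vertices. Duplicated facet
# corners are written from the same number and so are bit-identical; the
# weld tolerance only needs to catch those while staying below the scale of
# real features, crease-refined solids can carry ~1e-5 mm ones.

#' Read a surface mesh from STL or OBJ
#'
#' Binary and ASCII STL are auto-detected; OBJ parsing accepts `v` and `f`
#' records (the minimal dialect the optimizer stages exchange). Duplicate
#' vertices within the weld tolerance are merged on read.
#'
#' @param path file path.
#' @param format `"stl"`, `"obj"`, or `"auto"` (by extension).
#' @param weld_tol vertex welding tolerance in mm.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "obj"),
                      weld_tol = 1e-5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", obj = "obj",
                     stop("cannot infer mesh format from extension: ", ext))
  }
  raw <- switch(format,
                stl = read_stl(path),
                obj = read_obj(path))
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L)
    stop("empty mesh in ", path)
  welded <- weld_vertices(raw$vertices, raw$faces, weld_tol)
  mesh <- surface_mesh(welded$vertices, welded$faces)
  message(sprintf("read %s: %d vertices, %d faces (welded %d duplicates)",
                  basename(path), nrow(mesh$vertices), nrow(mesh$faces),
                  nrow(raw$vertices) - nrow(mesh$vertices)))
  mesh
}

read_stl <- function(path) {
  size <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  if (size >= 84) {
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.double(ntri)) {
      body <- readBin(con, "raw", n = size - 84L)
      rec <- 50L
      # 12 little-endian float32 per record (normal + 3 vertices), 2 pad bytes
      float_off <- as.vector(outer(1:48, seq(0L, by = rec,
                                             length.out = ntri), "+"))
      floats <- readBin(body[float_off], "numeric", size = 4L,
                        n = 12L * ntri, endian = "little")
      m <- matrix(floats, nrow = 12L)
      verts <- matrix(as.vector(m[4:12, ]), ncol = 3L, byrow = TRUE)
      faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
      return(list(vertices = verts, faces = faces))
    }
  }
  read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("unreadable STL file: ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    x <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(x)) stop("unreadable STL vertex record")
    x
  })
  verts <- do.call(rbind, nums)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L || length(fl) == 0L)
    stop("unreadable OBJ file (no v/f records): ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    x <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(x)) stop("unreadable OBJ vertex record")
    x
  }))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(tok) {
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok[-1])))
    if (anyNA(idx) || length(idx) < 3L) stop("unreadable OBJ face record")
    if (length(idx) > 3L) stop("OBJ face with more than 3 vertices; ",
                               "triangulate before import")
    idx
  }))
  list(vertices = verts, faces = faces)
}

# merge vertices falling in the same tolerance-sized grid cell
weld_vertices <- function(vertices, faces, tol) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- vertices[first, , drop = FALSE]
  new_f <- matrix(map[faces], ncol = 3L)
  keep <- !(new_f[, 1] == new_f[, 2] | new_f[, 2] == new_f[, 3] |
              new_f[, 1] == new_f[, 3])
  list(vertices = new_v, faces = new_f[keep, , drop = FALSE])
}

#' Write a surface mesh to STL or OBJ
#'
#' STL is written binary (little-endian, one facet record per triangle); OBJ
#' writes `v`/`f` records only, with 1-based face indices.
#'
#' @param mesh a [surface_mesh()].
#' @param path destination file path.
#' @param format `"stl"`, `"obj"`, or `"auto"` (by extension).
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", obj = "obj",
                     stop("cannot infer mesh format from extension: ", ext))
  }
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("refusing to write an empty mesh")
  if (format == "stl") {
    et <- mesh_edge_table(mesh$faces, nrow(mesh$vertices))
    if (any(table_counts(et$key)$n == 1L))
      warning("writing an open shell as STL: the file will not be printable")
    write_stl_binary(mesh, path)
  } else {
    write_obj(mesh, path)
  }
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "binary STL written by splintfab"))[1:80]
  writeBin(header, con)
  ntri <- nrow(mesh$faces)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  n <- face_normals(mesh$vertices, mesh$faces)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  block <- t(cbind(n, v1, v2, v3))  # 12 floats per facet, facet-major
  floats <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
  fm <- matrix(floats, nrow = 48L)
  pad <- matrix(as.raw(0L), nrow = 2L, ncol = ntri)
  writeBin(as.vector(rbind(fm, pad)), con)
  invisible(path)
}

write_obj <- function(mesh, path) {
  # %.17g round-trips doubles exactly, so resumed stages reproduce a full
  # run bit for bit
  vlines <- sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                    mesh$vertices[, 2], mesh$vertices[, 3])
  flines <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                    mesh$faces[, 3])
  writeLines(c(vlines, flines), path)
  invisible(path)
}
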
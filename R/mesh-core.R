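# Mesh data model shared by every pipeline stage. A surface mesh is an
# indexed triangle mesh in millimetres; a lattice graph is its wireframe.

#' Construct a triangle surface mesh
#'
#' The basic container used throughout the package: an indexed triangle mesh
#' with coordinates in millimetres. Face winding defines the outward
#' orientation (counter-clockwise seen from outside).
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z
#'   in mm).
#' @param faces integer matrix, one row per triangle, three 1-based vertex
#'   indices per row.
#' @param validate check index ranges and reject degenerate faces.
#' @return an object of class `splint_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have three columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have three columns")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (validate && nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate face: repeated vertex index")
  }
  structure(list(vertices = vertices, faces = faces), class = "splint_mesh")
}

#' @export
print.splint_mesh <- function(x, ...) {
  cat(sprintf("<splint_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# undirected edge table: one row per directed half-edge with a sortable key
mesh_edge_table <- function(faces, n_vertices) {
  he <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  lo <- pmin(he[, 1], he[, 2])
  hi <- pmax(he[, 1], he[, 2])
  key <- (as.double(lo) - 1) * n_vertices + as.double(hi)
  face <- rep.int(seq_len(nrow(faces)), 3L)
  list(from = he[, 1], to = he[, 2], lo = lo, hi = hi, key = key, face = face)
}

# unique undirected edges as a 2-column matrix (lo, hi)
mesh_unique_edges <- function(faces, n_vertices) {
  et <- mesh_edge_table(faces, n_vertices)
  keep <- !duplicated(et$key)
  cbind(et$lo[keep], et$hi[keep])
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume; positive when face winding is outward.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Total surface area of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(triangle_areas(mesh$vertices, mesh$faces))
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr * cr))
}

face_normals <- function(vertices, faces, normalize = TRUE) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n * n))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Boundary loops of an open shell
#'
#' Chains the edges used by exactly one face into closed polylines.
#'
#' @param mesh a [surface_mesh()].
#' @return list of integer vectors, each an ordered cycle of vertex indices;
#'   empty list for a closed mesh.
#' @export
mesh_boundary_loops <- function(mesh) {
  et <- mesh_edge_table(mesh$faces, nrow(mesh$vertices))
  cnt <- table_counts(et$key)
  bnd <- cnt[match(et$key, cnt$key), "n"] == 1L
  if (!any(bnd)) return(list())
  # boundary half-edges keep their face orientation, so loops chain from -> to
  from <- et$from[bnd]
  to <- et$to[bnd]
  nV <- max(c(et$from, et$to))
  nxt <- integer(nV)
  nxt[from] <- to
  used <- logical(nV)
  loops <- list()
  for (s in from) {
    if (used[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      if (cur == 0L || used[cur] || nxt[cur] == 0L) break
      used[cur] <- TRUE
      loop <- c(loop, cur)
      cur <- nxt[cur]
      if (cur == s) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

table_counts <- function(key) {
  ord <- order(key)
  k <- key[ord]
  new <- c(TRUE, k[-1] != k[-length(k)])
  grp <- cumsum(new)
  n <- tabulate(grp)
  data.frame(key = k[new], n = n)
}

#' Validate a mesh for printability
#'
#' Reports watertightness, boundary loops, non-manifold edges, a sampled
#' self-intersection count, and the enclosed volume when closed. Solids
#' emitted by the pipeline must pass with `expect_closed = TRUE`; drafted
#' shells are validated as open shells.
#'
#' @param mesh a [surface_mesh()].
#' @param expect_closed whether the mesh is supposed to be watertight.
#' @param check_intersections run the (bounding-volume-pruned) sampled
#'   triangle-pair intersection test.
#' @param max_pairs budget of candidate triangle pairs for the intersection
#'   sample; set `Inf` for the full pruned check.
#' @return a list of class `mesh_validation`: `watertight`,
#'   `consistent_winding`, `n_boundary_loops`, `n_nonmanifold_edges`,
#'   `n_degenerate_faces`, `self_intersections`, `volume` (mm^3, `NA` when
#'   open), `ok` (matches the expectation).
#' @export
validate_mesh <- function(mesh, expect_closed = TRUE,
                          check_intersections = TRUE, max_pairs = 2e5) {
  f <- mesh$faces
  v <- mesh$vertices
  nV <- nrow(v)
  deg <- sum(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]) +
    sum(triangle_areas(v, f) <= 1e-12)
  et <- mesh_edge_table(f, nV)
  cnt <- table_counts(et$key)
  n_bnd <- sum(cnt$n == 1L)
  n_nm <- sum(cnt$n > 2L)
  watertight <- n_bnd == 0L && n_nm == 0L
  # winding is consistent when every shared undirected edge is traversed once
  # in each direction
  dir_key <- (as.double(et$from) - 1) * nV + as.double(et$to)
  consistent <- !any(duplicated(dir_key))
  loops <- if (n_bnd > 0L) mesh_boundary_loops(mesh) else list()
  vol <- if (watertight) mesh_volume(mesh) else NA_real_
  si <- NA_integer_
  if (check_intersections && nrow(f) > 1L) {
    budget <- if (is.finite(max_pairs)) as.integer(max_pairs) else .Machine$integer.max
    si <- cpp_self_intersections(v, f, budget)
  }
  ok <- if (expect_closed) {
    watertight && consistent && deg == 0L && !is.na(vol) && vol > 0
  } else {
    n_nm == 0L && consistent && deg == 0L
  }
  structure(list(
    watertight = watertight,
    consistent_winding = consistent,
    n_boundary_loops = length(loops),
    boundary_loops = loops,
    n_nonmanifold_edges = n_nm,
    n_degenerate_faces = deg,
    self_intersections = si,
    volume = vol,
    ok = ok
  ), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(paste0(
    "<mesh_validation> watertight: %s | winding consistent: %s\n",
    "  boundary loops: %d | non-manifold edges: %d | degenerate faces: %d\n",
    "  self-intersections (sampled): %s | volume: %s mm^3 | ok: %s\n"),
    x$watertight, x$consistent_winding, x$n_boundary_loops,
    x$n_nonmanifold_edges, x$n_degenerate_faces,
    ifelse(is.na(x$self_intersections), "skipped", x$self_intersections),
    ifelse(is.na(x$volume), "-", format(x$volume, digits = 6)), x$ok))
  invisible(x)
}

#' Extract the wireframe lattice of a mesh
#'
#' Nodes are the mesh vertices and edges the unique undirected mesh edges;
#' these are the centerlines of the printed bars.
#'
#' @param mesh a [surface_mesh()] (open shell allowed).
#' @return an object of class `splint_lattice` with `nodes` (matrix),
#'   `edges` (2-column index matrix, lo < hi) and `faces` (back-reference to
#'   the source triangles).
#' @export
extract_lattice <- function(mesh) {
  edges <- mesh_unique_edges(mesh$faces, nrow(mesh$vertices))
  lat <- structure(list(nodes = mesh$vertices, edges = edges,
                        faces = mesh$faces),
                   class = "splint_lattice")
  lat
}

#' @export
print.splint_lattice <- function(x, ...) {
  cat(sprintf("<splint_lattice> %d nodes, %d edges (connected: %s)\n",
              nrow(x$nodes), nrow(x$edges), lattice_connected(x)))
  invisible(x)
}

#' Is the lattice a single connected piece?
#'
#' @param lattice a [extract_lattice()] result.
#' @return logical.
#' @export
lattice_connected <- function(lattice) {
  n <- nrow(lattice$nodes)
  if (n == 0L) return(TRUE)
  comp <- union_find_components(n, lattice$edges)
  length(unique(comp[unique(as.vector(lattice$edges))])) <= 1L &&
    all(tabulate(as.vector(lattice$edges), n) > 0L)
}

# plain union-find over an edge list
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1])
    b <- find(edges[k, 2])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}

#' Edge lengths of a lattice
#'
#' @param lattice a `splint_lattice`.
#' @return numeric vector of lengths in mm.
#' @export
lattice_edge_lengths <- function(lattice) {
  d <- lattice$nodes[lattice$edges[, 1], , drop = FALSE] -
    lattice$nodes[lattice$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Mean unsigned distance from points to a mesh surface
#'
#' Closest-point distance computed against a spatially indexed copy of the
#' mesh; the workhorse behind the offset-clearance checks.
#'
#' @param mesh a [surface_mesh()].
#' @param points numeric matrix of query points (n x 3, mm).
#' @return numeric vector of distances in mm.
#' @export
surface_distance <- function(mesh, points) {
  points <- matrix(as.double(points), ncol = 3L)
  cpp_closest_point_mesh(mesh$vertices, mesh$faces, points)$dist
}
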
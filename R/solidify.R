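# Wireframe-to-solid conversion: capsule struts along lattice edges and
# spheres at nodes, fastening blocks with through-holes, and the two-piece
# plane split. The union is evaluated on a signed-distance-field voxel grid
# and extracted with marching tetrahedra, which trades a pitch-controlled
# geometric error for robustness against the hundreds of touching
# primitives that defeat exact mesh booleans.

#' Strut solidification parameters
#'
#' @param diameter strut diameter in mm (sphere diameter = cylinder
#'   diameter).
#' @param method union evaluation method. Only `"sdf_voxel"` is
#'   implemented; `"exact_boolean"` is reserved.
#' @param voxel_pitch SDF grid pitch in mm; must be at most `diameter / 4`,
#'   default `diameter / 8`.
#' @return a list of class `strut_params`.
#' @export
strut_params <- function(diameter = 4,
                         method = c("sdf_voxel", "exact_boolean"),
                         voxel_pitch = diameter / 8) {
  method <- match.arg(method)
  if (diameter <= 0) stop("strut diameter must be positive")
  if (method == "exact_boolean")
    stop("exact_boolean union is not implemented; use sdf_voxel")
  if (voxel_pitch > diameter / 4)
    stop("voxel_pitch must be <= diameter / 4 for a resolved strut")
  structure(list(diameter = diameter, method = method,
                 voxel_pitch = voxel_pitch),
            class = "strut_params")
}

#' Specify a fastening block
#'
#' A rectangular block with an optional cylindrical through-hole, given by
#' its center, an orthonormal frame and dimensions along the frame axes.
#'
#' @param center block center (mm).
#' @param frame 3 x 3 matrix whose rows are the block's unit axes
#'   (right-handed).
#' @param dims block dimensions `(l, w, h)` in mm along the frame axes.
#' @param hole_diameter through-hole diameter in mm; 0 for no hole. Must be
#'   smaller than `min(l, w)`.
#' @param hole_axis which frame axis the hole runs along (1, 2 or 3).
#' @return a list of class `block_spec`.
#' @export
block_spec <- function(center, frame, dims = c(20, 12, 8),
                       hole_diameter = 4, hole_axis = 3L) {
  center <- as.numeric(center)
  frame <- as.matrix(frame)
  dims <- as.numeric(dims)
  if (length(center) != 3L || !all(dim(frame) == c(3L, 3L)) ||
      length(dims) != 3L)
    stop("block_spec: center (3), frame (3x3), dims (3) required")
  if (any(dims <= 0)) stop("block_spec: dimensions must be positive")
  gram <- frame %*% t(frame)
  if (max(abs(gram - diag(3))) > 1e-6)
    stop("block_spec: frame must be orthonormal")
  if (hole_diameter < 0) stop("block_spec: hole_diameter must be >= 0")
  if (hole_diameter >= min(dims[1], dims[2]))
    stop("block_spec: hole diameter must be < min(l, w)")
  hole_axis <- as.integer(hole_axis)
  if (!hole_axis %in% 1:3) stop("block_spec: hole_axis must be 1, 2 or 3")
  structure(list(center = center, frame = frame, dims = dims,
                 hole_diameter = hole_diameter, hole_axis = hole_axis),
            class = "block_spec")
}

#' Build a block pose from a surface anchor point
#'
#' Users specify where a block sits (a point on the strut-centerline shell
#' and its outward normal) plus the intended bolt direction; this computes
#' the orthonormal pose: axis 2 (width `w`) points outward along the
#' normal, axis 3 (height `h`) carries the hole along the bolt direction,
#' and axis 1 completes the frame. The block is sunk `embed` mm below the
#' anchor so it fuses with the struts.
#'
#' @param anchor point on the shell (mm).
#' @param normal outward surface normal at the anchor.
#' @param hole_dir bolt direction (typically the split-plane normal).
#' @param dims,hole_diameter passed to [block_spec()].
#' @param embed depth of the block's inner face below the anchor (mm).
#' @return a [block_spec()].
#' @export
block_from_anchor <- function(anchor, normal, hole_dir,
                              dims = c(20, 12, 8), hole_diameter = 4,
                              embed = 1) {
  normal <- normal / sqrt(sum(normal^2))
  a3 <- hole_dir / sqrt(sum(hole_dir^2))
  a2 <- normal - sum(normal * a3) * a3
  if (sqrt(sum(a2^2)) < 1e-9)
    stop("block_from_anchor: normal parallel to hole direction")
  a2 <- a2 / sqrt(sum(a2^2))
  a1 <- c(a2[2] * a3[3] - a2[3] * a3[2],
          a2[3] * a3[1] - a2[1] * a3[3],
          a2[1] * a3[2] - a2[2] * a3[1])
  center <- anchor + (dims[2] / 2 - embed) * a2
  block_spec(center, rbind(a1, a2, a3), dims = dims,
             hole_diameter = hole_diameter, hole_axis = 3L)
}

# Degenerate (zero-area) triangles and micro-edges can appear when
# extracted vertices are projected exactly onto the limit surface: three
# vertices land colinear, or two land almost on top of each other. Both are
# removed by collapsing the offending shortest edge — a closure-preserving
# operation — iterated in case a collapse creates a new sliver. Micro-edges
# must go because any feature below the file-format weld tolerance would be
# merged unpredictably on re-read.
clean_degenerate_faces <- function(mesh, area_tol = 1e-10, min_edge = 1e-3,
                                   max_rounds = 30L) {
  for (round in seq_len(max_rounds)) {
    nv <- nrow(mesh$vertices)
    f <- mesh$faces

    # candidate collapses: micro-edges, plus the shortest edge of every
    # (near-)zero-area face
    et <- mesh_edge_table(f, nv)
    keep_e <- !duplicated(et$key)
    elo <- et$lo[keep_e]
    ehi <- et$hi[keep_e]
    elen2 <- rowSums((mesh$vertices[elo, , drop = FALSE] -
                        mesh$vertices[ehi, , drop = FALSE])^2)
    short <- which(elen2 < min_edge^2)
    cand_a <- elo[short]
    cand_b <- ehi[short]
    ar <- triangle_areas(mesh$vertices, f)
    for (fc in which(ar <= area_tol)) {
      tri <- f[fc, ]
      p <- mesh$vertices[tri, , drop = FALSE]
      el <- c(sum((p[1, ] - p[2, ])^2), sum((p[2, ] - p[3, ])^2),
              sum((p[3, ] - p[1, ])^2))
      # offer all three edges, shortest first: the shortest can fail the
      # link condition while another succeeds
      for (pair in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))[order(el)]) {
        cand_a <- c(cand_a, tri[pair[1]])
        cand_b <- c(cand_b, tri[pair[2]])
      }
    }
    if (length(cand_a) == 0L) break

    # incidence for candidate vertices only
    cand_v <- unique(c(cand_a, cand_b))
    hit <- matrix(f %in% cand_v, ncol = 3L)
    rows <- which(hit, arr.ind = TRUE)[, 1]
    verts <- f[hit]
    vf <- split(rows, verts)

    map <- seq_len(nv)
    touched <- logical(nv)
    n_ops <- 0L
    for (k in seq_along(cand_a)) {
      a <- cand_a[k]
      b <- cand_b[k]
      if (a == b || touched[a] || touched[b]) next
      fa <- vf[[as.character(a)]]
      fb <- vf[[as.character(b)]]
      shared <- intersect(fa, fb)
      if (length(shared) != 2L) next
      ring_a <- setdiff(unique(as.vector(f[fa, , drop = FALSE])), a)
      ring_b <- setdiff(unique(as.vector(f[fb, , drop = FALSE])), b)
      opp <- setdiff(unique(as.vector(f[shared, , drop = FALSE])), c(a, b))
      # link condition keeps the collapse manifold-preserving
      if (!setequal(intersect(ring_a, ring_b), opp)) next
      if (any(touched[opp])) next
      map[b] <- a
      touched[c(a, b, opp)] <- TRUE
      n_ops <- n_ops + 1L
    }
    if (n_ops == 0L) break
    for (k in 1:3) map <- map[map]
    fnew <- matrix(map[f], ncol = 3L)
    ok <- fnew[, 1] != fnew[, 2] & fnew[, 2] != fnew[, 3] &
      fnew[, 1] != fnew[, 3]
    mesh <- drop_unreferenced(surface_mesh(mesh$vertices,
                                           fnew[ok, , drop = FALSE],
                                           validate = FALSE))
  }
  mesh
}

# --- internal: primitive bookkeeping ---------------------------------------

empty_prims <- function() {
  list(spheres = matrix(0, 0, 4),
       capsules = matrix(0, 0, 7),
       boxes = matrix(0, 0, 15),
       holes = matrix(0, 0, 7))
}

block_primitives <- function(blocks) {
  prims <- empty_prims()
  for (b in blocks) {
    prims$boxes <- rbind(prims$boxes,
                         c(b$center, t(b$frame)[, 1], t(b$frame)[, 2],
                           t(b$frame)[, 3], b$dims / 2))
    if (b$hole_diameter > 0) {
      ax <- b$frame[b$hole_axis, ]
      half <- b$dims[b$hole_axis] / 2 + 2  # overshoot so the cut is through
      prims$holes <- rbind(prims$holes,
                           c(b$center - half * ax, b$center + half * ax,
                             b$hole_diameter / 2))
    }
  }
  prims
}

prim_bbox <- function(prims) {
  lo <- rep(Inf, 3)
  hi <- rep(-Inf, 3)
  if (nrow(prims$spheres) > 0) {
    lo <- pmin(lo, apply(prims$spheres[, 1:3, drop = FALSE] -
                           prims$spheres[, 4], 2, min))
    hi <- pmax(hi, apply(prims$spheres[, 1:3, drop = FALSE] +
                           prims$spheres[, 4], 2, max))
  }
  if (nrow(prims$capsules) > 0) {
    r <- prims$capsules[, 7]
    lo <- pmin(lo, apply(pmin(prims$capsules[, 1:3, drop = FALSE],
                              prims$capsules[, 4:6, drop = FALSE]) - r, 2, min))
    hi <- pmax(hi, apply(pmax(prims$capsules[, 1:3, drop = FALSE],
                              prims$capsules[, 4:6, drop = FALSE]) + r, 2, max))
  }
  if (nrow(prims$boxes) > 0) {
    diag_ <- sqrt(rowSums(prims$boxes[, 13:15, drop = FALSE]^2))
    lo <- pmin(lo, apply(prims$boxes[, 1:3, drop = FALSE] - diag_, 2, min))
    hi <- pmax(hi, apply(prims$boxes[, 1:3, drop = FALSE] + diag_, 2, max))
  }
  list(lo = lo, hi = hi)
}

make_grid <- function(lo, hi, pitch) {
  pad <- 3 * pitch
  origin <- lo - pad
  dims <- as.integer(ceiling((hi + pad - origin) / pitch)) + 1L
  list(origin = origin, dims = dims, pitch = pitch)
}

extract_primitive_solid <- function(prims, grid, plane_vec = numeric(0)) {
  f <- cpp_sdf_primitives(grid$origin, grid$dims, grid$pitch,
                          prims$spheres, prims$capsules, prims$boxes,
                          prims$holes, plane_vec)
  mt <- cpp_marching_tetrahedra(f, grid$dims, grid$origin, grid$pitch)
  if (nrow(mt$vertices) == 0L)
    stop("SDF extraction produced an empty surface")
  # Newton-project the extracted vertices onto the exact zero-set: removes
  # the inscription bias of linear interpolation at curved surfaces
  refined <- cpp_refine_to_sdf(mt$vertices, prims$spheres, prims$capsules,
                               prims$boxes, prims$holes, plane_vec, 3L)
  mesh <- surface_mesh(refined, mt$faces, validate = FALSE)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  clean_degenerate_faces(mesh)
}

new_solid <- function(mesh, prims, grid, stage) {
  mesh$provenance <- list(primitives = prims, grid = grid, stage = stage)
  class(mesh) <- c("solid_model", "splint_mesh")
  mesh
}

#' @export
print.solid_model <- function(x, ...) {
  cat(sprintf("<solid_model> stage '%s': %d vertices, %d faces, %.1f mm^3\n",
              x$provenance$stage, nrow(x$vertices), nrow(x$faces),
              mesh_volume(x)))
  invisible(x)
}

#' Solidify a lattice into strut geometry
#'
#' The printable solid is the union of a sphere at every node and a capsule
#' (cylinder with hemispherical ends, same diameter) along every edge.
#'
#' @param lattice a `splint_lattice`.
#' @param params a [strut_params()].
#' @return a watertight `solid_model`.
#' @export
strut_solid <- function(lattice, params = strut_params()) {
  if (nrow(lattice$nodes) == 0L) stop("empty lattice")
  r <- params$diameter / 2
  prims <- empty_prims()
  if (nrow(lattice$edges) > 0L) {
    len <- lattice_edge_lengths(lattice)
    if (any(len < params$diameter))
      warning(sprintf("%d edges shorter than the strut diameter: %s",
                      sum(len < params$diameter),
                      "expect merged-blob regions"))
    prims$capsules <- cbind(lattice$nodes[lattice$edges[, 1], , drop = FALSE],
                            lattice$nodes[lattice$edges[, 2], , drop = FALSE],
                            r)
    used <- unique(as.vector(lattice$edges))
    lonely <- setdiff(seq_len(nrow(lattice$nodes)), used)
  } else {
    lonely <- seq_len(nrow(lattice$nodes))
  }
  if (length(lonely) > 0L)
    prims$spheres <- cbind(lattice$nodes[lonely, , drop = FALSE], r)
  bb <- prim_bbox(prims)
  grid <- make_grid(bb$lo, bb$hi, params$voxel_pitch)
  mesh <- extract_primitive_solid(prims, grid)
  new_solid(mesh, prims, grid, "struts")
}

#' Attach fastening blocks and drill their holes
#'
#' Unions the blocks with the solid, then subtracts each block's through-
#' hole cylinder, in one signed-distance evaluation so the result stays
#' watertight.
#'
#' @param solid a `solid_model` (one carrying primitive provenance is
#'   re-evaluated exactly; an arbitrary closed mesh is voxelized first).
#' @param blocks list of [block_spec()] objects.
#' @return a watertight `solid_model`.
#' @export
attach_blocks <- function(solid, blocks) {
  if (length(blocks) == 0L) return(solid)
  centers <- do.call(rbind, lapply(blocks, function(b) b$center))
  d <- surface_distance(solid, centers)
  too_far <- d > 2 * vapply(blocks, function(b) b$dims[3], numeric(1))
  if (any(too_far))
    stop("block(s) ", paste(which(too_far), collapse = ", "),
         " do not touch the solid")
  bp <- block_primitives(blocks)
  if (!is.null(solid$provenance)) {
    prims <- solid$provenance$primitives
    prims$boxes <- rbind(prims$boxes, bp$boxes)
    prims$holes <- rbind(prims$holes, bp$holes)
    bb <- prim_bbox(prims)
    grid <- make_grid(bb$lo, bb$hi,
                      solid$provenance$grid$pitch)
    mesh <- extract_primitive_solid(prims, grid)
    return(new_solid(mesh, prims, grid, "blocks"))
  }
  # mesh path: voxelize the solid, then combine fields in R
  pitch <- min(apply(solid$vertices, 2, function(x) diff(range(x)))) / 40
  bbm <- prim_bbox(bp)
  lo <- pmin(apply(solid$vertices, 2, min), bbm$lo)
  hi <- pmax(apply(solid$vertices, 2, max), bbm$hi)
  grid <- make_grid(lo, hi, pitch)
  grid$origin <- grid$origin + pitch * c(0.0137, 0.0071, 0.0029)
  fs <- cpp_mesh_sdf_grid(solid$vertices, solid$faces, grid$origin,
                          grid$dims, pitch)
  fb <- cpp_sdf_primitives(grid$origin, grid$dims, pitch,
                           empty_prims()$spheres, empty_prims()$capsules,
                           bp$boxes, matrix(0, 0, 7), numeric(0))
  f <- pmin(fs, fb)
  if (nrow(bp$holes) > 0) {
    fh <- hole_field(bp$holes, grid)
    f <- pmax(f, -fh)
  }
  mt <- cpp_marching_tetrahedra(f, grid$dims, grid$origin, pitch)
  mesh <- surface_mesh(mt$vertices, mt$faces, validate = FALSE)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  new_solid(clean_degenerate_faces(mesh), NULL, grid, "blocks")
}

# cylinder SDF field over the whole grid, vectorized (small grids only)
hole_field <- function(holes, grid) {
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 1L) * grid$pitch
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 1L) * grid$pitch
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 1L) * grid$pitch
  px <- rep(cx, times = grid$dims[2] * grid$dims[3])
  py <- rep(rep(cy, each = grid$dims[1]), times = grid$dims[3])
  pz <- rep(cz, each = grid$dims[1] * grid$dims[2])
  f <- rep(Inf, length(px))
  for (k in seq_len(nrow(holes))) {
    a <- holes[k, 1:3]
    b <- holes[k, 4:6]
    r <- holes[k, 7]
    ab <- b - a
    h <- sqrt(sum(ab^2))
    u <- ab / h
    dx <- px - a[1]; dy <- py - a[2]; dz <- pz - a[3]
    y <- dx * u[1] + dy * u[2] + dz * u[3]
    rad <- sqrt(pmax(dx^2 + dy^2 + dz^2 - y^2, 0)) - r
    zc <- pmax(-y, y - h)
    d <- pmin(pmax(rad, zc), 0) +
      sqrt(pmax(rad, 0)^2 + pmax(zc, 0)^2)
    f <- pmin(f, d)
  }
  f
}

#' Split a solid into two capped pieces with a plane
#'
#' Each piece is the intersection of the solid with one half-space,
#' evaluated on the same voxel grid so the two volumes sum to the whole.
#'
#' @param solid a `solid_model` or closed [surface_mesh()].
#' @param plane a [cut_plane()]; the first piece keeps the side the plane's
#'   `keep` points to, the second the other side.
#' @param pitch grid pitch override for solids without primitive
#'   provenance.
#' @return list of two watertight `solid_model`s, `$first` and `$second`.
#' @export
split_solid <- function(solid, plane, pitch = NULL) {
  stopifnot(inherits(plane, "cut_plane"))
  s <- plane_signed_distance(solid$vertices, plane)
  if (all(s >= 0) || all(s <= 0))
    stop("split plane misses the solid")
  n <- plane$normal * (if (plane$keep == "negative") -1 else 1)
  off <- -sum(n * plane$point)
  # half-space SDF c(n, off): inside (kept) where n.x + off <= 0 -> keep the
  # *positive* side means cutting with -(n.x + off)
  plane_first <- c(-n, sum(n * plane$point))
  plane_second <- c(n, off)
  if (!is.null(solid$provenance) &&
      !is.null(solid$provenance$primitives)) {
    prims <- solid$provenance$primitives
    grid <- solid$provenance$grid
    m1 <- extract_primitive_solid(prims, grid, plane_first)
    m2 <- extract_primitive_solid(prims, grid, plane_second)
    return(list(first = new_solid(m1, prims, grid, "split"),
                second = new_solid(m2, prims, grid, "split")))
  }
  if (is.null(pitch))
    pitch <- min(apply(solid$vertices, 2, function(x) diff(range(x)))) / 60
  lo <- apply(solid$vertices, 2, min)
  hi <- apply(solid$vertices, 2, max)
  grid <- make_grid(lo, hi, pitch)
  grid$origin <- grid$origin + pitch * c(0.0137, 0.0071, 0.0029)
  fs <- cpp_mesh_sdf_grid(solid$vertices, solid$faces, grid$origin,
                          grid$dims, pitch)
  pieces <- lapply(list(plane_first, plane_second), function(pl) {
    cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 1L) * grid$pitch
    cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 1L) * grid$pitch
    cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 1L) * grid$pitch
    px <- rep(cx, times = grid$dims[2] * grid$dims[3])
    py <- rep(rep(cy, each = grid$dims[1]), times = grid$dims[3])
    pz <- rep(cz, each = grid$dims[1] * grid$dims[2])
    f <- pmax(fs, pl[1] * px + pl[2] * py + pl[3] * pz + pl[4])
    mt <- cpp_marching_tetrahedra(f, grid$dims, grid$origin, grid$pitch)
    # snap vertices back to whichever surface generated them: the input
    # mesh for the side walls, the plane for the cap
    q <- cpp_closest_point_mesh(solid$vertices, solid$faces, mt$vertices)
    spl <- mt$vertices %*% pl[1:3] + pl[4]
    on_mesh <- q$dist <= abs(spl)
    refined <- mt$vertices
    refined[on_mesh, ] <- q$point[on_mesh, , drop = FALSE]
    refined[!on_mesh, ] <- mt$vertices[!on_mesh, , drop = FALSE] -
      as.vector(spl)[!on_mesh] %o% pl[1:3]
    mesh <- surface_mesh(refined, mt$faces, validate = FALSE)
    if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
    new_solid(clean_degenerate_faces(mesh), NULL, grid, "split")
  })
  list(first = pieces[[1]], second = pieces[[2]])
}

#' Probe the through-hole channels of a solid
#'
#' For each block, casts a probe segment along the hole axis through the
#' hole center, extended well beyond the solid on both sides, and counts
#' surface crossings. An open through-channel lets the probe pass entirely
#' through the void: zero crossings. A blocked hole is crossed by material
#' walls an even number of times.
#'
#' @param solid a closed `solid_model`.
#' @param blocks the list of [block_spec()]s whose holes to probe.
#' @return logical vector: is each block's channel open?
#' @export
through_channels <- function(solid, blocks) {
  bb <- apply(solid$vertices, 2, range)
  reach <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  vapply(blocks, function(b) {
    if (b$hole_diameter <= 0) return(NA)
    ax <- b$frame[b$hole_axis, ]
    a <- b$center - reach * ax
    bpt <- b$center + reach * ax
    cpp_segment_crossings(solid$vertices, solid$faces, a, bpt) == 0L
  }, logical(1))
}

#' Measure a strut's cross-section diameter
#'
#' Slices the solid with a plane perpendicular to `axis` at `point`, chains
#' the intersection into closed polyline loops, takes the loop passing
#' closest to `point` (the sliced strut itself; neighbouring struts form
#' separate loops), and returns its maximal pairwise point distance — the
#' printed bar's diameter at that station.
#'
#' @param solid a `solid_model`.
#' @param point slice location (typically a strut midpoint).
#' @param axis strut direction at that point.
#' @return diameter in mm.
#' @export
slice_diameter <- function(solid, point, axis) {
  axis <- axis / sqrt(sum(axis^2))
  pl <- cut_plane(point, axis, "positive")
  s <- plane_signed_distance(solid$vertices, pl)
  f <- solid$faces
  si <- matrix(s[f] > 0, ncol = 3L)
  crossing <- which(rowSums(si) %in% c(1L, 2L))
  if (length(crossing) == 0L) stop("slice found no cross-section")
  nv <- nrow(solid$vertices)
  pt_key <- character(0)
  pt_xyz <- list()
  seg_a <- integer(0)
  seg_b <- integer(0)
  key_id <- new.env(parent = emptyenv())
  get_pt <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- key_id[[key]]
    if (!is.null(hit)) return(hit)
    t <- s[i] / (s[i] - s[j])
    p <- solid$vertices[i, ] + t * (solid$vertices[j, ] - solid$vertices[i, ])
    id <- length(pt_xyz) + 1L
    pt_xyz[[id]] <<- p
    key_id[[key]] <- id
    id
  }
  for (fc in crossing) {
    tri <- f[fc, ]
    sv <- s[tri]
    ids <- integer(0)
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      if ((sv[pair[1]] > 0) != (sv[pair[2]] > 0))
        ids <- c(ids, get_pt(tri[pair[1]], tri[pair[2]]))
    }
    if (length(ids) == 2L) {
      seg_a <- c(seg_a, ids[1])
      seg_b <- c(seg_b, ids[2])
    }
  }
  n <- length(pt_xyz)
  if (n < 3L) stop("slice found no cross-section at this point")
  comp <- union_find_components(n, cbind(seg_a, seg_b))
  m <- do.call(rbind, pt_xyz)
  d <- sqrt(rowSums((m - matrix(point, n, 3L, byrow = TRUE))^2))
  target <- comp[which.min(d)]
  loop <- m[comp == target, , drop = FALSE]
  max(stats::dist(loop))
}
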
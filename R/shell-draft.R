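# Drafting stage: offset the limb surface by the bar radius, crop it with
# configured cut planes, and (in remesh.R) rebuild it quasi-uniformly. The
# offset shell carries the strut centerlines a constant clearance above the
# skin.

#' Define a cutting plane
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @param keep which half-space to keep: `"positive"` keeps points with
#'   `dot(x - point, normal) >= 0`.
#' @return a list of class `cut_plane`.
#' @export
cut_plane <- function(point, normal, keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("cut_plane: point and normal must be length-3")
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("cut_plane: zero normal")
  structure(list(point = point, normal = normal / len, keep = keep),
            class = "cut_plane")
}

#' Angle-weighted vertex normals
#'
#' Each face contributes its normal to its three corners weighted by the
#' corner angle; the result is robust to tessellation density.
#'
#' @param mesh a [surface_mesh()].
#' @return an n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(v, f)
  n <- matrix(0, nrow(v), 3L)
  for (c_ in 1:3) {
    i <- f[, c_]
    j <- f[, (c_ %% 3L) + 1L]
    k <- f[, ((c_ + 1L) %% 3L) + 1L]
    e1 <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    e2 <- v[k, , drop = FALSE] - v[i, , drop = FALSE]
    l1 <- sqrt(rowSums(e1 * e1))
    l2 <- sqrt(rowSums(e2 * e2))
    cosang <- rowSums(e1 * e2) / pmax(l1 * l2, 1e-300)
    ang <- acos(pmin(pmax(cosang, -1), 1))
    w <- fn * ang
    for (d in 1:3) {
      acc <- rowsum(w[, d], i, reorder = FALSE)
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n / len
}

#' Offset a closed surface along its vertex normals
#'
#' Every vertex moves by `distance` along its angle-weighted unit normal;
#' connectivity is untouched. For small offsets relative to the surface
#' curvature this matches a true offset surface. A warning is emitted if any
#' offset vertex ends up closer than `0.95 * distance` to the input surface
#' (a local self-intersection indicator); the offset is not repaired.
#'
#' @param mesh a closed, manifold [surface_mesh()].
#' @param distance offset distance in mm (> 0), the bar radius.
#' @return a [surface_mesh()] with the same connectivity.
#' @export
offset_surface <- function(mesh, distance) {
  if (!is.numeric(distance) || length(distance) != 1L || distance <= 0)
    stop("offset distance must be a single positive number (mm)")
  et <- mesh_edge_table(mesh$faces, nrow(mesh$vertices))
  cnt <- table_counts(et$key)
  if (any(cnt$n != 2L))
    stop("offset_surface requires a closed manifold mesh")
  n <- vertex_normals(mesh)
  out <- surface_mesh(mesh$vertices + distance * n, mesh$faces)
  d_back <- surface_distance(mesh, out$vertices)
  n_close <- sum(d_back < 0.95 * distance)
  if (n_close > 0)
    warning(sprintf(paste0("offset surface: %d vertices closer than 0.95*d ",
                           "to the input (local self-intersection likely)"),
                    n_close))
  out
}

plane_signed_distance <- function(points, plane) {
  s <- (points[, 1] - plane$point[1]) * plane$normal[1] +
    (points[, 2] - plane$point[2]) * plane$normal[2] +
    (points[, 3] - plane$point[3]) * plane$normal[3]
  if (plane$keep == "negative") -s else s
}

#' Cut a mesh with a plane, keeping one side
#'
#' Faces wholly on the kept side are retained; faces crossing the plane are
#' clipped exactly at the plane, with the new vertices shared between
#' neighbouring faces so the cut boundary is a clean polyline lying on the
#' plane. No cap is added: cutting a closed mesh yields an open shell.
#'
#' @param mesh a [surface_mesh()] (open or closed).
#' @param plane a [cut_plane()].
#' @return a [surface_mesh()]; identical to the input (with a warning) if
#'   the plane misses the mesh.
#' @export
plane_cut <- function(mesh, plane) {
  stopifnot(inherits(plane, "cut_plane"))
  v <- mesh$vertices
  f <- mesh$faces
  s <- plane_signed_distance(v, plane)
  s[abs(s) < 1e-9] <- 0
  if (all(s >= 0) || all(s <= 0)) {
    # the plane does not cross the mesh: no-op contract
    if (all(s > 0) || all(s < 0))
      warning("plane_cut: plane misses the mesh; returning input")
    return(mesh)
  }
  inside <- s >= 0
  fi <- matrix(inside[f], ncol = 3L)
  n_in <- rowSums(fi)
  keep_whole <- which(n_in == 3L)
  crossing <- which(n_in == 1L | n_in == 2L)
  # drop faces whose inside vertices all sit exactly on the plane
  new_v <- list()
  new_f <- list()
  # shared intersection vertices cached per undirected edge
  cache <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  ctr <- nv0
  edge_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- s[i] / (s[i] - s[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    ctr <<- ctr + 1L
    new_v[[length(new_v) + 1L]] <<- p
    cache[[key]] <- ctr
    ctr
  }
  rotate_tri <- function(tri, shift) {
    if (shift == 0L) tri else tri[c((shift %% 3L) + 1L:3L - 1L) %% 3L + 1L]
  }
  for (fc in crossing) {
    tri <- f[fc, ]
    ins <- inside[tri]
    if (sum(ins) == 1L) {
      # cyclic-rotate so the kept vertex comes first (winding preserved)
      tri <- rotate_tri(tri, which(ins) - 1L)
      a <- tri[1]; b <- tri[2]; c_ <- tri[3]
      new_f[[length(new_f) + 1L]] <- c(a, edge_point(a, b), edge_point(c_, a))
    } else {
      # rotate so the dropped vertex comes third
      tri <- rotate_tri(tri, which(!ins) %% 3L)
      a <- tri[1]; b <- tri[2]; c_ <- tri[3]
      pbc <- edge_point(b, c_)
      pca <- edge_point(c_, a)
      new_f[[length(new_f) + 1L]] <- c(a, b, pbc)
      new_f[[length(new_f) + 1L]] <- c(a, pbc, pca)
    }
  }
  verts <- rbind(v, do.call(rbind, new_v))
  faces <- rbind(f[keep_whole, , drop = FALSE],
                 do.call(rbind, lapply(new_f, rbind)))
  drop_unreferenced(surface_mesh(verts, faces, validate = FALSE))
}

# remove vertices not used by any face and reindex
drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(map[mesh$faces], ncol = 3L), validate = FALSE)
}

#' Apply an ordered list of cut planes
#'
#' @param mesh a [surface_mesh()].
#' @param planes list of [cut_plane()] objects.
#' @return the cropped [surface_mesh()].
#' @export
apply_cut_planes <- function(mesh, planes) {
  for (pl in planes) mesh <- plane_cut(mesh, pl)
  mesh
}
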
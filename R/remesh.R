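# Incremental isotropic remeshing (split long edges, collapse short ones,
# flip toward regular valence, tangential smoothing, projection back to the
# source surface). Boundary polylines are preserved as curves: boundary
# vertices only ever slide along the original boundary.

#' Remeshing parameters
#'
#' @param target_edge_length desired edge length `h` in mm.
#' @param iterations number of split/collapse/flip/smooth/project sweeps.
#' @param smoothing_weight tangential smoothing step in (0, 1].
#' @return a list of class `remesh_params`.
#' @export
remesh_params <- function(target_edge_length, iterations = 10L,
                          smoothing_weight = 0.5) {
  if (!is.numeric(target_edge_length) || target_edge_length <= 0)
    stop("target_edge_length must be positive (mm)")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (smoothing_weight <= 0 || smoothing_weight > 1)
    stop("smoothing_weight must be in (0, 1]")
  structure(list(target_edge_length = target_edge_length,
                 iterations = iterations,
                 smoothing_weight = smoothing_weight),
            class = "remesh_params")
}

#' Isotropic remeshing of a surface or open shell
#'
#' Repeats: split edges longer than `4/3 h`, collapse edges shorter than
#' `4/5 h`, flip edges toward valence 6 (4 on the boundary), tangentially
#' smooth, and project vertices back onto the input surface. Boundary
#' vertices are constrained to the input's boundary polylines throughout, so
#' the cropped profile survives remeshing.
#'
#' @param mesh a [surface_mesh()] (open shell or closed).
#' @param params a [remesh_params()].
#' @return a [surface_mesh()] approximating the same surface with
#'   quasi-uniform edge length.
#' @export
remesh_isotropic <- function(mesh, params) {
  stopifnot(inherits(params, "remesh_params"))
  h <- params$target_edge_length
  ext <- apply(mesh$vertices, 2, function(x) diff(range(x)))
  if (h >= min(ext[ext > 1e-9]) / 2)
    stop("target edge length too large for this mesh")

  st <- rm_init(mesh)
  lo <- 4 / 5 * h
  hi <- 4 / 3 * h
  for (it in seq_len(params$iterations)) {
    rm_split_pass(st, hi)
    rm_collapse_pass(st, lo, hi)
    rm_flip_pass(st)
    rm_smooth_pass(st, params$smoothing_weight)
    rm_project_pass(st)
  }
  rm_compact(st)
}

# mutable remeshing state
rm_init <- function(mesh) {
  st <- new.env(parent = emptyenv())
  st$V <- mesh$vertices
  st$F <- mesh$faces
  st$falive <- rep(TRUE, nrow(st$F))
  st$valive <- rep(TRUE, nrow(st$V))
  st$vface <- vector("list", nrow(st$V))
  for (k in seq_len(nrow(st$F)))
    for (c_ in 1:3) {
      v <- st$F[k, c_]
      st$vface[[v]] <- c(st$vface[[v]], k)
    }
  loops <- mesh_boundary_loops(mesh)
  st$vb <- rep(FALSE, nrow(st$V))
  st$vcorner <- rep(FALSE, nrow(st$V))
  segA <- NULL
  segB <- NULL
  for (lp in loops) {
    st$vb[lp] <- TRUE
    nxt <- c(lp[-1], lp[1])
    prv <- c(lp[length(lp)], lp[-length(lp)])
    # pin feature corners: boundary vertices where the rim polyline turns
    # by more than 30 degrees must not slide during smoothing
    e1 <- mesh$vertices[lp, , drop = FALSE] - mesh$vertices[prv, , drop = FALSE]
    e2 <- mesh$vertices[nxt, , drop = FALSE] - mesh$vertices[lp, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)), 1e-300)
    st$vcorner[lp[cosang < cos(30 * pi / 180)]] <- TRUE
    segA <- rbind(segA, mesh$vertices[lp, , drop = FALSE])
    segB <- rbind(segB, mesh$vertices[nxt, , drop = FALSE])
  }
  st$segA <- segA
  st$segB <- segB
  st$surf_index <- cpp_mesh_index(mesh$vertices, mesh$faces)
  st
}

rm_alive_faces <- function(st) {
  which(st$falive)
}

# undirected edges of the live mesh with adjacent face counts
rm_edges <- function(st) {
  fid <- rm_alive_faces(st)
  f <- st$F[fid, , drop = FALSE]
  he_lo <- pmin(cbind(f[, 1], f[, 2], f[, 3]), cbind(f[, 2], f[, 3], f[, 1]))
  he_hi <- pmax(cbind(f[, 1], f[, 2], f[, 3]), cbind(f[, 2], f[, 3], f[, 1]))
  lo <- as.vector(he_lo)
  hi <- as.vector(he_hi)
  key <- (as.double(lo) - 1) * nrow(st$V) + as.double(hi)
  first <- !duplicated(key)
  nadj <- tabulate(match(key, key[first]))
  list(lo = lo[first], hi = hi[first], nadj = nadj)
}

rm_faces_with_edge <- function(st, i, j) {
  fi <- st$vface[[i]]
  fi <- fi[st$falive[fi]]
  fj <- st$vface[[j]]
  fj <- fj[st$falive[fj]]
  intersect(fi, fj)
}

rm_ring <- function(st, i) {
  fi <- st$vface[[i]]
  fi <- fi[st$falive[fi]]
  setdiff(unique(as.vector(st$F[fi, , drop = FALSE])), i)
}

rm_add_vertex <- function(st, p, boundary) {
  n <- nrow(st$V)
  st$V <- rbind(st$V, p)
  st$valive <- c(st$valive, TRUE)
  st$vb <- c(st$vb, boundary)
  st$vcorner <- c(st$vcorner, FALSE)
  st$vface[[n + 1L]] <- integer(0)
  n + 1L
}

rm_add_face <- function(st, tri) {
  st$F <- rbind(st$F, tri)
  st$falive <- c(st$falive, TRUE)
  k <- nrow(st$F)
  for (v in tri) st$vface[[v]] <- c(st$vface[[v]], k)
  k
}

rm_kill_face <- function(st, k) {
  st$falive[k] <- FALSE
}

rm_split_pass <- function(st, hi) {
  e <- rm_edges(st)
  d <- st$V[e$lo, , drop = FALSE] - st$V[e$hi, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  longest_first <- order(len, decreasing = TRUE)
  for (k in longest_first) {
    if (len[k] <= hi) break
    i <- e$lo[k]
    j <- e$hi[k]
    faces <- rm_faces_with_edge(st, i, j)
    if (length(faces) == 0L) next
    cur_len <- sqrt(sum((st$V[i, ] - st$V[j, ])^2))
    if (cur_len <= hi) next
    is_boundary_edge <- length(faces) == 1L
    m <- rm_add_vertex(st, (st$V[i, ] + st$V[j, ]) / 2, is_boundary_edge)
    for (fc in faces) {
      tri <- st$F[fc, ]
      # rotate so the directed split edge occupies positions 1-2
      pos_i <- which(tri == i)
      nxt <- tri[(pos_i %% 3L) + 1L]
      if (nxt == j) {
        a <- i; b <- j
      } else {
        a <- j; b <- i
      }
      pos_a <- which(tri == a)
      tri <- tri[((pos_a - 1L + 0:2) %% 3L) + 1L]
      opp <- tri[3]
      rm_kill_face(st, fc)
      rm_add_face(st, c(a, m, opp))
      rm_add_face(st, c(m, b, opp))
    }
  }
  invisible(NULL)
}

rm_collapse_pass <- function(st, lo, hi) {
  e <- rm_edges(st)
  d <- st$V[e$lo, , drop = FALSE] - st$V[e$hi, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  shortest_first <- order(len)
  for (k in shortest_first) {
    if (len[k] >= lo) break
    i <- e$lo[k]
    j <- e$hi[k]
    if (!st$valive[i] || !st$valive[j]) next
    faces <- rm_faces_with_edge(st, i, j)
    if (length(faces) == 0L) next
    cur_len <- sqrt(sum((st$V[i, ] - st$V[j, ])^2))
    if (cur_len >= lo) next
    bi <- st$vb[i]
    bj <- st$vb[j]
    if (bi && bj) {
      if (length(faces) != 1L) next  # chord between boundary points: pinch
      if (st$vcorner[i] && st$vcorner[j]) next
      if (st$vcorner[i] || st$vcorner[j]) {
        keep <- if (st$vcorner[i]) i else j
        gone <- if (st$vcorner[i]) j else i
        target <- st$V[keep, ]
      } else {
        target <- (st$V[i, ] + st$V[j, ]) / 2
        keep <- i
        gone <- j
      }
    } else if (bi || bj) {
      keep <- if (bi) i else j
      gone <- if (bi) j else i
      target <- st$V[keep, ]
    } else {
      keep <- i
      gone <- j
      target <- (st$V[i, ] + st$V[j, ]) / 2
    }
    # link condition: shared ring must be exactly the opposite vertices
    opp <- unique(as.vector(st$F[faces, , drop = FALSE]))
    opp <- setdiff(opp, c(i, j))
    shared <- intersect(rm_ring(st, i), rm_ring(st, j))
    if (!setequal(shared, opp)) next
    # quality guard: no incident edge may become overlong
    nbrs <- setdiff(union(rm_ring(st, i), rm_ring(st, j)), c(i, j))
    dn <- st$V[nbrs, , drop = FALSE] -
      matrix(target, length(nbrs), 3L, byrow = TRUE)
    if (any(sqrt(rowSums(dn * dn)) > hi)) next
    # execute: merge `gone` into `keep`
    st$V[keep, ] <- target
    for (fc in faces) rm_kill_face(st, fc)
    gf <- st$vface[[gone]]
    gf <- gf[st$falive[gf]]
    for (fc in gf) {
      tri <- st$F[fc, ]
      tri[tri == gone] <- keep
      if (anyDuplicated(tri)) {
        rm_kill_face(st, fc)
      } else {
        st$F[fc, ] <- tri
        st$vface[[keep]] <- c(st$vface[[keep]], fc)
      }
    }
    st$valive[gone] <- FALSE
    st$vb[keep] <- bi || bj
    st$vcorner[keep] <- st$vcorner[keep] || st$vcorner[gone]
    len_keep <- st$vface[[keep]]
    st$vface[[keep]] <- len_keep[st$falive[len_keep]]
  }
  invisible(NULL)
}

rm_flip_pass <- function(st) {
  # valence per live vertex
  fid <- rm_alive_faces(st)
  f <- st$F[fid, , drop = FALSE]
  e <- rm_edges(st)
  val <- tabulate(c(e$lo, e$hi), nbins = nrow(st$V))
  targ <- ifelse(st$vb, 4L, 6L)
  for (k in seq_along(e$lo)) {
    if (e$nadj[k] != 2L) next
    i <- e$lo[k]
    j <- e$hi[k]
    faces <- rm_faces_with_edge(st, i, j)
    if (length(faces) != 2L) next
    t1 <- st$F[faces[1], ]
    t2 <- st$F[faces[2], ]
    c_ <- setdiff(t1, c(i, j))
    d_ <- setdiff(t2, c(i, j))
    if (length(c_) != 1L || length(d_) != 1L || c_ == d_) next
    # leave the boundary strip alone: valence targets are ill-defined on a
    # ragged rim and flips there can perturb an already-uniform mesh
    if (st$vb[i] && st$vb[j]) next
    if (d_ %in% rm_ring(st, c_)) next  # flipped edge already exists
    cost_before <- (val[i] - targ[i])^2 + (val[j] - targ[j])^2 +
      (val[c_] - targ[c_])^2 + (val[d_] - targ[d_])^2
    cost_after <- (val[i] - 1L - targ[i])^2 + (val[j] - 1L - targ[j])^2 +
      (val[c_] + 1L - targ[c_])^2 + (val[d_] + 1L - targ[d_])^2
    if (cost_after >= cost_before) next
    if (val[i] <= 3L || val[j] <= 3L) next
    # orientation bookkeeping: identify which input face holds edge (i -> j)
    pos_i <- which(t1 == i)
    f_ij <- if (t1[(pos_i %% 3L) + 1L] == j) faces[1] else faces[2]
    f_ji <- setdiff(faces, f_ij)
    cc <- setdiff(st$F[f_ij, ], c(i, j))   # opposite in the (i,j) face
    dd <- setdiff(st$F[f_ji, ], c(i, j))
    # geometric guard: reject folds (new normals must agree with old)
    n_old <- colSums(face_normals(st$V, st$F[faces, , drop = FALSE]))
    new1 <- c(cc, i, dd)
    new2 <- c(dd, j, cc)
    n_new <- face_normals(st$V, rbind(new1, new2))
    a_new <- triangle_areas(st$V, rbind(new1, new2))
    if (any(a_new < 1e-10)) next
    if (any((n_new %*% n_old) <= 0)) next
    # execute flip
    st$F[f_ij, ] <- new1
    st$F[f_ji, ] <- new2
    st$vface[[dd]] <- c(st$vface[[dd]], f_ij)
    st$vface[[cc]] <- c(st$vface[[cc]], f_ji)
    st$vface[[j]] <- setdiff(st$vface[[j]], f_ij)
    st$vface[[i]] <- setdiff(st$vface[[i]], f_ji)
    val[i] <- val[i] - 1L
    val[j] <- val[j] - 1L
    val[c_] <- val[c_] + 1L
    val[d_] <- val[d_] + 1L
  }
  invisible(NULL)
}

rm_smooth_pass <- function(st, lambda) {
  e <- rm_edges(st)
  live <- which(st$valive)
  n <- nrow(st$V)
  # neighbor centroids via the edge list
  acc <- matrix(0, n, 3L)
  cntv <- numeric(n)
  for (dim in 1:3) {
    s1 <- rowsum(st$V[e$hi, dim], e$lo)
    acc[as.integer(rownames(s1)), dim] <-
      acc[as.integer(rownames(s1)), dim] + s1
    s2 <- rowsum(st$V[e$lo, dim], e$hi)
    acc[as.integer(rownames(s2)), dim] <-
      acc[as.integer(rownames(s2)), dim] + s2
  }
  t1 <- tabulate(e$lo, nbins = n)
  t2 <- tabulate(e$hi, nbins = n)
  cntv <- t1 + t2
  interior <- live[!st$vb[live] & cntv[live] > 0L]
  cen <- acc[interior, , drop = FALSE] / cntv[interior]
  g <- cen - st$V[interior, , drop = FALSE]
  # tangential component only: remove the motion along the vertex normal
  nrm <- rm_vertex_normals(st, interior)
  gn <- rowSums(g * nrm)
  g <- g - nrm * gn
  st$V[interior, ] <- st$V[interior, , drop = FALSE] + lambda * g
  # boundary vertices: average of boundary neighbors, then re-projected
  bedges <- which(e$nadj == 1L)
  if (length(bedges) > 0L) {
    blo <- e$lo[bedges]
    bhi <- e$hi[bedges]
    accb <- matrix(0, n, 3L)
    cntb <- numeric(n)
    for (dim in 1:3) {
      s1 <- rowsum(st$V[bhi, dim], blo)
      accb[as.integer(rownames(s1)), dim] <-
        accb[as.integer(rownames(s1)), dim] + s1
      s2 <- rowsum(st$V[blo, dim], bhi)
      accb[as.integer(rownames(s2)), dim] <-
        accb[as.integer(rownames(s2)), dim] + s2
    }
    cntb <- tabulate(blo, nbins = n) + tabulate(bhi, nbins = n)
    bv <- live[st$vb[live] & !st$vcorner[live] & cntb[live] > 0L]
    cenb <- accb[bv, , drop = FALSE] / cntb[bv]
    st$V[bv, ] <- st$V[bv, , drop = FALSE] +
      lambda * (cenb - st$V[bv, , drop = FALSE])
  }
  invisible(NULL)
}

rm_vertex_normals <- function(st, vids) {
  fid <- rm_alive_faces(st)
  fn <- face_normals(st$V, st$F[fid, , drop = FALSE])
  n <- matrix(0, nrow(st$V), 3L)
  for (c_ in 1:3) {
    idx <- st$F[fid, c_]
    for (dim in 1:3) {
      s <- rowsum(fn[, dim], idx)
      n[as.integer(rownames(s)), dim] <- n[as.integer(rownames(s)), dim] + s
    }
  }
  n <- n[vids, , drop = FALSE]
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n / len
}

rm_project_pass <- function(st) {
  live <- which(st$valive)
  interior <- live[!st$vb[live]]
  if (length(interior) > 0L) {
    q <- cpp_closest_point(st$surf_index,
                           st$V[interior, , drop = FALSE])
    st$V[interior, ] <- q$point
  }
  bnd <- live[st$vb[live]]
  if (length(bnd) > 0L && !is.null(st$segA)) {
    q <- cpp_closest_on_segments(st$segA, st$segB,
                                 st$V[bnd, , drop = FALSE])
    st$V[bnd, ] <- q$point
  }
  invisible(NULL)
}

rm_compact <- function(st) {
  f <- st$F[st$falive, , drop = FALSE]
  drop_unreferenced(surface_mesh(st$V, f, validate = FALSE))
}
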
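# geometric fixtures built in code

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- matrix(c(1, 3, 4, 1, 4, 2, 5, 6, 8, 5, 8, 7,
                1, 2, 6, 1, 6, 5, 3, 7, 8, 3, 8, 4,
                1, 5, 7, 1, 7, 3, 2, 4, 8, 2, 8, 6),
              ncol = 3, byrow = TRUE)
  m <- surface_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

box_mesh <- function(lo, hi) {
  m <- unit_cube_mesh()
  m$vertices <- sweep(sweep(m$vertices, 2, hi - lo, "*"), 2, lo, "+")
  m
}

# latitude/longitude sphere, outward winding
uv_sphere_mesh <- function(r = 10, nth = 32, nph = 64) {
  th <- seq(0, pi, length.out = nth)[-c(1, nth)]
  ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
  nr <- length(th)
  v <- cbind(as.vector(outer(sin(th), cos(ph))),
             as.vector(outer(sin(th), sin(ph))),
             as.vector(outer(cos(th), rep(1, nph)))) * r
  idx <- function(i, j) (j - 1L) * nr + i
  f <- NULL
  for (j in seq_len(nph)) {
    jn <- if (j == nph) 1L else j + 1L
    i <- seq_len(nr - 1L)
    f <- rbind(f,
               cbind(idx(i, j), idx(i, jn), idx(i + 1L, j)),
               cbind(idx(i + 1L, j), idx(i, jn), idx(i + 1L, jn)))
  }
  np <- nrow(v) + 1L
  sp <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  for (j in seq_len(nph)) {
    jn <- if (j == nph) 1L else j + 1L
    f <- rbind(f, c(np, idx(1, jn), idx(1, j)), c(sp, idx(nr, j), idx(nr, jn)))
  }
  m <- surface_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# flat square patch in the z = 0 plane, triangulated on a regular grid
flat_patch_mesh <- function(side = 100, n = 21) {
  g <- seq(0, side, length.out = n)
  v <- cbind(as.matrix(expand.grid(x = g, y = g)), 0)
  dimnames(v) <- NULL
  idx <- function(i, j) (j - 1L) * n + i
  f <- NULL
  for (j in seq_len(n - 1L)) {
    i <- seq_len(n - 1L)
    f <- rbind(f,
               cbind(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
               cbind(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  surface_mesh(v, f)
}

# equilateral triangle grid with edge length h in the z = 0 plane
equilateral_grid_mesh <- function(h = 10, nx = 8, ny = 6) {
  v <- NULL
  for (j in 0:(ny - 1)) {
    x <- (0:(nx - 1)) * h + (j %% 2) * h / 2
    v <- rbind(v, cbind(x, j * h * sqrt(3) / 2, 0))
  }
  idx <- function(i, j) j * nx + i + 1L
  f <- NULL
  for (j in 0:(ny - 2)) {
    for (i in 0:(nx - 2)) {
      if (j %% 2 == 0) {
        f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                   c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
      } else {
        f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
      }
    }
  }
  surface_mesh(v, f)
}

single_node_lattice <- function(p = c(0, 0, 0)) {
  structure(list(nodes = matrix(p, 1, 3), edges = matrix(integer(0), 0, 2),
                 faces = NULL), class = "splint_lattice")
}

edge_lattice <- function(a, b) {
  structure(list(nodes = rbind(a, b), edges = matrix(c(1L, 2L), 1, 2),
                 faces = NULL), class = "splint_lattice")
}
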
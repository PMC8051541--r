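# Mass-spring relaxation of the draft lattice. Edges act as Hooke springs
# with a single uniform rest length (DistMesh-style uniform density scaling);
# momentum-based viscous damping lets the system settle instead of
# oscillating; nodes are projected back onto the offset shell every step so
# the splint keeps a constant clearance from the skin.

#' Optimizer parameters
#'
#' The damping factor `1 - damping * dt / mass` must lie in (0, 1) so the
#' speed of a force-free node decays monotonically. `fscale` inflates the
#' uniform rest length above the mean edge length, which keeps the lattice
#' gently pressurized and spreads nodes apart (the standard constant of the
#' cited mesh-generation scheme is 1.2).
#'
#' @param k spring stiffness (force per mm).
#' @param mass node mass.
#' @param dt time step.
#' @param damping viscous coefficient `c`; the viscous force is `-c * v`.
#' @param fscale rest-length scale factor applied to the RMS edge length.
#'   The default 1.0 is the neutral choice for relaxation on a
#'   fixed-topology shell of fixed area: the rest length equals the RMS
#'   edge length, so springs equalize lengths without net pressure. Values
#'   above ~1.05 over-pressurize the constrained lattice and make
#'   compressed spring chains buckle into sliver triangles (the classical
#'   1.2 of planar mesh generation relies on boundary outflow and
#'   retriangulation to vent that pressure, neither of which applies
#'   here).
#' @param mode `"bilateral"` (springs both push and pull) or
#'   `"repulsive_only"` (compressed springs push, stretched ones go slack).
#' @param max_iterations iteration cap.
#' @param tolerance convergence threshold on the max per-node displacement
#'   per step (mm); default `1e-3 * L0`, resolved when the system is built.
#' @return a list of class `optimizer_params`.
#' @export
optimizer_params <- function(k = 1, mass = 1, dt = 0.2, damping = 1,
                             fscale = 1.0,
                             mode = c("bilateral", "repulsive_only"),
                             max_iterations = 1000L, tolerance = NULL) {
  mode <- match.arg(mode)
  if (k <= 0 || mass <= 0 || dt <= 0 || fscale <= 0)
    stop("k, mass, dt and fscale must be positive")
  gamma <- damping * dt / mass
  if (gamma <= 0 || gamma >= 1)
    stop("damping factor 1 - c*dt/m must lie in (0, 1); got c*dt/m = ",
         signif(gamma, 4))
  if (!is.null(tolerance) && tolerance <= 0) stop("tolerance must be positive")
  structure(list(k = k, mass = mass, dt = dt, damping = damping,
                 fscale = fscale, mode = mode,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "optimizer_params")
}

#' Construct a spring system directly
#'
#' Low-level constructor used by [build_springs()] and by free-floating test
#' systems (no reference surface, no constraints).
#'
#' @param positions n x 3 node positions (mm).
#' @param edges 2-column index matrix.
#' @param params an [optimizer_params()].
#' @param rest_length uniform rest length `L0`; computed from the edges via
#'   the uniform-density scaling `fscale * sqrt(mean squared edge length)`
#'   when `NULL`.
#' @param surface optional [surface_mesh()] the nodes are projected onto.
#' @param boundary,fixed optional logical flags per node.
#' @return a list of class `spring_system`.
#' @export
spring_system <- function(positions, edges, params = optimizer_params(),
                          rest_length = NULL, surface = NULL,
                          boundary = NULL, fixed = NULL) {
  positions <- matrix(as.double(positions), ncol = 3L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  n <- nrow(positions)
  if (nrow(edges) == 0L) stop("spring system needs at least one edge")
  if (max(edges) > n || min(edges) < 1L) stop("edge index out of range")
  d <- positions[edges[, 1], , drop = FALSE] -
    positions[edges[, 2], , drop = FALSE]
  len2 <- rowSums(d * d)
  if (is.null(rest_length))
    rest_length <- params$fscale * sqrt(sum(len2) / nrow(edges))
  if (rest_length <= 0) stop("rest length must be positive")
  if (is.null(boundary)) boundary <- rep(FALSE, n)
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  tol <- params$tolerance
  if (is.null(tol)) tol <- 1e-3 * rest_length
  sys <- list(x = positions,
              v = matrix(0, n, 3L),
              edges = edges,
              L0 = rest_length,
              rest = rep(rest_length, nrow(edges)),
              params = params,
              tolerance = tol,
              boundary = boundary,
              fixed = fixed,
              surface = surface,
              surf_index = NULL,
              surf_normals = NULL,
              segA = NULL, segB = NULL)
  if (!is.null(surface)) {
    sys$surf_index <- cpp_mesh_index(surface$vertices, surface$faces)
    sys$surf_normals <- face_normals(surface$vertices, surface$faces)
    loops <- mesh_boundary_loops(surface)
    segA <- NULL; segB <- NULL
    for (lp in loops) {
      nxt <- c(lp[-1], lp[1])
      segA <- rbind(segA, surface$vertices[lp, , drop = FALSE])
      segB <- rbind(segB, surface$vertices[nxt, , drop = FALSE])
    }
    sys$segA <- segA
    sys$segB <- segB
  }
  structure(sys, class = "spring_system")
}

#' Build the spring system for a draft lattice on its offset shell
#'
#' Velocities start at zero; the uniform rest length is
#' `fscale * sqrt(sum(|e|^2) / E)`; nodes lying on the shell's boundary
#' polylines are flagged and will only slide along the boundary during
#' optimization.
#'
#' @param lattice a connected [extract_lattice()] result.
#' @param surface the cropped offset shell the lattice came from.
#' @param params an [optimizer_params()].
#' @return a `spring_system`.
#' @export
build_springs <- function(lattice, surface, params = optimizer_params()) {
  if (!lattice_connected(lattice))
    stop("lattice must be a single connected component")
  sys <- spring_system(lattice$nodes, lattice$edges, params,
                       surface = surface)
  d <- surface_distance(surface, sys$x)
  if (any(d > 0.5 * sys$L0))
    stop(sprintf(paste0("lattice/surface mismatch: %d nodes farther than ",
                        "0.5*L0 (%.3g mm) from the shell"),
                 sum(d > 0.5 * sys$L0), 0.5 * sys$L0))
  if (!is.null(sys$segA)) {
    q <- cpp_closest_on_segments(sys$segA, sys$segB, sys$x)
    sys$boundary <- q$dist < 1e-6
  }
  sys
}

#' Spring forces on every node
#'
#' For an edge `(i, j)` at length `L` with unit direction `u` from `i` to
#' `j`, bilateral mode applies `f = k * (L0 - L)`: node `i` receives
#' `-f * u` and node `j` receives `+f * u`, so compressed springs push the
#' endpoints apart and stretched springs pull them together.
#' `repulsive_only` clamps `f` at zero (pure repulsion). The total over all
#' nodes is always the zero vector.
#'
#' @param system a `spring_system`.
#' @return an n x 3 matrix of forces.
#' @export
spring_forces <- function(system) {
  e <- system$edges
  d <- system$x[e[, 2], , drop = FALSE] - system$x[e[, 1], , drop = FALSE]
  L <- sqrt(rowSums(d * d))
  if (any(L < 1e-12)) {
    bad <- which(L < 1e-12)[1]
    stop(sprintf("degenerate zero-length edge (%d, %d)",
                 e[bad, 1], e[bad, 2]))
  }
  u <- d / L
  f <- system$params$k * (system$rest - L)
  if (system$params$mode == "repulsive_only") f <- pmax(f, 0)
  n <- nrow(system$x)
  forces <- matrix(0, n, 3L)
  contrib <- rbind(-u * f, u * f)
  idx <- c(e[, 1], e[, 2])
  for (dim in 1:3) {
    s <- rowsum(contrib[, dim], idx)
    forces[as.integer(rownames(s)), dim] <- s
  }
  forces
}

#' Advance the spring system one step
#'
#' Semi-implicit Euler with multiplicative viscous damping:
#' `v <- (v + dt/m * F) * (1 - c*dt/m)`, `x <- x + dt * v`. When the system
#' has a reference surface, every non-fixed node is then projected to its
#' closest point (boundary nodes to the closest point on the boundary
#' polyline) and the velocity loses its surface-normal (resp. off-tangent)
#' component.
#'
#' @param system a `spring_system`.
#' @return the updated `spring_system`.
#' @export
spring_step <- function(system) {
  p <- system$params
  gamma <- 1 - p$damping * p$dt / p$mass
  forces <- spring_forces(system)
  v <- (system$v + (p$dt / p$mass) * forces) * gamma
  v[system$fixed, ] <- 0
  x <- system$x + p$dt * v
  if (!is.null(system$surf_index)) {
    free <- which(!system$fixed & !system$boundary)
    if (length(free) > 0L) {
      q <- cpp_closest_point(system$surf_index, x[free, , drop = FALSE])
      x[free, ] <- q$point
      nrm <- system$surf_normals[q$face, , drop = FALSE]
      vn <- rowSums(v[free, , drop = FALSE] * nrm)
      v[free, ] <- v[free, , drop = FALSE] - nrm * vn
    }
    bnd <- which(!system$fixed & system$boundary)
    if (length(bnd) > 0L && !is.null(system$segA)) {
      q <- cpp_closest_on_segments(system$segA, system$segB,
                                   x[bnd, , drop = FALSE])
      x[bnd, ] <- q$point
      tang <- system$segB[q$segment, , drop = FALSE] -
        system$segA[q$segment, , drop = FALSE]
      tang <- tang / sqrt(rowSums(tang * tang))
      vt <- rowSums(v[bnd, , drop = FALSE] * tang)
      v[bnd, ] <- tang * vt
    }
  }
  system$v <- v
  system$x <- x
  system
}

#' Total mechanical energy of a spring system
#'
#' Kinetic energy plus elastic energy `sum(0.5 * k * (L - L0)^2)`; used to
#' verify that damping dissipates energy on free-floating systems.
#'
#' @param system a `spring_system`.
#' @return energy (force * mm units).
#' @export
spring_energy <- function(system) {
  d <- system$x[system$edges[, 2], , drop = FALSE] -
    system$x[system$edges[, 1], , drop = FALSE]
  L <- sqrt(rowSums(d * d))
  kinetic <- 0.5 * system$params$mass * sum(system$v^2)
  elastic <- 0.5 * system$params$k * sum((L - system$rest)^2)
  kinetic + elastic
}

#' Relax a draft lattice on its offset shell
#'
#' Iterates [spring_step()] until the maximum per-node displacement in one
#' step falls below the tolerance or the iteration cap is reached.
#' Connectivity is never modified. Initial and final [lattice_quality()]
#' summaries, the iteration count and the convergence flag are attached as
#' attributes of the returned lattice.
#'
#' @param lattice a connected `splint_lattice`.
#' @param surface the cropped offset shell.
#' @param params an [optimizer_params()].
#' @return the lattice with updated node positions; attributes
#'   `iterations`, `converged`, `quality_initial`, `quality_final`.
#' @export
optimize_lattice <- function(lattice, surface, params = optimizer_params()) {
  sys <- build_springs(lattice, surface, params)
  q0 <- lattice_quality(lattice)
  it <- 0L
  converged <- FALSE
  while (it < params$max_iterations) {
    it <- it + 1L
    x_prev <- sys$x
    sys <- spring_step(sys)
    disp <- sqrt(max(rowSums((sys$x - x_prev)^2)))
    if (disp < sys$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("optimizer did not converge in %d iterations", it))
  out <- lattice
  out$nodes <- sys$x
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  attr(out, "quality_initial") <- q0
  attr(out, "quality_final") <- lattice_quality(out)
  out
}

#' Triangle and edge quality statistics of a lattice
#'
#' Quantifies what relaxation does to the lattice: large triangles shrink
#' and small ones grow, so the edge-length coefficient of variation drops,
#' the minimum triangle area rises and the maximum falls.
#'
#' @param lattice a `splint_lattice`.
#' @param faces triangle index matrix; defaults to the lattice's
#'   back-reference to its source mesh faces.
#' @return a list of class `lattice_quality`.
#' @export
lattice_quality <- function(lattice, faces = lattice$faces) {
  if (is.null(faces)) stop("lattice carries no faces; pass them explicitly")
  len <- lattice_edge_lengths(lattice)
  areas <- triangle_areas(lattice$nodes, faces)
  v <- lattice$nodes
  angs <- c()
  min_angle <- NA_real_
  # minimum inner angle over all triangles
  a <- v[faces[, 1], , drop = FALSE]
  b <- v[faces[, 2], , drop = FALSE]
  c_ <- v[faces[, 3], , drop = FALSE]
  ang1 <- tri_angle(b - a, c_ - a)
  ang2 <- tri_angle(a - b, c_ - b)
  ang3 <- tri_angle(a - c_, b - c_)
  min_angle <- min(c(ang1, ang2, ang3)) * 180 / pi
  cv <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / mean(x)
  structure(list(
    edge_mean = mean(len),
    edge_cv = cv(len),
    area_min = min(areas),
    area_max = max(areas),
    area_mean = mean(areas),
    area_cv = cv(areas),
    min_angle_deg = min_angle,
    n_edges = nrow(lattice$edges),
    n_triangles = nrow(faces)
  ), class = "lattice_quality")
}

tri_angle <- function(e1, e2) {
  l1 <- sqrt(rowSums(e1 * e1))
  l2 <- sqrt(rowSums(e2 * e2))
  acos(pmin(pmax(rowSums(e1 * e2) / pmax(l1 * l2, 1e-300), -1), 1))
}

#' @export
print.lattice_quality <- function(x, ...) {
  cat(sprintf(paste0(
    "<lattice_quality> %d edges, %d triangles\n",
    "  edge length: mean %.3f mm, CV %.3f\n",
    "  triangle area: min %.3f / mean %.3f / max %.3f mm^2, CV %.3f\n",
    "  min inner angle: %.1f deg\n"),
    x$n_edges, x$n_triangles, x$edge_mean, x$edge_cv,
    x$area_min, x$area_mean, x$area_max, x$area_cv, x$min_angle_deg))
  invisible(x)
}

#' Impose a graded triangle density on a lattice
#'
#' Smoothly warps the axial coordinate of the nodes with a sinusoidal
#' reparameterization `t -> t - a * sin(2*pi*t) / (2*pi)` and re-projects
#' them onto the shell. The warp's derivative stays in `[1 - a, 1 + a]`, so
#' triangles are compressed up to `1/(1 - a)`-fold in one band and
#' stretched up to `(1 + a)`-fold in another without ever folding or
#' degenerating — the kind of uneven density an interactive drafting tool
#' produces. This is the preset on which the optimizer's equalizing effect
#' is demonstrated and regression-tested.
#'
#' @param lattice a `splint_lattice`.
#' @param surface the shell the lattice lies on.
#' @param strength modulation amplitude `a` in `[0, 1)`; 0 is identity,
#'   the default 0.6 gives a 4:1 linear density ratio.
#' @return the warped lattice (same connectivity).
#' @export
grade_lattice_density <- function(lattice, surface, strength = 0.6) {
  if (strength < 0 || strength >= 1)
    stop("strength must be in [0, 1) so the warp stays bijective")
  z <- lattice$nodes[, 3]
  z0 <- min(z)
  z1 <- max(z)
  t <- (z - z0) / (z1 - z0)
  tw <- t - strength * sin(2 * pi * t) / (2 * pi)
  lattice$nodes[, 3] <- z0 + (z1 - z0) * tw
  q <- cpp_closest_point_mesh(surface$vertices, surface$faces, lattice$nodes)
  lattice$nodes <- q$point
  lattice
}
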
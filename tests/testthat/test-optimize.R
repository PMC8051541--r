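# mass-spring relaxation: rest lengths, forces, integration, convergence

test_that("uniform rest length follows the RMS scaling", {
  sys <- spring_system(rbind(c(0, 0, 0), c(10, 0, 0)),
                       matrix(c(1L, 2L), 1, 2),
                       optimizer_params(fscale = 1.2))
  expect_equal(sys$L0, 12)

  g <- equilateral_grid_mesh(10, 6, 5)
  lt <- extract_lattice(g)
  sys2 <- spring_system(lt$nodes, lt$edges, optimizer_params(fscale = 1.2))
  expect_equal(sys2$L0, 12, tolerance = 1e-12)
})

test_that("boundary nodes of the draft shell are flagged from its loops", {
  draft <- demo_draft()
  lt <- extract_lattice(draft)
  sys <- build_springs(lt, draft)
  n_loop <- length(unlist(mesh_boundary_loops(draft)))
  expect_equal(sum(sys$boundary), n_loop)
})

test_that("build_springs rejects a lattice far from its surface", {
  draft <- demo_draft()
  lt <- extract_lattice(draft)
  lt$nodes <- lt$nodes + 100
  expect_error(build_springs(lt, draft), "mismatch")
})

test_that("spring forces follow Hooke's law with the stated sign convention", {
  p <- optimizer_params()
  at_rest <- spring_system(rbind(c(0, 0, 0), c(12, 0, 0)),
                           matrix(c(1L, 2L), 1, 2), p, rest_length = 12)
  expect_equal(spring_forces(at_rest), matrix(0, 2, 3))

  compressed <- spring_system(rbind(c(0, 0, 0), c(8, 0, 0)),
                              matrix(c(1L, 2L), 1, 2), p, rest_length = 12)
  f <- spring_forces(compressed)
  # f = k (L0 - L) = 4; compressed spring pushes the nodes apart
  expect_equal(f[1, ], c(-4, 0, 0))
  expect_equal(f[2, ], c(4, 0, 0))

  stretched <- spring_system(rbind(c(0, 0, 0), c(16, 0, 0)),
                             matrix(c(1L, 2L), 1, 2), p, rest_length = 12)
  fs <- spring_forces(stretched)
  expect_equal(fs[1, ], c(4, 0, 0))   # stretched spring pulls together

  rep_only <- spring_system(rbind(c(0, 0, 0), c(16, 0, 0)),
                            matrix(c(1L, 2L), 1, 2),
                            optimizer_params(mode = "repulsive_only"),
                            rest_length = 12)
  expect_equal(spring_forces(rep_only), matrix(0, 2, 3))
})

test_that("an equilateral triangle at rest length has zero net force", {
  h <- 12
  pos <- rbind(c(0, 0, 0), c(h, 0, 0), c(h / 2, h * sqrt(3) / 2, 0))
  sys <- spring_system(pos, rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)),
                       optimizer_params(), rest_length = h)
  expect_lt(max(abs(spring_forces(sys))), 1e-12)
})

test_that("forces match a brute-force per-edge oracle", {
  set.seed(11)
  pos <- matrix(stats::runif(18, -5, 5), 6, 3)
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L),
                 c(6L, 1L), c(1L, 4L), c(2L, 5L))
  p <- optimizer_params(k = 2.5)
  sys <- spring_system(pos, edges, p, rest_length = 7)
  f <- spring_forces(sys)
  # independent oracle: explicit loop over edges
  oracle <- matrix(0, 6, 3)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]
    j <- edges[e, 2]
    d <- pos[j, ] - pos[i, ]
    L <- sqrt(sum(d^2))
    u <- d / L
    fe <- 2.5 * (7 - L)
    oracle[i, ] <- oracle[i, ] - fe * u
    oracle[j, ] <- oracle[j, ] + fe * u
  }
  expect_lt(max(abs(f - oracle)), 1e-12)
  # Newton's third law: total force is the zero vector
  expect_lt(max(abs(colSums(f))), 1e-9)
})

test_that("zero-length edges raise a degenerate-edge error", {
  sys <- spring_system(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                       rbind(c(1L, 2L), c(2L, 3L)), optimizer_params(),
                       rest_length = 1)
  expect_error(spring_forces(sys), "degenerate")
})

test_that("force-free motion decays by exactly the damping factor", {
  p <- optimizer_params(damping = 1, dt = 0.2, mass = 1)  # factor 0.8
  sys <- spring_system(rbind(c(0, 0, 0), c(12, 0, 0)),
                       matrix(c(1L, 2L), 1, 2), p, rest_length = 12)
  sys$v <- rbind(c(1, 2, 3), c(-1, 0.5, 2))
  v0 <- sys$v
  x0 <- sys$x
  out <- spring_step(sys)
  expect_equal(out$v, v0 * 0.8, tolerance = 1e-14)
  expect_equal(out$x, x0 + 0.2 * v0 * 0.8, tolerance = 1e-14)
})

test_that("a symmetric two-node system keeps its midpoint fixed", {
  p <- optimizer_params()
  sys <- spring_system(rbind(c(-4, 0, 0), c(4, 0, 0)),
                       matrix(c(1L, 2L), 1, 2), p, rest_length = 12)
  for (i in 1:100) {
    sys <- spring_step(sys)
    expect_lt(max(abs(colMeans(sys$x) - c(0, 0, 0))), 1e-12)
  }
})

test_that("one step on a plane surface matches an arithmetic oracle", {
  plane <- surface_mesh(rbind(c(-100, -100, 0), c(100, -100, 0),
                              c(100, 100, 0), c(-100, 100, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 9, 0), c(0, 11, 0))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L))
  p <- optimizer_params(k = 1.5, mass = 2, dt = 0.1, damping = 3)
  sys <- spring_system(pos, edges, p, rest_length = 10, surface = plane)
  out <- spring_step(sys)
  # independent straight-line arithmetic: forces, damped velocity, advance;
  # the plane projection leaves in-plane coordinates unchanged
  oracle_f <- matrix(0, 4, 3)
  for (e in seq_len(4)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    d <- pos[j, ] - pos[i, ]
    L <- sqrt(sum(d^2))
    fe <- 1.5 * (10 - L)
    oracle_f[i, ] <- oracle_f[i, ] - fe * d / L
    oracle_f[j, ] <- oracle_f[j, ] + fe * d / L
  }
  gamma <- 1 - 3 * 0.1 / 2
  oracle_v <- (0 + (0.1 / 2) * oracle_f) * gamma
  oracle_x <- pos + 0.1 * oracle_v
  oracle_x[, 3] <- 0
  expect_lt(max(abs(out$x - oracle_x)), 1e-12)
})

test_that("a free two-node system converges to the rest length", {
  p <- optimizer_params()
  sys <- spring_system(rbind(c(0, 0, 0), c(8, 0, 0)),
                       matrix(c(1L, 2L), 1, 2), p, rest_length = 12)
  for (i in 1:400) sys <- spring_step(sys)
  expect_equal(sqrt(sum((sys$x[2, ] - sys$x[1, ])^2)), 12,
               tolerance = 1e-3)
})

test_that("energy decays on free damped systems", {
  set.seed(5)
  pos <- matrix(stats::runif(15, -5, 5), 5, 3)
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 1L),
                 c(1L, 3L), c(2L, 4L))
  sys <- spring_system(pos, edges, optimizer_params(), rest_length = 6)
  energies <- numeric(60)
  for (i in 1:60) {
    sys <- spring_step(sys)
    energies[i] <- spring_energy(sys)
  }
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("an already uniform lattice is a near fixed point", {
  plane <- surface_mesh(rbind(c(-200, -200, 0), c(200, -200, 0),
                              c(200, 200, 0), c(-200, 200, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  g <- equilateral_grid_mesh(10, 7, 5)
  lt <- extract_lattice(g)
  p <- optimizer_params(max_iterations = 50)
  opt <- optimize_lattice(lt, plane, p)
  expect_true(attr(opt, "converged"))
  disp <- sqrt(rowSums((opt$nodes - lt$nodes)^2))
  expect_lt(max(disp), 0.05 * 10)
})

test_that("relaxation equalizes a graded wrist lattice (quantified)", {
  draft <- demo_draft()
  lt <- extract_lattice(draft)
  graded <- grade_lattice_density(lt, draft)
  q0 <- lattice_quality(graded)
  opt <- optimize_lattice(graded, draft)
  q1 <- attr(opt, "quality_final")
  # the dense patches open and the large holes shrink
  expect_lt(q1$edge_cv, q0$edge_cv)
  expect_lte(q1$edge_cv, 0.7 * q0$edge_cv)
  expect_gt(q1$area_min, q0$area_min)
  expect_lt(q1$area_max, q0$area_max)
  # connectivity untouched, nodes still on the shell, boundary on the rim
  expect_identical(opt$edges, lt$edges)
  expect_lt(max(surface_distance(draft, opt$nodes)), 1e-6)
  sys <- build_springs(lt, draft)
  bnd <- which(sys$boundary)
  q <- splintfab:::cpp_closest_on_segments(sys$segA, sys$segB,
                                           opt$nodes[bnd, , drop = FALSE])
  expect_lt(max(q$dist), 1e-6)
})

test_that("optimization is deterministic", {
  draft <- demo_draft()
  lt <- extract_lattice(draft)
  graded <- grade_lattice_density(lt, draft)
  a <- optimize_lattice(graded, draft)
  b <- optimize_lattice(graded, draft)
  expect_identical(a$nodes, b$nodes)
})

test_that("lattice quality statistics match direct recomputation", {
  h <- 1
  tri <- structure(list(
    nodes = rbind(c(0, 0, 0), c(h, 0, 0), c(h / 2, h * sqrt(3) / 2, 0)),
    edges = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)),
    faces = matrix(c(1L, 2L, 3L), 1, 3)), class = "splint_lattice")
  q <- lattice_quality(tri)
  expect_equal(q$edge_cv, 0, tolerance = 1e-12)
  expect_equal(q$min_angle_deg, 60, tolerance = 1e-9)
  expect_equal(q$area_cv, 0)

  two <- structure(list(
    nodes = rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, -4, 0)),
    edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 4L), c(2L, 4L)),
    faces = rbind(c(1L, 2L, 3L), c(1L, 4L, 2L))), class = "splint_lattice")
  q2 <- lattice_quality(two)
  expect_equal(q2$area_max / q2$area_min, 4)
  # mean edge length against a brute-force loop
  men <- mean(apply(two$edges, 1, function(e)
    sqrt(sum((two$nodes[e[1], ] - two$nodes[e[2], ])^2))))
  expect_lt(abs(q2$edge_mean - men), 1e-12)
})

test_that("invalid optimizer parameters are rejected", {
  expect_error(optimizer_params(damping = 10), "damping factor")
  expect_error(optimizer_params(dt = -1), "positive")
  expect_error(optimizer_params(tolerance = 0), "tolerance")
})
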
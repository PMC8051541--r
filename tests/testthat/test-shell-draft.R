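# offset surface, plane cutting, isotropic remeshing

test_that("offsetting a sphere moves every vertex to the larger radius", {
  sph <- uv_sphere_mesh(10, nth = 32, nph = 64)
  off <- offset_surface(sph, 2)
  r <- sqrt(rowSums(off$vertices^2))
  expect_lt(max(abs(r - 12)) / 12, 0.005)
  expect_identical(off$faces, sph$faces)
})

test_that("offsetting a capped cylinder moves lateral vertices outward", {
  cyl <- generate_limb(limb_preset("cylinder"))
  off <- offset_surface(cyl, 2)
  lateral <- which(cyl$vertices[, 3] > 40 & cyl$vertices[, 3] < 160)
  r <- sqrt(rowSums(off$vertices[lateral, 1:2]^2))
  expect_lt(max(abs(r - 32)) / 32, 0.01)
})

test_that("offset preconditions are enforced", {
  sph <- uv_sphere_mesh(10)
  expect_error(offset_surface(sph, 0), "positive")
  open_shell <- plane_cut(sph, cut_plane(c(0, 0, 0), c(0, 0, 1), "positive"))
  expect_error(offset_surface(open_shell, 2), "closed")
})

test_that("mean offset clearance equals the offset distance on all presets", {
  for (preset in c("cylinder", "wrist_default", "high_curvature")) {
    limb <- generate_limb(limb_preset(preset))
    off <- suppressWarnings(offset_surface(limb, 2))
    d <- surface_distance(limb, off$vertices)
    expect_equal(mean(d), 2, tolerance = 0.02)
  }
})

test_that("plane cut of a cube produces an open box with a planar rim", {
  cube <- unit_cube_mesh()
  cut <- plane_cut(cube, cut_plane(c(0, 0, 0.5), c(0, 0, 1), "positive"))
  v <- validate_mesh(cut, expect_closed = FALSE, check_intersections = FALSE)
  expect_false(v$watertight)
  expect_equal(v$n_boundary_loops, 1L)
  expect_true(v$ok)
  expect_equal(range(cut$vertices[, 3]), c(0.5, 1))
  loop <- v$boundary_loops[[1]]
  expect_lt(max(abs(cut$vertices[loop, 3] - 0.5)), 1e-6)
  # kept area: 4 half side walls + the top face
  expect_equal(mesh_area(cut), 3, tolerance = 1e-9)
})

test_that("a plane missing the mesh returns the input unchanged", {
  cube <- unit_cube_mesh()
  expect_warning(out <- plane_cut(cube,
                                  cut_plane(c(0, 0, 5), c(0, 0, 1),
                                            "positive")),
                 "misses")
  expect_identical(out$vertices, cube$vertices)
})

test_that("clipping a single triangle matches the hand-computed area", {
  # triangle in the xz plane: one vertex above z = 0, two below/at
  tri <- surface_mesh(rbind(c(0, 0, -1), c(1, 0, -1), c(0, 0, 1)),
                      matrix(c(1, 2, 3), 1, 3))
  cut <- plane_cut(tri, cut_plane(c(0, 0, 0), c(0, 0, 1), "positive"))
  # kept piece: apex (0,0,1) with base from (0,0,0) to (0.5,0,0); the
  # original triangle has area 1, the kept sub-triangle area 1/4
  expect_equal(mesh_area(cut), 0.25, tolerance = 1e-12)
  new_pts <- cut$vertices[abs(cut$vertices[, 3]) < 1e-12, , drop = FALSE]
  expect_equal(nrow(new_pts), 2L)
})

test_that("plane cutting conserves area between the two sides", {
  set.seed(42)
  for (rep in 1:5) {
    v <- matrix(stats::rnorm(30), 10, 3)
    f <- matrix(sample(10, 9, replace = FALSE), 3, 3)
    m <- surface_mesh(v, f)
    pl_pos <- cut_plane(c(0, 0, 0), c(1, 2, 3), "positive")
    pl_neg <- cut_plane(c(0, 0, 0), c(1, 2, 3), "negative")
    a_pos <- suppressWarnings(mesh_area(plane_cut(m, pl_pos)))
    a_neg <- suppressWarnings(mesh_area(plane_cut(m, pl_neg)))
    expect_equal(a_pos + a_neg, mesh_area(m), tolerance = 1e-6)
  }
})

test_that("remeshing a flat patch hits the target edge-length band", {
  patch <- flat_patch_mesh(100, 21)  # 5 mm grid
  out <- remesh_isotropic(patch, remesh_params(10))
  lt <- extract_lattice(out)
  len <- lattice_edge_lengths(lt)
  expect_true(all(len >= 6 & len <= 15.5))
  # still a disk
  expect_equal(nrow(lt$nodes) - nrow(lt$edges) + nrow(out$faces), 1L)
  # interior band: at least 90% of edges within [0.6h, 1.5h]
  expect_gte(mean(len >= 6 & len <= 15), 0.9)
  # the patch stays flat and inside its square
  expect_lt(max(abs(out$vertices[, 3])), 1e-9)
  expect_gte(min(out$vertices[, 1:2]), -1e-9)
  expect_lte(max(out$vertices[, 1:2]), 100 + 1e-9)
})

test_that("an already uniform grid stays uniform under remeshing", {
  g <- equilateral_grid_mesh(10, 9, 7)
  lt_in <- extract_lattice(g)
  cv_in <- stats::sd(lattice_edge_lengths(lt_in)) /
    mean(lattice_edge_lengths(lt_in))
  out <- remesh_isotropic(g, remesh_params(10, iterations = 5))
  lt_out <- extract_lattice(out)
  cv_out <- stats::sd(lattice_edge_lengths(lt_out)) /
    mean(lattice_edge_lengths(lt_out))
  expect_lte(cv_out, cv_in + 1e-12)
  # near-fixed-point: no vertex drifts far from the original surface
  expect_lt(max(abs(out$vertices[, 3])), 1e-9)
})

test_that("remeshing the cropped wrist shell keeps the profile and offset", {
  shell <- demo_shell()
  draft <- demo_draft()
  v <- validate_mesh(draft, expect_closed = FALSE,
                     check_intersections = FALSE)
  expect_true(v$ok)
  expect_equal(v$n_boundary_loops, 2L)
  expect_true(lattice_connected(extract_lattice(draft)))
  # projection contract: vertices sit on the offset shell
  expect_lt(max(surface_distance(shell, draft$vertices)), 0.1)
  expect_lt(max(surface_distance(shell, draft$vertices)), 0.2 * 12)
  # composition contract: every vertex 2 mm (+- 0.1) above the limb
  d <- surface_distance(demo_limb(), draft$vertices)
  expect_true(all(abs(d - 2) < 0.1))
  # boundary loops still lie on the cut planes
  loops <- mesh_boundary_loops(draft)
  for (lp in loops) {
    z <- draft$vertices[lp, 3]
    expect_lt(min(abs(mean(z) - c(55, 195))), 0.5)
  }
})

test_that("remesh rejects an over-coarse target", {
  patch <- flat_patch_mesh(100, 21)
  expect_error(remesh_isotropic(patch, remesh_params(60)), "too large")
})
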
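# wireframe -> solid conversion: closed forms, voxel oracles, blocks, split

test_that("a single node solidifies to a sphere of the right volume", {
  s <- strut_solid(single_node_lattice(), strut_params(4))
  v <- validate_mesh(s, check_intersections = FALSE)
  expect_true(v$ok)
  expect_equal(v$volume, 4 / 3 * pi * 2^3, tolerance = 0.02)
})

test_that("a single edge solidifies to a capsule of the right volume", {
  s <- strut_solid(edge_lattice(c(0, 0, 0), c(20, 0, 0)), strut_params(4))
  v <- validate_mesh(s, check_intersections = FALSE)
  expect_true(v$ok)
  expect_equal(v$volume, pi * 2^2 * 20 + 4 / 3 * pi * 2^3, tolerance = 0.02)
  # sliced at mid-edge the bar shows its full diameter
  expect_equal(slice_diameter(s, c(10, 0, 0), c(1, 0, 0)), 4,
               tolerance = 0.05)
})

test_that("a triangle cell matches the ray-cast union oracle", {
  tri <- structure(list(
    nodes = rbind(c(0, 0, 0), c(20, 0, 0), c(10, 17.3, 0)),
    edges = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)), faces = NULL),
    class = "splint_lattice")
  s <- strut_solid(tri, strut_params(4))
  expect_true(validate_mesh(s, check_intersections = FALSE)$ok)
  expect_equal(mesh_volume(s), voxel_volume(s, 0.25), tolerance = 0.03)
  # never more than the sum of primitive volumes
  cap_vol <- function(L) pi * 2^2 * L + 4 / 3 * pi * 2^3
  lens <- lattice_edge_lengths(tri)
  expect_lt(mesh_volume(s), sum(cap_vol(lens)))
})

test_that("strut volume grows monotonically with diameter", {
  tri <- structure(list(
    nodes = rbind(c(0, 0, 0), c(20, 0, 0), c(10, 17.3, 0)),
    edges = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)), faces = NULL),
    class = "splint_lattice")
  vols <- vapply(c(3, 4, 5), function(d)
    mesh_volume(strut_solid(tri, strut_params(d))), numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("short edges trigger the merged-blob warning; empty errors", {
  short <- edge_lattice(c(0, 0, 0), c(3, 0, 0))
  expect_warning(strut_solid(short, strut_params(4)), "shorter")
  empty <- structure(list(nodes = matrix(0, 0, 3),
                          edges = matrix(integer(0), 0, 2), faces = NULL),
                     class = "splint_lattice")
  expect_error(strut_solid(empty, strut_params(4)), "empty")
})

test_that("block specification invariants hold", {
  expect_error(block_spec(c(0, 0, 0), diag(3), dims = c(20, 12, 8),
                          hole_diameter = 12), "hole diameter")
  expect_error(block_spec(c(0, 0, 0), matrix(1, 3, 3)), "orthonormal")
  expect_error(block_spec(c(0, 0, 0), diag(3), dims = c(-1, 2, 3)),
               "positive")
})

test_that("attaching a block to a cube matches the voxel union oracle", {
  cube <- box_mesh(c(0, 0, 0), c(20, 20, 20))
  class(cube) <- c("solid_model", "splint_mesh")
  blk <- block_spec(c(10, 10, 22), diag(3), dims = c(12, 10, 8),
                    hole_diameter = 0)
  out <- attach_blocks(cube, list(blk))
  expect_true(validate_mesh(out, check_intersections = FALSE)$ok)
  blk_mesh <- box_mesh(c(4, 5, 18), c(16, 15, 26))
  oracle <- union_volume(cube, blk_mesh, 0.2)
  expect_equal(mesh_volume(out), oracle, tolerance = 0.03)
})

test_that("a block that misses the solid is rejected by index", {
  cube <- box_mesh(c(0, 0, 0), c(20, 20, 20))
  class(cube) <- c("solid_model", "splint_mesh")
  far <- block_spec(c(10, 10, 200), diag(3))
  expect_error(attach_blocks(cube, list(far)), "1")
})

test_that("splitting a sphere yields two half balls", {
  sph <- uv_sphere_mesh(10, nth = 48, nph = 96)
  ps <- split_solid(sph, cut_plane(c(0, 0, 0), c(0, 0, 1), "positive"),
                    pitch = 0.25)
  half <- 2 / 3 * pi * 1000
  expect_equal(mesh_volume(ps$first), half, tolerance = 0.01)
  expect_equal(mesh_volume(ps$second), half, tolerance = 0.01)
  expect_true(validate_mesh(ps$first, check_intersections = FALSE)$ok)
  expect_true(validate_mesh(ps$second, check_intersections = FALSE)$ok)
  expect_equal(mesh_volume(ps$first) + mesh_volume(ps$second),
               mesh_volume(sph), tolerance = 0.01)
  # the pieces occupy opposite half spaces
  expect_gte(min(ps$first$vertices[, 3]), -1e-6)
  expect_lte(max(ps$second$vertices[, 3]), 1e-6)
})

test_that("splitting a cube at one quarter gives a 1:3 volume ratio", {
  cube <- box_mesh(c(0, 0, 0), c(10, 10, 10))
  ps <- split_solid(cube, cut_plane(c(0, 0, 2.5), c(0, 0, 1), "positive"),
                    pitch = 0.2)
  expect_equal(mesh_volume(ps$first) / mesh_volume(ps$second), 3,
               tolerance = 0.01)
})

test_that("split then re-union recovers the input volume", {
  sph <- uv_sphere_mesh(10, nth = 48, nph = 96)
  ps <- split_solid(sph, cut_plane(c(0, 0, 1), c(0, 0, 1), "positive"),
                    pitch = 0.25)
  expect_equal(union_volume(ps$first, ps$second, 0.2), mesh_volume(sph),
               tolerance = 0.02)
})

test_that("a plane missing the solid raises a split error", {
  cube <- box_mesh(c(0, 0, 0), c(10, 10, 10))
  expect_error(split_solid(cube,
                           cut_plane(c(0, 0, 50), c(0, 0, 1), "positive")),
               "misses")
})

test_that("the demo splint has exactly six open through-channels", {
  run <- demo_run()
  expect_equal(length(run$blocks), 6L)
  open <- through_channels(run$solid, run$blocks)
  expect_equal(sum(open), 6L)
  # a sanity control: a probe aimed straight through a strut node (solid
  # material, no hole there) is blocked
  node <- run$optimized$nodes[1, ]
  phantom <- block_spec(node, diag(3), dims = c(20, 12, 8),
                        hole_diameter = 4, hole_axis = 3L)
  expect_false(through_channels(run$solid, list(phantom))[1])
})
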
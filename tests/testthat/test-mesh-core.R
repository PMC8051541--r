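# mesh container, file round trips, validation, lattice extraction

test_that("STL and OBJ round trips preserve geometry and connectivity", {
  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  for (ext in c("stl", "obj")) {
    path <- file.path(tempdir(), paste0("tet.", ext))
    write_mesh(tet, path)
    back <- suppressMessages(read_mesh(path))
    expect_equal(nrow(back$vertices), 4L)
    expect_equal(nrow(back$faces), 4L)
    # same vertex set within 1e-6 mm (order may differ after welding)
    d <- surface_distance(tet, back$vertices)
    expect_lt(max(d), 1e-6)
    expect_equal(abs(mesh_volume(back)), abs(mesh_volume(tet)),
                 tolerance = 1e-6)
  }
})

test_that("binary STL of a cube welds to 8 vertices and 12 faces", {
  cube <- unit_cube_mesh()
  path <- file.path(tempdir(), "cube.stl")
  write_mesh(cube, path)
  expect_equal(file.size(path), 84 + 50 * 12)  # one 50-byte record per facet
  back <- suppressMessages(read_mesh(path))
  expect_equal(nrow(back$vertices), 8L)
  expect_equal(nrow(back$faces), 12L)
  expect_equal(mesh_volume(back), 1, tolerance = 1e-6)
})

test_that("coincident OBJ vertices weld within tolerance", {
  path <- file.path(tempdir(), "weld.obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
               "v 0 0 0.00005",            # within 1e-4 of vertex 1
               "f 1 2 3", "f 4 2 3"), path)
  back <- suppressMessages(read_mesh(path, weld_tol = 1e-4))
  expect_equal(nrow(back$vertices), 3L)
})

test_that("writing an empty mesh errors; open shell as STL warns", {
  empty <- surface_mesh(matrix(0, 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_mesh(empty, file.path(tempdir(), "e.stl")), "empty")
  open_shell <- plane_cut(unit_cube_mesh(),
                          cut_plane(c(0, 0, 0.5), c(0, 0, 1), "positive"))
  expect_warning(write_mesh(open_shell, file.path(tempdir(), "o.stl")),
                 "printable")
})

test_that("validate_mesh reports watertightness, loops and volume", {
  cube <- unit_cube_mesh()
  v <- validate_mesh(cube)
  expect_true(v$watertight)
  expect_true(v$consistent_winding)
  expect_equal(v$n_boundary_loops, 0L)
  expect_equal(v$volume, 1)
  expect_equal(v$self_intersections, 0L)
  expect_true(v$ok)

  holed <- surface_mesh(cube$vertices, cube$faces[-1, ])
  vh <- validate_mesh(holed, expect_closed = TRUE)
  expect_false(vh$watertight)
  expect_equal(vh$n_boundary_loops, 1L)
  expect_false(vh$ok)
})

test_that("interpenetrating cubes are caught by the intersection sample", {
  a <- unit_cube_mesh()
  b <- unit_cube_mesh()
  b$vertices <- b$vertices + 0.5
  both <- surface_mesh(rbind(a$vertices, b$vertices),
                       rbind(a$faces, b$faces + nrow(a$vertices)))
  v <- validate_mesh(both, expect_closed = FALSE)
  expect_gt(v$self_intersections, 0L)
})

test_that("lattice extraction yields unique undirected edges", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1, 3))
  lt <- extract_lattice(tri)
  expect_equal(nrow(lt$nodes), 3L)
  expect_equal(nrow(lt$edges), 3L)

  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  lt2 <- extract_lattice(tet)
  expect_equal(nrow(lt2$edges), 6L)  # V - E + F = 2
  expect_true(lattice_connected(lt2))
})

test_that("open shells satisfy the Euler relation V - E + F = 2 - loops", {
  patch <- flat_patch_mesh(100, 11)   # disk topology: one boundary loop
  lt <- extract_lattice(patch)
  V <- nrow(lt$nodes)
  E <- nrow(lt$edges)
  F <- nrow(patch$faces)
  expect_equal(V - E + F, 1L)

  shell <- demo_shell()               # tube: two boundary loops
  lt2 <- extract_lattice(shell)
  expect_equal(nrow(lt2$nodes) - nrow(lt2$edges) + nrow(shell$faces), 0L)
  expect_equal(validate_mesh(shell, expect_closed = FALSE,
                             check_intersections = FALSE)$n_boundary_loops,
               2L)
})

test_that("mesh volume of a dense sphere approaches the closed form", {
  sph <- uv_sphere_mesh(10, nth = 52, nph = 100)  # ~10k faces
  expect_gt(nrow(sph$faces), 9000)
  expect_equal(mesh_volume(sph), 4 / 3 * pi * 1000, tolerance = 0.02)
  # ray-cast oracle agrees with the divergence theorem
  expect_equal(voxel_volume(sph, 0.25), mesh_volume(sph), tolerance = 0.005)
})
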
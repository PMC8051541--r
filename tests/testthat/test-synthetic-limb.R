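# synthetic limb generator: closed forms, determinism, symmetry, scaling

test_that("cylinder preset matches the closed-form volume", {
  cyl <- generate_limb(limb_preset("cylinder"))
  v <- validate_mesh(cyl, check_intersections = FALSE)
  expect_true(v$watertight)
  expect_true(v$ok)
  expect_equal(v$volume, pi * 30^2 * 200, tolerance = 0.01)
})

test_that("generation is bitwise deterministic for a fixed seed", {
  p <- limb_preset("wrist_default", seed = 7L)
  a <- generate_limb(p)
  b <- generate_limb(p)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  # and does not disturb the caller's RNG stream
  set.seed(123)
  before <- .Random.seed
  invisible(generate_limb(p))
  expect_identical(.Random.seed, before)
})

test_that("wrist preset is watertight and its volume matches the ray oracle", {
  wr <- demo_limb()
  v <- validate_mesh(wr, check_intersections = FALSE)
  expect_true(v$ok)
  expect_gte(nrow(wr$faces), 10000)
  expect_lte(nrow(wr$faces), 50000)
  expect_equal(voxel_volume(wr, 0.5), v$volume,
               tolerance = 0.02)
})

test_that("noise-free limbs are mirror symmetric across the bump plane", {
  p <- limb_params(noise_amplitude = 0, axial_samples = 40L,
                   radial_samples = 32L)
  m <- generate_limb(p)
  refl <- m$vertices
  refl[, 2] <- -refl[, 2]
  # reflected vertex set equals the original vertex set within 1e-6 mm
  key <- function(v) paste(round(v[, 1], 6), round(v[, 2], 6),
                           round(v[, 3], 6))
  expect_setequal(key(refl), key(m$vertices))
})

test_that("area and volume scale as s^2 and s^3 under uniform scaling", {
  base <- limb_params(noise_amplitude = 0, axial_samples = 40L,
                      radial_samples = 32L)
  s <- 2
  scaled <- limb_params(length = base$length * s,
                        proximal_semi_axes = base$proximal_semi_axes * s,
                        distal_semi_axes = base$distal_semi_axes * s,
                        cross_section_exponent = base$cross_section_exponent,
                        axis_curvature = base$axis_curvature / s,
                        bump_center = base$bump_center,
                        bump_amplitude = base$bump_amplitude * s,
                        bump_sigma = base$bump_sigma * s,
                        noise_amplitude = 0,
                        axial_samples = 40L, radial_samples = 32L)
  m1 <- generate_limb(base)
  m2 <- generate_limb(scaled)
  expect_equal(mesh_area(m2) / mesh_area(m1), s^2, tolerance = 1e-6)
  expect_equal(mesh_volume(m2) / mesh_volume(m1), s^3, tolerance = 1e-6)
})

test_that("invalid limb parameters are rejected", {
  expect_error(limb_params(length = -1), "positive")
  expect_error(limb_params(proximal_semi_axes = c(20, 20),
                           distal_semi_axes = c(30, 25)), "taper")
  expect_error(limb_params(noise_amplitude = 5), "noise")
  expect_error(limb_params(bump_center = 2), "fraction")
  expect_error(limb_params(axial_samples = 2), "coarse")
})
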
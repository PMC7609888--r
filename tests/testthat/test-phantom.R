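test_that("sphere_volume is the exact closed form", {
  expect_equal(sphere_volume(10), (pi / 6) * 1000)
  expect_equal(round(sphere_volume(10) / 1000, 2), 0.52)
  expect_equal(round(sphere_volume(17) / 1000, 2), 2.57)
  expect_equal(sphere_volume(0.002), (pi / 6) * 8e-9)
  expect_error(sphere_volume(0), "positive")
  expect_error(sphere_volume(-3), "positive")
})

test_that("scene construction validates geometry and contrast", {
  expect_error(sphere_scene(sphere_spec(10, uptake_suv = 5),
                            background_suv = 5, fov_mm = 40),
               "exceed background")
  expect_error(sphere_scene(sphere_spec(30), background_suv = 0, fov_mm = 20),
               "outside the field of view")
  expect_error(
    sphere_scene(list(sphere_spec(10, center_mm = c(-4, 0, 0)),
                      sphere_spec(10, center_mm = c(4, 0, 0))),
                 background_suv = 0, fov_mm = 60),
    "overlap")
})

test_that("voxelization conserves mass and is translation invariant", {
  v_true <- sphere_volume(10)
  sc <- sphere_scene(sphere_spec(10), background_suv = 0, fov_mm = 16)
  img <- voxelize(sc, 0.5)
  mass <- sum(img$values) * voxel_volume(img)
  expect_lt(abs(mass / (10 * v_true) - 1), 1e-3)

  sc_sh <- sphere_scene(sphere_spec(10, center_mm = c(0.25, 0.25, 0.25)),
                        background_suv = 0, fov_mm = 16)
  mass_sh <- sum(voxelize(sc_sh, 0.5)$values) * 0.5^3
  expect_lt(abs(mass_sh / (10 * v_true) - 1), 1e-3)

  # refinement: halving the spacing moves the mass by less than the
  # coarser grid's error bound
  mass_fine <- sum(voxelize(sc, 0.25)$values) * 0.25^3
  expect_lt(abs(mass_fine - mass), 1e-3 * 10 * v_true)
})

test_that("mass conservation holds across diameter/spacing ratios >= 1", {
  for (d in c(2, 5, 21)) {
    sc <- sphere_scene(sphere_spec(d), background_suv = 0, fov_mm = d + 6)
    img <- voxelize(sc, min(1, d))  # spacing <= diameter
    mass <- sum(img$values) * voxel_volume(img)
    expect_lt(abs(mass / (10 * sphere_volume(d)) - 1), 1e-3)
  }
})

test_that("a background-only scene voxelizes to a uniform field", {
  sc <- sphere_scene(list(), background_suv = 0.5, fov_mm = 10)
  img <- voxelize(sc, 1)
  expect_true(all(img$values == 0.5))
})

test_that("a centered sphere is exactly symmetric under reflections and permutations", {
  sc <- sphere_scene(sphere_spec(7), background_suv = 0.2, fov_mm = 12)
  v <- voxelize(sc, 1)$values
  for (a in 1:3) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[a]] <- dim(v)[a]:1
    expect_identical(v, do.call(`[`, c(list(v), idx)))
  }
  expect_identical(v, aperm(v, c(2, 1, 3)))
  expect_identical(v, aperm(v, c(3, 2, 1)))
})

test_that("the multi-sphere IQ scene has the standard diameters and contrast", {
  sc <- nema_iq_scene(contrast_ratio = 8, background_suv = 1)
  expect_length(sc$spheres, 4)
  expect_equal(sort(vapply(sc$spheres, `[[`, 0, "diameter_mm"),
                    decreasing = TRUE), c(37, 22, 17, 10))
  expect_true(all(vapply(sc$spheres, `[[`, 0, "uptake_suv") == 8))

  sc2 <- nema_iq_scene(contrast_ratio = 2, background_suv = 1)
  expect_equal(vapply(sc2$spheres, `[[`, 0, "uptake_suv") /
                 sc2$background_suv, rep(2, 4))

  expect_error(nema_iq_scene(contrast_ratio = 8, background_suv = 0),
               "exceed background")
  expect_error(nema_iq_scene(contrast_ratio = 1, background_suv = 1), ">")

  # blurred images must not overlap at the worst resolution (FWHM 9):
  # surface gaps of at least 8 sigma = 30.6 mm
  ctr <- t(vapply(sc$spheres, `[[`, numeric(3), "center_mm"))
  dmm <- vapply(sc$spheres, `[[`, 0, "diameter_mm")
  for (i in 1:3) for (j in (i + 1):4) {
    gap <- sqrt(sum((ctr[i, ] - ctr[j, ])^2)) - (dmm[i] + dmm[j]) / 2
    expect_gt(gap, 8 * 9 / (2 * sqrt(2 * log(2))))
  }
})
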
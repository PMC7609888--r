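test_that("relative/absolute threshold conversions are exact inverses", {
  expect_equal(absolute_from_relative(31, 10, 0), 3.1)
  expect_equal(absolute_from_relative(100, 7.3, 1.2), 7.3)
  expect_equal(absolute_from_relative(50, 8, 2), 5.0)
  expect_equal(relative_from_absolute(3.1, 10, 0), 31)
  expect_equal(relative_from_absolute(2, 10, 2), 0)

  set.seed(11)
  for (i in 1:200) {
    bg <- stats::runif(1, 0, 5)
    mx <- bg + stats::runif(1, 0.1, 10)
    p <- stats::runif(1, 0, 100)
    expect_equal(
      relative_from_absolute(absolute_from_relative(p, mx, bg), mx, bg),
      p, tolerance = 1e-9)
  }

  expect_error(absolute_from_relative(50, 2, 3), "exceed")
  expect_error(relative_from_absolute(11, 10, 0), "between")
})

test_that("MTV counting uses >= and whole voxels", {
  img <- image_volume(array(2, dim = c(4, 4, 4)), 1.5)
  fov_vol <- 64 * 1.5^3
  expect_equal(measure_mtv(img, 2), fov_vol)       # tie: >= keeps all
  expect_equal(measure_mtv(img, 2.0001), 0)        # above max: empty
  expect_equal(measure_mtv(img, -1), fov_vol)      # below min: full fov
})

test_that("the sweep produces 80 records with non-increasing MTV", {
  res <- solve_sphere(8, 4, 1, keep_image = TRUE)
  sw <- threshold_sweep(res$image, sphere_volume(8), 0)
  expect_equal(nrow(sw), 80)
  expect_equal(sw$percent, as.numeric(11:90))
  expect_true(all(diff(sw$mtv_mm3) <= 0))
  expect_true(any(sw$percent_error > 0) && any(sw$percent_error < 0))
  expect_error(threshold_sweep(res$image, 1, 0, percents = c(20, 20, 30)),
               "strictly increasing")
})

test_that("an unblurred sphere matches its volume at essentially any threshold", {
  sc <- sphere_scene(sphere_spec(10), background_suv = 0, fov_mm = 16)
  img <- voxelize(sc, 0.5)
  res <- volume_matching_threshold(img, sphere_volume(10), 0)
  expect_lt(abs(res$matched_volume_mm3 / sphere_volume(10) - 1), 0.01)
})

test_that("the solver reports thresholds outside the sweep range", {
  uni <- image_volume(array(c(1, rep(0.5, 999)), dim = c(10, 10, 10)), 1)
  expect_error(volume_matching_threshold(uni, 1e-3, 0), "outside sweep range")
})

test_that("the solved threshold is independent of the background", {
  t0 <- solve_sphere(8, 4, 1, bg_fraction = 0)$threshold
  t5 <- solve_sphere(8, 4, 1, bg_fraction = 0.5)$threshold
  expect_lt(abs(t0 - t5), 0.05)
})

test_that("round-trip consistency of the solved threshold", {
  res <- solve_sphere(12, 4, 1, keep_image = TRUE)
  sol <- volume_matching_threshold(res$image, sphere_volume(12), 0)
  expect_equal(
    relative_from_absolute(sol$absolute_suv, sol$suvmax, sol$suvbg),
    sol$relative_percent, tolerance = 1e-9)
})

test_that("delineation at 100% keeps only maximal voxels", {
  res <- solve_sphere(8, 4, 1, keep_image = TRUE)
  img <- res$image
  del <- delineate(img, 100, 0, c(0, 0, 0), 10)
  picked <- img$values[del$mask$values == 1]
  expect_true(all(picked == suv_max(img)))
  expect_gte(del$volume_mm3, voxel_volume(img))
})

test_that("delineation is restricted to the lesion's connected component", {
  sc <- sphere_scene(list(sphere_spec(8, center_mm = c(-12, 0, 0)),
                          sphere_spec(8, center_mm = c(12, 0, 0))),
                     background_suv = 0, fov_mm = c(54, 28, 28))
  img <- simulate_pet(sc, system_model(4, 1))
  del <- delineate(img, 40, 0, roi_center_mm = c(-12, 0, 0),
                   roi_radius_mm = 8)
  # lesion B's center voxel must not be in the mask
  ctr_b <- vapply(1:3, function(a) {
    coords <- img$origin_mm[a] + (seq_len(dim(img$values)[a]) - 0.5) *
      img$spacing_mm[a]
    which.min(abs(coords - c(12, 0, 0)[a]))
  }, integer(1))
  expect_equal(del$mask$values[ctr_b[1], ctr_b[2], ctr_b[3]], 0)
  # and the delineated volume is in the ballpark of one sphere, not two
  expect_lt(del$volume_mm3, 1.6 * sphere_volume(8))

  expect_error(delineate(img, 40, 0, c(500, 0, 0), 5), "outside")
})
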
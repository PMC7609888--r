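# Memoized simulation helpers shared across test files. All simulations
# are deterministic, so caching by parameter key is safe and keeps the
# suite runtime down when several tests probe the same geometry.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Simulate a centered sphere (uptake 10) and solve the volume-matching
# threshold. Returns list(threshold, suvmax, image).
solve_sphere <- function(d_mm, fwhm_mm, ps_mm, bg_fraction = 0,
                         keep_image = FALSE) {
  key <- paste("sph", d_mm, fwhm_mm, signif(ps_mm, 10), bg_fraction,
               keep_image, sep = "|")
  cached(key, {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
    bg <- bg_fraction * 10
    scene <- sphere_scene(sphere_spec(d_mm, 10),
                          background_suv = bg,
                          fov_mm = d_mm + 8 * sigma + 4 * ps_mm)
    sys <- suppressWarnings(system_model(fwhm_mm, ps_mm))
    img <- simulate_pet(scene, sys)
    res <- suppressWarnings(
      volume_matching_threshold(img, sphere_volume(d_mm), bg))
    list(threshold = res$relative_percent, suvmax = res$suvmax,
         image = if (keep_image) img else NULL)
  })
}

# Simulated synthetic NEMA-IQ phantom image (8:1 contrast, FWHM 8 mm,
# 3.65 x 3.65 x 3.27 mm pixels), plus its scene.
nema_fixture <- function() {
  cached("nema", {
    scene <- nema_iq_scene(contrast_ratio = 8, background_suv = 1)
    sys <- system_model(8, c(3.65, 3.65, 3.27))
    list(scene = scene, image = simulate_pet(scene, sys))
  })
}

# Threshold table over PS fractions for one geometry (default placement).
ps_sweep_thresholds <- function(d_mm, fwhm_mm, fractions) {
  vapply(fractions, function(fr)
    solve_sphere(d_mm, fwhm_mm, fr * fwhm_mm)$threshold, numeric(1))
}

# Synthetic threshold records generated from the closed-form formula on
# a (D/FWHM, PS/FWHM) grid, optionally with seeded Gaussian noise.
formula_records <- function(x = c(seq(0.3, 1.9, by = 0.1),
                                  seq(2, 12, by = 0.5)),
                            p = 1 / c(20, 18, 16, 14, 12, 10,
                                      9, 8, 7, 6, 5, 4, 3, 2),
                            fwhm_mm = 4, noise_sd = 0, seed = 42L,
                            constants = formula_constants()) {
  g <- expand.grid(x = x, p = p)
  y <- suppressWarnings(vapply(seq_len(nrow(g)), function(i)
    formula_threshold(g$x[i] * fwhm_mm, fwhm_mm, g$p[i] * fwhm_mm,
                      constants), numeric(1)))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  data.frame(d_mm = g$x * fwhm_mm, fwhm_mm = fwhm_mm,
             ps_mm = g$p * fwhm_mm, threshold_percent = y)
}
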
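test_that("the generator is reproducible from its seed", {
  a <- generate_growth_series(growth_series_config(seed = 42, n = 13))
  b <- generate_growth_series(growth_series_config(seed = 42, n = 13))
  expect_identical(a, b)
  c <- generate_growth_series(growth_series_config(seed = 43, n = 13))
  expect_false(identical(a$series$dsl_mm, c$series$dsl_mm))
  # the caller's RNG stream is untouched
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(generate_growth_series(
    growth_series_config(seed = 1))); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("config invariants are enforced", {
  expect_error(growth_series_config(), "seed is mandatory")
  expect_error(growth_series_config(seed = 1, n = 2), "n must be >= 3")
  expect_error(growth_series_config(seed = 1, dsl_min = 10, dsl_max = 5),
               "dsl_min < dsl_max")
  expect_error(growth_series_config(seed = 1, noise_sd_log10 = -0.1),
               "noise")
  expect_error(growth_series_config(seed = 1, beta_me = -3), "exponent")
})

test_that("noiseless construction is exactly collinear in log space", {
  gen <- generate_growth_series(isometric_growth_config(
    seed = 2, n = 13, noise_sd_log10 = 0))
  f <- fit_sma(log10(gen$series$gms_mm),
               log10(gen$series$middle_ear_volume_mm3))
  expect_equal(f$slope, 3, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("the default exponent preset is recovered at n = 200", {
  gen <- generate_growth_series(growth_series_config(seed = 42, n = 200))
  rep <- run_allometry(gen$series)
  gms <- rep[rep$regression == "ME_v on GMS", ]
  expect_true(gms$ci_low <= 1.9735 && 1.9735 <= gms$ci_high)
})

test_that("the series spans at most the printed 19-fold size range", {
  gen <- generate_growth_series(growth_series_config(seed = 4, n = 13))
  ratio <- max(gen$series$dsl_mm) / min(gen$series$dsl_mm)
  expect_lte(ratio, 551.6 / 29.26)
  expect_equal(nrow(gen$series), 13)
  expect_true(all(gen$series$dsl_mm >= 29.26 & gen$series$dsl_mm <= 551.6))
  # two resonator rows per specimen: tympanum + subtympanic
  expect_equal(nrow(gen$resonators), 26)
  expect_setequal(unique(gen$resonators$aperture),
                  c("tympanum", "subtympanic"))
})

test_that("phantom rasterization matches analytic ground truth", {
  spec <- phantom_spec(list(sphere(c(0, 0, 0), 3.2, 1L)), spacing = 0.1)
  lv <- generate_phantom(spec)
  truth <- analytic_metrics(spec)
  m <- measure_compartment(lv, 1, "voxel_faces")
  expect_lt(abs(m$volume_mm3 / truth$volume_mm3 - 1), 0.01)
  expect_equal(truth$volume_mm3, 4 / 3 * pi * 3.2^3)
  expect_equal(truth$surface_area_mm2, 4 * pi * 3.2^2)
})

test_that("rasterization error shrinks as spacing halves", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(sp) {
    spec <- phantom_spec(list(sphere(c(0, 0, 0), 3.2, 1L)), spacing = sp)
    v <- measure_compartment(generate_phantom(spec), 1,
                             "voxel_faces")$volume_mm3
    abs(v / (4 / 3 * pi * 3.2^3) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("phantom edge cases behave", {
  empty <- generate_phantom(phantom_spec(list(), spacing = 0.5))
  expect_length(labels_present(empty), 0)

  # conjoined equal spheres under one label form one connected component
  lv <- two_sphere_phantom()
  mesh <- extract_isosurface(lv, 1)
  expect_equal(mesh_components(mesh), 1L)

  # different labels may not overlap
  expect_error(generate_phantom(phantom_spec(
    list(sphere(c(0, 0, 0), 1, 1L), sphere(c(0.5, 0, 0), 1, 2L)),
    spacing = 0.1)), "ambiguity")
})

test_that("analytic union metrics match the frozen lens/cap oracle", {
  expect_equal(sphere_lens_volume(20, 20, 36), oracle$lens_v,
               tolerance = 1e-12)
  two <- phantom_spec(list(sphere(c(0, 0, 0), 20, 1L),
                           sphere(c(36, 0, 0), 20, 1L)), spacing = 1)
  m <- analytic_metrics(two)
  expect_equal(m$volume_mm3, oracle$two_sphere_union_v, tolerance = 1e-12)
  expect_equal(m$surface_area_mm2, oracle$two_sphere_union_a,
               tolerance = 1e-12)

  # tangent spheres: no lens
  tangent <- phantom_spec(list(sphere(c(0, 0, 0), 1, 1L),
                               sphere(c(2, 0, 0), 1, 1L)), spacing = 1)
  expect_equal(analytic_metrics(tangent)$volume_mm3, 2 * 4 / 3 * pi)

  # three collinear conjoined spheres
  three <- phantom_spec(list(sphere(c(0, 0, 0), 20, 1L),
                             sphere(c(36, 0, 0), 20, 1L),
                             sphere(c(72, 0, 0), 20, 1L)), spacing = 1)
  expect_equal(analytic_metrics(three)$volume_mm3,
               oracle$three_sphere_union_v, tolerance = 1e-12)

  # unsupported configurations refuse
  triple <- phantom_spec(list(sphere(c(0, 0, 0), 2, 1L),
                              sphere(c(2, 0, 0), 2, 1L),
                              sphere(c(1, 1.5, 0), 2, 1L)), spacing = 1)
  expect_error(analytic_metrics(triple), "unsupported-configuration")
  mixed <- phantom_spec(list(sphere(c(0, 0, 0), 2, 1L),
                             ellipsoid(c(1, 0, 0), c(2, 1, 1), 1L)),
                        spacing = 1)
  expect_error(analytic_metrics(mixed), "unsupported-configuration")
})

test_that("isolated ellipsoids get exact volume and flagged approximate area", {
  spec <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(3, 2, 1), 1L)),
                       spacing = 0.1)
  m <- analytic_metrics(spec)
  expect_equal(m$volume_mm3, 4 / 3 * pi * 6)
  expect_equal(m$method, "approx")
  v <- measure_compartment(generate_phantom(spec), 1,
                           "voxel_faces")$volume_mm3
  expect_lt(abs(v / m$volume_mm3 - 1), 0.01)
})
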
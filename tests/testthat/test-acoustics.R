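test_that("equivalent radius inverts the circle area", {
  expect_equal(equivalent_radius(pi * 1e-6), 1e-3)
  expect_equal(equivalent_radius(4 * pi * 1e-6), 2e-3)
  expect_error(equivalent_radius(0), "domain")
  # area from a polygonal aperture recovers its construction radius
  a_mm2 <- polygon_area(aperture_spec(polygon_loop(256, 2), "unflanged"))
  expect_lt(abs(equivalent_radius(a_mm2 * 1e-6) / 2e-3 - 1), 5e-4)
})

test_that("effective length applies the end corrections", {
  cfg <- acoustics_config()
  r <- 1e-3  # 1 mm equivalent radius -> A = pi mm2
  unflanged <- resonator_geometry(pi, 1000, "unflanged", neck_length_mm = 2)
  expect_equal(effective_length(unflanged, cfg), 2e-3 + 1.4 * r)
  flanged <- resonator_geometry(pi, 1000, "flanged")
  expect_equal(effective_length(flanged, cfg), 1.7 * r)
  # zero-neck unflanged is shorter than flanged at the same radius
  zero_neck <- resonator_geometry(pi, 1000, "unflanged")
  expect_lt(effective_length(zero_neck, cfg), effective_length(flanged, cfg))
})

test_that("the Helmholtz frequency matches its closed form", {
  g <- resonator_geometry(10, 1000, "unflanged", neck_length_mm = 2)
  res <- helmholtz_frequency(g)
  expect_equal(res$frequency, oracle$helmholtz_f, tolerance = 1e-12)
  expect_equal(res$equivalent_radius, sqrt(1e-5 / pi), tolerance = 1e-14)

  # doubling V alone divides f by sqrt(2)
  g2 <- resonator_geometry(10, 2000, "unflanged", neck_length_mm = 2)
  expect_equal(helmholtz_frequency(g2)$frequency,
               res$frequency / sqrt(2), tolerance = 1e-12)
})

test_that("isometric scaling of the resonator scales f as 1/k", {
  f1 <- helmholtz_frequency(
    resonator_geometry(10, 1000, "unflanged", neck_length_mm = 2))$frequency
  k <- 2
  fk <- helmholtz_frequency(
    resonator_geometry(10 * k^2, 1000 * k^3, "unflanged",
                       neck_length_mm = 2 * k))$frequency
  expect_equal(fk, f1 / k, tolerance = 1e-12)
})

test_that("f is monotone in aperture area, cavity volume and neck length", {
  f_of <- function(A, V, l) helmholtz_frequency(
    resonator_geometry(A, V, "unflanged", neck_length_mm = l))$frequency
  A <- c(1, 2, 5, 10, 20); V <- c(200, 500, 1000, 5000); l <- c(0, 1, 2, 5)
  expect_true(all(diff(vapply(A, f_of, numeric(1), V = 1000, l = 2)) > 0))
  expect_true(all(diff(vapply(V, function(v) f_of(10, v, 2), numeric(1))) < 0))
  expect_true(all(diff(vapply(l, function(x) f_of(10, 1000, x),
                              numeric(1))) < 0))
})

test_that("flanged beats unflanged downward in frequency at zero neck", {
  ff <- helmholtz_frequency(resonator_geometry(10, 1000, "flanged"))$frequency
  fu <- helmholtz_frequency(
    resonator_geometry(10, 1000, "unflanged"))$frequency
  expect_lt(ff, fu)  # 1.7 r > 1.4 r lengthens the neck
})

test_that("mm-input path agrees with direct SI computation to 1e-12", {
  A_mm2 <- 7.3; V_mm3 <- 812.5; l_mm <- 1.25; c <- 343
  via_pkg <- helmholtz_frequency(
    resonator_geometry(A_mm2, V_mm3, "unflanged", l_mm))$frequency
  A <- A_mm2 * 1e-6; V <- V_mm3 * 1e-9; l <- l_mm * 1e-3
  L <- l + 1.4 * sqrt(A / pi)
  direct <- c / (2 * pi) * sqrt(A / (L * V))
  expect_equal(via_pkg, direct, tolerance = 1e-12)
})

test_that("resonance series summarises bands and validates inputs", {
  one <- data.frame(specimen_id = "A", aperture = "tympanum",
                    kind = "flanged", aperture_area_mm2 = 10,
                    neck_length_mm = 0, cavity_volume_mm3 = 500)
  out <- resonance_series(one)
  expect_equal(out$band[1], out$band[2])
  expect_equal(out$band_ratio, 1)
  expect_equal(names(out$results),
               c("specimen_id", "aperture", "r_mm", "L_mm", "f_hz"))

  bad <- one; bad$aperture_area_mm2 <- -1
  expect_error(resonance_series(bad), "specimen A")
  expect_error(resonance_series(one[0, ]), "insufficient-data")
})

test_that("frequency-locked series return narrow bands", {
  gen0 <- generate_growth_series(growth_series_config(
    seed = 12, n = 13, noise_sd_log10 = 0, compensation = "frequency_locked"))
  for (ap in c("tympanum", "subtympanic")) {
    out <- resonance_series(gen0$resonators[gen0$resonators$aperture == ap, ])
    expect_lte(out$band_ratio, 1.05)
  }
  genN <- generate_growth_series(growth_series_config(
    seed = 12, n = 13, compensation = "frequency_locked"))
  for (ap in c("tympanum", "subtympanic")) {
    out <- resonance_series(genN$resonators[genN$resonators$aperture == ap, ])
    expect_lte(out$band_ratio, 1.31)  # as tight as the observed 1200/920 band
  }
})

test_that("an isometric series spans a band as wide as its size range", {
  gen <- generate_growth_series(isometric_growth_config(
    seed = 13, n = 13, noise_sd_log10 = 0))
  out <- resonance_series(gen$resonators[gen$resonators$aperture ==
                                           "tympanum", ])
  size_ratio <- max(gen$series$gms_mm) / min(gen$series$gms_mm)
  expect_equal(out$band_ratio, size_ratio, tolerance = 1e-9)
  # log f vs log size has SMA slope -1 (ties acoustics to allometry)
  merged <- merge(out$results, gen$series, by = "specimen_id")
  f <- fit_sma(log10(merged$gms_mm), log10(merged$f_hz))
  expect_equal(f$slope, -1, tolerance = 1e-9)
})

test_that("band overlap reports peaks, regions and degenerate curves", {
  curve <- data.frame(f_hz = seq(200, 3000, by = 200))
  curve$sensitivity <- exp(-((curve$f_hz - 1000) / 500)^2)
  hit <- band_overlap(c(920, 1200), curve)
  expect_true(hit$peak_in_band)
  expect_equal(hit$peak_hz, 1000)
  miss <- band_overlap(c(2200, 4000), curve)
  expect_false(miss$peak_in_band)

  flat <- data.frame(f_hz = c(100, 200, 300), sensitivity = c(1, 1, 1))
  rep <- band_overlap(c(100, 300), flat)
  expect_true(rep$flat_curve)
  expect_true(is.na(rep$peak_in_band))

  unsorted <- data.frame(f_hz = c(200, 100), sensitivity = c(1, 2))
  expect_error(band_overlap(c(100, 300), unsorted), "strictly increasing")
})
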
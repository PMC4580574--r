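test_that("compartment metrics handle trivial and closed-form cases", {
  # absent label -> zeroed metrics
  lv <- cube_phantom(4)
  m <- measure_compartment(lv, 9)
  expect_equal(m$volume_mm3, 0)
  expect_equal(m$surface_area_mm2, 0)
  expect_equal(m$voxel_count, 0L)

  # single voxel at isotropic 0.045 mm spacing
  vox <- array(0L, c(5, 5, 5)); vox[3, 3, 3] <- 1L
  one <- label_volume(vox, 0.045)
  m1 <- measure_compartment(one, 1, "voxel_faces")
  expect_equal(m1$volume_mm3, 0.045^3)
  expect_equal(m1$surface_area_mm2, 6 * 0.045^2)

  # 10 mm cube: exact voxel-face area 600 mm2, volume 1000 mm3
  mc <- measure_compartment(cube_phantom(10), 1, "voxel_faces")
  expect_equal(mc$volume_mm3, 1000)
  expect_equal(mc$surface_area_mm2, 600)
})

test_that("rasterized sphere volume and isosurface area match the analytic ball", {
  r_mm <- 3.2
  lv <- sphere_phantom(32, 0.1)
  m <- measure_compartment(lv, 1, "isosurface")
  expect_lt(abs(m$volume_mm3 / (4 / 3 * pi * r_mm^3) - 1), 0.01)
  expect_lt(abs(m$surface_area_mm2 / (4 * pi * r_mm^2) - 1), 0.03)
})

test_that("volume is invariant under axis permutation with permuted spacing", {
  lv <- generate_phantom(phantom_spec(
    list(ellipsoid(c(0, 0, 0), c(1.2, 0.8, 0.5), 1L)),
    spacing = c(0.1, 0.12, 0.08)))
  m0 <- measure_compartment(lv, 1, "voxel_faces")
  perm <- c(3, 1, 2)
  lvp <- label_volume(aperm(lv$voxels, perm), lv$spacing[perm])
  mp <- measure_compartment(lvp, 1, "voxel_faces")
  expect_equal(mp$volume_mm3, m0$volume_mm3)
  expect_equal(mp$voxel_count, m0$voxel_count)
})

test_that("isosurface extraction yields closed genus-0 meshes for balls", {
  mesh <- extract_isosurface(sphere_phantom(16, 0.1), 1)
  expect_true(mesh$closed)
  expect_equal(mesh_components(mesh), 1L)
  expect_equal(mesh_euler(mesh)$genus, 0)
  expect_error(extract_isosurface(sphere_phantom(16, 0.1), 5),
               "empty-selection")
})

test_that("cube isosurface encloses the analytic volume within 2%", {
  # axis-aligned solids are exact at the raw binary level set; smoothing is
  # for curved anatomy and would round the corners
  mesh <- extract_isosurface(cube_phantom(10), 1, smoothing_sigma = 0)
  expect_true(mesh$closed)
  expect_lt(abs(mesh_volume(mesh) / 1000 - 1), 0.02)
})

test_that("two disjoint balls under one label give a two-component mesh", {
  lv <- generate_phantom(phantom_spec(
    list(sphere(c(0, 0, 0), 0.8, 1L), sphere(c(4, 0, 0), 0.8, 1L)),
    spacing = 0.1))
  mesh <- extract_isosurface(lv, 1)
  expect_equal(mesh_components(mesh), 2L)
  expect_true(mesh$closed)
})

test_that("mesh volume/area are exact on a hand-built unit cube and origin-invariant", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  # 12 triangles, outward orientation
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),    # z = 0
    c(5, 6, 7), c(6, 8, 7),    # z = 1
    c(1, 2, 5), c(2, 6, 5),    # y = 0
    c(3, 7, 4), c(4, 7, 8),    # y = 1
    c(1, 5, 3), c(3, 5, 7),    # x = 0
    c(2, 4, 6), c(4, 8, 6))    # x = 1
  mesh <- tri_mesh(v, f)
  expect_true(mesh$closed)
  expect_equal(mesh_volume(mesh), 1)
  expect_equal(mesh_area(mesh), 6)
  shifted <- tri_mesh(sweep(v, 2, c(100, 100, 100), `+`), f)
  expect_equal(mesh_volume(shifted), 1)
  # open surface refuses a volume
  open_mesh <- tri_mesh(v, f[-1, , drop = FALSE])
  expect_false(open_mesh$closed)
  expect_error(mesh_volume(open_mesh), "closed")
})

test_that("isosurface area error decreases monotonically with resolution", {
  errs <- vapply(c(8, 16, 32), function(r) {
    m <- measure_compartment(sphere_phantom(r, 0.1), 1, "isosurface")
    abs(m$surface_area_mm2 / (4 * pi * (r * 0.1)^2) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("voxel-face area dominates isosurface area for convex solids", {
  for (r in c(8, 16)) {
    lv <- sphere_phantom(r, 0.1)
    a_faces <- measure_compartment(lv, 1, "voxel_faces")$surface_area_mm2
    a_iso <- measure_compartment(lv, 1, "isosurface")$surface_area_mm2
    expect_gt(a_faces, a_iso)
  }
})

test_that("mesh export writes readable STL and OBJ", {
  mesh <- extract_isosurface(sphere_phantom(8, 0.2), 1)
  stl <- withr::local_tempfile(fileext = ".stl")
  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh(mesh, stl)
  write_mesh(mesh, obj)
  expect_match(readLines(stl, n = 1), "^solid")
  objl <- readLines(obj)
  expect_equal(sum(grepl("^v ", objl)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", objl)), nrow(mesh$faces))
})

test_that("aperture areas follow the closed forms", {
  sq <- aperture_spec(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      "flanged")
  expect_equal(polygon_area(sq), 1)
  tri <- aperture_spec(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), "unflanged")
  expect_equal(polygon_area(tri), 6)
  poly <- aperture_spec(polygon_loop(256, 2), "unflanged", neck_length = 1)
  expect_lt(abs(polygon_area(poly) / (4 * pi) - 1), 0.001)
})

test_that("degenerate aperture loops are rejected", {
  line <- cbind(0:3, 0, 0)
  expect_error(aperture_spec(line, "flanged"), "degenerate-aperture")
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0.5), c(0, 1, 0))
  expect_error(aperture_spec(bent, "flanged"), "planarity")
  expect_error(aperture_spec(polygon_loop(8, 1), "flanged", neck_length = 2),
               "neck length zero")
})
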
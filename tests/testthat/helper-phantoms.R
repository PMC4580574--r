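# Shared phantom fixtures, built once per test run and cached.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .phantom_cache))
    assign(key, build(), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

# rasterized sphere of given radius in voxels at given isotropic spacing (mm)
sphere_phantom <- function(radius_vox, spacing = 0.1) {
  key <- sprintf("sphere_%g_%g", radius_vox, spacing)
  cached(key, function() {
    generate_phantom(phantom_spec(
      list(sphere(c(0, 0, 0), radius_vox * spacing, 1L, "ball")),
      spacing = spacing))
  })
}

# two equal spheres, R = 20 voxels, centres 36 voxels apart (conjoined)
two_sphere_phantom <- function(spacing = 0.1) {
  cached(sprintf("twosphere_%g", spacing), function() {
    R <- 20 * spacing
    d <- 36 * spacing
    generate_phantom(phantom_spec(
      list(sphere(c(0, 0, 0), R, 1L, "pair"),
           sphere(c(d, 0, 0), R, 1L)),
      spacing = spacing))
  })
}

# solid cube, n voxels on a side, 1 mm spacing
cube_phantom <- function(n = 10L) {
  cached(sprintf("cube_%d", n), function() {
    vox <- array(0L, dim = rep(n + 4L, 3))
    vox[3:(n + 2), 3:(n + 2), 3:(n + 2)] <- 1L
    label_volume(vox, spacing = c(1, 1, 1), legend = c("1" = "cube"))
  })
}

# regular polygon aperture loop in the z = 0 plane
polygon_loop <- function(n, radius) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(th), radius * sin(th), 0)
}

# frozen oracle constants (arbitrary-precision evaluation of the closed forms)
oracle <- list(
  helmholtz_f = 2574.040929800725,       # c=343, unflanged, A=10mm2, l=2mm, V=1000mm3
  lens_v = 485.8996637552214,            # R1=R2=20, d=36 (mm^3)
  two_sphere_union_v = 66534.74361282703,
  lobe_v = 33267.37180641352,            # sphere minus half-lens
  two_sphere_union_a = 9550.441666912971,
  three_sphere_union_v = 99559.16558736294,
  neck_radius = 8.717797887081348,       # sqrt(20^2 - 18^2)
  log10_dsl_min = 1.466274321789292      # log10(29.26)
)
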
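# Fixed per-measurement proportionality constants (fraction of dorsal skull
# length) for the 27 linear measurements. Arbitrary positive constants,
# fixed so that orbit/fenestra items stay well below DSL; item 11 IS the
# dorsal skull length.
measurement_fractions <- function() {
  f <- c(0.16, 0.10, 0.22, 0.08, 0.12, 0.45, 0.09, 0.38, 0.12, 0.55,
         1.00, 0.11, 0.05, 0.10, 0.14, 0.06, 0.10, 0.07, 0.25, 0.40,
         0.20, 0.05, 0.15, 0.12, 0.14, 0.18, 0.09)
  stats::setNames(f, skull_measurement_names())
}

# Amplitude constants anchoring the synthetic variables to realistic
# magnitudes (log10 intercepts of the generated relations at the default
# exponents).
generator_amplitudes <- function() {
  list(a_me = 10^(-0.13679),
       a_tsa = 10^((-0.13679 - 0.74106) / 1.4448),
       a_bc = 10^((-0.13679 + 0.52452) / 0.8273),
       sub_area_per_dsl2 = 30 / 551.6^2,   # subtympanic aperture, mm^2 per mm^2
       sub_neck_per_dsl = 8 / 551.6)       # subtympanic neck, mm per mm

}

#' Growth-series generator configuration
#'
#' Defines the study conditions emulated by the synthetic ontogenetic series:
#' 13 specimens spanning 29.26-551.6 mm dorsal skull length by default, with
#' configurable allometric exponents (as powers of the geometric-mean skull
#' size GMS) and lognormal (additive in log10) noise. The default exponents
#' reproduce the observed allometries (middle-ear volume exponent 1.9735 on
#' GMS; tympanum-area and braincase-volume exponents chosen so the implied
#' regressions of middle-ear volume on them have slopes 1.4448 and 0.8273).
#'
#' @param seed RNG seed (mandatory; the generator is fully reproducible).
#' @param n specimen count (default 13).
#' @param dsl_min,dsl_max dorsal-skull-length range, mm (defaults 29.26 and
#'   551.6; DSL is drawn log-uniformly over the range).
#' @param beta_me exponent of middle-ear volume on GMS (default 1.9735).
#' @param beta_tsa exponent of tympanum area on GMS (default
#'   `beta_me / 1.4448`, so ME_v on T_sa has slope 1.4448).
#' @param beta_bc exponent of braincase volume on GMS (default
#'   `beta_me / 0.8273`, so ME_v on BC_v has slope 0.8273).
#' @param noise_sd_log10 log10-scale noise SD applied independently to every
#'   generated variable (default 0.02; 0 gives exactly collinear logs).
#' @param compensation `"isometric"`: resonator geometry follows the series'
#'   own scaling (cavity volume = middle-ear volume); `"frequency_locked"`:
#'   the cavity volume is solved per aperture so the Helmholtz frequency sits
#'   at `target_f` regardless of size.
#' @param target_f named numeric, target frequencies (Hz) per aperture in
#'   frequency-locked mode (defaults: tympanum 2966, subtympanic 1051, the
#'   geometric mid-points of the observed bands).
#' @param c_sound speed of sound used when solving for frequency-locked
#'   cavity volumes, m/s.
#' @return A `growth_series_config`.
#' @export
growth_series_config <- function(seed, n = 13, dsl_min = 29.26,
                                 dsl_max = 551.6, beta_me = 1.9735,
                                 beta_tsa = beta_me / 1.4448,
                                 beta_bc = beta_me / 0.8273,
                                 noise_sd_log10 = 0.02,
                                 compensation = c("isometric",
                                                  "frequency_locked"),
                                 target_f = c(tympanum = 2966,
                                              subtympanic = 1051),
                                 c_sound = 343) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config error: seed is mandatory")
  compensation <- match.arg(compensation)
  if (n < 3) stop("config error: n must be >= 3")
  if (!(dsl_min > 0 && dsl_min < dsl_max))
    stop("config error: need 0 < dsl_min < dsl_max")
  if (noise_sd_log10 < 0) stop("config error: noise_sd_log10 must be >= 0")
  if (any(!is.finite(c(beta_me, beta_tsa, beta_bc))) ||
      any(c(beta_me, beta_tsa, beta_bc) <= 0))
    stop("config error: inconsistent exponent set (all betas must be > 0)")
  if (compensation == "frequency_locked" &&
      (!all(c("tympanum", "subtympanic") %in% names(target_f)) ||
       any(target_f <= 0)))
    stop("config error: target_f needs positive tympanum and subtympanic entries")
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 dsl_min = dsl_min, dsl_max = dsl_max, beta_me = beta_me,
                 beta_tsa = beta_tsa, beta_bc = beta_bc,
                 noise_sd_log10 = noise_sd_log10,
                 compensation = compensation, target_f = target_f,
                 c_sound = c_sound),
            class = "growth_series_config")
}

#' Isometric growth-series configuration
#'
#' Convenience preset in which every variable scales geometrically: middle-ear
#' volume as GMS^3, tympanum area as GMS^2, braincase volume as GMS^3, so the
#' three standard regressions have true slopes exactly at their isometry
#' nulls (3, 1.5, 1).
#'
#' @inheritParams growth_series_config
#' @param ... further arguments passed to [growth_series_config()].
#' @export
isometric_growth_config <- function(seed, ...) {
  growth_series_config(seed = seed, beta_me = 3, beta_tsa = 2, beta_bc = 3,
                       ...)
}

#' Generate a synthetic ontogenetic growth series
#'
#' Draws dorsal skull lengths log-uniformly over the configured range,
#' generates the 27 linear measurements as fixed fractions of DSL with
#' independent lognormal noise, computes the realized geometric-mean size
#' (GMS), and generates middle-ear volume, tympanum area and braincase volume
#' as power laws of the realized GMS with independent lognormal noise. A
#' matching resonator-geometry table is emitted with two apertures per
#' specimen: the tympanum (flanged) and the subtympanic foramen (unflanged),
#' sharing the middle-ear volume as cavity volume in `"isometric"` mode, or
#' with per-aperture cavity volumes solved to hold the Helmholtz frequency at
#' the configured target in `"frequency_locked"` mode.
#'
#' Reproducible: the same config (including seed) yields bit-identical tables;
#' the caller's RNG state is left untouched.
#'
#' @param cfg a [growth_series_config()].
#' @return list: `series` (morphometry schema + `gms_mm`), `resonators`
#'   (resonator CSV schema).
#' @examples
#' gen <- generate_growth_series(isometric_growth_config(seed = 1, n = 13,
#'                                                       noise_sd_log10 = 0))
#' run_allometry(gen$series)$slope  # exactly 3, 1, 1.5
#' @export
generate_growth_series <- function(cfg) {
  stopifnot(inherits(cfg, "growth_series_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n <- cfg$n
  sdl <- cfg$noise_sd_log10
  dsl <- sort(10^runif(n, log10(cfg$dsl_min), log10(cfg$dsl_max)))
  frac <- measurement_fractions()
  amp <- generator_amplitudes()

  meas <- sapply(frac, function(f) f * dsl * 10^rnorm(n, 0, sdl))
  meas <- matrix(meas, nrow = n,
                 dimnames = list(NULL, skull_measurement_names()))
  gms <- 10^rowMeans(log10(meas))

  me <- amp$a_me * gms^cfg$beta_me * 10^rnorm(n, 0, sdl)
  tsa <- amp$a_tsa * gms^cfg$beta_tsa * 10^rnorm(n, 0, sdl)
  bc <- amp$a_bc * gms^cfg$beta_bc * 10^rnorm(n, 0, sdl)

  series <- data.frame(specimen_id = sprintf("SYN%03d", seq_len(n)),
                       dsl_mm = dsl, stringsAsFactors = FALSE)
  series <- cbind(series, as.data.frame(meas))
  series$tympanum_area_mm2 <- tsa
  series$braincase_volume_mm3 <- bc
  series$middle_ear_volume_mm3 <- me
  series$gms_mm <- gms

  sub_area <- amp$sub_area_per_dsl2 * dsl^2 * 10^rnorm(n, 0, sdl)
  sub_neck <- amp$sub_neck_per_dsl * dsl
  res <- rbind(
    data.frame(specimen_id = series$specimen_id, aperture = "tympanum",
               kind = "flanged", aperture_area_mm2 = tsa,
               neck_length_mm = 0, cavity_volume_mm3 = me,
               stringsAsFactors = FALSE),
    data.frame(specimen_id = series$specimen_id, aperture = "subtympanic",
               kind = "unflanged", aperture_area_mm2 = sub_area,
               neck_length_mm = sub_neck, cavity_volume_mm3 = me,
               stringsAsFactors = FALSE))

  if (cfg$compensation == "frequency_locked") {
    v_noise <- 10^rnorm(nrow(res), 0, sdl)
    for (i in seq_len(nrow(res))) {
      a_m2 <- res$aperture_area_mm2[i] * 1e-6
      r <- sqrt(a_m2 / pi)
      L <- if (res$kind[i] == "flanged") 1.7 * r
           else res$neck_length_mm[i] * 1e-3 + 1.4 * r
      f0 <- cfg$target_f[[res$aperture[i]]]
      v_m3 <- a_m2 * cfg$c_sound^2 / (4 * pi^2 * f0^2 * L)
      res$cavity_volume_mm3[i] <- v_m3 * 1e9 * v_noise[i]
    }
  }
  rownames(res) <- NULL
  validate_series(series)
  list(series = series, resonators = res)
}

# ---------------------------------------------------------------------------
# Phantom label volumes with analytic ground truth
# ---------------------------------------------------------------------------

#' Spherical phantom primitive
#'
#' @param center numeric length-3, mm.
#' @param radius mm (> 0).
#' @param label positive integer compartment label.
#' @param name optional compartment name for the legend.
#' @export
sphere <- function(center, radius, label, name = NULL) {
  if (radius <= 0) stop("radius must be > 0")
  structure(list(center = as.numeric(center), radii = rep(radius, 3),
                 radius = radius, label = as.integer(label),
                 name = name, type = "sphere"), class = "phantom_primitive")
}

#' Axis-aligned ellipsoid phantom primitive
#'
#' @param center numeric length-3, mm.
#' @param radii numeric length-3 semi-axes, mm (> 0).
#' @inheritParams sphere
#' @export
ellipsoid <- function(center, radii, label, name = NULL) {
  radii <- as.numeric(radii)
  if (length(radii) != 3L || any(radii <= 0))
    stop("radii must be 3 positive semi-axes")
  structure(list(center = as.numeric(center), radii = radii, radius = NA_real_,
                 label = as.integer(label), name = name, type = "ellipsoid"),
            class = "phantom_primitive")
}

#' Phantom specification
#'
#' A collection of sphere/ellipsoid primitives plus a voxel spacing; the grid
#' is sized to the primitives' bounding box plus a margin. Primitives carrying
#' different labels must be disjoint (confluent shapes share a label).
#'
#' @param primitives list of [sphere()] / [ellipsoid()] primitives.
#' @param spacing voxel spacing, mm (scalar or length 3).
#' @param margin background margin around the bounding box, voxels.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(primitives, spacing, margin = 2L) {
  if (!length(primitives)) {
    return(structure(list(primitives = list(), spacing = rep(spacing, 3)[1:3],
                          margin = as.integer(margin)),
                     class = "phantom_spec"))
  }
  ok <- vapply(primitives, inherits, logical(1), "phantom_primitive")
  if (!all(ok)) stop("primitives must be sphere() / ellipsoid() objects")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  structure(list(primitives = primitives, spacing = spacing,
                 margin = as.integer(margin)), class = "phantom_spec")
}

#' Rasterize a phantom into a label volume
#'
#' A voxel receives a primitive's label when its centre lies inside the
#' primitive (no partial-volume weighting, so voxel counts are exactly
#' reproducible). Assigning one voxel to two different labels is an ambiguity
#' error. The volume's frame places voxel `[1,1,1]` at the physical origin;
#' the translation from phantom to volume coordinates is recorded in the
#' `offset_mm` attribute.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_volume()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  if (!length(spec$primitives)) {
    vox <- array(0L, c(2L, 2L, 2L) + 2L * spec$margin)
    return(label_volume(vox, sp))
  }
  lo <- apply(sapply(spec$primitives, function(p) p$center - p$radii), 1, min)
  hi <- apply(sapply(spec$primitives, function(p) p$center + p$radii), 1, max)
  origin <- lo - spec$margin * sp
  dims <- as.integer(ceiling((hi - origin) / sp)) + spec$margin + 1L
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 1L) * sp[d])
  vox <- array(0L, dims)
  legend <- character(0)
  for (p in spec$primitives) {
    q1 <- ((ax[[1]] - p$center[1]) / p$radii[1])^2
    q2 <- ((ax[[2]] - p$center[2]) / p$radii[2])^2
    q3 <- ((ax[[3]] - p$center[3]) / p$radii[3])^2
    inside <- outer(outer(q1, q2, `+`), q3, `+`) <= 1
    clash <- inside & vox != 0L & vox != p$label
    if (any(clash))
      stop("ambiguity error: primitives with different labels overlap")
    vox[inside] <- p$label
    key <- as.character(p$label)
    if (!is.null(p$name)) legend[key] <- p$name
    else if (is.na(legend[key]))
      legend[key] <- paste0("compartment_", p$label)
  }
  out <- label_volume(vox, sp, legend)
  attr(out, "offset_mm") <- origin
  out
}

#' Sphere-sphere lens (intersection) volume
#'
#' Volume of the lens where two spheres of radii `r1`, `r2` with centre
#' distance `d` intersect:
#' `pi (r1+r2-d)^2 (d^2 + 2d(r1+r2) - 3(r1-r2)^2) / (12 d)` for partially
#' overlapping spheres; 0 when disjoint; the smaller sphere's volume when
#' contained.
#'
#' @param r1,r2 sphere radii, mm.
#' @param d centre distance, mm.
#' @return lens volume, mm³.
#' @export
sphere_lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

#' Exact metrics of a phantom specification
#'
#' Closed-form volume and surface area per label: sphere unions by
#' inclusion-exclusion with the sphere-sphere lens volume and spherical-cap
#' subtraction for areas (exact); isolated ellipsoids have exact volume and a
#' Thomsen-approximated area (flagged `approx`). Pairwise intersections are
#' supported for spheres only, and three mutually overlapping spheres are an
#' unsupported configuration.
#'
#' @param spec a [phantom_spec()].
#' @return data.frame: `label`, `name`, `volume_mm3`, `surface_area_mm2`,
#'   `method` (`"exact"` or `"approx"`).
#' @export
analytic_metrics <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  prims <- spec$primitives
  if (!length(prims))
    return(data.frame(label = integer(0), name = character(0),
                      volume_mm3 = numeric(0), surface_area_mm2 = numeric(0),
                      method = character(0)))
  # unsupported overlaps: anything involving an ellipsoid, via bounding spheres
  np <- length(prims)
  overlap <- matrix(FALSE, np, np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i >= j) next
    d <- sqrt(sum((prims[[i]]$center - prims[[j]]$center)^2))
    bi <- max(prims[[i]]$radii); bj <- max(prims[[j]]$radii)
    if (d < bi + bj) {
      if (prims[[i]]$type == "ellipsoid" || prims[[j]]$type == "ellipsoid")
        stop("unsupported-configuration: ellipsoid intersections are not analytic")
      overlap[i, j] <- overlap[j, i] <- TRUE
    }
  }
  for (i in seq_len(np)) for (j in seq_len(np)) for (k in seq_len(np)) {
    if (i < j && j < k && overlap[i, j] && overlap[j, k] && overlap[i, k])
      stop("unsupported-configuration: three mutually overlapping spheres")
  }
  labels <- sort(unique(vapply(prims, function(p) p$label, integer(1))))
  rows <- lapply(labels, function(lab) {
    idx <- which(vapply(prims, function(p) p$label, integer(1)) == lab)
    vol <- 0; area <- 0; method <- "exact"
    for (i in idx) {
      p <- prims[[i]]
      if (p$type == "sphere") {
        vol <- vol + 4 / 3 * pi * p$radius^3
        area <- area + 4 * pi * p$radius^2
      } else {
        vol <- vol + 4 / 3 * pi * prod(p$radii)
        area <- area + ellipsoid_area_thomsen(p$radii)
        method <- "approx"
      }
    }
    for (i in idx) for (j in idx) {
      if (i >= j || !overlap[i, j]) next
      p1 <- prims[[i]]; p2 <- prims[[j]]
      d <- sqrt(sum((p1$center - p2$center)^2))
      vol <- vol - sphere_lens_volume(p1$radius, p2$radius, d)
      h1 <- min(max(p1$radius - (d^2 + p1$radius^2 - p2$radius^2) / (2 * d), 0),
                2 * p1$radius)
      h2 <- min(max(p2$radius - (d^2 + p2$radius^2 - p1$radius^2) / (2 * d), 0),
                2 * p2$radius)
      area <- area - 2 * pi * (p1$radius * h1 + p2$radius * h2)
    }
    nm <- NULL
    for (i in idx) if (!is.null(prims[[i]]$name)) nm <- prims[[i]]$name
    if (is.null(nm)) nm <- paste0("compartment_", lab)
    data.frame(label = lab, name = nm, volume_mm3 = vol,
               surface_area_mm2 = area, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Thomsen approximation (p = 1.6075), max relative error ~1.06%
ellipsoid_area_thomsen <- function(radii) {
  p <- 1.6075
  a <- radii[1]; b <- radii[2]; c <- radii[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}
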
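#' Acoustic model configuration
#'
#' Constants for the Helmholtz resonator model: the speed of sound in air `c`
#' (m/s; default 343, dry air at 20 degrees C — results scale linearly in c)
#' and the end-correction constants applied to the equivalent aperture radius:
#' gamma = 1.4 for an unflanged opening with a real neck, gamma = 1.7 for a
#' flanged opening (neck length zero). Overriding a gamma is allowed but
#' announced via a message, since the defaults define the model.
#'
#' @param c speed of sound, m/s.
#' @param gamma_unflanged end-correction multiplier for unflanged apertures.
#' @param gamma_flanged end-correction multiplier for flanged apertures.
#' @return An `acoustics_config`.
#' @export
acoustics_config <- function(c = 343, gamma_unflanged = 1.4,
                             gamma_flanged = 1.7) {
  if (!is.finite(c) || c <= 0) stop("speed of sound must be > 0")
  if (!is.finite(gamma_unflanged) || gamma_unflanged <= 0 ||
      !is.finite(gamma_flanged) || gamma_flanged <= 0)
    stop("gamma end corrections must be > 0")
  if (gamma_unflanged != 1.4 || gamma_flanged != 1.7)
    message("acoustics_config: end-correction gamma overridden (unflanged = ",
            gamma_unflanged, ", flanged = ", gamma_flanged, ")")
  structure(list(c = c, gamma_unflanged = gamma_unflanged,
                 gamma_flanged = gamma_flanged),
            class = "acoustics_config")
}

#' Resonator geometry
#'
#' One candidate middle-ear resonator: aperture area, actual neck length,
#' aperture kind, and cavity volume. Inputs are in the measurement units
#' (mm², mm, mm³) and converted to SI here — this constructor is the only
#' place unit conversion happens.
#'
#' @param aperture_area_mm2 aperture area A, mm² (> 0).
#' @param cavity_volume_mm3 cavity air volume V, mm³ (> 0).
#' @param kind `"flanged"` (e.g. tympanic membrane) or `"unflanged"`
#'   (e.g. subtympanic foramen).
#' @param neck_length_mm actual neck length l, mm (>= 0; must be 0 for
#'   flanged apertures).
#' @return A `resonator_geometry` holding SI fields `aperture_area` (m²),
#'   `neck_length` (m), `cavity_volume` (m³), and `kind`.
#' @export
resonator_geometry <- function(aperture_area_mm2, cavity_volume_mm3,
                               kind = c("unflanged", "flanged"),
                               neck_length_mm = 0) {
  kind <- match.arg(kind)
  if (!is.finite(aperture_area_mm2) || aperture_area_mm2 <= 0)
    stop("domain error: aperture area must be > 0")
  if (!is.finite(cavity_volume_mm3) || cavity_volume_mm3 <= 0)
    stop("domain error: cavity volume must be > 0")
  if (!is.finite(neck_length_mm) || neck_length_mm < 0)
    stop("domain error: neck length must be >= 0")
  if (kind == "flanged" && neck_length_mm != 0)
    stop("flanged apertures have actual neck length zero")
  structure(list(aperture_area = aperture_area_mm2 * 1e-6,
                 neck_length = neck_length_mm * 1e-3,
                 cavity_volume = cavity_volume_mm3 * 1e-9,
                 kind = kind),
            class = "resonator_geometry")
}

#' Equivalent-circle radius of an aperture
#'
#' Non-circular apertures are characterised only by their area, so the radius
#' entering the end correction is that of the circle of equal area,
#' r = sqrt(A / pi).
#'
#' @param aperture_area area in m².
#' @return radius in m.
#' @export
equivalent_radius <- function(aperture_area) {
  if (!is.finite(aperture_area) || aperture_area <= 0)
    stop("domain error: aperture area must be > 0")
  sqrt(aperture_area / pi)
}

#' Effective neck length of a resonator opening
#'
#' Unflanged: L = l + 1.4 r; flanged: L = 1.7 r (with l = 0), where r is the
#' equivalent-circle radius of the aperture and the gammas come from the
#' configuration.
#'
#' @param geom a [resonator_geometry()].
#' @param cfg an [acoustics_config()].
#' @return effective length L in m.
#' @export
effective_length <- function(geom, cfg = acoustics_config()) {
  stopifnot(inherits(geom, "resonator_geometry"))
  r <- equivalent_radius(geom$aperture_area)
  if (r == 0) stop("degenerate-aperture: zero equivalent radius")
  if (geom$kind == "flanged") cfg$gamma_flanged * r
  else geom$neck_length + cfg$gamma_unflanged * r
}

#' Helmholtz resonant frequency of a middle-ear cavity
#'
#' f = (c / 2 pi) * sqrt(A / (L V)), with A the aperture area, V the cavity
#' volume and L the end-corrected effective neck length. The square root is
#' evaluated in log space so extreme magnitudes cannot overflow.
#'
#' @inheritParams effective_length
#' @return A `resonance_result`: list with `equivalent_radius` (m),
#'   `effective_length` (m), `frequency` (Hz).
#' @examples
#' g <- resonator_geometry(10, 1000, "unflanged", neck_length_mm = 2)
#' helmholtz_frequency(g)$frequency  # ~2574 Hz
#' @export
helmholtz_frequency <- function(geom, cfg = acoustics_config()) {
  stopifnot(inherits(geom, "resonator_geometry"))
  L <- effective_length(geom, cfg)
  r <- equivalent_radius(geom$aperture_area)
  logf <- log(cfg$c) - log(2 * pi) +
    0.5 * (log(geom$aperture_area) - log(L) - log(geom$cavity_volume))
  structure(list(equivalent_radius = r, effective_length = L,
                 frequency = exp(logf)),
            class = "resonance_result")
}

#' @export
print.resonance_result <- function(x, ...) {
  cat(sprintf("resonance: f = %.4g Hz (r = %.4g mm, L = %.4g mm)\n",
              x$frequency, 1e3 * x$equivalent_radius,
              1e3 * x$effective_length))
  invisible(x)
}

#' Resonant frequencies over an ontogenetic series
#'
#' Evaluates the Helmholtz model for every specimen/aperture row and
#' summarises the band of resonant frequencies spanned by the series.
#'
#' @param resonators data.frame with columns `specimen_id`, `aperture`,
#'   `kind`, `aperture_area_mm2`, `neck_length_mm`, `cavity_volume_mm3`
#'   (the resonator CSV schema), or a list of `list(id, geom)` pairs.
#' @param cfg an [acoustics_config()].
#' @return list: `results` (data.frame `specimen_id`, `aperture`, `r_mm`,
#'   `L_mm`, `f_hz`, input order preserved), `band` = c(min f, max f),
#'   `band_ratio` = max / min.
#' @export
resonance_series <- function(resonators, cfg = acoustics_config()) {
  if (is.data.frame(resonators)) {
    need <- c("specimen_id", "kind", "aperture_area_mm2", "cavity_volume_mm3")
    miss <- setdiff(need, names(resonators))
    if (length(miss))
      stop("schema error: resonator table missing column(s): ",
           paste(miss, collapse = ", "))
    if (!nrow(resonators)) stop("insufficient-data: empty resonator table")
    if (!"neck_length_mm" %in% names(resonators))
      resonators$neck_length_mm <- 0
    if (!"aperture" %in% names(resonators)) resonators$aperture <- "aperture"
    items <- lapply(seq_len(nrow(resonators)), function(i) {
      row <- resonators[i, ]
      geom <- tryCatch(
        resonator_geometry(row$aperture_area_mm2, row$cavity_volume_mm3,
                           row$kind, row$neck_length_mm),
        error = function(e) stop("specimen ", row$specimen_id, ": ",
                                 conditionMessage(e), call. = FALSE))
      list(id = row$specimen_id, aperture = row$aperture, geom = geom)
    })
  } else {
    if (!length(resonators)) stop("insufficient-data: no resonators supplied")
    items <- lapply(resonators, function(it)
      list(id = it$id, aperture = if (!is.null(it$aperture)) it$aperture
           else "aperture", geom = it$geom))
  }
  rows <- lapply(items, function(it) {
    res <- helmholtz_frequency(it$geom, cfg)
    data.frame(specimen_id = it$id, aperture = it$aperture,
               r_mm = 1e3 * res$equivalent_radius,
               L_mm = 1e3 * res$effective_length,
               f_hz = res$frequency, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  band <- c(min(results$f_hz), max(results$f_hz))
  list(results = results, band = band, band_ratio = band[2] / band[1])
}

#' Overlap of a resonance band with a hearing-sensitivity curve
#'
#' Reports whether the band of resonant frequencies intersects the
#' best-sensitivity region of a user-supplied curve (the points whose
#' sensitivity reaches the given quantile), and whether the curve's peak
#' frequency falls inside the band. A flat curve has no unique peak; the
#' report is flagged and makes no containment claim.
#'
#' @param band numeric length-2, (min f, max f) in Hz.
#' @param curve data.frame with strictly increasing `f_hz` and `sensitivity`.
#' @param quantile sensitivity quantile defining the best region
#'   (default 0.75).
#' @return list: `peak_hz`, `peak_in_band`, `best_region_hz` (range),
#'   `overlaps_best_region`, `flat_curve` flag.
#' @export
band_overlap <- function(band, curve, quantile = 0.75) {
  if (length(band) != 2L || band[1] > band[2])
    stop("band must be (min, max) with min <= max")
  if (!all(c("f_hz", "sensitivity") %in% names(curve)))
    stop("schema error: curve needs columns f_hz, sensitivity")
  if (nrow(curve) < 2L) stop("schema error: curve needs >= 2 points")
  if (any(diff(curve$f_hz) <= 0))
    stop("schema error: curve frequencies must be strictly increasing")
  s <- curve$sensitivity
  if (diff(range(s)) == 0) {
    return(list(peak_hz = NA_real_, peak_in_band = NA,
                best_region_hz = range(curve$f_hz),
                overlaps_best_region = NA, flat_curve = TRUE))
  }
  peak <- curve$f_hz[which.max(s)]
  thr <- stats::quantile(s, quantile)
  best <- curve$f_hz[s >= thr]
  list(peak_hz = peak,
       peak_in_band = peak >= band[1] && peak <= band[2],
       best_region_hz = range(best),
       overlaps_best_region = any(best >= band[1] & best <= band[2]),
       flat_curve = FALSE)
}

#' Load a resonator geometry table from CSV
#'
#' Schema: `specimen_id`, `aperture`, `kind`, `aperture_area_mm2`,
#' `neck_length_mm`, `cavity_volume_mm3`.
#'
#' @param path CSV path.
#' @export
load_resonators <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "kind", "aperture_area_mm2", "cavity_volume_mm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: resonator CSV missing column(s): ",
         paste(miss, collapse = ", "))
  df
}
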
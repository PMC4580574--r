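#' Names of the 27 linear skull measurements
#'
#' The composite skull-size variable is the geometric mean of 27 linear
#' measurements spanning the skull (orbit, mandible, fenestrae, rostrum,
#' braincase, temporal region). Two of the printed measurements carry the same
#' anatomical name (infratemporal fossa width, items 7 and 14); the schema
#' keeps 27 distinct keyed slots (`_a`/`_b`) rather than collapsing them, so
#' the printed count of 27 is preserved.
#'
#' @return Character vector of 27 column keys, `m01_...` to `m27_...`.
#' @export
skull_measurement_names <- function() {
  base <- c(
    "orbit_length", "orbit_width", "mandible_height",
    "mandibular_fenestra_height", "mandibular_fenestra_length",
    "postorbital_skull_length", "infratemporal_fossa_width_a",
    "braincase_length", "retroarticular_process_length", "rostrum_length",
    "dorsal_skull_length", "interorbital_width", "palatal_foramen_width",
    "infratemporal_fossa_width_b", "supratemporal_fossa_max_length",
    "supratemporal_fossa_min_width", "supratemporal_foramen_length",
    "supratemporal_fenestra_width", "braincase_width",
    "skull_width_at_quadrates", "braincase_height", "foramen_magnum_width",
    "pterygoid_height", "rostrum_width_2nd_maxillary_alveolus",
    "rostrum_width_4th_maxillary_alveolus",
    "rostrum_width_palatine_fenestra", "palatal_fossa_length")
  sprintf("m%02d_%s", seq_along(base), base)
}

#' Geometric-mean skull size (GMS)
#'
#' Computes `(prod m_i)^(1/k)` over the supplied linear measurements, in log
#' space for numerical stability. This is the composite linear size variable
#' used as the allometric predictor.
#'
#' @param measurements named numeric vector of measurements, mm; names should
#'   come from [skull_measurement_names()] when `require_complete = TRUE`.
#' @param require_complete if TRUE, all 27 measurements must be present;
#'   otherwise the geometric mean is taken over the `k` values supplied
#'   (`k` is recorded as an attribute on the result).
#' @return GMS in mm, with attribute `k` = number of measurements used.
#' @examples
#' geometric_mean_size(c(a = 4, b = 9))  # sqrt(36) = 6
#' @export
geometric_mean_size <- function(measurements, require_complete = FALSE) {
  m <- measurements[!is.na(measurements)]
  if (!length(m)) stop("no measurements supplied")
  if (any(m <= 0)) {
    bad <- names(m)[m <= 0]
    stop("domain error: non-positive measurement(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  }
  if (require_complete) {
    need <- skull_measurement_names()
    missing <- setdiff(need, names(m))
    if (length(missing))
      stop("completeness error: missing measurement(s): ",
           paste(missing, collapse = ", "))
    m <- m[need]
  }
  out <- 10^mean(log10(m))
  attr(out, "k") <- length(m)
  out
}

series_numeric_cols <- function() {
  c("dsl_mm", skull_measurement_names(), "tympanum_area_mm2",
    "braincase_volume_mm3", "middle_ear_volume_mm3")
}

#' Validate a specimen series table
#'
#' Checks the morphometry CSV schema: unique specimen ids, positive values
#' where present, and dorsal skull length at least as large as every orbit or
#' fenestra measurement present.
#'
#' @param table data.frame with `specimen_id`, `dsl_mm` and any of the
#'   measurement/area/volume columns.
#' @return The table, invisibly, or an error describing the violation.
#' @export
validate_series <- function(table) {
  if (!"specimen_id" %in% names(table))
    stop("schema error: missing column specimen_id")
  if (anyDuplicated(table$specimen_id))
    stop("schema error: duplicate specimen_id: ",
         paste(unique(table$specimen_id[duplicated(table$specimen_id)]),
               collapse = ", "))
  if (!"dsl_mm" %in% names(table))
    stop("schema error: missing column dsl_mm")
  for (col in intersect(series_numeric_cols(), names(table))) {
    v <- table[[col]]
    if (!is.numeric(v))
      stop("schema error: column ", col, " is not numeric")
    if (any(v <= 0, na.rm = TRUE))
      stop("domain error: non-positive value in ", col, " (specimen ",
           table$specimen_id[which(v <= 0)[1]], ")")
  }
  small <- intersect(names(table), sprintf("m%02d_%s", c(1, 2, 4, 5, 18),
    c("orbit_length", "orbit_width", "mandibular_fenestra_height",
      "mandibular_fenestra_length", "supratemporal_fenestra_width")))
  for (col in small) {
    bad <- which(table[[col]] > table$dsl_mm)
    if (length(bad))
      stop("domain error: ", col, " exceeds dorsal skull length (specimen ",
           table$specimen_id[bad[1]], ")")
  }
  invisible(table)
}

#' Load a specimen series from CSV
#'
#' Expects the morphometry schema: `specimen_id`, `dsl_mm`, optionally
#' `m01_...`..`m27_...` (mm), `tympanum_area_mm2`, `braincase_volume_mm3`,
#' `middle_ear_volume_mm3`. Comma-separated, decimal point, UTF-8.
#'
#' @param path CSV path.
#' @return Validated data.frame ordered as on disk.
#' @export
load_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  numeric_cols <- union(intersect(series_numeric_cols(), names(raw)),
                        setdiff(names(raw),
                                c("specimen_id", "specimen_type")))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(is.na(raw[[col]]) | raw[[col]] == "" |
                                toupper(raw[[col]]) == "NA"))
    if (length(bad))
      stop("parse error: non-numeric cell in column ", col, ", row ", bad[1],
           " (value '", raw[[col]][bad[1]], "')")
    raw[[col]] <- v
  }
  validate_series(raw)
  raw
}

#' Save a specimen series to CSV
#'
#' Round-trips with [load_series()] to at least 1e-9 relative precision.
#'
#' @param table series data.frame.
#' @param path destination CSV path.
#' @export
save_series <- function(table, path) {
  validate_series(table)
  out <- table
  for (col in names(out)[vapply(out, is.numeric, logical(1))])
    out[[col]] <- sprintf("%.12g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Add the geometric-mean size column to a series
#'
#' Computes `gms_mm` per specimen from whichever of the 27 measurement columns
#' are present (see [geometric_mean_size()]).
#'
#' @param table series data.frame.
#' @param require_complete demand all 27 measurements per specimen.
#' @return The table with a `gms_mm` column appended (replaced if present).
#' @export
add_gms <- function(table, require_complete = FALSE) {
  cols <- intersect(skull_measurement_names(), names(table))
  if (!length(cols)) stop("no skull measurement columns (m01_...m27_) found")
  table$gms_mm <- vapply(seq_len(nrow(table)), function(i) {
    m <- unlist(table[i, cols])
    as.numeric(geometric_mean_size(m, require_complete))
  }, numeric(1))
  table
}

#' The printed ontogenetic reference series
#'
#' Specimen ids, dorsal skull lengths (mm) and specimen types for the
#' 13-specimen *Alligator mississippiensis* ontogenetic series, spanning
#' 29.26 mm (neonate) to 551.6 mm (near-asymptotic adult) dorsal skull length.
#'
#' @return data.frame with `specimen_id`, `dsl_mm`, `specimen_type`.
#' @export
alligator_series <- function() {
  path <- system.file("extdata", "table1_specimens.csv", package = "paratymp",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
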
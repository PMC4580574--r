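#' Segmented label volume
#'
#' A `label_volume` is the digital stand-in for a segmented sinus system: a 3D
#' grid of non-negative integer labels (0 = background, each positive label one
#' compartment), the physical voxel edge lengths along each axis in mm, and a
#' legend mapping labels to compartment names.
#'
#' The coordinate convention places the centre of voxel `[1, 1, 1]` at the
#' physical origin; voxel `[i, j, k]` is centred at
#' `((i-1)*sx, (j-1)*sy, (k-1)*sz)` mm.
#'
#' @param voxels 3D integer array of labels (non-negative).
#' @param spacing numeric length-3, voxel edge length per axis in mm (all > 0).
#' @param legend named character vector mapping label (name = integer as
#'   string) to compartment name. Every nonzero label present in `voxels`
#'   must appear; missing entries are auto-filled as `"compartment_<label>"`.
#' @return An object of class `label_volume`.
#' @examples
#' vox <- array(0L, c(5, 5, 5)); vox[2:4, 2:4, 2:4] <- 1L
#' lv <- label_volume(vox, spacing = c(0.1, 0.1, 0.1), legend = c("1" = "cube"))
#' lv
#' @export
label_volume <- function(voxels, spacing, legend = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (is.double(voxels)) {
    if (any(voxels != round(voxels), na.rm = TRUE))
      stop("`voxels` must hold integer labels")
    storage.mode(voxels) <- "integer"
  }
  if (anyNA(voxels) || any(voxels < 0L))
    stop("labels must be non-negative integers with no NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid-volume: all spacing components must be finite and > 0")
  present <- setdiff(sort(unique(as.vector(voxels))), 0L)
  if (is.null(legend)) legend <- character(0)
  legend <- stats::setNames(as.character(legend), names(legend))
  if (length(legend) && is.null(names(legend)))
    stop("`legend` must be named by label")
  missing <- setdiff(as.character(present), names(legend))
  if (length(missing))
    legend[missing] <- paste0("compartment_", missing)
  legend <- legend[order(as.integer(names(legend)))]
  structure(list(voxels = voxels, spacing = spacing, legend = legend),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 6), collapse = " x ")))
  lv <- labels_present(x)
  cat(sprintf("  %d compartment(s): %s\n", length(lv),
              paste(sprintf("%d=%s", lv, x$legend[as.character(lv)]),
                    collapse = ", ")))
  invisible(x)
}

#' Labels present in a label volume
#'
#' @param volume a [label_volume()].
#' @return Sorted integer vector of the nonzero labels present in the grid.
#' @export
labels_present <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  setdiff(sort(unique(as.vector(volume$voxels))), 0L)
}

# physical voxel volume in mm^3
voxel_volume <- function(volume) prod(volume$spacing)

# ---------------------------------------------------------------------------
# I/O: NRRD (minimal attached-header reader/writer), NIfTI via RNifti,
# multipage TIFF with sidecar spacing.
# ---------------------------------------------------------------------------

#' Read a segmented label volume from disk
#'
#' Dispatches on extension: `.nrrd` (raw or gzip encodings, attached header),
#' `.nii`/`.nii.gz` (spacing taken from the NIfTI pixdim, assumed mm), or
#' `.tif`/`.tiff` multipage stacks (spacing must be supplied since TIFF carries
#' no 3D spacing).
#'
#' @param path file path.
#' @param spacing optional numeric length-3 spacing in mm; required for TIFF,
#'   overrides the header for other formats when given.
#' @param legend optional named character legend (label -> compartment name).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, spacing = NULL, legend = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) {
    lv <- read_nrrd(path)
    if (!is.null(spacing)) lv$spacing <- as.numeric(spacing)
    vol <- label_volume(lv$voxels, lv$spacing, legend)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vox <- array(as.integer(round(as.array(img))), dim = dim(img))
    sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:3] else spacing
    vol <- label_volume(vox, sp, legend)
  } else if (grepl("\\.tiff?$", lower)) {
    if (is.null(spacing))
      stop("TIFF stacks carry no 3D spacing; supply `spacing` (mm)")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    vox <- array(0L, c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) vox[, , k] <- as.integer(round(pages[[k]]))
    vol <- label_volume(vox, spacing, legend)
  } else {
    stop("unsupported label-volume format: ", path)
  }
  vol
}

#' Write a label volume to disk
#'
#' Writes `.nrrd` (gzip-encoded) or `.nii`/`.nii.gz`. The legend is written as
#' a sidecar CSV (`<path>.legend.csv`, columns label,name) because neither
#' format has a standard slot for it.
#'
#' @param volume a [label_volume()].
#' @param path destination; extension selects the format.
#' @param legend_sidecar write the legend CSV alongside (default TRUE).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path, legend_sidecar = TRUE) {
  stopifnot(inherits(volume, "label_volume"))
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) {
    write_nrrd(volume, path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vox <- volume$voxels
    attr(vox, "pixdim") <- volume$spacing
    img <- RNifti::asNifti(vox, datatype = "int32", internal = FALSE)
    RNifti::writeNifti(img, path)
  } else {
    stop("unsupported label-volume format: ", path)
  }
  if (legend_sidecar && length(volume$legend)) {
    write.csv(data.frame(label = as.integer(names(volume$legend)),
                         name = unname(volume$legend)),
              paste0(path, ".legend.csv"), row.names = FALSE)
  }
  invisible(path)
}

# Minimal NRRD: attached header, encodings raw | gzip, types uint8..int32,
# 3 dimensions, "space directions" diagonal or "spacings" field.
read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  pair <- which(diff(nl) == 1L)[1]
  if (is.na(pair)) stop("truncated NRRD header")
  boundary <- nl[pair + 1L]  # second newline of the blank line
  header <- strsplit(rawToChar(bytes[seq_len(nl[pair] - 1L)]), "\n",
                     fixed = TRUE)[[1]]
  if (!grepl("^NRRD000", header[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (line in header[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    fields[[key]] <- val
  }
  payload <- bytes[(boundary + 1L):length(bytes)]
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- if (!is.null(fields[["spacings"]])) {
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    sapply(seq_along(vecs), function(i) {
      v <- as.numeric(strsplit(gsub("[()]", "", vecs[i]), ",")[[1]])
      sqrt(sum(v^2))
    })
  } else rep(1, 3)
  type <- tolower(fields[["type"]])
  sizes <- c("uint8" = 1L, "int8" = 1L, "uchar" = 1L,
             "uint16" = 2L, "int16" = 2L, "short" = 2L, "ushort" = 2L,
             "uint32" = 4L, "int32" = 4L, "int" = 4L, "uint" = 4L)
  if (!type %in% names(sizes)) stop("unsupported NRRD type: ", type)
  size <- sizes[[type]]
  signed <- grepl("^int|^short$", type)
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  n <- prod(dims)
  enc <- tolower(fields[["encoding"]])
  data <- if (enc %in% c("gzip", "gz")) {
    memDecompress(payload, type = "gzip")
  } else if (enc == "raw") payload else {
    stop("unsupported NRRD encoding: ", enc)
  }
  vals <- readBin(data, "integer", n = n, size = size,
                  signed = if (size == 4L) TRUE else signed, endian = endian)
  if (length(vals) != n) stop("truncated NRRD data block")
  list(voxels = array(as.integer(vals), dims), spacing = spacing)
}

write_nrrd <- function(volume, path) {
  dims <- dim(volume$voxels)
  header <- c(
    "NRRD0004",
    "# label volume written by paratymp",
    "type: int32",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("spacings: %.10g %.10g %.10g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    "endian: little",
    "encoding: gzip",
    "")
  con <- file(path, "wb")
  writeLines(header, con, sep = "\n")
  gz <- memCompress(writeBin(as.vector(volume$voxels), raw(),
                             size = 4L, endian = "little"), "gzip")
  writeBin(gz, con)
  close(con)
  invisible(path)
}
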
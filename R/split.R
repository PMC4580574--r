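#' Split a confluent compartment at its constrictions
#'
#' Confluent sinus spaces meet at well-defined constrictions, like conjoined
#' soap bubbles; this operation partitions one labelled compartment into lobes
#' at those necks. The binary compartment is distance-transformed (Euclidean,
#' computed in physical mm so anisotropic spacing is handled), the transform is
#' Gaussian-smoothed, its regional maxima seed a marker-based watershed, and
#' every candidate boundary is then audited: a split between two lobes is
#' accepted only when the neck's maximum inscribed-sphere radius is smaller
#' than `neck_ratio` times the smaller lobe's maximum inscribed-sphere radius.
#' Rejected boundaries are merged away. Voxel membership is conserved: no voxel
#' is gained or lost.
#'
#' @param volume a [label_volume()].
#' @param label the compartment to split (must be present).
#' @param smoothing_sigma Gaussian sigma in voxels applied to the distance
#'   transform before peak detection (default 1).
#' @param neck_ratio acceptance threshold in (0,1) (default 0.8); smaller
#'   values demand more pronounced necks.
#' @return A new [label_volume()]. If no split is accepted the input is
#'   returned unchanged; otherwise the lobes receive fresh labels above the
#'   current maximum and legend entries suffixed `.lobe1`, `.lobe2`, ...
#' @examples
#' spec <- phantom_spec(list(sphere(c(0, 2, 2), 1.8, 1),
#'                           sphere(c(3.2, 2, 2), 1.8, 1)), spacing = 0.2)
#' lv <- generate_phantom(spec)
#' split <- split_at_constrictions(lv, 1)
#' labels_present(split)
#' @export
split_at_constrictions <- function(volume, label, smoothing_sigma = 1,
                                   neck_ratio = 0.8) {
  stopifnot(inherits(volume, "label_volume"))
  label <- as.integer(label)
  if (!is.finite(neck_ratio) || neck_ratio <= 0 || neck_ratio >= 1)
    stop("parameter error: neck_ratio must lie strictly in (0, 1)")
  mask <- volume$voxels == label
  if (!any(mask)) stop("empty-selection: label ", label, " absent from volume")
  d <- dim(mask)
  maski <- array(as.integer(mask), d)

  edt <- cpp_edt3d(maski, d, volume$spacing)
  sm <- if (smoothing_sigma > 0) cpp_smooth3d(edt, d, smoothing_sigma) else edt
  markers <- cpp_marker_labels(sm, maski, d)
  ws <- cpp_watershed(sm, maski, markers, d)

  regs <- setdiff(sort(unique(as.vector(ws))), 0L)
  if (length(regs) <= 1L) return(volume)

  # per-region maximum inscribed-sphere radius (true EDT, mm)
  radius <- tapply(edt[ws > 0L], ws[ws > 0L], max)

  # neck radius for each adjacent pair: max EDT over the shared interface
  pair_neck <- interface_necks(ws, edt)

  # audit splits; merge away boundaries that are not real constrictions
  group <- stats::setNames(regs, regs)  # region id -> group representative
  find <- function(r) {
    while (group[[as.character(r)]] != r) r <- group[[as.character(r)]]
    r
  }
  repeat {
    if (!nrow(pair_neck)) break
    ga <- vapply(pair_neck$a, find, numeric(1))
    gb <- vapply(pair_neck$b, find, numeric(1))
    live <- ga != gb
    if (!any(live)) break
    key <- paste(pmin(ga, gb), pmax(ga, gb))[live]
    neck <- tapply(pair_neck$neck[live], key, max)
    roots <- vapply(regs, find, numeric(1))
    gr_radius <- tapply(as.numeric(radius), as.character(roots), max)
    ab <- do.call(rbind, strsplit(names(neck), " "))
    ra <- gr_radius[ab[, 1]]
    rb <- gr_radius[ab[, 2]]
    failing <- neck >= neck_ratio * pmin(ra, rb)
    if (!any(failing)) break
    worst <- which.max(ifelse(failing, neck, -Inf))
    a <- as.numeric(ab[worst, 1]); b <- as.numeric(ab[worst, 2])
    group[[as.character(max(a, b))]] <- min(a, b)
  }
  final <- vapply(regs, find, numeric(1))
  groups <- sort(unique(final))
  if (length(groups) <= 1L) return(volume)

  # relabel accepted lobes with fresh labels above the current maximum
  base <- max(c(labels_present(volume), 0L))
  old_name <- volume$legend[as.character(label)]
  if (is.na(old_name)) old_name <- paste0("compartment_", label)
  map <- stats::setNames(base + seq_along(groups), groups)
  vox <- volume$voxels
  grp_of_region <- stats::setNames(vapply(regs, find, numeric(1)), regs)
  sel <- ws > 0L
  vox[sel] <- as.integer(map[as.character(grp_of_region[as.character(ws[sel])])])
  legend <- volume$legend[names(volume$legend) != as.character(label)]
  new_names <- stats::setNames(paste0(old_name, ".lobe", seq_along(groups)),
                               as.character(base + seq_along(groups)))
  label_volume(vox, volume$spacing, c(legend, new_names))
}

# For each pair of adjacent watershed regions, the maximum EDT value on the
# 6-connected interface between them (a proxy for the neck's inscribed-sphere
# radius).
interface_necks <- function(ws, edt) {
  d <- dim(ws)
  a <- integer(0); b <- integer(0); v <- numeric(0)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    i1 <- i2 <- list(TRUE, TRUE, TRUE)
    i1[[ax]] <- seq_len(n - 1L)
    i2[[ax]] <- seq_len(n - 1L) + 1L
    w1 <- do.call(`[`, c(list(ws), i1, list(drop = FALSE)))
    w2 <- do.call(`[`, c(list(ws), i2, list(drop = FALSE)))
    e1 <- do.call(`[`, c(list(edt), i1, list(drop = FALSE)))
    e2 <- do.call(`[`, c(list(edt), i2, list(drop = FALSE)))
    sel <- w1 > 0L & w2 > 0L & w1 != w2
    if (any(sel)) {
      a <- c(a, pmin(w1[sel], w2[sel]))
      b <- c(b, pmax(w1[sel], w2[sel]))
      v <- c(v, pmax(e1[sel], e2[sel]))
    }
  }
  if (!length(a)) return(data.frame(a = integer(0), b = integer(0),
                                    neck = numeric(0)))
  key <- paste(a, b)
  agg <- tapply(v, key, max)
  ab <- do.call(rbind, strsplit(names(agg), " "))
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             neck = as.numeric(agg))
}
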
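#' Measure one sinus compartment of a label volume
#'
#' Volume is the voxel count times the physical voxel volume (the canonical
#' definition used throughout the package). Surface area is measured either by
#' summing exposed voxel faces (`"voxel_faces"`; exact for axis-aligned solids,
#' a systematic overestimate for curved anatomy) or by triangulating the
#' compartment boundary and summing triangle areas (`"isosurface"`, the
#' default).
#'
#' @param volume a [label_volume()].
#' @param label positive integer label to measure.
#' @param area_method `"isosurface"` (default) or `"voxel_faces"`.
#' @param smoothing_sigma Gaussian sigma in voxels applied to the binary mask
#'   before isosurface extraction (see [extract_isosurface()]).
#' @return One-row data.frame: `label`, `name`, `voxel_count`, `volume_mm3`,
#'   `surface_area_mm2`, `method`. A label absent from the grid yields zeroed
#'   metrics.
#' @examples
#' vox <- array(0L, c(12, 12, 12)); vox[2:11, 2:11, 2:11] <- 1L
#' lv <- label_volume(vox, 1, c("1" = "cube"))
#' measure_compartment(lv, 1, area_method = "voxel_faces")
#' @export
measure_compartment <- function(volume, label,
                                area_method = c("isosurface", "voxel_faces"),
                                smoothing_sigma = 1) {
  stopifnot(inherits(volume, "label_volume"))
  area_method <- match.arg(area_method)
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 1L)
    stop("`label` must be a single integer >= 1")
  mask <- volume$voxels == label
  nvox <- sum(mask)
  name <- volume$legend[as.character(label)]
  if (is.na(name)) name <- paste0("compartment_", label)
  if (nvox == 0L) {
    return(data.frame(label = label, name = name, voxel_count = 0L,
                      volume_mm3 = 0, surface_area_mm2 = 0,
                      method = area_method, stringsAsFactors = FALSE))
  }
  vol <- nvox * voxel_volume(volume)
  area <- if (area_method == "voxel_faces") {
    voxel_face_area(mask, volume$spacing)
  } else {
    mesh_area(extract_isosurface(volume, label, smoothing_sigma = smoothing_sigma))
  }
  data.frame(label = label, name = unname(name), voxel_count = as.integer(nvox),
             volume_mm3 = vol, surface_area_mm2 = area,
             method = area_method, stringsAsFactors = FALSE)
}

#' Measure every compartment of a label volume
#'
#' @inheritParams measure_compartment
#' @param specimen_id optional id recorded in the output.
#' @return data.frame of per-label metrics (see [measure_compartment()]),
#'   with a `specimen_id` column when given.
#' @export
compartment_table <- function(volume, area_method = c("isosurface", "voxel_faces"),
                              smoothing_sigma = 1, specimen_id = NULL) {
  area_method <- match.arg(area_method)
  rows <- lapply(labels_present(volume), function(l)
    measure_compartment(volume, l, area_method, smoothing_sigma))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(), name = character(),
                      voxel_count = integer(), volume_mm3 = numeric(),
                      surface_area_mm2 = numeric(), method = character())
  if (!is.null(specimen_id)) out <- cbind(specimen_id = specimen_id, out)
  out
}

#' Write compartment metrics to CSV
#'
#' Columns: specimen_id, label, name, voxel_count, volume_mm3,
#' surface_area_mm2, method.
#'
#' @param metrics data.frame from [compartment_table()].
#' @param path destination CSV path.
#' @export
write_compartment_metrics <- function(metrics, path) {
  if (!"specimen_id" %in% names(metrics)) metrics <- cbind(specimen_id = NA, metrics)
  write.csv(metrics[, c("specimen_id", "label", "name", "voxel_count",
                        "volume_mm3", "surface_area_mm2", "method")],
            path, row.names = FALSE)
  invisible(path)
}

# sum of exposed voxel faces, in mm^2, for a logical mask
voxel_face_area <- function(mask, spacing) {
  d <- dim(mask)
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  total <- 0
  for (ax in 1:3) {
    n <- d[ax]
    idx1 <- idx2 <- list(TRUE, TRUE, TRUE)
    idx1[[ax]] <- seq_len(n - 1L)
    idx2[[ax]] <- seq_len(n - 1L) + 1L
    a <- do.call(`[`, c(list(mask), idx1, list(drop = FALSE)))
    b <- do.call(`[`, c(list(mask), idx2, list(drop = FALSE)))
    internal_exposed <- sum(xor(a, b))
    # grid-boundary faces of the mask are exposed too
    idxlo <- idxhi <- list(TRUE, TRUE, TRUE)
    idxlo[[ax]] <- 1L
    idxhi[[ax]] <- n
    boundary <- sum(do.call(`[`, c(list(mask), idxlo))) +
      sum(do.call(`[`, c(list(mask), idxhi)))
    total <- total + face[ax] * (internal_exposed + boundary)
  }
  total
}

#' Extract a triangulated boundary surface for one compartment
#'
#' The binary compartment mask is padded with a background shell, optionally
#' Gaussian-smoothed (in voxel units), and triangulated at the 0.5 level with
#' a marching-tetrahedra scheme whose cell decomposition is translation
#' invariant, so the surface is watertight whenever the compartment does not
#' touch the grid boundary (the padding guarantees this). Smoothing places the
#' level set close to the smooth anatomical surface instead of the jagged
#' voxel staircase; set `smoothing_sigma = 0` for the raw binary level set.
#'
#' @inheritParams measure_compartment
#' @param smoothing_sigma Gaussian sigma in voxels (default 1).
#' @return A `tri_mesh`: list with `vertices` (n x 3 mm), `faces` (m x 3,
#'   1-based), and `closed` flag.
#' @export
extract_isosurface <- function(volume, label, smoothing_sigma = 1) {
  stopifnot(inherits(volume, "label_volume"))
  label <- as.integer(label)
  mask <- volume$voxels == label
  if (!any(mask)) stop("empty-selection: label ", label, " absent from volume")
  pad <- as.integer(ceiling(3 * max(smoothing_sigma, 0)) + 1L)
  d <- dim(mask)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  if (smoothing_sigma > 0)
    field <- cpp_smooth3d(field, dim(field), smoothing_sigma)
  raw <- cpp_marching_tetra(field, dim(field), volume$spacing, 0.5)
  verts <- raw$vertices
  # undo padding offset: voxel [1,1,1] centre sits at the physical origin
  verts <- sweep(verts, 2, pad * volume$spacing, `-`)
  faces <- raw$faces
  tri_mesh(verts, faces)
}

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `tri_mesh` with a recorded `closed` flag (every edge shared by
#'   exactly two faces). Faces of exactly zero area are rejected.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range")
  a <- triangle_areas(vertices, faces)
  if (any(a == 0)) stop("zero-area face in mesh construction")
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  m$closed <- mesh_is_closed(m)
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, %s\n", nrow(x$vertices),
              nrow(x$faces), if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

triangle_areas <- function(vertices, faces) {
  if (!nrow(faces)) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Mesh surface area
#'
#' Sum of triangle areas, mm².
#' @param mesh a [tri_mesh()].
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  sum(triangle_areas(mesh$vertices, mesh$faces))
}

#' Mesh-enclosed volume
#'
#' Divergence-theorem volume of a closed triangulated surface
#' (sum of signed tetrahedron volumes against the origin), mm³. Independent of
#' the coordinate origin for closed surfaces.
#'
#' @param mesh a closed [tri_mesh()].
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!isTRUE(mesh$closed))
    stop("mesh_volume requires a closed surface")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det6)) / 6
}

#' Connected components of a mesh
#'
#' Faces are connected when they share a vertex.
#' @param mesh a [tri_mesh()].
#' @return Number of connected components.
#' @export
mesh_components <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(0L)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  used <- sort(unique(as.vector(f)))
  comps <- igraph::components(g)
  length(unique(comps$membership[used]))
}

#' Euler characteristic and genus of a closed mesh
#'
#' chi = V - E + F over used vertices and unique undirected edges; for a
#' single closed component the genus is (2 - chi) / 2.
#' @param mesh a [tri_mesh()].
#' @return list with `chi` and `genus` (genus NA when the mesh has several
#'   components or is open).
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  used <- unique(as.vector(f))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  chi <- length(used) - length(key) + nrow(f)
  genus <- if (isTRUE(mesh$closed) && mesh_components(mesh) == 1L)
    (2 - chi) / 2 else NA_real_
  list(chi = chi, genus = genus)
}

#' Export a mesh as ASCII STL or Wavefront OBJ
#'
#' @param mesh a [tri_mesh()].
#' @param path destination; `.stl` or `.obj` selects the format.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (grepl("\\.stl$", tolower(path))) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid paratymp", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- sqrt(sum(n^2))
      if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g",
                           tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid paratymp", con)
  } else if (grepl("\\.obj$", tolower(path))) {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else stop("unsupported mesh format: ", path)
  invisible(path)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# ---------------------------------------------------------------------------
# Apertures
# ---------------------------------------------------------------------------

#' Planar aperture specification
#'
#' An aperture is a planar polygon loop (in mm) through which sound energy may
#' enter the middle-ear cavity, together with its acoustic kind: `"flanged"`
#' (opening in a baffle, actual neck length zero, e.g. the tympanic membrane)
#' or `"unflanged"` (free-standing opening with a real neck, e.g. the
#' subtympanic foramen).
#'
#' Planarity is enforced: the maximum point-to-plane distance must not exceed
#' 2% of the loop diameter.
#'
#' @param boundary n x 3 matrix of loop points, mm, ordered around the loop.
#' @param kind `"flanged"` or `"unflanged"`.
#' @param neck_length actual neck length l, mm (must be 0 for flanged).
#' @return An `aperture_spec` with the computed `area` (mm²).
#' @export
aperture_spec <- function(boundary, kind = c("unflanged", "flanged"),
                          neck_length = 0) {
  kind <- match.arg(kind)
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 3L || nrow(boundary) < 3L)
    stop("degenerate-aperture: boundary needs >= 3 points in 3D")
  if (neck_length < 0) stop("neck_length must be >= 0")
  if (kind == "flanged" && neck_length != 0)
    stop("flanged apertures have actual neck length zero")
  ctr <- colMeans(boundary)
  x <- sweep(boundary, 2, ctr)
  sv <- svd(x)
  diam <- max(dist(boundary))
  if (diam == 0 || sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate-aperture: boundary points are collinear")
  plane_dev <- max(abs(x %*% sv$v[, 3]))
  if (plane_dev > 0.02 * diam)
    stop("degenerate-aperture: loop departs from planarity by ",
         signif(plane_dev, 3), " mm (> 2% of diameter)")
  area <- fan_area(boundary, ctr)
  if (area <= 0) stop("degenerate-aperture: zero enclosed area")
  structure(list(boundary = boundary, area = area, kind = kind,
                 neck_length = neck_length), class = "aperture_spec")
}

fan_area <- function(boundary, ctr) {
  n <- nrow(boundary)
  tot <- 0
  for (i in seq_len(n)) {
    a <- boundary[i, ] - ctr
    b <- boundary[if (i == n) 1L else i + 1L, ] - ctr
    tot <- tot + 0.5 * sqrt(sum(pracma_cross(a, b)^2))
  }
  tot
}

#' Aperture area
#'
#' Area of the planar loop by fan triangulation about the centroid, mm².
#' @param aperture an [aperture_spec()].
#' @export
polygon_area <- function(aperture) {
  stopifnot(inherits(aperture, "aperture_spec"))
  aperture$area
}
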
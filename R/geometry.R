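#' Cylindrical sonicated-ROI specification
#'
#' Each emitter of the implant insonifies a cylinder of brain tissue in front
#' of it. The grading analysis uses bare 10 mm diameter x 75 mm cylinders;
#' tumor-field analyses extend them by a 5 mm diffusion margin to
#' 20 mm x 80 mm.
#'
#' @param radius_mm cylinder radius (default 5).
#' @param length_mm cylinder length along the emitter axis (default 75).
#' @param margin_mm radial and axial dilation in mm (default 0; use 5 for the
#'   diffusion-margin cylinders).
#' @return A `cylinder_spec` object.
#' @export
cylinder_spec <- function(radius_mm = 5, length_mm = 75, margin_mm = 0) {
  stopifnot(radius_mm > 0, length_mm > 0, margin_mm >= 0)
  structure(list(radius_mm = radius_mm, length_mm = length_mm,
                 margin_mm = margin_mm), class = "cylinder_spec")
}

#' Nine-emitter implant geometry
#'
#' Builds the flat 3x3 grid of 10-mm ultrasound emitters as implanted in
#' place of a 58 mm x 58 mm bone flap. Emitter centres lie in the plate
#' plane; all axes point along the plate normal into the brain. Emitters are
#' numbered row-major: 1..3 bottom row, 9 top-right.
#'
#' @param pitch_mm centre-to-centre spacing of adjacent emitters; default
#'   58/3 mm so the 3x3 footprint fits the bone flap.
#' @param plate_center_mm world coordinates of the central emitter.
#' @param normal unit vector of the emitter axes (into the brain).
#' @param emitter_radius_mm active element radius (default 5, i.e. 10-mm
#'   diameter pistons).
#' @return An `emitter_array`: a tibble with one row per emitter
#'   (`emitter`, centre `cx, cy, cz`, axis `ax, ay, az`) and attributes
#'   `pitch_mm`, `emitter_radius_mm`.
#' @examples
#' arr <- emitter_array()
#' arr
#' @export
emitter_array <- function(pitch_mm = 58 / 3, plate_center_mm = c(0, 0, 0),
                          normal = c(0, 0, 1), emitter_radius_mm = 5) {
  if (pitch_mm <= 2 * emitter_radius_mm)
    stop("invalid geometry: pitch (", pitch_mm,
         " mm) must exceed the emitter diameter (", 2 * emitter_radius_mm,
         " mm)", call. = FALSE)
  normal <- normal / sqrt(sum(normal^2))
  # orthonormal in-plane basis
  seedv <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- seedv - sum(seedv * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  offs <- expand.grid(du = c(-1, 0, 1), dv = c(-1, 0, 1))
  centers <- t(apply(offs, 1, function(o)
    plate_center_mm + pitch_mm * (o[["du"]] * u + o[["dv"]] * v)))
  out <- tibble::tibble(
    emitter = 1:9,
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    ax = normal[1], ay = normal[2], az = normal[3]
  )
  structure(out, pitch_mm = pitch_mm, emitter_radius_mm = emitter_radius_mm,
            class = c("emitter_array", class(out)))
}

array_centers <- function(array) as.matrix(array[, c("cx", "cy", "cz")])
array_axes <- function(array) as.matrix(array[, c("ax", "ay", "az")])

# per-voxel axial and radial coordinates w.r.t. emitter k
emitter_cyl_coords <- function(coords, array, k) {
  ctr <- array_centers(array)[k, ]
  ax <- array_axes(array)[k, ]
  dx <- coords$x - ctr[1]
  dy <- coords$y - ctr[2]
  dz <- coords$z - ctr[3]
  t_ax <- dx * ax[1] + dy * ax[2] + dz * ax[3]
  r2 <- dx * dx + dy * dy + dz * dz - t_ax * t_ax
  list(axial = t_ax, radial = sqrt(pmax(r2, 0)))
}

#' Rasterize per-emitter cylindrical ROIs onto a voxel grid
#'
#' A voxel belongs to emitter k's ROI when its centre lies within
#' `radius + margin` of axis k and within `[0, length + margin]` along it
#' (margins dilate radially and at the distal end). Where dilated cylinders
#' overlap, the voxel is assigned to the nearest axis (ties to the lowest
#' emitter index), so per-emitter labels partition the union.
#'
#' @param array an [emitter_array()].
#' @param grid a [voxel_grid()].
#' @param spec a [cylinder_spec()].
#' @return An `roi_label_map`: list with `labels` (integer array, 0 outside,
#'   1-9 emitter index) and `grid`.
#' @export
rasterize_cylinder_rois <- function(array, grid, spec = cylinder_spec()) {
  coords <- voxel_coords(grid)
  r_eff <- spec$radius_mm + spec$margin_mm
  l_eff <- spec$length_mm + spec$margin_mm
  best <- array(Inf, grid$dim)
  labels <- array(0L, grid$dim)
  for (k in 1:9) {
    cc <- emitter_cyl_coords(coords, array, k)
    inside <- cc$axial >= 0 & cc$axial <= l_eff & cc$radial <= r_eff
    take <- inside & cc$radial < best
    labels[take] <- k
    best[take] <- cc$radial[take]
  }
  if (!any(labels > 0L))
    warning("cylinders do not intersect the grid: empty ROI map")
  structure(list(labels = labels, grid = grid), class = "roi_label_map")
}

#' @export
print.roi_label_map <- function(x, ...) {
  v <- tabulate(x$labels[x$labels > 0], 9) * voxel_volume(x$grid) / 1000
  cat("<roi_label_map> 9 cylinders,", format(sum(v), digits = 4),
      "mL total\n")
  invisible(x)
}

#' Per-emitter and union ROI masks
#' @param rois an `roi_label_map`.
#' @param emitter emitter index 1-9, or `NULL` for the union mask.
#' @return Logical array.
#' @export
roi_mask <- function(rois, emitter = NULL) {
  if (is.null(emitter)) rois$labels > 0L else rois$labels == as.integer(emitter)
}

#' Minimum radial distance to the emitter axes
#'
#' For every voxel, the minimum over emitters of the perpendicular distance
#' to that emitter's axis, counting only emitters whose axial coordinate for
#' the voxel lies in `[0, max_length_mm]`. Voxels qualifying for no emitter
#' get `Inf`.
#'
#' @param array an [emitter_array()].
#' @param grid a [voxel_grid()].
#' @param max_length_mm axial extent over which an emitter's axis counts
#'   (default 75, the sonicated cylinder length).
#' @return A `distance_map`: list with `radial_mm` (array, `Inf` sentinel
#'   outside the axial slab) and `grid`.
#' @export
axial_distance_map <- function(array, grid, max_length_mm = 75) {
  stopifnot(max_length_mm > 0)
  coords <- voxel_coords(grid)
  radial <- array(Inf, grid$dim)
  for (k in 1:9) {
    cc <- emitter_cyl_coords(coords, array, k)
    valid <- cc$axial >= 0 & cc$axial <= max_length_mm
    take <- valid & cc$radial < radial
    radial[take] <- cc$radial[take]
  }
  structure(list(radial_mm = radial, grid = grid), class = "distance_map")
}

#' Tube-shaped shell masks between radial distances
#'
#' Partitions the brain around the emitter axes into "ring-shaped" regions:
#' shell i holds voxels whose minimal axis distance falls in
#' `[edges[i], edges[i+1])`.
#'
#' @param dmap a [axial_distance_map()] result.
#' @param bin_edges strictly increasing distances in mm (>= 2 values).
#' @return A named list of disjoint logical masks, one per bin, named
#'   `"lo-hi"`.
#' @export
tube_shell_masks <- function(dmap, bin_edges) {
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with at least 2 values",
         call. = FALSE)
  n <- length(bin_edges) - 1
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- dmap$radial_mm >= bin_edges[i] & dmap$radial_mm < bin_edges[i + 1]
  }
  names(out) <- paste0(bin_edges[-length(bin_edges)], "-", bin_edges[-1])
  out
}
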
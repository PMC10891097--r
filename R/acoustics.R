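#' Sonication protocol parameters
#'
#' Pulsing scheme of the implant: each of the nine 1-MHz emitters fires
#' 25-ms pulses every 2 s for 270 s (duty cycle 1.25%), at a calibrated
#' surface pressure of 1.03 MPa, emitters activated sequentially.
#'
#' @param frequency_MHz operating frequency (default 1).
#' @param surface_pressure_MPa calibrated peak pressure at the emitter
#'   surface (default 1.03).
#' @param pulse_length_s pulse duration (default 0.025).
#' @param pulse_period_s pulse repetition period (default 2).
#' @param total_duration_s sonication duration (default 270).
#' @return A `sonication_protocol` list with derived `duty_cycle`.
#' @export
sonication_protocol <- function(frequency_MHz = 1, surface_pressure_MPa = 1.03,
                                pulse_length_s = 0.025, pulse_period_s = 2,
                                total_duration_s = 270) {
  stopifnot(frequency_MHz > 0, surface_pressure_MPa > 0,
            pulse_length_s > 0, pulse_period_s >= pulse_length_s,
            total_duration_s > 0)
  structure(list(frequency_MHz = frequency_MHz,
                 surface_pressure_MPa = surface_pressure_MPa,
                 pulse_length_s = pulse_length_s,
                 pulse_period_s = pulse_period_s,
                 total_duration_s = total_duration_s,
                 duty_cycle = pulse_length_s / pulse_period_s),
            class = "sonication_protocol")
}

#' Homogeneous tissue acoustic medium
#'
#' Standard soft-tissue constants; the implant sits epidurally in place of
#' the bone flap, so no skull layer is modeled.
#'
#' @param sound_speed_m_s speed of sound (default 1540).
#' @param attenuation_dB_cm_MHz amplitude attenuation (default 0.5).
#' @param density_kg_m3 mass density (default 1040).
#' @return An `acoustic_medium` list.
#' @export
acoustic_medium <- function(sound_speed_m_s = 1540,
                            attenuation_dB_cm_MHz = 0.5,
                            density_kg_m3 = 1040) {
  stopifnot(sound_speed_m_s > 0, attenuation_dB_cm_MHz >= 0,
            density_kg_m3 > 0)
  structure(list(sound_speed_m_s = sound_speed_m_s,
                 attenuation_dB_cm_MHz = attenuation_dB_cm_MHz,
                 density_kg_m3 = density_kg_m3),
            class = "acoustic_medium")
}

wavelength_mm <- function(medium, protocol) {
  medium$sound_speed_m_s / (protocol$frequency_MHz * 1000)
}

# amplitude attenuation coefficient in Np/mm at the protocol frequency
attenuation_np_mm <- function(medium, protocol) {
  medium$attenuation_dB_cm_MHz * protocol$frequency_MHz /
    (20 / log(10)) / 10
}

#' Closed-form on-axis pressure of a lossless baffled circular piston
#'
#' `p/p0 = 2 |sin( (pi / lambda) (sqrt(z^2 + a^2) - z) )|` — the exact
#' axial solution of the Rayleigh integral for a uniformly vibrating disc,
#' used as the independent oracle for the numerical field solver.
#'
#' @param a_mm piston radius.
#' @param wavelength_mm acoustic wavelength.
#' @param z_mm axial distance(s) from the piston face (> 0).
#' @return Pressure amplitude ratio(s) p/p0.
#' @examples
#' on_axis_pressure(5, 1.54, 75)
#' @export
on_axis_pressure <- function(a_mm, wavelength_mm, z_mm) {
  stopifnot(all(z_mm > 0))
  2 * abs(sin((pi / wavelength_mm) * (sqrt(z_mm^2 + a_mm^2) - z_mm)))
}

# equal-area polar discretization of the piston face
piston_elements <- function(a_mm, ds_mm) {
  n_r <- max(2L, ceiling(a_mm / ds_mm))
  dr <- a_mm / n_r
  xs <- ys <- areas <- list()
  for (j in seq_len(n_r)) {
    rj <- (j - 0.5) * dr
    n_th <- max(6L, ceiling(2 * pi * rj / ds_mm))
    th <- (seq_len(n_th) - 0.5) * 2 * pi / n_th
    ring_area <- pi * ((j * dr)^2 - ((j - 1) * dr)^2)
    xs[[j]] <- rj * cos(th)
    ys[[j]] <- rj * sin(th)
    areas[[j]] <- rep(ring_area / n_th, n_th)
  }
  list(x = unlist(xs), y = unlist(ys), area = unlist(areas))
}

#' Axisymmetric Rayleigh-Sommerfeld pressure table for one piston
#'
#' Steady-state pressure magnitude of a baffled circular piston in a lossy
#' homogeneous medium, by direct Rayleigh-Sommerfeld summation over surface
#' elements: `p(x) = p0 (k / 2 pi) | sum_j exp((ik - alpha) R_j) / R_j dS_j |`,
#' normalized so the plane-wave surface pressure equals `p0`. The field of a
#' flat piston is axisymmetric, so it is tabulated on an (r, z) half-plane
#' and later interpolated onto 3-D grids per emitter.
#'
#' @param a_mm piston radius.
#' @param medium an [acoustic_medium()].
#' @param protocol a [sonication_protocol()].
#' @param r_max_mm,z_max_mm table extent (defaults 40 and 85 mm).
#' @param dr_mm,dz_mm table spacing (defaults 0.25 and 0.5 mm).
#' @param elements_per_wavelength piston surface sampling density
#'   (default 10; fewer than 10 warns of reduced accuracy).
#' @return A `piston_table`: list with vectors `r`, `z` and matrix
#'   `ratio` (`length(r)` x `length(z)`) of p/p0.
#' @export
rayleigh_piston_table <- function(a_mm = 5, medium = acoustic_medium(),
                                  protocol = sonication_protocol(),
                                  r_max_mm = 40, z_max_mm = 85,
                                  dr_mm = 0.25, dz_mm = 0.5,
                                  elements_per_wavelength = 10) {
  if (elements_per_wavelength < 10)
    warning("piston under-discretized (<10 elements per wavelength); ",
            "field accuracy reduced")
  lam <- wavelength_mm(medium, protocol)
  alpha <- attenuation_np_mm(medium, protocol)
  k <- 2 * pi / lam
  el <- piston_elements(a_mm, lam / elements_per_wavelength)
  r <- seq(0, r_max_mm, by = dr_mm)
  z <- seq(dz_mm, z_max_mm, by = dz_mm)
  pts_r <- rep(r, times = length(z))
  pts_z <- rep(z, each = length(r))
  acc <- complex(length.out = length(pts_r))
  idx <- seq_along(el$x)
  chunks <- split(idx, ceiling(idx / 250))
  for (ch in chunks) {
    dx <- outer(pts_r, el$x[ch], `-`)
    R <- sqrt(dx * dx + outer(pts_z^2, el$y[ch]^2, `+`))
    acc <- acc + (exp((1i * k - alpha) * R) / R) %*% el$area[ch]
  }
  ratio <- matrix(Mod(acc) * k / (2 * pi), nrow = length(r))
  structure(list(r = r, z = z, ratio = ratio, a_mm = a_mm,
                 wavelength_mm = lam, alpha_np_mm = alpha),
            class = "piston_table")
}

# bilinear interpolation of a piston table at (radial, axial) mm; 0 beyond
# the radial extent, clamped axially
interp_piston <- function(table, radial, axial) {
  out <- numeric(length(radial))
  ax <- pmin(pmax(axial, table$z[1]), table$z[length(table$z)])
  ok <- radial <= table$r[length(table$r)] & axial > 0
  if (!any(ok)) return(out)
  r <- radial[ok]; zz <- ax[ok]
  ir <- pmin(findInterval(r, table$r), length(table$r) - 1L)
  iz <- pmin(findInterval(zz, table$z), length(table$z) - 1L)
  fr <- (r - table$r[ir]) / (table$r[ir + 1L] - table$r[ir])
  fz <- (zz - table$z[iz]) / (table$z[iz + 1L] - table$z[iz])
  nr <- length(table$r)
  v00 <- table$ratio[cbind(ir, iz)]
  v10 <- table$ratio[cbind(ir + 1L, iz)]
  v01 <- table$ratio[cbind(ir, iz + 1L)]
  v11 <- table$ratio[cbind(ir + 1L, iz + 1L)]
  out[ok] <- (1 - fr) * (1 - fz) * v00 + fr * (1 - fz) * v10 +
    (1 - fr) * fz * v01 + fr * fz * v11
  out
}

#' Per-emitter acoustic pressure fields of the implant array
#'
#' Computes the steady-state peak-pressure magnitude field of each of the
#' nine emitters independently (the emitters fire sequentially, so fields
#' are never summed coherently) on a voxel grid, scaled to the protocol's
#' surface pressure. A single axisymmetric Rayleigh-Sommerfeld table is
#' computed per piston geometry and interpolated per emitter.
#'
#' @param array an [emitter_array()].
#' @param grid target [voxel_grid()] (in front of the implant plane).
#' @param medium an [acoustic_medium()].
#' @param protocol a [sonication_protocol()].
#' @param table optional precomputed [rayleigh_piston_table()].
#' @param ... passed to [rayleigh_piston_table()].
#' @return A `pressure_field`: list with `fields` (list of 9 arrays, MPa),
#'   `grid`, `protocol`, `medium`.
#' @export
rayleigh_field <- function(array, grid, medium = acoustic_medium(),
                           protocol = sonication_protocol(),
                           table = NULL, ...) {
  if (is.null(table)) {
    radius <- attr(array, "emitter_radius_mm")
    coords <- voxel_coords(grid)
    z_need <- max(vapply(1:9, function(k)
      max(emitter_cyl_coords(coords, array, k)$axial), numeric(1)))
    table <- rayleigh_piston_table(radius, medium, protocol,
                                   z_max_mm = max(85, z_need + 1), ...)
  }
  coords <- voxel_coords(grid)
  p0 <- protocol$surface_pressure_MPa
  fields <- lapply(1:9, function(k) {
    cc <- emitter_cyl_coords(coords, array, k)
    array(p0 * interp_piston(table, c(cc$radial), c(cc$axial)), grid$dim)
  })
  structure(list(fields = fields, grid = grid, protocol = protocol,
                 medium = medium, table = table),
            class = "pressure_field")
}

#' Thresholded BBB-disruption region of a pressure field
#'
#' @param field a [rayleigh_field()] result.
#' @param threshold_MPa disruption threshold (default 0.2 MPa).
#' @return List with `masks` (9 logical arrays `p > threshold`), `union`,
#'   and `n_beams` (integer array counting beams above threshold).
#' @export
bbbd_region <- function(field, threshold_MPa = 0.2) {
  masks <- lapply(field$fields, function(p) p > threshold_MPa)
  n_beams <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m),
                                                         dim(m))))
  list(masks = masks, union = n_beams > 0L, n_beams = n_beams)
}

#' Beam-overlap metrics of the sonicated volume
#'
#' Fraction of the sonicated volume (above threshold for at least one
#' emitter) that lies above threshold for two or more beams, and the
#' acoustic-energy deficit in the overlap zone: per-voxel energy is taken
#' proportional to `p^2 * duty_cycle` of the strongest single beam, and the
#' deficit is the best overlap voxel's energy relative to the global
#' maximum in the sonicated volume, as a signed percentage (negative:
#' overlap zones receive less energy than the field maximum because of
#' diffraction and attenuation before beams cross).
#'
#' @inheritParams bbbd_region
#' @return One-row tibble: `sonicated_mL`, `overlap_mL`,
#'   `overlap_fraction`, `overlap_pct`, `energy_deficit_pct`.
#' @export
overlap_metrics <- function(field, threshold_MPa = 0.2) {
  reg <- bbbd_region(field, threshold_MPa)
  if (!any(reg$union)) stop("empty sonicated volume", call. = FALSE)
  vv <- voxel_volume(field$grid) / 1000
  pmax_all <- Reduce(pmax, field$fields)
  energy <- pmax_all^2 * field$protocol$duty_cycle
  overlap <- reg$n_beams >= 2L
  e_max <- max(energy[reg$union])
  deficit <- if (any(overlap)) {
    100 * (max(energy[overlap]) - e_max) / e_max
  } else NA_real_
  tibble::tibble(
    sonicated_mL = sum(reg$union) * vv,
    overlap_mL = sum(overlap) * vv,
    overlap_fraction = sum(overlap) / sum(reg$union),
    overlap_pct = 100 * sum(overlap) / sum(reg$union),
    energy_deficit_pct = deficit
  )
}
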
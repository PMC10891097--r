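#' Synthetic head-phantom specification
#'
#' The phantom is geometric, not anatomical: the analyses under test depend
#' only on tissue labels and distances from the implant plane, so the brain
#' is modeled as a cylinder of tissue under the plate with depth-layered
#' labels — a subarachnoid/CSF rim at the surface, a gray-matter ribbon,
#' and a white-matter core — plus an optional spherical resection cavity
#' wrapped in enhancing tumor. Layer thicknesses are deliberately generous
#' so that subarachnoid-confined and gray-only openings can exceed the
#' 0.5 mL grading floor inside a 10-mm cylinder.
#'
#' @param shape grid shape (default `c(128, 128, 128)`).
#' @param voxel_mm isotropic voxel size (default 1.5).
#' @param rim_mm subarachnoid rim thickness (default 12).
#' @param gray_mm gray-matter ribbon thickness (default 12).
#' @param cavity_radius_mm resection-cavity radius, 0 for none (default 10).
#' @param tumor_thickness_mm enhancing-tumor shell thickness around the
#'   cavity (default 5).
#' @param cavity_center_mm world position of the cavity centre (default
#'   under a corner emitter).
#' @param texture_sd multiplicative T1w texture noise (default 0.05).
#' @param seed integer RNG seed; every phantom is a pure function of its
#'   spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), voxel_mm = 1.5,
                         rim_mm = 12, gray_mm = 12, cavity_radius_mm = 10,
                         tumor_thickness_mm = 5,
                         cavity_center_mm = c(58 / 3, 58 / 3, 25),
                         texture_sd = 0.05, seed = 1) {
  stopifnot(all(shape >= 8), voxel_mm > 0, rim_mm > 0, gray_mm > 0,
            cavity_radius_mm >= 0, tumor_thickness_mm >= 0, texture_sd >= 0)
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 rim_mm = rim_mm, gray_mm = gray_mm,
                 cavity_radius_mm = cavity_radius_mm,
                 tumor_thickness_mm = tumor_thickness_mm,
                 cavity_center_mm = cavity_center_mm,
                 texture_sd = texture_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# baseline T1w intensities per tissue label
T1W_BASE <- c(`1` = 300, `2` = 800, `3` = 1000, `4` = 200, `5` = 1100)

#' Generate a synthetic pre-sonication head phantom
#'
#' @param spec a [phantom_spec()].
#' @return List: `pre` (T1w array), `seg` (integer label array: 1
#'   subarachnoid, 2 gray, 3 white, 4 cavity, 5 tumor), `brain_mask`,
#'   `grid`. The grid is centred on the plate: the implant plane is z = 0,
#'   z grows into the brain, and z voxel centres sit at integer multiples
#'   of the voxel size starting on the plate plane.
#' @export
make_head_phantom <- function(spec = phantom_spec()) {
  d <- spec$shape
  v <- spec$voxel_mm
  grid <- voxel_grid(d, voxel_mm = v,
                     origin_mm = c(-(d[1] - 1) / 2 * v, -(d[2] - 1) / 2 * v, 0))
  co <- voxel_coords(grid)
  depth_max <- (d[3] - 1) * v
  if (spec$rim_mm + spec$gray_mm >= depth_max)
    stop("tissue layers exceed the grid depth", call. = FALSE)
  r_brain <- (min(d[1], d[2]) - 1) / 2 * v - 2
  brain <- (co$x^2 + co$y^2) <= r_brain^2 & co$z >= 0
  seg <- array(0L, d)
  seg[brain & co$z < spec$rim_mm] <- LBL_SUBARACHNOID
  seg[brain & co$z >= spec$rim_mm &
        co$z < spec$rim_mm + spec$gray_mm] <- LBL_GRAY
  seg[brain & co$z >= spec$rim_mm + spec$gray_mm] <- LBL_WHITE
  if (spec$cavity_radius_mm > 0) {
    cc <- spec$cavity_center_mm
    r2 <- (co$x - cc[1])^2 + (co$y - cc[2])^2 + (co$z - cc[3])^2
    tum_r <- spec$cavity_radius_mm + spec$tumor_thickness_mm
    seg[brain & r2 <= tum_r^2] <- LBL_TUMOR
    seg[brain & r2 <= spec$cavity_radius_mm^2] <- LBL_CAVITY
  }
  pre <- array(0, d)
  pre[brain] <- T1W_BASE[as.character(seg[brain])]
  if (spec$texture_sd > 0) {
    pre[brain] <- withr::with_seed(spec$seed,
      pre[brain] * (1 + stats::rnorm(sum(brain), 0, spec$texture_sd)))
  }
  list(pre = pre, seg = seg, brain_mask = brain, grid = grid)
}

#' Per-emitter opening plan for one synthetic sonication session
#'
#' @param grades character vector of length 9 with values `"none"`,
#'   `"subarachnoid"` (grade-1 pattern), `"gray"` (grade-2 pattern) or
#'   `"gray_white"` (grade-3 pattern).
#' @param e0 injected relative-enhancement amplitude at zero delay
#'   (default 0.3).
#' @param delay_min sonication-to-contrast delay in minutes (default 30).
#' @param half_time_h BBB half-closure time governing the amplitude decay
#'   with delay (default 1.3 h).
#' @param noise_sd multiplicative acquisition noise on the post image, as a
#'   fraction of baseline (default 0.02).
#' @param depth_mm axial truncation of the injected enhancement, measured
#'   from the plate plane (default `Inf` = full 75-mm cylinder).
#' @param seed RNG seed for the acquisition noise.
#' @return A `session_plan` list.
#' @export
session_plan <- function(grades = rep("gray_white", 9), e0 = 0.3,
                         delay_min = 30, half_time_h = 1.3,
                         noise_sd = 0.02, depth_mm = Inf, seed = 1) {
  grades <- match.arg(grades, c("none", "subarachnoid", "gray", "gray_white"),
                      several.ok = TRUE)
  if (length(grades) != 9)
    stop("a session plan needs exactly 9 per-emitter entries", call. = FALSE)
  stopifnot(e0 >= 0, delay_min >= 0, half_time_h > 0, noise_sd >= 0,
            depth_mm > 0)
  structure(list(grades = grades, e0 = e0, delay_min = delay_min,
                 half_time_h = half_time_h, noise_sd = noise_sd,
                 depth_mm = depth_mm, seed = as.integer(seed)),
            class = "session_plan")
}

plan_tissue_labels <- list(
  none = integer(0),
  subarachnoid = LBL_SUBARACHNOID,
  gray = LBL_GRAY,
  gray_white = c(LBL_GRAY, LBL_WHITE)
)

#' Inject a planned sonication session into a phantom
#'
#' Multiplies the baseline image by `1 + e_eff` inside each planned
#' emitter's 10 x 75 mm cylinder, restricted to the planned tissue classes
#' and to axial positions up to `depth_mm`, where
#' `e_eff = e0 * 2^(-delay / half_time)` models the BBB closing between
#' sonication and contrast injection. Multiplicative Gaussian acquisition
#' noise is then applied to the post image within the brain.
#'
#' @param phantom a [make_head_phantom()] result.
#' @param array an [emitter_array()].
#' @param plan a [session_plan()].
#' @param spec cylinder geometry (default [cylinder_spec()]).
#' @param rois optional precomputed ROI label map for `array` on the
#'   phantom grid (to avoid re-rasterizing across sessions).
#' @return List: `pre`, `post`, `grid`, `e_eff`.
#' @export
inject_session <- function(phantom, array, plan, spec = cylinder_spec(),
                           rois = NULL) {
  if (!inherits(plan, "session_plan")) stop("plan must be a session_plan",
                                            call. = FALSE)
  if (is.null(rois)) rois <- rasterize_cylinder_rois(array, phantom$grid, spec)
  check_same_grid(phantom$grid, rois$grid, "phantom and ROI map")
  e_eff <- plan$e0 * 2^(-plan$delay_min / 60 / plan$half_time_h)
  post <- phantom$pre
  coords <- NULL
  for (k in 1:9) {
    labs <- plan_tissue_labels[[plan$grades[k]]]
    if (length(labs) == 0) next
    region <- rois$labels == k & phantom$seg %in% labs
    if (is.finite(plan$depth_mm)) {
      if (is.null(coords)) coords <- voxel_coords(phantom$grid)
      region <- region &
        emitter_cyl_coords(coords, array, k)$axial <= plan$depth_mm
    }
    post[region] <- phantom$pre[region] * (1 + e_eff)
  }
  if (plan$noise_sd > 0) {
    b <- phantom$brain_mask
    post[b] <- withr::with_seed(plan$seed,
      post[b] * (1 + stats::rnorm(sum(b), 0, plan$noise_sd)))
  }
  list(pre = phantom$pre, post = post, grid = phantom$grid, e_eff = e_eff)
}

#' Simulate BBB-closure observations
#'
#' Sonication-to-contrast delays drawn uniformly on the study's observed
#' range, intensities on an exponential closure curve with additive
#' Gaussian noise.
#'
#' @param n number of sonications (default 31).
#' @param delay_range_min delay range in minutes (default `c(10, 77)`).
#' @param half_time_h true half-closure time (default 1.3).
#' @param e0 intensity at zero delay (default 1).
#' @param sigma noise standard deviation as a fraction of `e0`
#'   (default 0.15).
#' @param seed integer RNG seed (required).
#' @return Tibble: `session_id`, `delay_min`, `intensity`.
#' @export
simulate_closure_observations <- function(n = 31, delay_range_min = c(10, 77),
                                          half_time_h = 1.3, e0 = 1,
                                          sigma = 0.15, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n >= 3, delay_range_min[2] > delay_range_min[1])
  withr::with_seed(seed, {
    t <- stats::runif(n, delay_range_min[1], delay_range_min[2])
    e <- e0 * 2^(-t / 60 / half_time_h) + stats::rnorm(n, 0, sigma * e0)
    tibble::tibble(session_id = sprintf("S%03d", seq_len(n)),
                   delay_min = t, intensity = e)
  })
}

#' Growth-cohort specification
#'
#' Parameters of a synthetic tumor-growth cohort: per-patient true in-field
#' growth slopes are drawn from a normal (hence symmetric) distribution
#' whose median is `median_slope`, and monthly in-field volumes follow
#' `baseline + slope * month` plus measurement noise, floored at zero.
#' Out-of-field volumes share one slope across cohorts (the treatment
#' effect under study is in-field only). A positive `control_radius_mm`
#' suppresses mask growth within that distance of any emitter axis,
#' emulating local tumor control near the sonicated axes.
#'
#' @param n_patients cohort size.
#' @param median_slope median true in-field slope, mL/month.
#' @param slope_sd dispersion of true slopes, mL/month.
#' @param n_cycles_range inclusive range of monthly measurements per
#'   patient (default `c(4, 6)`).
#' @param baseline_mL in-field volume at month 0 (default 10).
#' @param noise_mL measurement noise sd (default 0.2).
#' @param outfield_baseline_mL,outfield_slope out-of-field volume model
#'   (defaults 5 and 1).
#' @param control_radius_mm near-axis growth-suppression radius (default 0
#'   = none).
#' @param cohort cohort label (e.g. `"C"` or `"D"`).
#' @param seed integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, median_slope, slope_sd,
                        n_cycles_range = c(4, 6), baseline_mL = 10,
                        noise_mL = 0.2, outfield_baseline_mL = 5,
                        outfield_slope = 1, control_radius_mm = 0,
                        cohort = "C", seed = 1) {
  stopifnot(n_patients >= 2, slope_sd >= 0, baseline_mL > 0, noise_mL >= 0,
            n_cycles_range[1] >= 2)
  structure(list(n_patients = as.integer(n_patients),
                 median_slope = median_slope, slope_sd = slope_sd,
                 n_cycles_range = as.integer(n_cycles_range),
                 baseline_mL = baseline_mL, noise_mL = noise_mL,
                 outfield_baseline_mL = outfield_baseline_mL,
                 outfield_slope = outfield_slope,
                 control_radius_mm = control_radius_mm,
                 cohort = cohort, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate one cohort's volume trajectories
#'
#' @param spec a [cohort_spec()].
#' @return Tibble: `patient_id`, `cohort`, `month`, `true_slope`,
#'   `infield_mL`, `outfield_mL`.
#' @export
simulate_growth_trajectories <- function(spec) {
  withr::with_seed(spec$seed, {
    purrr::map_dfr(seq_len(spec$n_patients), function(i) {
      slope <- stats::rnorm(1, spec$median_slope, spec$slope_sd)
      nc <- sample(seq(spec$n_cycles_range[1], spec$n_cycles_range[2]), 1)
      month <- 0:(nc - 1)
      tibble::tibble(
        patient_id = sprintf("%s%02d", spec$cohort, i),
        cohort = spec$cohort,
        month = month,
        true_slope = slope,
        infield_mL = pmax(0, spec$baseline_mL + slope * month +
                            stats::rnorm(nc, 0, spec$noise_mL)),
        outfield_mL = pmax(0, spec$outfield_baseline_mL +
                             spec$outfield_slope * month +
                             stats::rnorm(nc, 0, spec$noise_mL))
      )
    })
  })
}

# nearest-voxel tumor mask: take the m candidate voxels closest to `center`
# (among `allowed`) so that the voxel volume matches `target_mL`
grow_mask_to_volume <- function(order_idx, n_allowed, target_mL, vv_mL, dims) {
  m <- min(round(target_mL / vv_mL), n_allowed)
  mask <- array(FALSE, dims)
  if (m > 0) mask[order_idx[seq_len(m)]] <- TRUE
  mask
}

#' Simulate two tumor-growth cohorts
#'
#' Generates per-patient volume trajectories for both cohorts and, when
#' `masks = TRUE`, longitudinal voxel tumor masks consistent with the
#' in-field trajectories: each patient's tumor grows voxel-by-voxel around
#' a seed point near an emitter axis, with growth excluded within
#' `control_radius_mm` of any axis for cohorts that specify one (so
#' near-axis radial coverage is suppressed, as under effective local
#' control).
#'
#' @param spec_1,spec_2 two [cohort_spec()]s.
#' @param masks also generate first/last tumor masks per patient
#'   (default FALSE).
#' @param phantom,array phantom and emitter array used for mask growth
#'   (defaults: a 64^3, 1.5 mm phantom without cavity and the default
#'   array); only used when `masks = TRUE`.
#' @return List: `trajectories` (tibble), and when requested `masks` (named
#'   list per patient with `first`, `last` logical arrays), `grid`,
#'   `dmap` (the axis [axial_distance_map()]).
#' @export
simulate_growth_cohorts <- function(spec_1, spec_2, masks = FALSE,
                                    phantom = NULL, array = emitter_array()) {
  traj <- dplyr::bind_rows(simulate_growth_trajectories(spec_1),
                           simulate_growth_trajectories(spec_2))
  out <- list(trajectories = traj)
  if (masks) {
    if (is.null(phantom))
      phantom <- make_head_phantom(phantom_spec(shape = c(64, 64, 64),
                                                cavity_radius_mm = 0))
    grid <- phantom$grid
    vv <- voxel_volume(grid) / 1000
    dmap <- axial_distance_map(array, grid)
    co <- voxel_coords(grid)
    specs <- list(spec_1, spec_2)
    names(specs) <- c(spec_1$cohort, spec_2$cohort)
    centers_all <- array_centers(array)
    mask_list <- list()
    for (sp in specs) {
      pats <- unique(traj$patient_id[traj$cohort == sp$cohort])
      jit <- withr::with_seed(sp$seed + 10000L,
        matrix(stats::runif(3 * length(pats), -3, 3), ncol = 3))
      for (i in seq_along(pats)) {
        pid <- pats[i]
        rows <- traj[traj$patient_id == pid, ]
        # seed the tumor on the central emitter axis at mid-depth
        ctr <- centers_all[5, ] + c(0, 0, 35) + jit[i, ]
        d2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
        allowed <- phantom$brain_mask &
          (sp$control_radius_mm <= 0 | dmap$radial_mm > sp$control_radius_mm)
        ord <- which(allowed)[order(d2[allowed])]
        first <- grow_mask_to_volume(ord, length(ord),
                                     rows$infield_mL[1], vv, grid$dim)
        last <- grow_mask_to_volume(ord, length(ord),
                                    rows$infield_mL[nrow(rows)], vv, grid$dim)
        mask_list[[pid]] <- list(first = first, last = last)
      }
    }
    out$masks <- mask_list
    out$grid <- grid
    out$dmap <- dmap
    out$brain_mask <- phantom$brain_mask
  }
  out
}
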
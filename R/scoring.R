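#' Scoring configuration for automated BBB-opening grading
#'
#' Tunable constants of the per-emitter grading pipeline. Defaults follow the
#' published automated analysis: enhancement threshold at the upper 1% tail
#' of a non-sonicated control region, gradable openings above 0.5 mL, and
#' emitters facing mostly resection cavity or enhancing tumor excluded.
#'
#' @param control_tail_fraction fraction of control voxels allowed above the
#'   threshold (default 0.01, i.e. the 99th percentile of control
#'   enhancement).
#' @param min_graded_volume_mL enhanced volume required before any grade
#'   above 0 is assigned (default 0.5 mL).
#' @param exclusion_overlap_fraction an emitter is non-evaluable when cavity
#'   plus tumor occupy strictly more than this fraction of its cylinder
#'   (default 0.30).
#' @param subarachnoid_confinement_fraction grade 1 (subarachnoid-confined)
#'   when at least this fraction of enhanced voxels carry the subarachnoid
#'   label (default 0.90).
#' @param white_volume_for_grade3_mL grade 3 when enhanced white-matter
#'   volume exceeds this (default 0.25 mL), otherwise grade 2.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(control_tail_fraction = 0.01,
                           min_graded_volume_mL = 0.5,
                           exclusion_overlap_fraction = 0.30,
                           subarachnoid_confinement_fraction = 0.90,
                           white_volume_for_grade3_mL = 0.25) {
  stopifnot(control_tail_fraction > 0, control_tail_fraction < 1,
            exclusion_overlap_fraction > 0, exclusion_overlap_fraction < 1,
            subarachnoid_confinement_fraction > 0,
            subarachnoid_confinement_fraction < 1,
            min_graded_volume_mL > 0, white_volume_for_grade3_mL > 0)
  structure(list(control_tail_fraction = control_tail_fraction,
                 min_graded_volume_mL = min_graded_volume_mL,
                 exclusion_overlap_fraction = exclusion_overlap_fraction,
                 subarachnoid_confinement_fraction =
                   subarachnoid_confinement_fraction,
                 white_volume_for_grade3_mL = white_volume_for_grade3_mL),
            class = "scoring_config")
}

# tissue label codes shared by scoring and the phantom generator
LBL_SUBARACHNOID <- 1L
LBL_GRAY <- 2L
LBL_WHITE <- 3L
LBL_CAVITY <- 4L
LBL_TUMOR <- 5L

#' Relative gadolinium enhancement map from a pre/post T1w pair
#'
#' The post image is rescaled so that its median over a reference region
#' (normal brain away from the sonicated field and tumor) matches the pre
#' image's; the map is then the voxelwise relative signal change
#' `(post' - pre) / max(pre, eps)` inside the brain mask and 0 outside,
#' with `eps` set to 1% of the pre image's within-brain median.
#'
#' @param pre,post co-registered T1w arrays on `grid`.
#' @param grid their [voxel_grid()].
#' @param brain_mask logical array delimiting brain tissue.
#' @param reference_mask logical array of normal non-sonicated brain used for
#'   intensity normalization.
#' @return An `enhancement_map`: list with `map` (array of relative
#'   enhancement) and `grid`.
#' @export
compute_enhancement_map <- function(pre, post, grid, brain_mask,
                                    reference_mask) {
  if (!all(dim(pre) == grid$dim) || !all(dim(post) == grid$dim))
    stop("pre/post images must match the grid", call. = FALSE)
  if (!any(reference_mask)) stop("reference mask is empty", call. = FALSE)
  scale <- stats::median(pre[reference_mask]) /
    stats::median(post[reference_mask])
  post_n <- post * scale
  eps <- 0.01 * stats::median(pre[brain_mask])
  map <- array(0, grid$dim)
  map[brain_mask] <- (post_n[brain_mask] - pre[brain_mask]) /
    pmax(pre[brain_mask], eps)
  structure(list(map = map, grid = grid), class = "enhancement_map")
}

#' Enhancement detection threshold from a control region
#'
#' The threshold is the value exceeded by `control_tail_fraction` of the
#' control voxels, i.e. the (1 - fraction) quantile of control enhancement
#' (linear-interpolation quantile), floored at 0. With the default 0.01 this
#' is the "1st centile" rule: 1% of non-sonicated control tissue is allowed
#' above threshold.
#'
#' @param emap an [compute_enhancement_map()] result.
#' @param control_mask logical array of non-sonicated control tissue.
#' @param config a [scoring_config()].
#' @return Scalar threshold tau in relative-enhancement units.
#' @export
control_threshold <- function(emap, control_mask, config = scoring_config()) {
  vals <- emap$map[control_mask]
  if (length(vals) == 0) stop("control mask is empty", call. = FALSE)
  if (max(vals) == min(vals)) {
    warning("control region is constant; threshold degenerate")
    return(max(vals[1], 0))
  }
  tau <- stats::quantile(vals, 1 - config$control_tail_fraction,
                         names = FALSE, type = 7)
  max(tau, 0)
}

#' Which emitters are evaluable for grading
#'
#' An emitter is excluded when resection cavity plus pre-enhancing tumor
#' occupy more than `exclusion_overlap_fraction` of its cylinder.
#'
#' @param rois an [rasterize_cylinder_rois()] label map.
#' @param seg integer tissue label array (1 subarachnoid/CSF, 2 gray,
#'   3 white, 4 cavity, 5 enhancing tumor) on the same grid.
#' @param config a [scoring_config()].
#' @return Logical vector of length 9.
#' @export
evaluable_emitters <- function(rois, seg, config = scoring_config()) {
  bad <- seg == LBL_CAVITY | seg == LBL_TUMOR
  vapply(1:9, function(k) {
    m <- rois$labels == k
    n <- sum(m)
    if (n == 0) return(FALSE)
    sum(bad[m]) / n <= config$exclusion_overlap_fraction
  }, logical(1))
}

# grading of one evaluable emitter; enhanced voxels exclude tissue that was
# already enhancing before sonication (cavity rim / tumor labels)
score_one_emitter <- function(emap, tau, roi_mask_k, seg, config) {
  vv <- voxel_volume(emap$grid) / 1000 # mL per voxel
  enh <- emap$map > tau & roi_mask_k & seg != LBL_CAVITY & seg != LBL_TUMOR
  n_enh <- sum(enh)
  v_e <- n_enh * vv
  grade <- 0L
  if (v_e > config$min_graded_volume_mL) {
    frac_sas <- sum(seg[enh] == LBL_SUBARACHNOID) / n_enh
    if (frac_sas >= config$subarachnoid_confinement_fraction) {
      grade <- 1L
    } else {
      v_white <- sum(seg[enh] == LBL_WHITE) * vv
      grade <- if (v_white > config$white_volume_for_grade3_mL) 3L else 2L
    }
  }
  list(v_e = v_e, grade = grade, enh = enh)
}

#' Grade a single emitter
#'
#' Applies the 0-3 BBB-disruption grading scale to one evaluable emitter:
#' suprathreshold enhancement within the emitter's cylinder (in tissue not
#' enhancing before sonication) is measured; grade 0 when the enhanced
#' volume is at or below the 0.5 mL floor, grade 1 when it is above but
#' subarachnoid-confined, otherwise grade 2 (gray matter) or grade 3 (gray
#' and substantial white matter).
#'
#' @param emap an [compute_enhancement_map()] result.
#' @param tau threshold from [control_threshold()].
#' @param rois ROI label map.
#' @param emitter emitter index 1-9.
#' @inheritParams evaluable_emitters
#' @return One-row tibble: `emitter`, `evaluable`, `v_e_mL`, `grade`.
#' @export
score_emitter <- function(emap, tau, rois, emitter, seg,
                          config = scoring_config()) {
  if (is.null(tau) || is.na(tau)) stop("threshold tau is missing", call. = FALSE)
  res <- score_one_emitter(emap, tau, rois$labels == as.integer(emitter),
                           seg, config)
  tibble::tibble(emitter = as.integer(emitter), evaluable = TRUE,
                 v_e_mL = res$v_e, grade = res$grade)
}

#' Score one sonication session
#'
#' Runs the full per-emitter grading, the two-thirds session success rule,
#' the I90 intensity metric (90th percentile of relative enhancement over
#' the union of evaluable cylinders) and the opening-depth metric (largest
#' axial distance from the implant plane reached by suprathreshold
#' enhancement in an evaluable cylinder).
#'
#' @inheritParams score_emitter
#' @param array the [emitter_array()] (needed for axial depth coordinates).
#' @return A `bbbd_session` object; see [tidy.bbbd_session()] /
#'   [glance.bbbd_session()].
#' @export
score_session <- function(emap, tau, rois, seg, array,
                          config = scoring_config()) {
  if (is.null(tau) || is.na(tau)) stop("threshold tau is missing", call. = FALSE)
  evaluable <- evaluable_emitters(rois, seg, config)
  if (!any(evaluable))
    stop("undefined session: no evaluable emitter", call. = FALSE)
  coords <- voxel_coords(emap$grid)
  depth <- 0
  rows <- vector("list", 9)
  union_eval <- array(FALSE, emap$grid$dim)
  for (k in 1:9) {
    if (!evaluable[k]) {
      rows[[k]] <- tibble::tibble(emitter = k, evaluable = FALSE,
                                  v_e_mL = NA_real_, grade = NA_integer_)
      next
    }
    mk <- rois$labels == k
    union_eval <- union_eval | mk
    res <- score_one_emitter(emap, tau, mk, seg, config)
    rows[[k]] <- tibble::tibble(emitter = k, evaluable = TRUE,
                                v_e_mL = res$v_e, grade = res$grade)
    if (any(res$enh)) {
      cc <- emitter_cyl_coords(coords, array, k)
      depth <- max(depth, max(cc$axial[res$enh]))
    }
  }
  emitters <- dplyr::bind_rows(rows)
  n_eval <- sum(evaluable)
  n_open <- sum(emitters$grade >= 2L, na.rm = TRUE)
  i90 <- stats::quantile(emap$map[union_eval], 0.9, names = FALSE, type = 7)
  structure(list(emitters = emitters,
                 success = n_open / n_eval >= 2 / 3,
                 n_evaluable = n_eval, n_open = n_open,
                 I90 = i90, depth_mm = depth, tau = tau),
            class = "bbbd_session")
}

#' @export
print.bbbd_session <- function(x, ...) {
  cat("<bbbd_session> ", x$n_open, "/", x$n_evaluable,
      " evaluable emitters grade 2-3; success: ", x$success,
      "; I90 = ", format(x$I90, digits = 3),
      "; depth = ", format(x$depth_mm, digits = 4), " mm\n", sep = "")
  invisible(x)
}

#' Tidy per-emitter results of a scored session
#' @param x a `bbbd_session`.
#' @param ... unused.
#' @return Tibble with one row per emitter.
#' @export
tidy.bbbd_session <- function(x, ...) x$emitters

#' One-row session summary
#' @param x a `bbbd_session`.
#' @param ... unused.
#' @return Tibble: `success`, `n_open`, `n_evaluable`, `I90`, `depth_mm`,
#'   `tau`.
#' @export
glance.bbbd_session <- function(x, ...) {
  tibble::tibble(success = x$success, n_open = x$n_open,
                 n_evaluable = x$n_evaluable, I90 = x$I90,
                 depth_mm = x$depth_mm, tau = x$tau)
}
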
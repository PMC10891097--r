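#' In-field and out-of-field enhancing-tumor volumes
#'
#' Splits an enhancing-tumor mask into the part inside the sonication field
#' (the union of the margin-extended emitter cylinders) and the remainder of
#' the brain. The two volumes sum exactly to the total enhancing volume.
#'
#' @param tumor_mask logical array of contrast-enhancing tumor.
#' @param margin_rois ROI label map of the margin cylinders (typically
#'   [rasterize_cylinder_rois()] with `margin_mm = 5`).
#' @param brain_mask logical array of brain tissue.
#' @param grid the shared [voxel_grid()].
#' @return Tibble with `infield_mL`, `outfield_mL`, `total_mL`.
#' @export
infield_outfield_volumes <- function(tumor_mask, margin_rois, brain_mask,
                                     grid) {
  check_same_grid(grid, margin_rois$grid, "mask and ROI map")
  stopifnot(all(dim(tumor_mask) == grid$dim),
            all(dim(brain_mask) == grid$dim))
  field <- margin_rois$labels > 0L
  infield <- tumor_mask & field
  outfield <- tumor_mask & brain_mask & !field
  tibble::tibble(infield_mL = mask_volume_mL(infield, grid),
                 outfield_mL = mask_volume_mL(outfield, grid),
                 total_mL = mask_volume_mL(tumor_mask & (brain_mask | field),
                                           grid))
}

#' Per-patient tumor growth slopes
#'
#' Ordinary least-squares slope of enhancing-tumor volume against time for
#' each patient, from first sonication to end of treatment, in mL/month.
#' Patients with fewer than 2 time points are flagged (`NA` slope) and are
#' dropped from cohort summaries downstream.
#'
#' @param trajectories data frame with columns `patient_id`, `cohort`, a
#'   time column in months and a volume column in mL.
#' @param time_col,volume_col column names (defaults `"month"`,
#'   `"infield_mL"`).
#' @return Tibble: `patient_id`, `cohort`, `slope_mL_per_month`,
#'   `intercept_mL`, `n_points`.
#' @export
growth_slopes <- function(trajectories, time_col = "month",
                          volume_col = "infield_mL") {
  trajectories |>
    dplyr::group_by(.data$patient_id, .data$cohort) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      slope_mL_per_month = if (dplyr::n() >= 2) {
        stats::coef(stats::lm(.data[[volume_col]] ~ .data[[time_col]]))[[2]]
      } else NA_real_,
      intercept_mL = if (dplyr::n() >= 2) {
        stats::coef(stats::lm(.data[[volume_col]] ~ .data[[time_col]]))[[1]]
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::select("patient_id", "cohort", "slope_mL_per_month",
                  "intercept_mL", "n_points")
}

#' Compare growth slopes between two cohorts
#'
#' Cohort medians plus a two-sided Wilcoxon-Mann-Whitney rank-sum test
#' (exact when the combined sample is at most 20 without ties, normal
#' approximation with continuity correction otherwise). Patients with
#' missing slopes are excluded.
#'
#' @param slopes a [growth_slopes()] tibble (or any data frame with
#'   `cohort` and a value column).
#' @param value_col column to compare (default `"slope_mL_per_month"`).
#' @return One-row tibble: cohort labels, per-cohort `n` and medians,
#'   `statistic` (Mann-Whitney U for the first cohort), `p_value`, `exact`.
#' @export
cohort_slope_comparison <- function(slopes, value_col = "slope_mL_per_month") {
  ok <- !is.na(slopes[[value_col]])
  slopes <- slopes[ok, , drop = FALSE]
  groups <- sort(unique(as.character(slopes$cohort)))
  if (length(groups) != 2) stop("exactly two cohorts required", call. = FALSE)
  x <- slopes[[value_col]][slopes$cohort == groups[1]]
  y <- slopes[[value_col]][slopes$cohort == groups[2]]
  if (!length(x) || !length(y)) stop("both cohorts must be nonempty",
                                     call. = FALSE)
  res <- mann_whitney(x, y)
  tibble::tibble(cohort_1 = groups[1], cohort_2 = groups[2],
                 n_1 = length(x), n_2 = length(y),
                 median_1 = stats::median(x), median_2 = stats::median(y),
                 statistic = res$U, p_value = res$p, exact = res$exact)
}

# two-sided Wilcoxon-Mann-Whitney; exact null for combined n <= 20 and no
# ties, otherwise normal approximation with continuity correction
mann_whitney <- function(x, y) {
  if (length(unique(c(x, y))) == 1) # no evidence either way
    return(list(U = length(x) * length(y) / 2, p = 1, exact = FALSE))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Progression mask between first and last MRI
#'
#' Voxels enhancing on the last image but not at the first cycle.
#'
#' @param first_mask,last_mask co-registered logical arrays.
#' @param grid their shared [voxel_grid()] (used for a shape check).
#' @return Logical array.
#' @export
progression_mask <- function(first_mask, last_mask, grid = NULL) {
  if (!all(dim(first_mask) == dim(last_mask)))
    stop("first/last masks must share one grid", call. = FALSE)
  if (!is.null(grid) && !all(dim(first_mask) == grid$dim))
    stop("masks do not match the grid", call. = FALSE)
  last_mask & !first_mask
}

#' Radial coverage profile of a progression mask
#'
#' Fraction of each tube-shaped shell around the emitter axes covered by
#' the progression mask: `f_i = volume(mask & shell_i) / volume(shell_i)`.
#' Shells are restricted to brain tissue when a brain mask is supplied.
#'
#' @param prog_mask logical array (see [progression_mask()]).
#' @param shells list of shell masks from [tube_shell_masks()].
#' @param grid shared [voxel_grid()].
#' @param brain_mask optional logical array; shells are intersected with it.
#' @return Tibble: `bin` (label), `bin_lo`, `bin_hi`, `shell_mL`,
#'   `covered_mL`, `coverage` (NA for empty shells).
#' @export
radial_coverage_profile <- function(prog_mask, shells, grid,
                                    brain_mask = NULL) {
  edges <- strsplit(names(shells), "-", fixed = TRUE)
  purrr::imap_dfr(shells, function(shell, nm) {
    if (!is.null(brain_mask)) shell <- shell & brain_mask
    n_shell <- sum(shell)
    lohi <- as.numeric(strsplit(nm, "-", fixed = TRUE)[[1]])
    tibble::tibble(
      bin = nm, bin_lo = lohi[1], bin_hi = lohi[2],
      shell_mL = n_shell * voxel_volume(grid) / 1000,
      covered_mL = sum(prog_mask & shell) * voxel_volume(grid) / 1000,
      coverage = if (n_shell == 0) NA_real_ else sum(prog_mask & shell) / n_shell
    )
  })
}

#' Per-bin cohort comparison of radial coverage
#'
#' For each radial bin, a two-sided Mann-Whitney U test of the per-patient
#' coverage fractions between the two cohorts. Raw p-values are reported by
#' default (matching the published analysis); Holm adjustment is available
#' behind a flag.
#'
#' @param profiles data frame stacking per-patient
#'   [radial_coverage_profile()] rows with `patient_id` and `cohort`
#'   columns; all patients must share bin edges.
#' @param holm also report Holm-adjusted p-values (default FALSE).
#' @return Tibble with one row per bin: medians per cohort, `p_value`, and
#'   optionally `p_holm`.
#' @export
per_bin_cohort_test <- function(profiles, holm = FALSE) {
  groups <- sort(unique(as.character(profiles$cohort)))
  if (length(groups) != 2) stop("exactly two cohorts required", call. = FALSE)
  out <- profiles |>
    dplyr::filter(!is.na(.data$coverage)) |>
    dplyr::group_by(.data$bin, .data$bin_lo, .data$bin_hi) |>
    dplyr::summarise(
      n_1 = sum(.data$cohort == groups[1]),
      n_2 = sum(.data$cohort == groups[2]),
      median_1 = stats::median(.data$coverage[.data$cohort == groups[1]]),
      median_2 = stats::median(.data$coverage[.data$cohort == groups[2]]),
      p_value = mann_whitney(.data$coverage[.data$cohort == groups[1]],
                             .data$coverage[.data$cohort == groups[2]])$p,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin_lo)
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Plot radial coverage profiles by cohort
#'
#' @param profiles stacked per-patient profiles as in
#'   [per_bin_cohort_test()].
#' @return A ggplot object: coverage fraction against bin midpoint, one
#'   line per patient, coloured by cohort.
#' @export
plot_radial_coverage <- function(profiles) {
  profiles |>
    dplyr::mutate(mid = (.data$bin_lo + .data$bin_hi) / 2) |>
    ggplot2::ggplot(ggplot2::aes(.data$mid, .data$coverage,
                                 colour = .data$cohort,
                                 group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$cohort),
                          fun = stats::median, geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "distance to nearest emitter axis (mm)",
                  y = "fraction of shell covered by progression") +
    ggplot2::theme_minimal()
}
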
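dyn_fixture <- function() {
  arr <- emitter_array()
  g <- generic_grid(69, 1.5, depth = 60)
  margin <- rasterize_cylinder_rois(arr, g, cylinder_spec(margin_mm = 5))
  brain <- array(TRUE, g$dim)
  list(arr = arr, g = g, margin = margin, brain = brain,
       co = voxel_coords(g))
}

test_that("in-field plus out-of-field volumes conserve the total exactly", {
  fx <- dyn_fixture()
  field <- fx$margin$labels > 0L
  # tumor fully inside one margin cylinder
  t_in <- fx$margin$labels == 5L
  v <- infield_outfield_volumes(t_in, fx$margin, fx$brain, fx$g)
  expect_equal(v$outfield_mL, 0)
  expect_equal(v$infield_mL, v$total_mL)
  # tumor disjoint from all cylinders
  t_out <- !field & fx$co$x > 30
  v2 <- infield_outfield_volumes(t_out, fx$margin, fx$brain, fx$g)
  expect_equal(v2$infield_mL, 0)
  # a sphere straddling the field boundary splits exactly
  sph <- (fx$co$x - 25)^2 + fx$co$y^2 + (fx$co$z - 30)^2 <= 12^2
  v3 <- infield_outfield_volumes(sph, fx$margin, fx$brain, fx$g)
  expect_equal(v3$infield_mL + v3$outfield_mL, v3$total_mL, tolerance = 1e-12)
  expect_gt(v3$infield_mL, 0); expect_gt(v3$outfield_mL, 0)
  # random masks: conservation holds voxel-exactly
  set.seed(1)
  rnd <- array(stats::runif(prod(fx$g$dim)) < 0.1, fx$g$dim)
  v4 <- infield_outfield_volumes(rnd, fx$margin, fx$brain, fx$g)
  expect_equal(v4$infield_mL + v4$outfield_mL, v4$total_mL, tolerance = 1e-12)
})

test_that("growth slopes are exact on lines and flagged for short series", {
  traj <- tibble::tibble(patient_id = rep(c("A", "B", "C"), c(4, 3, 1)),
                         cohort = "C",
                         month = c(0:3, 0:2, 0),
                         infield_mL = c(10, 12, 14, 16, 5, 5, 5, 9))
  sl <- growth_slopes(traj)
  expect_equal(sl$slope_mL_per_month[sl$patient_id == "A"], 2.0)
  expect_equal(sl$slope_mL_per_month[sl$patient_id == "B"], 0.0)
  expect_true(is.na(sl$slope_mL_per_month[sl$patient_id == "C"]))
})

test_that("slope estimation is unbiased and unit-consistent", {
  est <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      m <- 0:5
      v <- 4 + 2.31 * m + stats::rnorm(6, 0, 0.5)
      stats::coef(stats::lm(v ~ m))[[2]]
    })
  }, numeric(1))
  expect_lt(abs(mean(est) - 2.31), 0.06)
  # invariance to volume offsets, linear scaling with units
  traj <- tibble::tibble(patient_id = "A", cohort = "C", month = 0:4,
                         infield_mL = c(3, 5, 4, 8, 9))
  s0 <- growth_slopes(traj)$slope_mL_per_month
  traj2 <- dplyr::mutate(traj, infield_mL = infield_mL + 100)
  expect_equal(growth_slopes(traj2)$slope_mL_per_month, s0)
  traj3 <- dplyr::mutate(traj, infield_mL = infield_mL * 1000)
  expect_equal(growth_slopes(traj3)$slope_mL_per_month, s0 * 1000)
})

test_that("cohort slope comparison matches the exact rank-sum oracle", {
  sl <- tibble::tibble(patient_id = letters[1:6],
                       cohort = rep(c("C", "D"), each = 3),
                       slope_mL_per_month = c(3, 4, 5, 0, 1, 2))
  cmp <- cohort_slope_comparison(sl)
  expect_equal(cmp$statistic, 9) # complete separation
  expect_equal(cmp$p_value, 0.1, tolerance = 1e-12)
  expect_equal(cmp$p_value, oracle_mw_p(c(3, 4, 5), c(0, 1, 2)),
               tolerance = 1e-12)
  expect_equal(cmp$median_1, 4)
  # identical cohorts -> p = 1
  sl2 <- tibble::tibble(patient_id = letters[1:6],
                        cohort = rep(c("C", "D"), 3),
                        slope_mL_per_month = c(1.3, 1.3, 2.7, 2.7, 9, 9))
  expect_equal(cohort_slope_comparison(sl2)$p_value, 1)
  expect_equal(stats::median(c(1, 2.31, 5)), 2.31)
})

test_that("progression mask is the voxelwise set difference", {
  fx <- dyn_fixture()
  first <- fx$co$x^2 + fx$co$y^2 + (fx$co$z - 30)^2 <= 100
  shell <- !first & fx$co$x^2 + fx$co$y^2 + (fx$co$z - 30)^2 <= 225
  expect_true(all(progression_mask(first, first) == FALSE))
  expect_identical(progression_mask(first, first | shell), shell)
  set.seed(2)
  a <- array(stats::runif(prod(fx$g$dim)) < 0.2, fx$g$dim)
  b <- array(stats::runif(prod(fx$g$dim)) < 0.2, fx$g$dim)
  pm <- progression_mask(a, b)
  expect_equal(sum(pm), sum(b) - sum(a & b))
  expect_error(progression_mask(a, b[, , 1:10]), "share")
})

test_that("radial coverage profile is exact on constructed masks", {
  fx <- dyn_fixture()
  dm <- axial_distance_map(fx$arr, fx$g, max_length_mm = 75)
  shells <- tube_shell_masks(dm, c(0, 2.5, 5, 7.5, 10))
  all_mask <- array(TRUE, fx$g$dim)
  p1 <- radial_coverage_profile(all_mask, shells, fx$g)
  expect_true(all(p1$coverage == 1))
  p0 <- radial_coverage_profile(array(FALSE, fx$g$dim), shells, fx$g)
  expect_true(all(p0$coverage == 0))
  # mask equal to the 0-5 mm tube -> full coverage in 0-5, zero beyond
  tube5 <- tube_shell_masks(dm, c(0, 5))[[1]]
  p5 <- radial_coverage_profile(tube5, shells, fx$g)
  expect_equal(p5$coverage, c(1, 1, 0, 0))
})

test_that("per-bin cohort tests detect near-axis suppression only", {
  spec_c <- cohort_spec(14, 2.31, 1.0, cohort = "C", seed = 41,
                        baseline_mL = 12)
  spec_d <- cohort_spec(12, 0.54, 0.5, cohort = "D", seed = 42,
                        baseline_mL = 12, control_radius_mm = 10)
  hits <- 0L
  n_rep <- 5L
  for (r in seq_len(n_rep)) {
    spec_c$seed <- 41L + 100L * r
    spec_d$seed <- 42L + 100L * r
    sim <- simulate_growth_cohorts(spec_c, spec_d, masks = TRUE)
    shells <- tube_shell_masks(sim$dmap, seq(0, 20, by = 2.5))
    profs <- purrr::imap_dfr(sim$masks, function(m, pid) {
      pr <- radial_coverage_profile(progression_mask(m$first, m$last),
                                    shells, sim$grid, sim$brain_mask)
      pr$patient_id <- pid
      pr$cohort <- substr(pid, 1, 1)
      pr
    })
    tst <- per_bin_cohort_test(profs)
    near <- tst$p_value[tst$bin_lo < 7.5]
    far <- tst$p_value[tst$bin_lo >= 15]
    if (all(near < 0.05) && all(far > 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("identical cohorts give p = 1 in every bin", {
  prof <- tidyr::expand_grid(patient_id = sprintf("P%d", 1:6),
                             tibble::tibble(bin_lo = c(0, 5),
                                            bin_hi = c(5, 10)))
  prof <- dplyr::mutate(prof, bin = paste0(bin_lo, "-", bin_hi),
                        cohort = rep(c("C", "D"), each = 6),
                        coverage = rep(c(0.2, 0.4), 6))
  tst <- per_bin_cohort_test(prof)
  expect_true(all(tst$p_value == 1))
  # single bin, complete separation at 3+3 -> exact p = 0.1
  prof2 <- tibble::tibble(patient_id = sprintf("P%d", 1:6),
                          cohort = rep(c("C", "D"), each = 3),
                          bin = "0-5", bin_lo = 0, bin_hi = 5,
                          coverage = c(0.5, 0.6, 0.7, 0.1, 0.2, 0.3))
  expect_equal(per_bin_cohort_test(prof2)$p_value, 0.1, tolerance = 1e-12)
  t_holm <- per_bin_cohort_test(prof2, holm = TRUE)
  expect_true("p_holm" %in% names(t_holm))
})
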
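# shared tiny fixture: one emitter array on a small generic grid with a
# layered segmentation, built in code
scoring_fixture <- function(vox = 1.5) {
  arr <- emitter_array()
  spec <- small_phantom_spec()
  phantom <- make_head_phantom(spec)
  rois <- rasterize_cylinder_rois(arr, phantom$grid)
  control <- phantom$brain_mask & rois$labels == 0L &
    phantom$seg != 4L & phantom$seg != 5L
  list(arr = arr, phantom = phantom, rois = rois, control = control)
}

test_that("enhancement map is zero for identical or globally rescaled images", {
  fx <- scoring_fixture()
  ph <- fx$phantom
  em1 <- compute_enhancement_map(ph$pre, ph$pre, ph$grid, ph$brain_mask,
                                 fx$control)
  expect_true(all(em1$map == 0))
  em2 <- compute_enhancement_map(ph$pre, 1.2 * ph$pre, ph$grid,
                                 ph$brain_mask, fx$control)
  expect_lt(max(abs(em2$map)), 1e-12)
})

test_that("enhancement map recovers a known relative step", {
  g <- voxel_grid(c(20, 20, 20), voxel_mm = 2, origin_mm = c(-19, -19, 1))
  brain <- array(TRUE, g$dim)
  pre <- array(100, g$dim)
  post <- pre
  cyl <- voxel_coords(g)$x^2 + voxel_coords(g)$y^2 <= 25
  post[cyl] <- 130
  em <- compute_enhancement_map(pre, post, g, brain, brain & !cyl)
  expect_equal(unique(em$map[cyl]), 0.30, tolerance = 1e-12)
  expect_true(all(em$map[!cyl] == 0))
})

test_that("enhancement map rejects empty reference and wrong grids", {
  g <- voxel_grid(c(4, 4, 4))
  a <- array(1, g$dim)
  expect_error(compute_enhancement_map(a, a, g, a > 0, a > 2), "empty")
  expect_error(compute_enhancement_map(array(1, c(3, 3, 3)), a, g, a > 0,
                                       a > 0), "match the grid")
})

test_that("control threshold follows the upper-tail quantile convention", {
  g <- voxel_grid(c(10, 10, 1))
  mk_emap <- function(v) {
    m <- array(0, c(10, 10, 1)); m[seq_along(v)] <- v
    structure(list(map = m, grid = g), class = "enhancement_map")
  }
  ctrl <- array(FALSE, c(10, 10, 1)); ctrl[1:100] <- TRUE
  # all zero -> 0 (degenerate, warns)
  expect_warning(tau0 <- control_threshold(mk_emap(rep(0, 100)), ctrl),
                 "degenerate")
  expect_equal(tau0, 0)
  # 100 evenly spaced values: type-7 99th percentile = 0.9801
  vals <- seq(0, 0.99, by = 0.01)
  expect_equal(control_threshold(mk_emap(vals), ctrl), 0.9801,
               tolerance = 1e-9)
  expect_equal(control_threshold(mk_emap(vals), ctrl),
               sort(vals)[99] + 0.01 * 0.01, tolerance = 1e-9) # brute force
})

test_that("Gaussian control tail reproduces the 2.326-sigma quantile", {
  g <- voxel_grid(c(40, 40, 40))
  set.seed(5)
  sigma <- 0.04
  m <- array(rnorm(40^3, 0, sigma), g$dim)
  emap <- structure(list(map = m, grid = g), class = "enhancement_map")
  tau <- control_threshold(emap, array(TRUE, g$dim))
  expect_equal(tau, qnorm(0.99) * sigma, tolerance = 0.02)
})

test_that("emitters facing cavity or tumor are excluded by the overlap rule", {
  arr <- emitter_array()
  g <- generic_grid(69, 1.5, depth = 55)
  rois <- rasterize_cylinder_rois(arr, g)
  seg <- array(2L, g$dim)
  expect_true(all(evaluable_emitters(rois, seg)))
  # fill 50% of emitter 1 cylinder with cavity -> excluded at default 0.30
  m1 <- which(rois$labels == 1L)
  seg50 <- seg; seg50[m1[seq_len(round(0.5 * length(m1)))]] <- 4L
  ev <- evaluable_emitters(rois, seg50)
  expect_false(ev[1]); expect_true(all(ev[-1]))
  # fraction exactly at the threshold stays evaluable (strict >)
  cfg <- scoring_config(exclusion_overlap_fraction = 0.5)
  n_half <- floor(0.5 * length(m1))
  seg_half <- seg; seg_half[m1[seq_len(n_half)]] <- 4L
  expect_true(evaluable_emitters(rois, seg_half, cfg)[1])
})

test_that("grading rules split 0/1/2/3 as specified", {
  # direct construction on a 1-mm grid: 1 voxel = 0.001 mL
  g <- voxel_grid(c(30, 30, 30), voxel_mm = 1, origin_mm = c(0.3, 0.3, 0.3))
  rois <- structure(list(labels = array(1L, g$dim), grid = g),
                    class = "roi_label_map")
  mk <- function(n_enh, labels_of_enh) {
    map <- array(0, g$dim)
    seg <- array(2L, g$dim)
    map[seq_len(n_enh)] <- 1
    seg[seq_len(n_enh)] <- labels_of_enh
    list(emap = structure(list(map = map, grid = g),
                          class = "enhancement_map"), seg = seg)
  }
  tau <- 0.5
  # 0.4 mL -> grade 0 (below the >0.5 mL floor)
  f <- mk(400, 2L)
  expect_equal(score_emitter(f$emap, tau, rois, 1, f$seg)$grade, 0L)
  # 2.0 mL, 95% subarachnoid -> grade 1
  f <- mk(2000, rep(c(1L, 2L), c(1900, 100)))
  expect_equal(score_emitter(f$emap, tau, rois, 1, f$seg)$grade, 1L)
  # 2.0 mL with 0.8 mL white -> grade 3; with 0.1 mL white -> grade 2
  f <- mk(2000, rep(c(2L, 3L), c(1200, 800)))
  expect_equal(score_emitter(f$emap, tau, rois, 1, f$seg)$grade, 3L)
  f <- mk(2000, rep(c(2L, 3L), c(1900, 100)))
  expect_equal(score_emitter(f$emap, tau, rois, 1, f$seg)$grade, 2L)
  # missing threshold is an error
  expect_error(score_emitter(f$emap, NA, rois, 1, f$seg), "tau")
})

test_that("session success applies the two-thirds rule inclusively", {
  fx <- scoring_fixture()
  ph <- fx$phantom
  # 6 of 9 emitters open (grades 2-3): exactly two thirds -> success
  plan <- session_plan(c(rep("gray_white", 3), rep("gray", 3),
                         "subarachnoid", "none", "none"), seed = 3)
  ses <- inject_session(ph, fx$arr, plan, rois = fx$rois)
  emap <- compute_enhancement_map(ses$pre, ses$post, ph$grid, ph$brain_mask,
                                  fx$control)
  tau <- control_threshold(emap, fx$control)
  sc <- score_session(emap, tau, fx$rois, ph$seg, fx$arr)
  expect_identical(sc$emitters$grade, c(3L, 3L, 3L, 2L, 2L, 2L, 1L, 0L, 0L))
  expect_true(sc$success)
  expect_equal(sc$n_open, 6)
  expect_gt(sc$I90, 0)
})

test_that("a session with no enhancement has grade 0 everywhere, zero depth", {
  fx <- scoring_fixture()
  ph <- fx$phantom
  plan <- session_plan(rep("none", 9), noise_sd = 0, seed = 1)
  ses <- inject_session(ph, fx$arr, plan, rois = fx$rois)
  emap <- compute_enhancement_map(ses$pre, ses$post, ph$grid, ph$brain_mask,
                                  fx$control)
  sc <- score_session(emap, 0.05, fx$rois, ph$seg, fx$arr)
  expect_true(all(sc$emitters$grade == 0L))
  expect_false(sc$success)
  expect_equal(sc$depth_mm, 0)
})

test_that("depth metric returns the injected axial truncation exactly", {
  arr <- emitter_array()
  ph <- make_head_phantom(phantom_spec(shape = c(72, 72, 80), voxel_mm = 1,
                                       cavity_radius_mm = 0))
  rois <- rasterize_cylinder_rois(arr, ph$grid)
  control <- ph$brain_mask & rois$labels == 0L
  # depth = max axial coordinate of any suprathreshold voxel, so the
  # identity construction fills cylinders noiselessly up to the truncation
  plan <- session_plan(rep("gray_white", 9), depth_mm = 64, noise_sd = 0,
                       seed = 2)
  ses <- inject_session(ph, arr, plan, rois = rois)
  emap <- compute_enhancement_map(ses$pre, ses$post, ph$grid, ph$brain_mask,
                                  control)
  tau <- suppressWarnings(control_threshold(emap, control))
  sc <- score_session(emap, tau, rois, ph$seg, arr)
  expect_equal(sc$depth_mm, 64)
})

test_that("scoring is monotone in injected amplitude", {
  fx <- scoring_fixture()
  ph <- fx$phantom
  res <- lapply(c(0.12, 0.3, 0.6), function(e0) {
    plan <- session_plan(c(rep("gray_white", 2), rep("gray", 2),
                           rep("subarachnoid", 2), rep("none", 3)),
                         e0 = e0, seed = 9)
    ses <- inject_session(ph, fx$arr, plan, rois = fx$rois)
    emap <- compute_enhancement_map(ses$pre, ses$post, ph$grid,
                                    ph$brain_mask, fx$control)
    # fixed tau across amplitudes isolates the monotonicity of the metrics
    score_session(emap, 0.05, fx$rois, ph$seg, fx$arr)
  })
  for (i in 2:3) {
    expect_true(all(res[[i]]$emitters$v_e_mL >= res[[i - 1]]$emitters$v_e_mL))
    expect_true(all(res[[i]]$emitters$grade >= res[[i - 1]]$emitters$grade))
    expect_gte(res[[i]]$I90, res[[i - 1]]$I90)
    expect_gte(res[[i]]$depth_mm, res[[i - 1]]$depth_mm)
  }
})

test_that("enhancement outside all cylinders changes no emitter result", {
  fx <- scoring_fixture()
  ph <- fx$phantom
  plan <- session_plan(c(rep("gray", 4), rep("none", 5)), noise_sd = 0,
                       seed = 4)
  ses <- inject_session(ph, fx$arr, plan, rois = fx$rois)
  base_emap <- compute_enhancement_map(ses$pre, ses$post, ph$grid,
                                       ph$brain_mask, fx$control)
  sc0 <- score_session(base_emap, 0.05, fx$rois, ph$seg, fx$arr)
  # add strong enhancement in a far-out blob outside every cylinder
  co <- voxel_coords(ph$grid)
  blob <- ph$brain_mask & fx$rois$labels == 0L &
    (co$x - 40)^2 + (co$y - 40)^2 + (co$z - 40)^2 <= 100
  expect_gt(sum(blob), 0)
  post2 <- ses$post
  post2[blob] <- post2[blob] * 1.5
  emap2 <- compute_enhancement_map(ses$pre, post2, ph$grid, ph$brain_mask,
                                   fx$control & !blob)
  sc2 <- score_session(emap2, 0.05, fx$rois, ph$seg, fx$arr)
  expect_equal(sc2$emitters, sc0$emitters)
})

test_that("I90 lies between the extremes of the evaluated region", {
  fx <- scoring_fixture()
  ph <- fx$phantom
  plan <- session_plan(rep("gray_white", 9), seed = 8)
  ses <- inject_session(ph, fx$arr, plan, rois = fx$rois)
  emap <- compute_enhancement_map(ses$pre, ses$post, ph$grid, ph$brain_mask,
                                  fx$control)
  tau <- control_threshold(emap, fx$control)
  sc <- score_session(emap, tau, fx$rois, ph$seg, fx$arr)
  u <- emap$map[fx$rois$labels > 0L]
  expect_gte(sc$I90, min(u))
  expect_lte(sc$I90, max(u))
})

test_that("a session with zero evaluable emitters is an error", {
  fx <- scoring_fixture()
  seg_all_cavity <- array(4L, fx$phantom$grid$dim)
  emap <- structure(list(map = array(0, fx$phantom$grid$dim),
                         grid = fx$phantom$grid), class = "enhancement_map")
  expect_error(score_session(emap, 0.05, fx$rois, seg_all_cavity, fx$arr),
               "no evaluable")
})
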
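test_that("an exactly embedded template is found with score 1", {
  withr::with_seed(60, tpl <- matrix(runif(11 * 9), 11, 9))
  img <- matrix(0, 50, 50)
  img[20:30, 33:41] <- tpl
  loc <- match_template(img, tpl)
  expect_identical(loc$row, 20L)
  expect_identical(loc$col, 33L)
  expect_equal(loc$score, 1)
  expect_false(loc$low_confidence)
})

test_that("the window contract restricts and flags the search", {
  withr::with_seed(61, tpl <- matrix(runif(64), 8, 8))
  withr::with_seed(62, img <- matrix(rnorm(2500, sd = 0.05), 50, 50))
  img[10:17, 10:17] <- img[10:17, 10:17] + tpl
  # a window that excludes the true position returns an in-window peak
  loc <- match_template(img, tpl, window = c(25, 50, 25, 50))
  expect_gte(loc$row, 25); expect_lte(loc$row + 7, 50)
  expect_gte(loc$col, 25); expect_lte(loc$col + 7, 50)
  expect_lt(loc$score, 1)
  expect_true(loc$low_confidence)
  # window smaller than the template is rejected
  expect_error(match_template(img, tpl, window = c(1, 5, 1, 5)), "window")
})

test_that("noisy matching equals the exhaustive oracle", {
  withr::with_seed(63, tpl <- matrix(runif(100, 0, 1), 10, 10))
  img <- matrix(0.5, 60, 60)
  img[23:32, 41:50] <- tpl
  withr::with_seed(64, img <- img + matrix(rnorm(3600, sd = 0.05), 60, 60))
  loc <- match_template(img, tpl)
  ref <- ncc_scan_ref(img, tpl)
  pk <- which(ref == max(ref), arr.ind = TRUE)[1, ]
  expect_identical(c(loc$row, loc$col), unname(as.integer(pk)))
  expect_identical(c(loc$row, loc$col), c(23L, 41L))
  expect_equal(loc$score, max(ref), tolerance = 1e-10)
})

test_that("sub-pixel refinement stays within half a pixel", {
  withr::with_seed(65, {
    for (k in 1:10) {
      tpl <- matrix(runif(81), 9, 9)
      img <- matrix(rnorm(1600, sd = 0.1), 40, 40)
      r <- sample(5:25, 1); c <- sample(5:25, 1)
      img[r:(r + 8), c:(c + 8)] <- img[r:(r + 8), c:(c + 8)] + tpl
      l0 <- match_template(img, tpl, subpixel = FALSE)
      l1 <- match_template(img, tpl, subpixel = TRUE)
      expect_identical(c(l1$row, l1$col), c(l0$row, l0$col))
      expect_lte(abs(l1$center_row - l0$center_row), 0.5)
      expect_lte(abs(l1$center_col - l0$center_col), 0.5)
    }
  })
})

test_that("pixel offsets convert to isocenter millimetres linearly", {
  geom <- projection_geometry()
  expect_identical(pixels_to_mm(0, geom), 0)
  expect_identical(pixels_to_mm(10, geom), 10 * 0.4 * 1000 / 1876)
  expect_equal(pixels_to_mm(10, geom), 2.1322, tolerance = 1e-4)
  expect_equal(pixels_to_mm(1, geom), 0.21322, tolerance = 1e-4)
  px <- c(-3, 0.5, 7)
  expect_equal(pixels_to_mm(px, geom), px * pixels_to_mm(1, geom))
})

test_that("evaluate_tracking reproduces hand-computed summaries", {
  geom <- projection_geometry()
  mmpx <- pixels_to_mm(1, geom)
  traj <- data.frame(frame = 0:1, u_px = c(100, 110), v_px = c(90, 95),
                     ncc_peak = 0.9, flag = "ok")
  attr(traj, "geometry") <- geom
  truth <- data.frame(frame = 0:1, true_u_px = traj$u_px,
                      true_v_px = traj$v_px)
  ev <- evaluate_tracking(traj, truth)
  expect_identical(ev$max_mm, 0)
  expect_identical(ev$mean_mm, 0)
  # constant 1 mm offset on every frame
  truth1 <- truth; truth1$true_u_px <- truth$true_u_px - 1 / mmpx
  ev1 <- evaluate_tracking(traj, truth1)
  expect_equal(ev1$max_mm, 1, tolerance = 1e-12)
  expect_equal(ev1$mean_mm, 1, tolerance = 1e-12)
  # mixed 0.5 / 1.5 mm offsets
  truth2 <- truth
  truth2$true_v_px <- truth$true_v_px + c(0.5, 1.5) / mmpx
  ev2 <- evaluate_tracking(traj, truth2)
  expect_equal(ev2$max_mm, 1.5, tolerance = 1e-12)
  expect_equal(ev2$mean_mm, 1.0, tolerance = 1e-12)
  expect_gte(ev2$max_mm, ev2$mean_mm)
  expect_error(evaluate_tracking(traj, truth[1, ]), "length")
})

# Shared pieces for the end-to-end fixtures below.
plan_drrs <- function(phantom, geom) {
  spec <- phantom$spec
  ct_plan <- remove_markers_volume(
    phantom$ct, phantom$marker_centers,
    radius_mm = spec$marker_diameter / 2 + max(spec$voxel_mm))
  split <- split_volume(ct_plan, phantom$tumor_mask, "shell")
  list(bg = compute_drr(split$background, geom),
       tumor = compute_drr(split$tumor_only, geom),
       centroid = tiletrack:::mask_centroid_mm(phantom$tumor_mask))
}

e2e_options <- function(phantom, geom, ...) {
  spec <- phantom$spec
  mag <- geom$sdd / geom$sad
  extent <- max(spec$tumor_diameter, spec$tumor_height) * mag / geom$pitch
  track_options(
    tile_px = recommend_tile_size(extent),
    markers = list(
      template = marker_template(spec$marker_diameter / 2 * mag / geom$pitch),
      count = nrow(phantom$marker_centers)),
    ...)
}

test_that("a distortion-free frame is located within one pixel of truth", {
  phantom <- default_phantom()
  geom <- projection_geometry(detector_px = c(256L, 256L), pitch = 1.6,
                              gantry_deg = 30, imager_deg = 45, step_mm = 1)
  pd <- plan_drrs(phantom, geom)
  disp <- c(4, -2, 6)
  sim <- simulate_kv_projection(phantom$ct, phantom$tumor_mask, geom, disp)
  traj <- track_sequence(list(sim$projection), pd$bg, pd$tumor, geom,
                         e2e_options(phantom, geom),
                         planning_center_mm = pd$centroid)
  expect_identical(traj$flag, "ok")
  expect_lt(abs(traj$u_px - sim$truth$u_px), 1)
  expect_lt(abs(traj$v_px - sim$truth$v_px), 1)
})

test_that("a static sequence returns identical locations on every frame", {
  phantom <- default_phantom()
  geom <- projection_geometry(detector_px = c(256L, 256L), pitch = 1.6,
                              gantry_deg = 120, imager_deg = -45, step_mm = 1)
  pd <- plan_drrs(phantom, geom)
  sim <- simulate_kv_projection(phantom$ct, phantom$tumor_mask, geom,
                                c(0, 0, 0))
  traj <- track_sequence(rep(list(sim$projection), 3), pd$bg, pd$tumor,
                         geom, e2e_options(phantom, geom),
                         planning_center_mm = pd$centroid)
  expect_identical(traj$flag, rep("ok", 3))
  expect_identical(traj$u_px, rep(traj$u_px[1], 3))
  expect_identical(traj$v_px, rep(traj$v_px[1], 3))
})

test_that("a 20-frame sinusoid is recovered with r > 0.99", {
  phantom <- default_phantom()
  geom <- projection_geometry(detector_px = c(256L, 256L), pitch = 1.6,
                              gantry_deg = 0, imager_deg = 45, step_mm = 1)
  pattern <- motion_pattern("sinusoid", amplitude_mm = c(3, 2, 20),
                            period_s = 4, frame_rate_hz = 5, n_frames = 20L)
  distortion <- distortion_spec(gamma = 1.3, bias_amplitude = 0.1,
                                bias_scale_px = 64, noise_sd = 0.02,
                                seed = 9L)
  sim <- simulate_kv_sequence(phantom, geom, pattern, distortion)
  pd <- plan_drrs(phantom, geom)
  traj <- track_sequence(sim$projections, pd$bg, pd$tumor, geom,
                         e2e_options(phantom, geom, subpixel = TRUE),
                         planning_center_mm = pd$centroid)
  expect_true(all(traj$flag == "ok"))
  # z motion dominates the v axis on a +/-45 degree imager
  expect_gt(stats::cor(traj$v_px, sim$truth$true_v_px), 0.99)
})
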
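test_that("split_volume partitions the planning volume", {
  a <- array(runif(6 * 5 * 4), c(6, 5, 4))
  ct <- volume3d(a, c(1, 1, 1))
  empty <- volume3d(array(0, dim(a)), c(1, 1, 1))
  sv <- split_volume(ct, empty)
  expect_identical(sv$background$data, ct$data)
  expect_true(all(sv$tumor_only$data == 0))

  m <- array(0, dim(a)); m[3:4, 2:3, 2:3] <- 1
  mask <- volume3d(m, c(1, 1, 1))
  sv <- split_volume(ct, mask, "constant", fill_value = 7)
  inside <- m > 0
  expect_true(all(sv$background$data[inside] == 7))
  expect_identical(sv$background$data[!inside], ct$data[!inside])
  expect_identical(sv$tumor_only$data[inside], ct$data[inside])
  expect_true(all(sv$tumor_only$data[!inside] == 0))

  # shell fill inside a uniform neighborhood recovers that value
  b <- array(0.2, dim(a)); b[3:4, 2:3, 2:3] <- 1.1
  sv <- split_volume(volume3d(b, c(1, 1, 1)), mask, "shell")
  expect_true(all(abs(sv$background$data[inside] - 0.2) < 1e-12))

  bad <- volume3d(array(0, c(2, 2, 2)), c(1, 1, 1))
  expect_error(split_volume(ct, bad), "grid")
})

test_that("DRR of a uniform cube matches the slab path length", {
  vol <- cube_volume(side = 100, spacing = 2)
  geom <- projection_geometry(detector_px = c(33L, 33L), pitch = 2,
                              step_mm = 1)
  drr <- compute_drr(vol, geom)
  # central pixel: near-axial ray, path ~ 100 mm of unit density
  expect_equal(drr[17, 17], 100, tolerance = 0.01)
  # empty volume gives a zero image
  empty <- volume3d(array(0, dim(vol$data)), vol$spacing, vol$origin)
  expect_true(all(compute_drr(empty, geom) == 0))
})

test_that("oblique rays match the closed-form ray-box intersection", {
  vol <- cube_volume(side = 100, spacing = 2)
  geom <- projection_geometry(detector_px = c(33L, 33L), pitch = 4,
                              gantry_deg = 25, step_mm = 0.5)
  drr <- compute_drr(vol, geom)
  phi <- 25 * pi / 180
  src <- -1000 * c(-sin(phi), cos(phi), 0)
  det_center <- src + 1876 * c(-sin(phi), cos(phi), 0)
  eu <- c(cos(phi), sin(phi), 0)
  for (px in list(c(10L, 17L), c(17L, 24L), c(22L, 12L))) {
    umm <- (px[2] - 17) * 4; vmm <- (px[1] - 17) * 4
    target <- det_center + umm * eu + vmm * c(0, 0, 1)
    dir <- (target - src) / sqrt(sum((target - src)^2))
    len <- ray_box_length_ref(src, dir, rep(-50, 3), rep(50, 3))
    expect_equal(drr[px[1], px[2]], len, tolerance = 0.01 * max(len, 1))
  }
})

test_that("ray tracing is linear and splits compose", {
  spec <- small_phantom_spec()
  ph <- build_torso_volume(spec)
  geom <- projection_geometry(detector_px = c(48L, 48L), pitch = 8,
                              gantry_deg = 40, step_mm = 2)
  A <- ph$ct
  B <- volume3d(ph$tumor_mask$data * 0.7, A$spacing, A$origin)
  lin <- compute_drr(volume3d(2 * A$data + 3 * B$data, A$spacing, A$origin),
                     geom)
  expect_equal(lin, 2 * compute_drr(A, geom) + 3 * compute_drr(B, geom),
               tolerance = 1e-10)
  # complementary fills: background(fill 0) + tumor_only = composite
  sv <- split_volume(A, ph$tumor_mask, "constant", fill_value = 0)
  total <- compute_drr(sv$background, geom) + compute_drr(sv$tumor_only, geom)
  composite <- compute_drr(A, geom)
  expect_lt(max(abs(total - composite)) / max(composite), 1e-6)
})

test_that("halving the march step barely changes a smooth DRR", {
  spec <- small_phantom_spec()
  ph <- build_torso_volume(spec)
  g1 <- projection_geometry(detector_px = c(32L, 32L), pitch = 8,
                            gantry_deg = 10, step_mm = 2)
  g2 <- projection_geometry(detector_px = c(32L, 32L), pitch = 8,
                            gantry_deg = 10, step_mm = 1)
  d1 <- compute_drr(ph$ct, g1)
  d2 <- compute_drr(ph$ct, g2)
  scale <- max(abs(d2))
  expect_lt(max(abs(d1 - d2)) / scale, 0.005)
})

test_that("project_point follows the pinhole model", {
  geom <- projection_geometry()
  iso <- project_point(geom, c(0, 0, 0))
  expect_equal(iso$u_mm, 0)
  expect_equal(iso$v_mm, 0)
  # 10 mm lateral offset in the isocenter plane at gantry 0
  p <- project_point(geom, c(10, 0, 0))
  expect_equal(p$u_mm, 18.76)
  expect_equal(p$u_px - (geom$detector_px[1] + 1) / 2, 46.9)
  # magnification at the isocenter is exactly SDD/SAD
  expect_identical(p$u_mm / 10, 1876 / 1000)
  expect_error(project_point(geom, c(0, -2000, 0)), "behind")
})

test_that("project_point agrees with a homogeneous-matrix oracle", {
  withr::with_seed(42, {
    for (k in 1:20) {
      geom <- projection_geometry(gantry_deg = runif(1, 0, 360),
                                  imager_deg = sample(c(-45, 0, 45), 1))
      pt <- runif(3, -150, 150)
      got <- project_point(geom, pt)
      ref <- project_point_ref(geom, pt)
      expect_lt(abs(got$u_mm - ref["u_mm"]), 1e-9)
      expect_lt(abs(got$v_mm - ref["v_mm"]), 1e-9)
    }
  })
})

test_that("MetaImage volumes round-trip", {
  vol <- volume3d(array(rnorm(4 * 3 * 5), c(4, 3, 5)),
                  c(1.5, 2, 3), c(-10, 0, 5))
  path <- withr::local_tempfile(fileext = ".mha")
  write_mha(vol, path, type = "double")
  back <- read_mha(path)
  expect_equal(back$data, vol$data)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
})
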
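make_match <- function(P, D, shape, tile, off = c(0, 0), bad = c(u = 1L, v = 1L)) {
  cfg <- make_tile_config(shape, 3L, 3L, tile, p_offset = off)
  list(config = cfg, bad = bad)
}

test_that("the per-tile fit recovers exact and noisy linear maps", {
  withr::with_seed(40, D <- matrix(runif(144, 1, 2), 12, 12))
  P <- 1.7 * D - 0.4
  fit <- fit_tile_intensity_map(P, D)
  expect_equal(unname(fit["a"]), 1.7, tolerance = 1e-12)
  expect_equal(unname(fit["b"]), -0.4, tolerance = 1e-12)
  expect_false(attr(fit, "degenerate"))
  expect_equal(unname(fit_tile_intensity_map(D, D)), c(1, 0),
               ignore_attr = TRUE)
  # full-size noisy tile: agree with the normal equations directly
  withr::with_seed(41, {
    D2 <- matrix(runif(168^2, 10, 110), 168, 168)
    noise <- matrix(rnorm(168^2, sd = 0.01 * 100), 168, 168)
  })
  Pn <- 1.3 * D2 - 40 + noise
  fitn <- fit_tile_intensity_map(Pn, D2)
  ab <- stats::coef(stats::lm(as.numeric(Pn) ~ as.numeric(D2)))
  expect_equal(unname(fitn["a"]), unname(ab[2]), tolerance = 1e-10)
  expect_equal(unname(fitn["b"]), unname(ab[1]), tolerance = 1e-10)
  expect_lt(abs(fitn["a"] - 1.3) / 1.3, 0.01)
  # degenerate DRR tile
  fd <- fit_tile_intensity_map(P, matrix(2, 12, 12))
  expect_true(attr(fd, "degenerate"))
  expect_identical(unname(fd["a"]), 0)
  expect_equal(unname(fd["b"]), mean(P))
  expect_error(fit_tile_intensity_map(P, matrix(1, 3, 3)), "congruent")
})

test_that("a globally affine pair leaves a numerically zero residual", {
  withr::with_seed(50, D <- matrix(runif(60 * 60, 0, 10), 60, 60))
  P <- 2.5 * D + 3
  m <- make_match(P, D, c(60L, 60L), 20L)
  grid <- build_map_grid(P, D, m)
  expect_true(all(abs(grid$a - 2.5) < 1e-10))
  expect_true(all(abs(grid$b - 3) < 1e-10))
  res <- subtract_background(P, D, grid)
  expect_lt(max(abs(res)), 1e-10 * diff(range(P)))
})

test_that("coefficient fields equal grid values exactly at tile centres", {
  # odd tile size so centres land on integer pixels
  withr::with_seed(51, D <- matrix(runif(63 * 63, 1, 4), 63, 63))
  withr::with_seed(52, P <- D * matrix(runif(63 * 63, 0.8, 1.2), 63, 63))
  m <- make_match(P, D, c(63L, 63L), 21L, bad = c(u = 2L, v = 2L))
  grid <- build_map_grid(P, D, m)
  for (v in 1:3) for (u in 1:3) {
    r <- grid$centers_row[v]; c <- grid$centers_col[u]
    expect_identical(grid$a_field[r, c], grid$a[v, u])
    expect_identical(grid$b_field[r, c], grid$b[v, u])
  }
})

test_that("bilinear fields hit the midpoint between adjacent centres", {
  withr::with_seed(58, D <- matrix(runif(63 * 63), 63, 63))
  m <- make_match(D, D, c(63L, 63L), 21L)
  grid <- build_map_grid(D, D, m)
  # odd tile size puts the centres on integer pixels (11, 32, 53);
  # overwrite the coefficients with a hand pattern and rebuild
  A <- matrix(c(1, 1, 1, 1, 2, 1, 1, 1, 1), 3, 3)
  Wr <- tiletrack:::interp_weights(1:63, grid$centers_row)
  Wc <- tiletrack:::interp_weights(1:63, grid$centers_col)
  f <- Wr %*% A %*% t(Wc)
  r <- grid$centers_row; c <- grid$centers_col
  expect_equal(f[r[2], c[2]], 2)
  # halfway between centre (2,2)=2 and (1,2)=1 the field is 1.5; the
  # midpoint 21.5 sits between pixels, and the field is linear there
  expect_equal((f[21, c[2]] + f[22, c[2]]) / 2, 1.5)
  # clamped constant extrapolation outside the outer centres
  expect_equal(f[1, c[2]], f[r[1], c[2]])
})

test_that("interior bad tiles take the mean of their four neighbors", {
  withr::with_seed(53, D <- matrix(runif(60 * 60, 1, 3), 60, 60))
  gains <- matrix(c(1.5, 1.0, 1.5,
                    2.0, 9.9, 3.0,
                    1.5, 4.0, 1.5), 3, 3, byrow = TRUE)
  P <- matrix(NA_real_, 60, 60)
  cfg <- make_tile_config(c(60L, 60L), 3L, 3L, 20L)
  for (v in 1:3) for (u in 1:3) {
    rect <- tiletrack:::tile_rect(cfg, u, v, "P")
    P[rect$rows, rect$cols] <- gains[v, u] * D[rect$rows, rect$cols]
  }
  m <- list(config = cfg, bad = c(u = 2L, v = 2L))
  grid <- build_map_grid(P, D, m)
  expect_equal(grid$a[2, 2], mean(c(1, 2, 3, 4)), tolerance = 1e-10)
  expect_equal(grid$b[2, 2], 0, tolerance = 1e-8)
  # interpolation stays inside the convex hull of the neighbors
  expect_gte(grid$a[2, 2], 1); expect_lte(grid$a[2, 2], 4)
  # corner bad tile uses its two axial neighbors
  m2 <- list(config = cfg, bad = c(u = 1L, v = 1L))
  grid2 <- build_map_grid(P, D, m2)
  expect_equal(grid2$a[1, 1], mean(c(1.0, 2.0)), tolerance = 1e-10)
})

test_that("a disc discrepancy survives subtraction almost exactly", {
  fx <- disc_fixture(77)
  match <- optimize_tile_shift(fx$P, fx$D, fx$base, step_px = 5L)
  grid <- build_map_grid(fx$P, fx$D, match)
  res <- subtract_background(fx$P, fx$D, grid)
  inside <- fx$disc > 0
  # residual carries the disc: mean inside close to its amplitude
  expect_gt(mean(res[inside]), 2.5)
  expect_lt(mean(abs(res[!inside])), 0.25)
})

test_that("piecewise gains plus a disc leave the disc dominant", {
  withr::with_seed(54, D <- matrix(runif(60 * 60, 1, 3), 60, 60))
  cfg <- make_tile_config(c(60L, 60L), 3L, 3L, 20L)
  gains <- matrix(seq(0.8, 1.2, length.out = 9), 3, 3)
  P <- matrix(NA_real_, 60, 60)
  for (v in 1:3) for (u in 1:3) {
    rect <- tiletrack:::tile_rect(cfg, u, v, "P")
    P[rect$rows, rect$cols] <- gains[v, u] * D[rect$rows, rect$cols]
  }
  # bright disc inside the central tile; per the construction, the
  # residual energy concentrates in the disc
  disc <- outer((1:60 - 30.5)^2, (1:60 - 30.5)^2, "+") <= 8^2
  P[disc] <- P[disc] + 3
  m <- list(config = cfg, bad = c(u = 2L, v = 2L))
  res <- subtract_background(P, D, build_map_grid(P, D, m))
  expect_lt(sum(res[!disc]^2), 0.05 * sum(res[disc]^2))
})

test_that("an additive disc with identity maps is returned exactly", {
  fx <- disc_fixture(303)
  match <- optimize_tile_shift(fx$P, fx$D, fx$base, step_px = 5L)
  # every good tile satisfies P = D exactly, so all fits are (1, 0),
  # the interpolated bad tile is (1, 0), and the residual is the disc
  grid <- build_map_grid(fx$P, fx$D, match)
  expect_equal(as.numeric(grid$a), rep(1, 9), tolerance = 1e-12)
  expect_equal(as.numeric(grid$b), rep(0, 9), tolerance = 1e-12)
  res <- subtract_background(fx$P, fx$D, grid)
  expect_equal(res, 3 * fx$disc, tolerance = 1e-10)
})

test_that("subtraction is linear in the projection for a fixed grid", {
  withr::with_seed(55, {
    D <- matrix(runif(60 * 60, 1, 3), 60, 60)
    P <- 1.2 * D + 0.5
    delta <- matrix(rnorm(60 * 60), 60, 60)
  })
  m <- make_match(P, D, c(60L, 60L), 20L)
  grid <- build_map_grid(P, D, m)
  r1 <- subtract_background(P, D, grid)
  r2 <- subtract_background(P + delta, D, grid)
  expect_equal(r2 - r1, delta, tolerance = 1e-12)
})

test_that("coefficient fields are continuous within the bilinear bound", {
  withr::with_seed(56, D <- matrix(runif(60 * 60, 1, 3), 60, 60))
  withr::with_seed(57, P <- D * matrix(runif(3600, 0.5, 2), 60, 60))
  m <- make_match(P, D, c(60L, 60L), 20L, bad = c(u = 2L, v = 2L))
  grid <- build_map_grid(P, D, m)
  bound <- diff(range(grid$a)) / 20 + 1e-12
  expect_lt(max(abs(diff(grid$a_field))), bound)
  expect_lt(max(abs(t(diff(t(grid$a_field))))), bound)
})

test_that("subtraction validates congruence", {
  withr::with_seed(59, D <- matrix(runif(3600), 60, 60))
  m <- make_match(D, D, c(60L, 60L), 20L)
  grid <- build_map_grid(D, D, m)
  expect_error(subtract_background(matrix(0, 30, 30), matrix(0, 30, 30), grid),
               "congruent")
})
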
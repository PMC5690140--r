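# Small fixtures shared across test files; everything is generated in
# code under fixed seeds.

# Uniform unit-density cube of the given side, rasterized so the faces
# fall midway between voxel centres (the trilinear ramp then integrates
# to the exact side length).
cube_volume <- function(side = 100, spacing = 2) {
  half_n <- ceiling((side / 2 + 3 * spacing) / spacing)
  centers <- (seq_len(2 * half_n) - half_n - 0.5) * spacing
  a <- array(0, c(length(centers), length(centers), length(centers)))
  inside <- abs(centers) < side / 2
  a[inside, inside, inside] <- 1
  volume3d(a, rep(spacing, 3), rep(centers[1], 3))
}

# Default-spec phantom, built once per test run.
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_torso_volume(phantom_spec())
    cache
  }
})

# Coarse torso phantom used where full resolution is unnecessary.
small_phantom_spec <- function(...) {
  phantom_spec(voxel_mm = c(5, 5, 5), ...)
}

# P = D + a bright disc; D is a smooth seeded background. The disc is
# centred on the junction of four tiles of the base config so that only
# a shifted grid can isolate it.
disc_fixture <- function(seed, n = 120L, tile = 30L, disc_frac = 0.4) {
  withr::with_seed(seed, {
    fx <- outer(seq_len(n), seq_len(n), function(r, c)
      sin(r / 17) + cos(c / 23))
    D <- fx + matrix(rnorm(n * n, sd = 0.05), n, n)
  })
  base_off <- floor((n - 3L * tile) / 2)
  base <- make_tile_config(c(n, n), 3L, 3L, tile,
                           p_offset = c(base_off, base_off))
  # junction of tiles (1,1)...(2,2): grid start + tile size
  jr <- base_off + tile + 0.5
  jc <- base_off + tile + 0.5
  rad <- disc_frac * tile
  disc <- outer(seq_len(n), seq_len(n), function(r, c)
    as.numeric((r - jr)^2 + (c - jc)^2 <= rad^2))
  list(P = D + 3 * disc, D = D, base = base, disc = disc,
       center = c(jr, jc), radius = rad)
}
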
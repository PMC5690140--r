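#' Specification of the digital respiratory torso phantom
#'
#' Analytic humanoid torso used to validate the tracker: an elliptic
#' body, two lung ellipsoids, elliptical bony rib rings, a spherical
#' water-density heart, a cylindrical tumor (default 30 mm diameter x
#' 30 mm height) inside one lung, and spherical radio-opaque fiducial
#' markers (default 5.5 mm diameter) implanted next to the tumor. All
#' shapes are closed-form primitives so rasterized volumes can be
#' checked against analytic volumes and ground truth is exact. The
#' world origin is the planning tumor centre, which is also the
#' treatment isocenter. Densities are unitless attenuation per mm.
#'
#' @param voxel_mm voxel spacing (x, y, z); default 3 mm slices along z.
#' @param volume_extent list of `x`, `y`, `z` ranges (mm) of the grid.
#'   The defaults are deliberately off round numbers so the analytic
#'   structure boundaries (at integer or half-integer mm) never fall
#'   exactly on voxel centres, where binary centre-sampling would
#'   double-count a knife-edge face.
#' @param body_center,body_semi ellipsoid centre / semi-axes of the torso.
#' @param lung_centers,lung_semi lung ellipsoid centres (list) and
#'   common semi-axes.
#' @param rib_count,rib_scale,rib_thickness_mm,rib_height_mm,rib_spacing_mm
#'   number of rib rings, their radial position as a fraction of the
#'   body cross-section ellipse, radial thickness, axial height, and z
#'   spacing.
#' @param heart_center,heart_radius sphere centre / radius of the heart.
#' @param tumor_center,tumor_diameter,tumor_height tumor cylinder
#'   (axis along z).
#' @param marker_diameter,marker_offsets marker sphere diameter and
#'   offsets (list of length-3 mm vectors) from the tumor centre.
#' @param densities named list: `air`, `body`, `lung`, `bone`, `water`,
#'   `tumor`, `marker`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(
    voxel_mm = c(2.5, 2.5, 3),
    volume_extent = list(x = c(-217.3, 87.7), y = c(-117.3, 117.7),
                         z = c(-126.8, 125.2)),
    body_center = c(-65, 5, 0), body_semi = c(150, 110, 320),
    lung_centers = list(c(0, 0, 5), c(-130, 0, 5)),
    lung_semi = c(55, 70, 110),
    rib_count = 10L, rib_scale = 0.91, rib_thickness_mm = 8,
    rib_height_mm = 10, rib_spacing_mm = 22,
    heart_center = c(-55, -25, -25), heart_radius = 40,
    tumor_center = c(0, 0, 0), tumor_diameter = 30, tumor_height = 30,
    marker_diameter = 5.5,
    marker_offsets = list(c(25, 0, 0), c(0, 25, 8), c(-18, 18, -10)),
    densities = list(air = 0, body = 1.0, lung = 0.2, bone = 1.8,
                     water = 1.0, tumor = 1.1, marker = 8.0)) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(all(spec$voxel_mm > 0), all(spec$body_semi > 0),
            all(spec$lung_semi > 0), spec$tumor_diameter > 0,
            spec$tumor_height > 0, spec$marker_diameter > 0,
            spec$heart_radius > 0, spec$rib_count >= 0)
  # tumor cylinder must sit fully inside one lung ellipsoid
  inside <- vapply(spec$lung_centers, function(lc) {
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    r <- spec$tumor_diameter / 2
    rim <- rbind(
      cbind(r * cos(th), r * sin(th), spec$tumor_height / 2),
      cbind(r * cos(th), r * sin(th), -spec$tumor_height / 2))
    pts <- sweep(rim, 2, spec$tumor_center, "+")
    q <- sweep(pts, 2, lc, "-")
    all(rowSums(sweep(q, 2, spec$lung_semi, "/")^2) <= 1)
  }, logical(1))
  if (!any(inside)) stop("tumor cylinder is not fully inside a lung ellipsoid")
  # markers must not overlap each other
  if (length(spec$marker_offsets) > 1) {
    ctr <- do.call(rbind, spec$marker_offsets)
    dmin <- min(stats::dist(ctr))
    if (dmin <= spec$marker_diameter)
      stop("marker spheres overlap each other")
  }
  invisible(spec)
}

#' Rasterize the torso phantom
#'
#' Evaluates the analytic primitives at voxel centres, later shapes
#' overwriting earlier ones (body, lungs, ribs, heart, tumor, markers).
#'
#' @param spec a [phantom_spec()].
#' @return List: `ct` ([volume3d()]), `tumor_mask` (binary
#'   [volume3d()]), `marker_centers` (matrix of mm positions, one row
#'   per marker), and `spec`.
#' @export
build_torso_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_mm
  nvox <- vapply(c("x", "y", "z"), function(a) {
    i <- match(a, c("x", "y", "z"))
    floor(diff(spec$volume_extent[[a]]) / sp[i]) + 1L
  }, numeric(1))
  origin <- c(spec$volume_extent$x[1], spec$volume_extent$y[1],
              spec$volume_extent$z[1])
  xs <- origin[1] + (seq_len(nvox[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(nvox[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(nvox[3]) - 1) * sp[3]
  d <- as.integer(nvox)
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  dn <- spec$densities
  vol <- array(dn$air, d)

  in_ellipsoid <- function(c0, semi)
    ((X - c0[1]) / semi[1])^2 + ((Y - c0[2]) / semi[2])^2 +
      ((Z - c0[3]) / semi[3])^2 <= 1
  vol[in_ellipsoid(spec$body_center, spec$body_semi)] <- dn$body
  for (lc in spec$lung_centers)
    vol[in_ellipsoid(lc, spec$lung_semi)] <- dn$lung
  if (spec$rib_count > 0) {
    bs <- spec$body_semi; bc <- spec$body_center
    s <- sqrt(((X - bc[1]) / bs[1])^2 + ((Y - bc[2]) / bs[2])^2)
    half_w <- spec$rib_thickness_mm / (2 * sqrt(bs[1] * bs[2]))
    z0 <- -(spec$rib_count - 1) / 2 * spec$rib_spacing_mm
    ring <- abs(s - spec$rib_scale) <= half_w
    for (k in seq_len(spec$rib_count)) {
      zk <- z0 + (k - 1) * spec$rib_spacing_mm
      vol[ring & abs(Z - zk) <= spec$rib_height_mm / 2] <- dn$bone
    }
  }
  hq <- (X - spec$heart_center[1])^2 + (Y - spec$heart_center[2])^2 +
    (Z - spec$heart_center[3])^2
  vol[hq <= spec$heart_radius^2] <- dn$water

  tc <- spec$tumor_center
  tmask <- ((X - tc[1])^2 + (Y - tc[2])^2 <= (spec$tumor_diameter / 2)^2) &
    abs(Z - tc[3]) <= spec$tumor_height / 2
  vol[tmask] <- dn$tumor

  centers <- if (length(spec$marker_offsets)) {
    m <- do.call(rbind, lapply(spec$marker_offsets, function(o) tc + o))
    r2 <- (spec$marker_diameter / 2)^2
    for (i in seq_len(nrow(m))) {
      mq <- (X - m[i, 1])^2 + (Y - m[i, 2])^2 + (Z - m[i, 3])^2
      vol[mq <= r2] <- dn$marker
    }
    m
  } else matrix(numeric(0), 0, 3)

  list(ct = volume3d(vol, sp, origin),
       tumor_mask = volume3d(array(as.numeric(tmask), d), sp, origin),
       marker_centers = centers,
       spec = spec)
}

# Binary mask of the structures that ride on the motion platform
# (tumor cylinder plus marker spheres, with a small margin so partial
# voxels are included).
moving_structure_mask <- function(phantom, margin_mm = 1) {
  spec <- phantom$spec
  vol <- phantom$ct
  d <- dim(vol$data)
  xs <- voxel_coords(vol, 1); ys <- voxel_coords(vol, 2)
  zs <- voxel_coords(vol, 3)
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  tc <- spec$tumor_center
  m <- ((X - tc[1])^2 + (Y - tc[2])^2 <=
          (spec$tumor_diameter / 2 + margin_mm)^2) &
    abs(Z - tc[3]) <= spec$tumor_height / 2 + margin_mm
  r <- spec$marker_diameter / 2 + margin_mm
  if (nrow(phantom$marker_centers))
    for (i in seq_len(nrow(phantom$marker_centers))) {
      mc <- phantom$marker_centers[i, ]
      m <- m | ((X - mc[1])^2 + (Y - mc[2])^2 + (Z - mc[3])^2 <= r^2)
    }
  volume3d(array(as.numeric(m), d), vol$spacing, vol$origin)
}

#' Respiratory motion pattern
#'
#' Deterministic tumor displacement as a function of frame index.
#' Patterns: `"sinusoid"`, `a * sin(2*pi*t/T + phase)` per axis;
#' `"cos4"`, `-a * cos(pi*t/T + phase)^4`, a Lujan-type waveform that
#' dwells at exhale (its extreme `-a` falls at `t = 0` for phase 0);
#' `"piecewise"`, linear interpolation of a user table with columns
#' `t`, `dx`, `dy`, `dz`, wrapped periodically at `period_s`.
#'
#' @param pattern one of `"sinusoid"`, `"cos4"`, `"piecewise"`.
#' @param amplitude_mm length-3 amplitude per axis (>= 0), mm.
#' @param period_s breathing period, s (> 0).
#' @param phase_rad phase offset, rad.
#' @param frame_rate_hz imaging frame rate, Hz.
#' @param n_frames number of frames (>= 1).
#' @param table data.frame for the piecewise pattern.
#' @return An object of class `motion_pattern`.
#' @export
motion_pattern <- function(pattern = c("sinusoid", "cos4", "piecewise"),
                           amplitude_mm = c(0, 0, 10), period_s = 4,
                           phase_rad = 0, frame_rate_hz = 5,
                           n_frames = 20L, table = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(all(amplitude_mm >= 0), period_s > 0, frame_rate_hz > 0,
            n_frames >= 1)
  if (pattern == "piecewise") {
    if (is.null(table) || !all(c("t", "dx", "dy", "dz") %in% names(table)))
      stop("piecewise pattern needs a table with columns t, dx, dy, dz")
  }
  structure(list(pattern = pattern, amplitude_mm = amplitude_mm,
                 period_s = period_s, phase_rad = phase_rad,
                 frame_rate_hz = frame_rate_hz,
                 n_frames = as.integer(n_frames), table = table),
            class = "motion_pattern")
}

#' Displacement at a frame
#'
#' @param pattern a [motion_pattern()].
#' @param frame_index 0-based frame index in `[0, n_frames)`.
#' @return Numeric length-3 displacement (mm).
#' @export
sample_trajectory <- function(pattern, frame_index) {
  stopifnot(inherits(pattern, "motion_pattern"))
  if (frame_index < 0 || frame_index >= pattern$n_frames)
    stop("frame_index out of range")
  t <- frame_index / pattern$frame_rate_hz
  a <- pattern$amplitude_mm
  switch(pattern$pattern,
    sinusoid = a * sin(2 * pi * t / pattern$period_s + pattern$phase_rad),
    cos4 = -a * cos(pi * t / pattern$period_s + pattern$phase_rad)^4,
    piecewise = {
      tb <- pattern$table
      tw <- t %% pattern$period_s
      vapply(c("dx", "dy", "dz"), function(col)
        stats::approx(tb$t, tb[[col]], xout = tw, rule = 2)$y,
        numeric(1))
    })
}

#' Projection-vs-DRR discrepancy model
#'
#' Controls the intensity mismatch between simulated kV projections and
#' DRRs: a monotone nonlinear (gamma) map, a low-frequency
#' multiplicative bias field standing in for angle-dependent scatter,
#' and additive Gaussian noise, applied in that order. Each component
#' is disabled at its neutral value (gamma 1, amplitude 0, SD 0).
#'
#' @param gamma exponent of the monotone map (> 0).
#' @param bias_amplitude peak multiplicative bias as a fraction of 1.
#' @param bias_scale_px spatial scale of the bias field, px.
#' @param noise_sd additive noise SD as a fraction of dynamic range.
#' @param seed integer seed for the bias field and noise.
#' @return An object of class `distortion_spec`.
#' @export
distortion_spec <- function(gamma = 1, bias_amplitude = 0,
                            bias_scale_px = 64, noise_sd = 0, seed = 1L) {
  stopifnot(gamma > 0, bias_amplitude >= 0, noise_sd >= 0,
            bias_scale_px > 0)
  structure(list(gamma = gamma, bias_amplitude = bias_amplitude,
                 bias_scale_px = bias_scale_px, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "distortion_spec")
}

# Smooth multiplicative bias field in [1 - amp, 1 + amp]: a coarse
# uniform(-1, 1) grid bilinearly upsampled to the image size.
bias_field <- function(nr, nc, spec) {
  gr <- max(2L, ceiling(nr / spec$bias_scale_px) + 1L)
  gc <- max(2L, ceiling(nc / spec$bias_scale_px) + 1L)
  coarse <- withr::with_seed(spec$seed,
    matrix(stats::runif(gr * gc, -1, 1), gr, gc))
  ri <- seq(1, gr, length.out = nr)
  ci <- seq(1, gc, length.out = nc)
  r0 <- pmin(floor(ri), gr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), gc - 1L); fc <- ci - c0
  A <- coarse[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    coarse[r0 + 1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    coarse[r0, c0 + 1, drop = FALSE] * outer(1 - fr, fc) +
    coarse[r0 + 1, c0 + 1, drop = FALSE] * outer(fr, fc)
  1 + spec$bias_amplitude * A
}

#' Apply the discrepancy model to a DRR
#'
#' Normalizes the line-integral image by `norm_ref`, then applies the
#' gamma map, the multiplicative bias field and additive Gaussian
#' noise of the [distortion_spec()]. Bit-reproducible given the spec's
#' seed and the frame index (noise is redrawn per frame, the bias field
#' is fixed per spec).
#'
#' @param image numeric matrix of line integrals.
#' @param spec a [distortion_spec()] (or NULL for the identity).
#' @param norm_ref normalization constant (defaults to `max(image)`).
#' @param frame_index frame number used to vary the noise stream.
#' @return Numeric matrix in normalized units.
#' @export
apply_distortion <- function(image, spec, norm_ref = NULL, frame_index = 0L) {
  if (is.null(spec)) return(image)
  if (is.null(norm_ref)) norm_ref <- max(image)
  if (norm_ref <= 0) norm_ref <- 1
  x <- pmax(image / norm_ref, 0)
  if (spec$gamma != 1) x <- x^spec$gamma
  if (spec$bias_amplitude > 0)
    x <- x * bias_field(nrow(x), ncol(x), spec)
  if (spec$noise_sd > 0)
    x <- x + withr::with_seed(spec$seed + 7919L * (frame_index + 1L),
      matrix(stats::rnorm(length(x), 0, spec$noise_sd), nrow(x)))
  x
}

#' Simulate one kV projection of the phantom with a displaced tumor
#'
#' Composes a frame-specific volume by filling the moving structures
#' (shell mean), shifting the masked difference by the displacement
#' with trilinear resampling, and re-inserting it over the background;
#' ray-traces the composite and applies the discrepancy model. Ground
#' truth is the displaced tumor centre projected through the pinhole
#' geometry. With zero displacement the composite volume is the
#' unmodified input, so the undistorted projection equals its DRR
#' exactly.
#'
#' @param ct planning [volume3d()] (tumor and markers at planning
#'   positions).
#' @param tumor_mask binary tumor-contour [volume3d()].
#' @param geometry a [projection_geometry()].
#' @param displacement length-3 mm displacement of the moving
#'   structures.
#' @param distortion a [distortion_spec()] or NULL (no distortion).
#' @param moving_mask binary mask of everything that moves (defaults to
#'   the tumor mask; pass tumor + markers to move implanted markers
#'   along).
#' @param norm_ref normalization constant forwarded to
#'   [apply_distortion()]; pass one value for a whole sequence.
#' @param frame_index frame number (seeds the per-frame noise).
#' @param precomp optional precomputed list from
#'   [precompute_motion_split()] to avoid refilling per frame.
#' @return List: `projection` (matrix), `truth` (list with `u_px`,
#'   `v_px`, `u_mm`, `v_mm`, `center_mm`).
#' @export
simulate_kv_projection <- function(ct, tumor_mask, geometry, displacement,
                                   distortion = NULL,
                                   moving_mask = tumor_mask,
                                   norm_ref = NULL, frame_index = 0L,
                                   precomp = NULL) {
  displacement <- as.numeric(displacement)
  stopifnot(length(displacement) == 3L)
  if (!same_grid(ct, tumor_mask)) stop("tumor mask grid mismatch")
  if (is.null(precomp)) precomp <- precompute_motion_split(ct, moving_mask)
  # displaced moving region must stay inside the volume
  idx <- which(precomp$mask_arr, arr.ind = TRUE)
  if (nrow(idx)) {
    lims <- t(apply(idx, 2, range))
    pos_lo <- ct$origin + (lims[, 1] - 1) * ct$spacing + displacement
    pos_hi <- ct$origin + (lims[, 2] - 1) * ct$spacing + displacement
    vol_hi <- ct$origin + (dim(ct$data) - 1) * ct$spacing
    if (any(pos_lo < ct$origin) || any(pos_hi > vol_hi))
      stop("displacement moves the tumor outside the volume")
  }
  frame_vol <- if (all(displacement == 0)) ct else {
    if (any(abs(displacement) > precomp$margin_mm))
      stop("displacement exceeds the precomputed motion margin")
    moved <- shift_volume(precomp$diff, displacement)
    arr <- precomp$background$data
    lo <- precomp$box$lo; hi <- precomp$box$hi
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + moved$data
    volume3d(arr, ct$spacing, ct$origin)
  }
  drr <- compute_drr(frame_vol, geometry)
  proj <- apply_distortion(drr, distortion, norm_ref, frame_index)
  center <- mask_centroid_mm(tumor_mask) + displacement
  tp <- project_point(geometry, center)
  list(projection = proj,
       truth = list(u_px = tp$u_px, v_px = tp$v_px,
                    u_mm = tp$u_mm, v_mm = tp$v_mm, center_mm = center))
}

#' @rdname simulate_kv_projection
#' @param margin_mm padding of the moving-structure bounding box; the
#'   shifted difference volume is composed only inside this box, so the
#'   largest displacement magnitude must not exceed it.
#' @export
precompute_motion_split <- function(ct, moving_mask, margin_mm = 25) {
  sv <- split_volume(ct, moving_mask, "shell")
  diff_arr <- ct$data - sv$background$data
  idx <- which(moving_mask$data > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("moving mask is empty")
  d <- dim(ct$data)
  pad <- ceiling(margin_mm / ct$spacing) + 1L
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  sub <- diff_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(background = sv$background,
       diff = volume3d(sub, ct$spacing, ct$origin + (lo - 1) * ct$spacing),
       box = list(lo = lo, hi = hi),
       margin_mm = margin_mm,
       mask_arr = moving_mask$data > 0)
}

#' Intensity-weighted centroid of a mask volume, in world mm
#'
#' The centroid of the rasterized planning contour is the point the
#' simulator's ground truth tracks, and therefore the natural
#' `planning_center_mm` anchor for [track_sequence()].
#'
#' @param mask a [volume3d()] with nonzero voxels marking the structure.
#' @return Numeric length-3 world coordinate (mm).
#' @export
mask_centroid_mm <- function(mask) {
  idx <- which(mask$data > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  mask$origin + (colMeans(idx) - 1) * mask$spacing
}

#' Simulate a kV fluoro sequence
#'
#' Runs [simulate_kv_projection()] over all frames of a motion pattern,
#' with the moving-structure split precomputed once and a common
#' normalization reference (the static-frame DRR maximum) so frame
#' intensities are comparable.
#'
#' @param phantom result of [build_torso_volume()].
#' @param geometry a [projection_geometry()].
#' @param pattern a [motion_pattern()].
#' @param distortion a [distortion_spec()] or NULL.
#' @param move_markers move the implanted markers with the tumor
#'   (default TRUE, as on a physical motion platform).
#' @return List: `projections` (list of matrices), `truth`
#'   (data.frame: frame, t_s, dx/dy/dz_mm, true_u_px, true_v_px,
#'   true_x_mm, true_y_mm), `norm_ref`.
#' @export
simulate_kv_sequence <- function(phantom, geometry, pattern,
                                 distortion = NULL, move_markers = TRUE) {
  ct <- phantom$ct
  mmask <- if (move_markers) moving_structure_mask(phantom) else
    phantom$tumor_mask
  precomp <- precompute_motion_split(ct, mmask)
  norm_ref <- max(compute_drr(ct, geometry)) * 1.05
  n <- pattern$n_frames
  projections <- vector("list", n)
  truth <- data.frame(frame = seq_len(n) - 1L, t_s = NA_real_,
                      dx_mm = NA_real_, dy_mm = NA_real_, dz_mm = NA_real_,
                      true_u_px = NA_real_, true_v_px = NA_real_,
                      true_x_mm = NA_real_, true_y_mm = NA_real_)
  for (k in seq_len(n)) {
    disp <- sample_trajectory(pattern, k - 1L)
    sim <- simulate_kv_projection(ct, phantom$tumor_mask, geometry, disp,
                                  distortion = distortion,
                                  moving_mask = mmask,
                                  norm_ref = norm_ref,
                                  frame_index = k - 1L, precomp = precomp)
    projections[[k]] <- sim$projection
    truth$t_s[k] <- (k - 1L) / pattern$frame_rate_hz
    truth[k, c("dx_mm", "dy_mm", "dz_mm")] <- disp
    truth$true_u_px[k] <- sim$truth$u_px
    truth$true_v_px[k] <- sim$truth$v_px
    ctr_px <- (geometry$detector_px + 1) / 2
    truth$true_x_mm[k] <- pixels_to_mm(sim$truth$u_px - ctr_px[1], geometry)
    truth$true_y_mm[k] <- pixels_to_mm(sim$truth$v_px - ctr_px[2], geometry)
  }
  list(projections = projections, truth = truth, norm_ref = norm_ref)
}
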
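#' kV imaging geometry
#'
#' Pinhole projection geometry of an on-board kV imager: a point source
#' at source-to-axis distance SAD from the isocenter and a flat detector
#' at source-to-detector distance SDD, both rotating about the
#' superior-inferior (z) axis. The effective beam angle is
#' `gantry_deg + imager_deg`. At beam angle 0 the source sits at
#' (0, -SAD, 0) and the central ray points along +y. Detector axes: u
#' (columns) is the rotated +x direction, v (rows) is +z. Pixel
#' coordinates are 1-based pixel centres with the detector centre (the
#' central-ray piercing point) at ((nu+1)/2, (nv+1)/2).
#'
#' Defaults follow a Vero-type imager: SAD 1000 mm, SDD 1876 mm,
#' 0.4 mm detector pixels.
#'
#' @param sad source-to-axis distance, mm.
#' @param sdd source-to-detector distance, mm (> sad).
#' @param pitch detector pixel pitch, mm.
#' @param detector_px integer length-2: detector size (nu columns,
#'   nv rows).
#' @param gantry_deg gantry angle, degrees.
#' @param imager_deg imager angle offset from the gantry, degrees.
#' @param step_mm ray-march step for DRR computation, mm.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(sad = 1000, sdd = 1876, pitch = 0.4,
                                detector_px = c(512L, 512L),
                                gantry_deg = 0, imager_deg = 0,
                                step_mm = 1) {
  if (!(sad > 0 && sdd > sad)) stop("require 0 < SAD < SDD")
  if (pitch <= 0) stop("pixel pitch must be > 0")
  if (step_mm <= 0) stop("ray-march step must be > 0")
  detector_px <- as.integer(detector_px)
  if (length(detector_px) != 2L || any(detector_px < 1L))
    stop("detector_px must be two positive integers (nu, nv)")
  structure(list(sad = sad, sdd = sdd, pitch = pitch,
                 detector_px = detector_px,
                 gantry_deg = gantry_deg, imager_deg = imager_deg,
                 step_mm = step_mm),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf(
    "<projection_geometry> SAD %g mm, SDD %g mm (mag %.4g), %d x %d px @ %g mm\n",
    x$sad, x$sdd, x$sdd / x$sad, x$detector_px[1], x$detector_px[2], x$pitch))
  cat(sprintf("  gantry %g deg + imager %g deg, step %g mm\n",
              x$gantry_deg, x$imager_deg, x$step_mm))
  invisible(x)
}

# Source position, detector centre and detector in-plane axes (mm).
beam_frame <- function(geometry) {
  phi <- (geometry$gantry_deg + geometry$imager_deg) * pi / 180
  bhat <- c(-sin(phi), cos(phi), 0)            # central ray direction
  src <- -geometry$sad * bhat                  # (0, -SAD, 0) at phi = 0
  list(src = src,
       det_center = src + geometry$sdd * bhat,
       eu = c(cos(phi), sin(phi), 0),
       ev = c(0, 0, 1),
       bhat = bhat)
}

#' Project a 3D point onto the detector
#'
#' Perspective projection through the source. The returned millimetre
#' coordinates are measured on the detector plane from the central-ray
#' piercing point; pixel coordinates follow the 1-based pixel-centre
#' convention of [projection_geometry()].
#'
#' @param geometry a [projection_geometry()].
#' @param point numeric length-3 world position, mm.
#' @return List with `u_mm`, `v_mm`, `u_px`, `v_px`.
#' @export
project_point <- function(geometry, point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3L, all(is.finite(point)))
  bf <- beam_frame(geometry)
  depth <- geometry$sad + sum(point * bf$bhat)  # distance from source plane
  if (depth <= 0) stop("point at or behind the source")
  mag <- geometry$sdd / depth
  u_mm <- sum(point * bf$eu) * mag
  v_mm <- sum(point * bf$ev) * mag
  list(u_mm = u_mm, v_mm = v_mm,
       u_px = u_mm / geometry$pitch + (geometry$detector_px[1] + 1) / 2,
       v_px = v_mm / geometry$pitch + (geometry$detector_px[2] + 1) / 2)
}

#' Convert detector pixel offsets to isocenter-plane millimetres
#'
#' A displacement of `d_px` detector pixels corresponds to
#' `d_px * pitch * SAD / SDD` mm in the isocenter plane (demagnified by
#' SDD/SAD).
#'
#' @param d_px pixel offset(s) on the detector.
#' @param geometry a [projection_geometry()].
#' @return Millimetres at the isocenter plane (same length as `d_px`).
#' @export
pixels_to_mm <- function(d_px, geometry) {
  d_px * geometry$pitch * geometry$sad / geometry$sdd
}
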
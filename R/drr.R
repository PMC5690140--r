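#' Split a planning volume into background and tumor-only volumes
#'
#' Removes the contoured tumor from the planning volume: the tumor-only
#' volume keeps the planning intensities inside the contour and is
#' zero-attenuation outside; the background volume keeps the planning
#' intensities outside and replaces contoured voxels either by a
#' constant or by the mean intensity of a surrounding shell (so the
#' excised region blends into the local lung background).
#'
#' @param ct planning [volume3d()].
#' @param tumor_mask binary [volume3d()] on the same grid (1 inside the
#'   tumor contour).
#' @param fill_mode `"shell"` (mean of a boundary shell, the default) or
#'   `"constant"`.
#' @param fill_value constant used when `fill_mode = "constant"`.
#' @param shell_voxels shell width in voxels for `"shell"` mode.
#' @return List with `background` and `tumor_only` volumes.
#' @export
split_volume <- function(ct, tumor_mask, fill_mode = c("shell", "constant"),
                         fill_value = 0, shell_voxels = 2L) {
  fill_mode <- match.arg(fill_mode)
  if (!same_grid(ct, tumor_mask)) stop("mask grid does not match the volume")
  m <- tumor_mask$data
  if (!all(m %in% c(0, 1))) stop("tumor mask must be binary")
  m <- m > 0
  tumor_only <- ct$data
  tumor_only[!m] <- 0
  background <- ct$data
  if (any(m)) {
    fill <- if (fill_mode == "constant") fill_value else {
      shell <- dilate_mask(m, shell_voxels) & !m
      if (!any(shell)) stop("tumor mask fills the volume; no shell available")
      mean(ct$data[shell])
    }
    background[m] <- fill
  }
  list(background = volume3d(background, ct$spacing, ct$origin),
       tumor_only = volume3d(tumor_only, ct$spacing, ct$origin))
}

# 6-connected binary dilation by `iter` voxels
dilate_mask <- function(m, iter = 1L) {
  d <- dim(m)
  for (k in seq_len(iter)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  m
}

#' Compute a digitally reconstructed radiograph
#'
#' Ray-traces the volume from the source to every detector pixel and
#' integrates trilinearly interpolated attenuation with a fixed-step
#' midpoint rule along the clipped ray. The pixel value is the raw
#' attenuation line integral (density x mm); rays missing the volume
#' yield 0.
#'
#' @param volume a [volume3d()].
#' @param geometry a [projection_geometry()].
#' @return Numeric matrix (nv rows x nu columns) of line integrals.
#' @export
compute_drr <- function(volume, geometry) {
  bf <- beam_frame(geometry)
  raycast_cpp(as.numeric(volume$data), dim(volume$data),
              volume$spacing, volume$origin,
              bf$src, bf$det_center, bf$eu, bf$ev,
              geometry$pitch,
              geometry$detector_px[1], geometry$detector_px[2],
              geometry$step_mm)
}
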
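#' Locate a template in an image by exhaustive NCC matching
#'
#' Evaluates normalized cross-correlation at every integer placement of
#' the template inside the search window and returns the argmax (ties
#' resolve to the smallest placement in row-major order). Optional
#' sub-pixel refinement fits a 1D quadratic through the NCC peak and
#' its axial neighbors; the refinement is clamped to half a pixel.
#'
#' @param image numeric matrix (e.g. a background-subtracted residual).
#' @param template numeric matrix, strictly smaller than the window.
#' @param window integer length-4 `c(r1, r2, c1, c2)` region of `image`
#'   the template must fit inside; NULL uses the whole image.
#' @param subpixel apply quadratic sub-pixel refinement.
#' @param conf_threshold peaks below this NCC are flagged low
#'   confidence.
#' @return An object of class `tumor_location`: list with `row`, `col`
#'   (template top-left placement, px), `center_row`, `center_col`
#'   (template centre incl. refinement), `score`, `low_confidence`,
#'   `window`.
#' @export
match_template <- function(image, template, window = NULL,
                           subpixel = FALSE, conf_threshold = 0.5) {
  if (is.null(window)) window <- c(1L, nrow(image), 1L, ncol(image))
  window <- as.integer(round(window))
  window[1] <- max(window[1], 1L); window[3] <- max(window[3], 1L)
  window[2] <- min(window[2], nrow(image))
  window[4] <- min(window[4], ncol(image))
  sub <- image[window[1]:window[2], window[3]:window[4], drop = FALSE]
  if (nrow(template) > nrow(sub) || ncol(template) > ncol(sub))
    stop("search window smaller than the template")
  ncc <- ncc_scan_cpp(sub, template)
  m <- max(ncc)
  cand <- which(ncc == m, arr.ind = TRUE)
  pk <- unname(cand[order(cand[, 1], cand[, 2])[1], ])
  dr <- dc <- 0
  if (subpixel) {
    refine <- function(sm, s0, sp) {
      den <- sm - 2 * s0 + sp
      if (!is.finite(den) || den >= 0) return(0)
      min(0.5, max(-0.5, 0.5 * (sm - sp) / den))
    }
    if (pk[1] > 1 && pk[1] < nrow(ncc))
      dr <- refine(ncc[pk[1] - 1, pk[2]], m, ncc[pk[1] + 1, pk[2]])
    if (pk[2] > 1 && pk[2] < ncol(ncc))
      dc <- refine(ncc[pk[1], pk[2] - 1], m, ncc[pk[1], pk[2] + 1])
  }
  row <- window[1] + pk[1] - 1L
  col <- window[3] + pk[2] - 1L
  structure(list(
    row = row, col = col,
    center_row = row + (nrow(template) - 1) / 2 + dr,
    center_col = col + (ncol(template) - 1) / 2 + dc,
    score = m, low_confidence = m < conf_threshold,
    window = window), class = "tumor_location")
}

#' Tracking options
#'
#' Bundles the per-frame processing parameters of [track_sequence()].
#'
#' @param U,V tile grid dimensions.
#' @param tile_px tile size, px (see [recommend_tile_size()]).
#' @param p_offset base grid start `c(u, v)`; NULL centres the grid.
#' @param search_step_px tile-shift search step (default tile/8).
#' @param clahe a [clahe_params()] applied to projection and DRR, or
#'   NULL to skip contrast correction.
#' @param markers NULL, or a list with `template` (a
#'   [marker_template()]) and `count`: markers are detected and
#'   inpainted on every projection before matching.
#' @param template_margin_px margin kept around the tumor DRR's
#'   bounding box when cropping the matching template.
#' @param window_halfwidth_px half-width of the search window centred
#'   on the previous frame's location (default 0.75 x tile size).
#' @param subpixel enable sub-pixel refinement in [match_template()].
#' @return A list of class `track_options`.
#' @export
track_options <- function(U = 3L, V = 3L, tile_px, p_offset = NULL,
                          search_step_px = NULL, clahe = clahe_params(),
                          markers = NULL, template_margin_px = 4L,
                          window_halfwidth_px = NULL, subpixel = FALSE) {
  if (is.null(window_halfwidth_px))
    window_halfwidth_px <- ceiling(0.75 * max(tile_px))
  structure(list(U = U, V = V, tile_px = tile_px, p_offset = p_offset,
                 search_step_px = search_step_px, clahe = clahe,
                 markers = markers,
                 template_margin_px = template_margin_px,
                 window_halfwidth_px = window_halfwidth_px,
                 subpixel = subpixel),
            class = "track_options")
}

# Crop the tumor DRR to its support (plus margin); returns the template
# and the (row, col) of the projected planning centre inside it.
crop_tumor_template <- function(tumor_drr, center_px, margin_px = 4L,
                                support_frac = 0.05) {
  keep <- tumor_drr > max(tumor_drr) * support_frac
  if (!any(keep)) stop("tumor DRR is empty")
  idx <- which(keep, arr.ind = TRUE)
  r1 <- max(1L, min(idx[, 1]) - margin_px)
  r2 <- min(nrow(tumor_drr), max(idx[, 1]) + margin_px)
  c1 <- max(1L, min(idx[, 2]) - margin_px)
  c2 <- min(ncol(tumor_drr), max(idx[, 2]) + margin_px)
  list(template = tumor_drr[r1:r2, c1:c2],
       anchor_row = center_px["v_px"] - r1 + 1,
       anchor_col = center_px["u_px"] - c1 + 1)
}

#' Track a tumor through a projection sequence
#'
#' Runs the full two-step matching per frame: optional marker removal,
#' CLAHE on projection and background DRR, tile-shift NCC registration
#' with bad-tile exclusion on the contrast-corrected pair, then
#' per-tile linear intensity mapping and background subtraction in the
#' raw intensity space (the linear maps absorb the global intensity
#' discrepancy directly, and the residual tumor shape stays
#' undeformed), then NCC template matching of the tumor DRR over the
#' residual. The search window is centred on the last confident
#' estimate, seeded with the projected planning tumor position (the
#' first frame, and any frame following only low-confidence matches,
#' searches a doubled window so an unknown initial offset is still
#' covered). A failing stage flags the frame and the trajectory
#' continues.
#'
#' @param projections list of projection matrices (one per frame).
#' @param background_drr background DRR matrix for this beam angle.
#' @param tumor_drr tumor-only DRR matrix for this beam angle.
#' @param geometry the [projection_geometry()] shared by all frames.
#' @param options a [track_options()].
#' @param planning_center_mm planning tumor centre in world mm (the
#'   template anchor); defaults to the isocenter.
#' @return A `trajectory` data.frame: `frame` (0-based), `u_px`,
#'   `v_px`, `x_mm_iso`, `y_mm_iso`, `ncc_peak`, `flag`; attributes
#'   `geometry` and `diagnostics` (per-frame tile offsets and NCC
#'   matrices).
#' @export
track_sequence <- function(projections, background_drr, tumor_drr,
                           geometry, options,
                           planning_center_mm = c(0, 0, 0)) {
  n <- length(projections)
  stopifnot(n >= 1)
  shape <- dim(background_drr)
  tile_px <- options$tile_px
  base_off <- options$p_offset
  if (is.null(base_off)) {
    base_off <- c(floor((shape[2] - options$U * max(tile_px)) / 2),
                  floor((shape[1] - options$V * max(tile_px)) / 2))
  }
  base <- make_tile_config(shape, options$U, options$V, tile_px,
                           p_offset = base_off)
  pc <- project_point(geometry, planning_center_mm)
  tpl <- crop_tumor_template(tumor_drr,
                             c(u_px = pc$u_px, v_px = pc$v_px),
                             options$template_margin_px)
  D_cl <- if (is.null(options$clahe)) background_drr else
    apply_clahe(background_drr, options$clahe)
  ctr_px <- (geometry$detector_px + 1) / 2
  out <- data.frame(frame = seq_len(n) - 1L, u_px = NA_real_,
                    v_px = NA_real_, x_mm_iso = NA_real_,
                    y_mm_iso = NA_real_, ncc_peak = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  diagnostics <- vector("list", n)
  # window anchor (row, col): last confident estimate, seeded with the
  # projected planning position
  anchor <- c(pc$v_px, pc$u_px)
  anchored <- FALSE
  hw <- options$window_halfwidth_px
  for (k in seq_len(n)) {
    loc <- tryCatch({
      P <- projections[[k]]
      if (!is.null(options$markers)) {
        mk <- suppressWarnings(
          detect_markers(P, options$markers$template, options$markers$count))
        if (nrow(mk)) P <- remove_markers(P, mk)
      }
      P_cl <- if (is.null(options$clahe)) P else
        apply_clahe(P, options$clahe)
      # contrast-corrected images drive the similarity search; the
      # intensity fit and subtraction stay in the raw intensity space,
      # which the per-tile linear maps model directly
      match <- optimize_tile_shift(P_cl, D_cl, base,
                                   step_px = options$search_step_px)
      grid <- build_map_grid(P, background_drr, match)
      residual <- subtract_background(P, background_drr, grid)
      whw <- if (anchored) hw else 2 * hw
      window <- c(anchor[1] - whw, anchor[1] + whw,
                  anchor[2] - whw, anchor[2] + whw)
      loc <- match_template(residual, tpl$template, window = window,
                            subpixel = options$subpixel)
      diagnostics[[k]] <- list(offset = match$offset, s = match$s,
                               bad = match$bad, S = match$S)
      loc
    }, error = function(e) e)
    if (inherits(loc, "error")) {
      out$flag[k] <- paste0("error: ", conditionMessage(loc))
      next
    }
    # estimated tumor centre: placement + anchor position in the
    # template + sub-pixel refinement
    u <- loc$col - 1 + tpl$anchor_col +
      (loc$center_col - (loc$col + (ncol(tpl$template) - 1) / 2))
    v <- loc$row - 1 + tpl$anchor_row +
      (loc$center_row - (loc$row + (nrow(tpl$template) - 1) / 2))
    if (!loc$low_confidence) {
      anchor <- c(v, u)
      anchored <- TRUE
    }
    out$u_px[k] <- u
    out$v_px[k] <- v
    out$x_mm_iso[k] <- pixels_to_mm(u - ctr_px[1], geometry)
    out$y_mm_iso[k] <- pixels_to_mm(v - ctr_px[2], geometry)
    out$ncc_peak[k] <- loc$score
    if (loc$low_confidence) out$flag[k] <- "low_confidence"
  }
  attr(out, "geometry") <- geometry
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("trajectory", class(out))
  out
}

#' Score a trajectory against ground truth
#'
#' Per-frame 2D Euclidean difference in isocenter-plane millimetres
#' between tracked and true detector positions, with the maximum and
#' average over the sequence.
#'
#' @param traj a `trajectory` from [track_sequence()].
#' @param truth data.frame with `frame`, `true_u_px`, `true_v_px`
#'   (e.g. from [simulate_kv_sequence()]).
#' @param geometry geometry used for the px-to-mm conversion; defaults
#'   to the trajectory's.
#' @return An object of class `tracking_error_summary`: list with
#'   `per_frame` (data.frame incl. `error_mm`), `max_mm`, `mean_mm`,
#'   `n`.
#' @export
evaluate_tracking <- function(traj, truth, geometry = attr(traj, "geometry")) {
  if (nrow(traj) != nrow(truth))
    stop("trajectory and truth have different lengths")
  m <- merge(as.data.frame(traj)[c("frame", "u_px", "v_px", "ncc_peak",
                                   "flag")],
             truth[c("frame", "true_u_px", "true_v_px")], by = "frame")
  if (nrow(m) != nrow(traj)) stop("frame indices do not align")
  du <- pixels_to_mm(m$u_px - m$true_u_px, geometry)
  dv <- pixels_to_mm(m$v_px - m$true_v_px, geometry)
  m$error_mm <- sqrt(du^2 + dv^2)
  structure(list(per_frame = m,
                 max_mm = max(m$error_mm),
                 mean_mm = mean(m$error_mm),
                 n = nrow(m)),
            class = "tracking_error_summary")
}

#' @export
print.tracking_error_summary <- function(x, ...) {
  cat(sprintf(
    "<tracking_error_summary> %d frames: max %.3f mm, mean %.3f mm\n",
    x$n, x$max_mm, x$mean_mm))
  invisible(x)
}
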
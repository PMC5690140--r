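#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization settings. The image
#' is divided into a grid of contextual regions; each region's
#' histogram is clipped at `clip_limit * n_region_pixels` counts (never
#' below the uniform bin height) and the excess is redistributed
#' equally over all bins before the cumulative mapping is formed.
#' Region mappings are blended bilinearly between region centres.
#' An infinite clip limit with a 1 x 1 grid reduces to plain global
#' histogram equalization.
#'
#' @param grid integer length-2, contextual regions (rows, cols).
#' @param clip_limit clip limit as a fraction of the region pixel
#'   count (> 0; `Inf` disables clipping).
#' @param bins histogram bin count (>= 2).
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(grid = c(8L, 8L), clip_limit = 0.01, bins = 256L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2L, all(grid >= 1L), clip_limit > 0, bins >= 2L)
  structure(list(grid = grid, clip_limit = clip_limit,
                 bins = as.integer(bins)),
            class = "clahe_params")
}

#' Apply CLAHE to an image
#'
#' Values are first normalized to `[0, 1]` by the global range and
#' binned as `floor(x * bins) + 1` (clamped to `bins`). Output is in
#' `[0, 1]`. A constant image is returned clamped to `[0, 1]`
#' unchanged otherwise (there is no contrast to equalize).
#'
#' @param image numeric matrix (finite values).
#' @param params a [clahe_params()].
#' @return Numeric matrix in `[0, 1]` of the same size.
#' @export
apply_clahe <- function(image, params = clahe_params()) {
  if (!is.matrix(image) || nrow(image) < 1 || ncol(image) < 1)
    stop("image must be a non-empty numeric matrix")
  if (any(!is.finite(image))) stop("image must be finite")
  nr <- nrow(image); nc <- ncol(image)
  rng <- range(image)
  if (rng[2] == rng[1]) return(matrix(pmin(pmax(image, 0), 1), nr, nc))
  xn <- (image - rng[1]) / (rng[2] - rng[1])
  bins <- params$bins
  B <- pmin(floor(xn * bins) + 1L, bins)
  gr <- params$grid[1]; gc <- params$grid[2]
  rb <- round(seq(0, nr, length.out = gr + 1))
  cb <- round(seq(0, nc, length.out = gc + 1))
  maps <- array(0, c(gr, gc, bins))
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      rows <- (rb[i] + 1):rb[i + 1]
      cols <- (cb[j] + 1):cb[j + 1]
      h <- tabulate(B[rows, cols], nbins = bins)
      npix <- length(rows) * length(cols)
      clip <- max(params$clip_limit * npix, npix / bins)
      if (is.finite(clip)) {
        excess <- sum(pmax(h - clip, 0))
        h <- pmin(h, clip) + excess / bins
      }
      maps[i, j, ] <- cumsum(h) / sum(h)
    }
  }
  # bilinear blend between region-centre mappings, clamped outside
  blend_weights <- function(n, bounds, g) {
    centers <- (bounds[-1] + bounds[-(g + 1)] + 1) / 2
    pos <- seq_len(n)
    if (g == 1L) return(list(i0 = rep(1L, n), w = rep(0, n)))
    i0 <- findInterval(pos, centers, rightmost.closed = FALSE)
    i0 <- pmin(pmax(i0, 1L), g - 1L)
    w <- (pos - centers[i0]) / (centers[i0 + 1] - centers[i0])
    list(i0 = i0, w = pmin(pmax(w, 0), 1))
  }
  wr <- blend_weights(nr, rb, gr)
  wc <- blend_weights(nc, cb, gc)
  Ri <- matrix(wr$i0, nr, nc); Rw <- matrix(wr$w, nr, nc)
  Ci <- matrix(wc$i0, nr, nc, byrow = TRUE)
  Cw <- matrix(wc$w, nr, nc, byrow = TRUE)
  Ri1 <- pmin(Ri + 1L, gr); Ci1 <- pmin(Ci + 1L, gc)
  look <- function(I, J) array(maps[cbind(as.vector(I), as.vector(J),
                                          as.vector(B))], dim(B))
  out <- (1 - Rw) * (1 - Cw) * look(Ri, Ci) +
    Rw * (1 - Cw) * look(Ri1, Ci) +
    (1 - Rw) * Cw * look(Ri, Ci1) +
    Rw * Cw * look(Ri1, Ci1)
  out
}

#' Analytic projected-sphere template
#'
#' Template for detecting spherical fiducial markers: each pixel holds
#' the chord length of a ray through a sphere of the given radius,
#' `2 * sqrt(r^2 - d^2)`, matching a marker's contribution to a line
#' integral. NCC matching is invariant to the template's scale.
#'
#' @param radius_px marker radius on the detector, px.
#' @return Numeric square matrix with attribute `radius_px`.
#' @export
marker_template <- function(radius_px) {
  stopifnot(radius_px > 0)
  half <- ceiling(radius_px) + 1L
  d <- seq(-half, half)
  D2 <- outer(d^2, d^2, "+")
  tpl <- 2 * sqrt(pmax(radius_px^2 - D2, 0))
  attr(tpl, "radius_px") <- radius_px
  tpl
}

#' Detect implanted markers by template matching
#'
#' Scans the template over the image with normalized cross-correlation
#' and returns the `count` highest non-overlapping peaks (greedy
#' maximum with suppression of a neighborhood of `min_separation_px`
#' around each accepted peak). If fewer acceptable peaks exist, the
#' available ones are returned with a warning.
#'
#' @param image numeric matrix.
#' @param template matching template (e.g. [marker_template()]),
#'   strictly smaller than the image.
#' @param count number of markers expected.
#' @param min_separation_px minimum centre separation between peaks.
#' @param min_score peaks below this NCC are not reported.
#' @return `marker_set`: data.frame with columns `row`, `col` (centre,
#'   px), `score`; attribute `radius_px`.
#' @export
detect_markers <- function(image, template, count,
                           min_separation_px = max(dim(template)),
                           min_score = 0.2) {
  if (any(dim(template) >= dim(image)))
    stop("template must be strictly smaller than the image")
  ncc <- ncc_scan_cpp(image, template)
  off_r <- (nrow(template) - 1) / 2
  off_c <- (ncol(template) - 1) / 2
  res <- data.frame(row = numeric(0), col = numeric(0), score = numeric(0))
  for (k in seq_len(count)) {
    best <- which.max(ncc)
    s <- ncc[best]
    if (!is.finite(s) || s < min_score) break
    r <- (best - 1) %% nrow(ncc) + 1
    c <- (best - 1) %/% nrow(ncc) + 1
    res <- rbind(res, data.frame(row = r + off_r, col = c + off_c,
                                 score = s))
    rr <- pmax(1, r - min_separation_px):pmin(nrow(ncc), r + min_separation_px)
    cc <- pmax(1, c - min_separation_px):pmin(ncol(ncc), c + min_separation_px)
    ncc[rr, cc] <- -Inf
  }
  if (nrow(res) < count)
    warning(sprintf("requested %d markers but only %d acceptable peaks found",
                    count, nrow(res)))
  attr(res, "radius_px") <- attr(template, "radius_px")
  class(res) <- c("marker_set", class(res))
  res
}

#' Remove markers by shrinking-radius inpainting
#'
#' Places a disk mask over each marker and fills it from the boundary
#' inward: at each peel, every masked pixel with at least one valid
#' 8-neighbor is replaced (in row-major raster order, newly filled
#' pixels immediately becoming valid) by the mean of its valid
#' 8-neighbors; the masked radius effectively shrinks by one per peel
#' until the marker vanishes. The filled pixels are then relaxed to the
#' discrete harmonic (Laplace) solution with the surrounding pixels as
#' boundary, which removes the fill-order anisotropy. Pixels outside
#' the disks are returned bit-identical.
#'
#' @param image numeric matrix.
#' @param markers a `marker_set` from [detect_markers()], or a
#'   data.frame with `row`, `col` columns.
#' @param radius_px disk radius to inpaint (defaults to the marker
#'   set's `radius_px` plus one pixel of margin).
#' @return Numeric matrix with the marker disks filled smoothly.
#' @export
remove_markers <- function(image, markers,
                           radius_px = attr(markers, "radius_px") + 1) {
  if (is.null(radius_px)) stop("radius_px must be given")
  nr <- nrow(image); nc <- ncol(image)
  mask <- matrix(FALSE, nr, nc)
  rad <- ceiling(radius_px)
  for (i in seq_len(nrow(markers))) {
    r0 <- markers$row[i]; c0 <- markers$col[i]
    if (r0 - rad < 1 || r0 + rad > nr || c0 - rad < 1 || c0 + rad > nc)
      stop("marker disk touches the image border")
    rs <- (round(r0) - rad):(round(r0) + rad)
    cs <- (round(c0) - rad):(round(c0) + rad)
    dd <- outer((rs - r0)^2, (cs - c0)^2, "+")
    mask[rs, cs] <- mask[rs, cs] | (dd <= radius_px^2)
  }
  inpaint_mask(image, mask)
}

# Peel-fill a logical mask in 2D (8-neighbor means, raster order),
# then relax the filled pixels to the discrete harmonic (4-neighbor
# Laplace) solution with the surrounding image as Dirichlet boundary.
# The peel supplies a good initial guess; Gauss-Seidel sweeps converge
# it the rest of the way.
inpaint_mask <- function(image, mask) {
  out <- peel_fill(image, mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  nr <- nrow(out); nc <- ncol(out)
  if (any(idx[, 1] == 1 | idx[, 1] == nr | idx[, 2] == 1 | idx[, 2] == nc))
    stop("mask touches the image border")
  scale <- max(diff(range(image)), .Machine$double.eps)
  up <- cbind(idx[, 1] - 1L, idx[, 2]); down <- cbind(idx[, 1] + 1L, idx[, 2])
  left <- cbind(idx[, 1], idx[, 2] - 1L); right <- cbind(idx[, 1], idx[, 2] + 1L)
  for (it in seq_len(10000L)) {
    new <- (out[up] + out[down] + out[left] + out[right]) / 4
    delta <- max(abs(new - out[idx]))
    out[idx] <- new
    if (delta < 1e-10 * scale) break
  }
  out
}

peel_fill <- function(image, mask) {
  out <- image
  nr <- nrow(out); nc <- ncol(out)
  noff <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  noff <- noff[!(noff[, 1] == 0 & noff[, 2] == 0), ]
  while (any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    # boundary: masked pixels with a valid neighbor at peel start
    is_boundary <- vapply(seq_len(nrow(idx)), function(k) {
      r <- idx[k, 1]; c <- idx[k, 2]
      rs <- r + noff[, 1]; cs <- c + noff[, 2]
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      any(!mask[cbind(rs[ok], cs[ok])])
    }, logical(1))
    bnd <- idx[is_boundary, , drop = FALSE]
    if (!nrow(bnd)) stop("mask has no boundary to fill from")
    ord <- order(bnd[, 1], bnd[, 2])  # row-major raster order
    for (k in ord) {
      r <- bnd[k, 1]; c <- bnd[k, 2]
      rs <- r + noff[, 1]; cs <- c + noff[, 2]
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      rc <- cbind(pmin(pmax(rs, 1), nr), pmin(pmax(cs, 1), nc))
      valid <- ok & !mask[rc]
      vi <- cbind(rs[valid], cs[valid])
      out[r, c] <- mean(out[vi])
      mask[r, c] <- FALSE
    }
  }
  out
}

#' Remove markers from a CT volume
#'
#' 3D analogue of [remove_markers()]: spheres at the known planning
#' marker positions are peeled from the boundary inward using
#' 26-neighbor means in raster order.
#'
#' @param vol a [volume3d()].
#' @param centers_mm matrix of marker centres (one row per marker), mm.
#' @param radius_mm sphere radius to replace, mm.
#' @return A [volume3d()] with marker voxels replaced.
#' @export
remove_markers_volume <- function(vol, centers_mm, radius_mm) {
  if (!nrow(centers_mm)) return(vol)
  d <- dim(vol$data)
  xs <- voxel_coords(vol, 1); ys <- voxel_coords(vol, 2)
  zs <- voxel_coords(vol, 3)
  mask <- array(FALSE, d)
  for (i in seq_len(nrow(centers_mm))) {
    m <- centers_mm[i, ]
    ix <- which(abs(xs - m[1]) <= radius_mm + max(vol$spacing))
    iy <- which(abs(ys - m[2]) <= radius_mm + max(vol$spacing))
    iz <- which(abs(zs - m[3]) <= radius_mm + max(vol$spacing))
    for (k in iz) for (j in iy) {
      dd <- (xs[ix] - m[1])^2 + (ys[j] - m[2])^2 + (zs[k] - m[3])^2
      mask[ix[dd <= radius_mm^2], j, k] <- TRUE
    }
  }
  out <- vol$data
  noff <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  noff <- noff[rowSums(noff != 0) > 0, ]
  while (any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    is_boundary <- vapply(seq_len(nrow(idx)), function(k) {
      p <- idx[k, ]
      nb <- sweep(noff, 2, p, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      any(!mask[nb[ok, , drop = FALSE]])
    }, logical(1))
    bnd <- idx[is_boundary, , drop = FALSE]
    if (!nrow(bnd)) stop("marker mask has no boundary to fill from")
    ord <- order(bnd[, 1], bnd[, 2], bnd[, 3])
    for (k in ord) {
      p <- bnd[k, ]
      nb <- sweep(noff, 2, p, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      valid <- !mask[nb]
      out[p[1], p[2], p[3]] <- mean(out[nb[valid, , drop = FALSE]])
      mask[p[1], p[2], p[3]] <- FALSE
    }
  }
  volume3d(out, vol$spacing, vol$origin)
}
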
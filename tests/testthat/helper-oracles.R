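# Independent reference implementations used as oracles. These are
# deliberately written from the definitions (direct formulas, exhaustive
# scans, dense solves) and share no code with the package internals.

# Direct element-wise evaluation of the tile NCC definition.
ncc_ref <- function(p, d) {
  pm <- sum(p) / length(p)
  dm <- sum(d) / length(d)
  num <- sum((p - pm) * (d - dm))
  den <- sqrt(sum((p - pm)^2)) * sqrt(sum((d - dm)^2))
  if (den == 0) return(0)
  num / den
}

# Exhaustive NCC scan of a template over an image; returns the full
# placement map computed via ncc_ref.
ncc_scan_ref <- function(img, tpl) {
  nr <- nrow(img) - nrow(tpl) + 1
  nc <- ncol(img) - ncol(tpl) + 1
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr))
    for (c in seq_len(nc))
      out[r, c] <- ncc_ref(img[r:(r + nrow(tpl) - 1),
                               c:(c + ncol(tpl) - 1)], tpl)
  out
}

# Homogeneous-matrix pinhole projection: rotate the world into the beam
# frame, then project with a 3x4 camera matrix.
project_point_ref <- function(geometry, point) {
  phi <- (geometry$gantry_deg + geometry$imager_deg) * pi / 180
  Rz <- matrix(c(cos(-phi), -sin(-phi), 0,
                 sin(-phi), cos(-phi), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  q <- Rz %*% point          # beam frame: source on -y axis
  # camera at (0, -SAD, 0) looking along +y; image plane at y = SDD - SAD
  P <- rbind(c(geometry$sdd, 0, 0, 0),
             c(0, 0, geometry$sdd, 0),
             c(0, 1, 0, geometry$sad))
  h <- P %*% c(q[1], q[2], q[3], 1)
  c(u_mm = h[1] / h[3], v_mm = h[2] / h[3])
}

# Closed-form length of a ray segment inside an axis-aligned box.
ray_box_length_ref <- function(orig, dir, lo, hi) {
  tmin <- -Inf; tmax <- Inf
  for (a in 1:3) {
    if (abs(dir[a]) < 1e-14) {
      if (orig[a] < lo[a] || orig[a] > hi[a]) return(0)
    } else {
      t1 <- (lo[a] - orig[a]) / dir[a]
      t2 <- (hi[a] - orig[a]) / dir[a]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  max(0, tmax - tmin)
}

# Plain global histogram equalization by direct CDF mapping, using the
# same binning convention as the package (floor(x * bins) + 1, clamped).
hist_eq_ref <- function(img, bins = 256L) {
  rng <- range(img)
  xn <- (img - rng[1]) / (rng[2] - rng[1])
  b <- pmin(floor(xn * bins) + 1L, bins)
  h <- tabulate(b, nbins = bins)
  cdf <- cumsum(h) / sum(h)
  matrix(cdf[b], nrow(img), ncol(img))
}

# Dense solve of the discrete Laplace equation on masked pixels with
# the surrounding image as Dirichlet boundary (4-neighbor stencil).
laplace_fill_ref <- function(img, mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  id <- matrix(0L, nrow(img), ncol(img))
  id[mask] <- seq_len(n)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (k in seq_len(n)) {
    r <- idx[k, 1]; c <- idx[k, 2]
    A[k, k] <- 4
    for (nb in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      if (mask[nb[1], nb[2]]) {
        A[k, id[nb[1], nb[2]]] <- A[k, id[nb[1], nb[2]]] - 1
      } else {
        b[k] <- b[k] + img[nb[1], nb[2]]
      }
    }
  }
  out <- img
  out[mask] <- solve(A, b)
  out
}

# Density-weighted centroid of a mask volume in world mm, computed by
# direct summation over voxel centres.
mask_centroid_ref <- function(vol) {
  idx <- which(vol$data > 0, arr.ind = TRUE)
  w <- vol$data[vol$data > 0]
  xyz <- sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  colSums(xyz * w) / sum(w)
}

# Brute-force equivalent of the tile-shift optimizer: scan the same
# joint-offset grid, score every valid configuration by the mean NCC of
# all tiles except the minimum, pick the first maximum.
optimize_shift_ref <- function(P, D, base, step) {
  tile <- min(base$tile_w, base$tile_h)
  offs <- seq(0L, tile - 1L, by = step)
  best <- NULL
  for (ou in offs) for (ov in offs) {
    p <- base$p_offset + c(ou, ov)
    if (base$U * base$tile_w + p[1] > ncol(P)) next
    if (base$V * base$tile_h + p[2] > nrow(P)) next
    s <- matrix(NA_real_, base$V, base$U)
    for (v in seq_len(base$V)) for (u in seq_len(base$U)) {
      rows <- p[2] + (v - 1) * base$tile_h + seq_len(base$tile_h)
      cols <- p[1] + (u - 1) * base$tile_w + seq_len(base$tile_w)
      s[v, u] <- ncc_ref(P[rows, cols], D[rows, cols])
    }
    S <- mean(sort(as.numeric(s))[-1])
    if (is.null(best) || S > best$S)
      best <- list(S = S, offset = c(ou, ov), s = s)
  }
  best
}
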
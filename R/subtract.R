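#' Fit a linear intensity transform between a DRR tile and a projection tile
#'
#' Ordinary least squares for `P ~ a * D + b` over one tile pair. A
#' constant (zero-variance) DRR tile is degenerate: the fit falls back
#' to `a = 0`, `b = mean(P)` and is flagged.
#'
#' @param P_tile,D_tile congruent numeric matrices.
#' @return Named numeric `c(a, b)` with attribute `degenerate`.
#' @export
fit_tile_intensity_map <- function(P_tile, D_tile) {
  if (!identical(dim(P_tile), dim(D_tile)))
    stop("tiles must be congruent")
  dmean <- mean(D_tile); pmean <- mean(P_tile)
  dz <- D_tile - dmean
  ssd <- sum(dz^2)
  if (ssd <= 0) {
    out <- c(a = 0, b = pmean)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  a <- sum(dz * (P_tile - pmean)) / ssd
  out <- c(a = a, b = pmean - a * dmean)
  attr(out, "degenerate") <- FALSE
  out
}

#' Per-tile intensity maps interpolated to pixel level
#'
#' Fits a linear gain/offset per good tile, replaces the bad tile's
#' coefficients by interpolation from its axial neighbors (mean of the
#' equidistant 4-neighborhood in the tile grid; edge and corner bad
#' tiles use the available neighbors, inverse-distance weighted), and
#' builds continuous pixel-level coefficient fields by bilinear
#' interpolation between tile centres, clamped to constants outside the
#' outermost centres. The fields equal the grid values exactly at tile
#' centres, so tile-induced boundaries cannot appear in the transformed
#' DRR.
#'
#' @param P projection image (matrix).
#' @param D background DRR (matrix).
#' @param match a `tile_match` from [optimize_tile_shift()], or any
#'   list with a `config` and a `bad` index.
#' @return An object of class `intensity_map_grid`: `a`, `b` (`V x U`
#'   coefficient matrices), `centers_row`/`centers_col` (tile-centre
#'   pixel coordinates on the projection), `a_field`, `b_field`
#'   (pixel-level matrices), `bad`, `degenerate` (logical `V x U`).
#' @export
build_map_grid <- function(P, D, match) {
  cfg <- match$config
  A <- matrix(NA_real_, cfg$V, cfg$U)
  B <- matrix(NA_real_, cfg$V, cfg$U)
  degen <- matrix(FALSE, cfg$V, cfg$U)
  for (v in seq_len(cfg$V)) for (u in seq_len(cfg$U)) {
    rp <- tile_rect(cfg, u, v, "P"); rd <- tile_rect(cfg, u, v, "D")
    fit <- fit_tile_intensity_map(P[rp$rows, rp$cols], D[rd$rows, rd$cols])
    A[v, u] <- fit["a"]; B[v, u] <- fit["b"]
    degen[v, u] <- attr(fit, "degenerate")
  }
  bu <- match$bad["u"]; bv <- match$bad["v"]
  nb <- rbind(c(bv - 1, bu), c(bv + 1, bu), c(bv, bu - 1), c(bv, bu + 1))
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= cfg$V & nb[, 2] >= 1 & nb[, 2] <= cfg$U,
           , drop = FALSE]
  if (sum(degen[nb]) > 1)
    stop("more than one degenerate tile adjacent to the bad tile; ",
         "intensity interpolation is unreliable")
  nb <- nb[!degen[nb], , drop = FALSE]
  if (!nrow(nb)) stop("bad tile has no usable neighbors")
  # neighbors are axial, so distances are one tile pitch per axis;
  # inverse-distance weighting over the available ones reduces to the
  # plain mean for the equidistant interior case
  d <- sqrt(((nb[, 1] - bv) * cfg$tile_h)^2 + ((nb[, 2] - bu) * cfg$tile_w)^2)
  w <- (1 / d) / sum(1 / d)
  A[bv, bu] <- sum(w * A[nb]); B[bv, bu] <- sum(w * B[nb])
  centers_col <- cfg$p_offset[1] + (seq_len(cfg$U) - 1) * cfg$tile_w +
    (cfg$tile_w + 1) / 2
  centers_row <- cfg$p_offset[2] + (seq_len(cfg$V) - 1) * cfg$tile_h +
    (cfg$tile_h + 1) / 2
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  Wr <- interp_weights(seq_len(nr), centers_row)
  Wc <- interp_weights(seq_len(nc), centers_col)
  grid <- list(a = A, b = B,
               centers_row = centers_row, centers_col = centers_col,
               a_field = Wr %*% A %*% t(Wc), b_field = Wr %*% B %*% t(Wc),
               bad = match$bad, degenerate = degen, config = cfg)
  class(grid) <- "intensity_map_grid"
  grid
}

# n x k matrix of clamped piecewise-linear interpolation weights from k
# ordered node positions to n query positions.
interp_weights <- function(pos, nodes) {
  k <- length(nodes)
  W <- matrix(0, length(pos), k)
  if (k == 1L) { W[, 1] <- 1; return(W) }
  i0 <- pmin(pmax(findInterval(pos, nodes), 1L), k - 1L)
  t <- (pos - nodes[i0]) / (nodes[i0 + 1] - nodes[i0])
  t <- pmin(pmax(t, 0), 1)  # constant extrapolation beyond the ends
  W[cbind(seq_along(pos), i0)] <- 1 - t
  W[cbind(seq_along(pos), i0 + 1L)] <- W[cbind(seq_along(pos), i0 + 1L)] + t
  W
}

#' Subtract the intensity-transformed DRR from the projection
#'
#' Applies the pixel-level linear transform to the (grid-aligned) DRR
#' and subtracts it from the projection:
#' `residual = P - (a_field * D + b_field)`. When the matched
#' configuration tiled the DRR at a different start offset than the
#' projection, the DRR is first translated by the relative offset
#' (edge-replicated) so corresponding content lines up.
#'
#' @param P projection image (matrix).
#' @param D background DRR (matrix).
#' @param grid an [build_map_grid()] result.
#' @return Residual matrix, with the tumor left as the dominant
#'   difference when the background model fits.
#' @export
subtract_background <- function(P, D, grid) {
  if (!identical(dim(P), dim(D)) ||
      !identical(dim(P), dim(grid$a_field)))
    stop("projection, DRR and coefficient fields must be congruent")
  cfg <- grid$config
  rel <- cfg$p_offset - cfg$d_offset  # (u, v) shift aligning D to P
  Ds <- translate_replicate(D, rel[2], rel[1])
  P - (grid$a_field * Ds + grid$b_field)
}

# Integer translation with edge replication: out[r, c] = x[r - dr, c - dc].
translate_replicate <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}
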
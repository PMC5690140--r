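#' Tile configuration for tiled NCC matching
#'
#' Partitions a projection and a background DRR into a `U x V` matrix of
#' non-overlapping tiles. Tile `(u, v)` covers, on the projection,
#' columns `p_u + (u-1)*w + 1 ... p_u + u*w` and rows
#' `p_v + (v-1)*h + 1 ... p_v + v*h` (offsets in px, 0 meaning the grid
#' starts at the first pixel), and correspondingly on the DRR with the
#' `d` offsets. Tiles must lie fully inside both images; configurations
#' that would overflow are rejected.
#'
#' @param image_shape integer length-2 `c(rows, cols)` of both images.
#' @param U,V tile columns and rows.
#' @param tile_px tile size in px: scalar or `c(width, height)`.
#' @param p_offset projection grid start offset `c(u, v)` in px (>= 0).
#' @param d_offset DRR grid start offset `c(u, v)` in px (defaults to
#'   `p_offset`).
#' @return An object of class `tile_config`.
#' @export
make_tile_config <- function(image_shape, U = 3L, V = 3L, tile_px,
                             p_offset = c(0, 0), d_offset = p_offset) {
  U <- as.integer(U); V <- as.integer(V)
  stopifnot(U >= 1L, V >= 1L)
  if (length(tile_px) == 1L) tile_px <- c(tile_px, tile_px)
  w <- as.integer(tile_px[1]); h <- as.integer(tile_px[2])
  stopifnot(w >= 1L, h >= 1L)
  p_offset <- as.integer(round(p_offset)); d_offset <- as.integer(round(d_offset))
  if (any(p_offset < 0) || any(d_offset < 0)) stop("offsets must be >= 0")
  nr <- image_shape[1]; nc <- image_shape[2]
  max_pu <- nc - U * w; max_pv <- nr - V * h
  if (max_pu < 0 || max_pv < 0)
    stop(sprintf("%d x %d tiles of %d x %d px exceed a %d x %d image",
                 U, V, w, h, nr, nc))
  for (off in list(p = p_offset, d = d_offset)) {
    if (off[1] > max_pu || off[2] > max_pv)
      stop(sprintf(
        "tile grid overflows the image; maximal feasible offset is (%d, %d)",
        max_pu, max_pv))
  }
  structure(list(U = U, V = V, tile_w = w, tile_h = h,
                 p_offset = p_offset, d_offset = d_offset,
                 image_shape = as.integer(image_shape)),
            class = "tile_config")
}

#' @export
print.tile_config <- function(x, ...) {
  cat(sprintf(
    "<tile_config> %d x %d tiles of %d x %d px, P start (%d, %d), D start (%d, %d)\n",
    x$U, x$V, x$tile_w, x$tile_h, x$p_offset[1], x$p_offset[2],
    x$d_offset[1], x$d_offset[2]))
  invisible(x)
}

#' Recommended tile size for a given tumor extent
#'
#' Tiles should be a little larger than the tumor so the whole tumor
#' can be isolated inside one tile: the recommendation is
#' `ceiling(1.35 * extent)`, inside the guidance band of 1.2 to 1.5
#' times the tumor size.
#'
#' @param tumor_extent_px projected tumor extent in px.
#' @return Integer tile size in px.
#' @export
recommend_tile_size <- function(tumor_extent_px) {
  stopifnot(tumor_extent_px > 0)
  as.integer(ceiling(1.35 * tumor_extent_px))
}

# Row / column index ranges of tile (u, v) on the projection (side =
# "P") or DRR (side = "D").
tile_rect <- function(config, u, v, side = c("P", "D")) {
  side <- match.arg(side)
  off <- if (side == "P") config$p_offset else config$d_offset
  list(rows = off[2] + (v - 1L) * config$tile_h + seq_len(config$tile_h),
       cols = off[1] + (u - 1L) * config$tile_w + seq_len(config$tile_w))
}

#' Per-tile normalized cross-correlation
#'
#' NCC between projection tile `(u, v)` and the corresponding DRR tile:
#' mean-subtracted cross-products normalized by the product of
#' root-sum-square deviations. A tile with zero variance on either side
#' scores 0 by convention (a constant tile carries no matching
#' evidence).
#'
#' @param P projection image (matrix).
#' @param D background DRR (matrix).
#' @param config a [make_tile_config()].
#' @param u,v tile column and row indices (1-based).
#' @return NCC value in `[-1, 1]`.
#' @export
tile_ncc <- function(P, D, config, u, v) {
  rp <- tile_rect(config, u, v, "P")
  rd <- tile_rect(config, u, v, "D")
  pz <- P[rp$rows, rp$cols]; pz <- pz - mean(pz)
  dz <- D[rd$rows, rd$cols]; dz <- dz - mean(dz)
  den <- sqrt(sum(pz^2) * sum(dz^2))
  if (den <= 0) return(0)
  min(1, max(-1, sum(pz * dz) / den))
}

#' NCC matrix over all tiles
#'
#' @inheritParams tile_ncc
#' @return `V x U` matrix `s` with `s[v, u] = tile_ncc(P, D, config, u, v)`.
#' @export
tile_ncc_matrix <- function(P, D, config) {
  s <- matrix(NA_real_, config$V, config$U)
  for (v in seq_len(config$V))
    for (u in seq_len(config$U))
      s[v, u] <- tile_ncc(P, D, config, u, v)
  s
}

#' Total NCC over the tile matrix
#'
#' Mean of the per-tile NCC values; with bad-tile exclusion the single
#' lowest tile (assumed to hold the tumor) is dropped before averaging.
#'
#' @param s_matrix `V x U` matrix of per-tile NCC values.
#' @param exclude_bad drop the minimum tile before averaging.
#' @return Total NCC in `[-1, 1]`.
#' @export
total_ncc <- function(s_matrix, exclude_bad = TRUE) {
  vals <- as.numeric(s_matrix)
  if (exclude_bad) {
    if (length(vals) <= 1L)
      stop("bad-tile exclusion undefined for a single tile")
    vals <- vals[-which.min(vals)]
  }
  mean(vals)
}

#' Index of the bad tile
#'
#' The tile with the lowest similarity is taken to contain the tumor.
#' Ties break to the first occurrence in row-major order (smallest v,
#' then smallest u).
#'
#' @param s_matrix `V x U` matrix of per-tile NCC values.
#' @return Named integer vector `c(u, v)` (1-based).
#' @export
find_bad_tile <- function(s_matrix) {
  cand <- which(s_matrix == min(s_matrix), arr.ind = TRUE)
  first <- cand[order(cand[, 1], cand[, 2])[1], ]
  c(u = unname(first[2]), v = unname(first[1]))
}

#' Optimize the tile-grid shift to isolate the tumor in one tile
#'
#' Exhaustively evaluates grid start offsets over a search grid, scoring
#' each candidate by the total NCC with the bad tile excluded, and
#' returns the best configuration. In the default `"joint"` mode a
#' common offset is added to the projection and DRR grid starts, so the
#' compared content stays aligned and only the tile boundaries move
#' (relocating them until the tumor discrepancy falls inside a single
#' tile). Mode `"both"` additionally searches a relative offset of the
#' DRR grid (a rigid-registration search for misaligned acquisitions).
#' Candidates whose tiles would extend past an image are skipped rather
#' than padded. Ties resolve to the lexicographically smallest offset.
#'
#' @param P projection image (matrix).
#' @param D background DRR (matrix).
#' @param base a [make_tile_config()]; the search is relative to its
#'   offsets and the base offset is part of the grid.
#' @param search_range_px largest offset tried per axis (default: tile
#'   size minus one).
#' @param step_px search step (default: tile size / 8, at least 1).
#' @param mode `"joint"` (default) or `"both"`.
#' @param relative_range_px,relative_step_px search grid for the DRR's
#'   relative offset in `"both"` mode.
#' @return An object of class `tile_match`: list with `config`, `s`
#'   (the NCC matrix), `bad` (bad-tile index `c(u, v)`), `S` (total NCC
#'   excluding the bad tile), `offset` (chosen common offset), and
#'   `rel_offset` (chosen DRR-relative offset).
#' @export
optimize_tile_shift <- function(P, D, base,
                                search_range_px = NULL, step_px = NULL,
                                mode = c("joint", "both"),
                                relative_range_px = 4L,
                                relative_step_px = 2L) {
  mode <- match.arg(mode)
  tile <- min(base$tile_w, base$tile_h)
  if (is.null(search_range_px)) search_range_px <- tile - 1L
  if (is.null(step_px)) step_px <- max(1L, tile %/% 8L)
  offs <- seq(0L, as.integer(search_range_px), by = as.integer(step_px))
  rels <- if (mode == "both")
    seq(-as.integer(relative_range_px), relative_range_px,
        by = as.integer(relative_step_px)) else 0L
  best <- NULL
  for (ou in offs) for (ov in offs) for (eu in rels) for (ev in rels) {
    cfg <- tryCatch(
      make_tile_config(base$image_shape, base$U, base$V,
                       c(base$tile_w, base$tile_h),
                       p_offset = base$p_offset + c(ou, ov),
                       d_offset = base$d_offset + c(ou + eu, ov + ev)),
      error = function(e) NULL)
    if (is.null(cfg)) next
    s <- tile_ncc_matrix(P, D, cfg)
    S <- total_ncc(s, exclude_bad = TRUE)
    if (is.null(best) || S > best$S) {
      best <- list(config = cfg, s = s, bad = find_bad_tile(s), S = S,
                   offset = c(u = ou, v = ov),
                   rel_offset = c(u = eu, v = ev))
    }
  }
  if (is.null(best)) stop("no valid tile configuration in the search grid")
  class(best) <- "tile_match"
  best
}

#' @export
print.tile_match <- function(x, ...) {
  cat(sprintf(
    "<tile_match> S = %.4f (bad tile u=%d, v=%d excluded), offset (%d, %d)\n",
    x$S, x$bad["u"], x$bad["v"], x$offset["u"], x$offset["v"]))
  print(round(x$s, 3))
  invisible(x)
}
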
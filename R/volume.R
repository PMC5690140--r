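#' Scalar volume on a regular grid
#'
#' Container for a 3D voxel grid with physical spacing and origin, used
#' for the planning CT, the tumor contour mask, and the split
#' background / tumor-only volumes. Axis 1 is left-right (x), axis 2
#' anterior-posterior (y), axis 3 superior-inferior (z, the gantry
#' rotation axis). `origin` is the physical position (mm) of the centre
#' of voxel `[1, 1, 1]`.
#'
#' @param data numeric 3D array of voxel intensities (finite).
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (any(!is.finite(data))) stop("voxel intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Physical coordinates of voxel centres
#'
#' @param vol a [volume3d()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of mm positions along that axis.
#' @export
voxel_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Shift a volume by a physical displacement with trilinear resampling
#'
#' Samples the input at `x - displacement`, i.e. the content moves by
#' `+displacement` mm. Samples falling outside the voxel-centre hull
#' take `fill`.
#'
#' @param vol a [volume3d()].
#' @param displacement numeric length-3 displacement in mm.
#' @param fill value used outside the input grid.
#' @return A [volume3d()] on the same grid.
#' @export
shift_volume <- function(vol, displacement, fill = 0) {
  displacement <- as.numeric(displacement)
  stopifnot(length(displacement) == 3L, all(is.finite(displacement)))
  d <- dim(vol$data)
  # continuous 0-based source indices per axis
  g <- lapply(1:3, function(a) {
    (voxel_coords(vol, a) - displacement[a] - vol$origin[a]) / vol$spacing[a]
  })
  interp_axis <- function(gv, n) {
    i0 <- floor(gv)
    f <- gv - i0
    oob <- gv < 0 | gv > (n - 1)
    i0c <- pmin(pmax(i0, 0), n - 2)
    list(i0 = i0c + 1L, f = ifelse(oob, NA_real_, gv - i0c), oob = oob)
  }
  ax <- interp_axis(g[[1]], d[1]); ay <- interp_axis(g[[2]], d[2])
  az <- interp_axis(g[[3]], d[3])
  out <- array(fill, d)
  vx <- vol$data
  # gather the 8 corners with outer index arithmetic (vectorised)
  IX <- array(ax$i0, d); FX <- array(ax$f, d)
  IY <- array(rep(ay$i0, each = d[1]), d)
  FY <- array(rep(ay$f, each = d[1]), d)
  IZ <- array(rep(az$i0, each = d[1] * d[2]), d)
  FZ <- array(rep(az$f, each = d[1] * d[2]), d)
  ok <- !(array(ax$oob, d) | array(rep(ay$oob, each = d[1]), d) |
            array(rep(az$oob, each = d[1] * d[2]), d))
  idx <- function(dx, dy, dz) {
    (IX + dx) + d[1] * ((IY + dy - 1L) + d[2] * (IZ + dz - 1L))
  }
  w000 <- (1 - FX) * (1 - FY) * (1 - FZ); w100 <- FX * (1 - FY) * (1 - FZ)
  w010 <- (1 - FX) * FY * (1 - FZ);       w110 <- FX * FY * (1 - FZ)
  w001 <- (1 - FX) * (1 - FY) * FZ;       w101 <- FX * (1 - FY) * FZ
  w011 <- (1 - FX) * FY * FZ;             w111 <- FX * FY * FZ
  val <- vx[idx(0L, 0L, 0L)] * w000 + vx[idx(1L, 0L, 0L)] * w100 +
    vx[idx(0L, 1L, 0L)] * w010 + vx[idx(1L, 1L, 0L)] * w110 +
    vx[idx(0L, 0L, 1L)] * w001 + vx[idx(1L, 0L, 1L)] * w101 +
    vx[idx(0L, 1L, 1L)] * w011 + vx[idx(1L, 1L, 1L)] * w111
  out[ok] <- val[ok]
  volume3d(out, vol$spacing, vol$origin)
}

#' Read / write uncompressed MetaImage (.mha) volumes
#'
#' Minimal MetaImage support for local (single-file, uncompressed)
#' volumes with element types MET_UCHAR, MET_SHORT, MET_USHORT,
#' MET_FLOAT or MET_DOUBLE.
#'
#' @param vol a [volume3d()].
#' @param path file path ending in `.mha`.
#' @param type element type written, `"float"` or `"double"`.
#' @return `write_mha()` returns `path` invisibly; `read_mha()` a
#'   [volume3d()].
#' @export
write_mha <- function(vol, path, type = c("float", "double")) {
  type <- match.arg(type)
  d <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", if (type == "float") "MET_FLOAT" else "MET_DOUBLE"),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol$data), con,
           size = if (type == "float") 4L else 8L, endian = "little")
  invisible(path)
}

#' @rdname write_mha
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only local (single-file) MetaImage data is supported")
  if (identical(hdr[["CompressedData"]], "True"))
    stop("compressed MetaImage data is not supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  et <- hdr[["ElementType"]]
  spec <- switch(et,
    MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
    MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_FLOAT = list(what = "numeric", size = 4L),
    MET_DOUBLE = list(what = "numeric", size = 8L),
    stop("unsupported ElementType: ", et))
  n <- prod(d)
  raw <- if (spec$what == "integer") {
    readBin(con, "integer", n = n, size = spec$size,
            signed = spec$signed, endian = "little")
  } else {
    readBin(con, "numeric", n = n, size = spec$size, endian = "little")
  }
  volume3d(array(as.numeric(raw), d), spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
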
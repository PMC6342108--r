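#' Rectangular raster surface
#'
#' A minimal matrix-backed raster: `values` is an n_rows x n_cols numeric
#' matrix with row 1 the northernmost row, `cell_size` the square cell edge in
#' metres and `origin` the (x, y) of the top-left corner.  Cells cover
#' half-open intervals `[origin, origin + n * cell_size)`.  `NA` values are the
#' nodata mask.
#'
#' @param values numeric matrix (row 1 = north).
#' @param cell_size cell edge length, metres (> 0).
#' @param origin numeric length-2, (x, y) of the top-left (NW) corner.
#' @param nodata value treated as nodata on input (converted to `NA`).
#' @return object of class `grid_surface`.
#' @export
grid_surface <- function(values, cell_size, origin = c(0, 0), nodata = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (!is.null(nodata)) values[values == nodata] <- NA
  if (any(!is.finite(values) & !is.na(values))) stop("non-finite unmasked values")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf("grid_surface: %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  range [%g, %g], %d nodata cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_surface <- function(x) dim(x$values)

#' @export
plot.grid_surface <- function(x, main = "", ...) {
  v <- x$values
  nr <- nrow(v); nc <- ncol(v)
  xs <- x$origin[1] + (seq_len(nc) - 0.5) * x$cell_size
  ys <- x$origin[2] - (seq_len(nr) - 0.5) * x$cell_size
  graphics::image(xs, rev(ys), t(v[nr:1, , drop = FALSE]),
                  xlab = "x (m)", ylab = "y (m)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Map point coordinates to (row, col) cell indices
#'
#' Containing-cell rule under the half-open cell convention; points outside
#' the grid extent are an error.
#'
#' @param s a [grid_surface()].
#' @param xy two-column matrix of (x, y) coordinates.
#' @return integer matrix with columns `row`, `col`.
#' @export
cell_of <- function(s, xy) {
  xy <- matrix(as.numeric(unlist(xy)), ncol = 2)
  col <- floor((xy[, 1] - s$origin[1]) / s$cell_size) + 1L
  row <- floor((s$origin[2] - xy[, 2]) / s$cell_size) + 1L
  bad <- row < 1 | row > nrow(s$values) | col < 1 | col > ncol(s$values)
  if (any(bad)) stop("point(s) outside grid extent: rows ",
                     paste(which(bad), collapse = ", "))
  cbind(row = as.integer(row), col = as.integer(col))
}

# ---- ESRI ASCII grid I/O ---------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' @param path file path (.asc).
#' @return a [grid_surface()]; `NODATA_value` cells become `NA`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- hdr$nrows; nc <- hdr$ncols
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("cell count mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  cs <- hdr$cellsize
  # header gives lower-left corner; our origin is the top-left corner
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  grid_surface(m, cs, origin = c(xll, yll + nr * cs), nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Round-trips bit-exactly with [read_esri_ascii()] at the printed precision
#' (`%.10g`), including the nodata mask.
#'
#' @param s a [grid_surface()].
#' @param path output path.
#' @param nodata numeric code written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(s, path, nodata = -9999) {
  v <- s$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", s$origin[1]),
           sprintf("yllcorner %.10g", s$origin[2] - nr * s$cell_size),
           sprintf("cellsize %.10g", s$cell_size),
           sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- derived surfaces ------------------------------------------------------

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - Red) / (NIR + Red)`, computed cell-wise on co-registered
#' grids.  Cells where `NIR + Red == 0` (and any masked input cell) are masked.
#'
#' @param red,nir [grid_surface()] objects with identical geometry.
#' @return a `grid_surface` with values in `[-1, 1]`.
#' @export
compute_ndvi <- function(red, nir) {
  if (!identical(dim(red$values), dim(nir$values)) ||
      red$cell_size != nir$cell_size) {
    stop("red and NIR grids are not co-registered (shape/cell size mismatch)")
  }
  den <- nir$values + red$values
  out <- (nir$values - red$values) / den
  out[!is.na(den) & den == 0] <- NA
  grid_surface(out, red$cell_size, red$origin)
}

#' Binary presence/absence reclassification
#'
#' Presence (1) where `value >= threshold`, absence (0) otherwise; the nodata
#' mask is preserved.  Idempotent for thresholds in (0, 1].
#'
#' @param s a [grid_surface()].
#' @param threshold finite numeric cut point.
#' @return a binary `grid_surface`.
#' @export
reclassify_binary <- function(s, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  grid_surface((s$values >= threshold) * 1, s$cell_size, s$origin)
}

#' Resample a surface to a new cell size
#'
#' Bilinear interpolation for continuous surfaces, majority vote for
#' categorical/binary ones.  Values stay within the input range.
#'
#' @param s a [grid_surface()].
#' @param cell_size target resolution, metres.
#' @param method `"bilinear"` or `"majority"`.
#' @return a `grid_surface` covering the same extent.
#' @export
resample_surface <- function(s, cell_size, method = c("bilinear", "majority")) {
  method <- match.arg(method)
  v <- s$values
  nr0 <- nrow(v); nc0 <- ncol(v)
  w <- nc0 * s$cell_size; h <- nr0 * s$cell_size
  nr <- max(1L, round(h / cell_size)); nc <- max(1L, round(w / cell_size))
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    # cell centre in source fractional (row, col) coordinates
    fr <- (i - 0.5) * cell_size / s$cell_size + 0.5
    fc <- (j - 0.5) * cell_size / s$cell_size + 0.5
    if (method == "bilinear") {
      r0 <- max(1L, min(nr0 - 1L, floor(fr))); c0 <- max(1L, min(nc0 - 1L, floor(fc)))
      if (nr0 == 1L) r0 <- 1L
      if (nc0 == 1L) c0 <- 1L
      r1 <- min(nr0, r0 + 1L); c1 <- min(nc0, c0 + 1L)
      tr <- min(1, max(0, fr - r0)); tc <- min(1, max(0, fc - c0))
      out[i, j] <- (1 - tr) * ((1 - tc) * v[r0, c0] + tc * v[r0, c1]) +
        tr * ((1 - tc) * v[r1, c0] + tc * v[r1, c1])
    } else {
      rr <- max(1, ceiling((i - 1) * cell_size / s$cell_size + 1e-9)):
        min(nr0, ceiling(i * cell_size / s$cell_size))
      cc <- max(1, ceiling((j - 1) * cell_size / s$cell_size + 1e-9)):
        min(nc0, ceiling(j * cell_size / s$cell_size))
      block <- v[rr, cc]
      block <- block[!is.na(block)]
      if (length(block)) {
        tab <- table(block)
        out[i, j] <- as.numeric(names(tab)[which.max(tab)])
      }
    }
  }
  grid_surface(out, cell_size, s$origin)
}
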
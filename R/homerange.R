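#' Telemetry tracks
#'
#' @param df data.frame with columns `individual`, `sex`, `x`, `y`,
#'   `timestamp` (POSIXct or ISO 8601 text).
#' @return list of class `telemetry_tracks`, one element per individual with
#'   fields `individual`, `sex`, `fixes` (data.frame `x, y, timestamp` sorted
#'   by time).
#' @export
telemetry_tracks <- function(df) {
  ts <- df$timestamp
  if (!inherits(ts, "POSIXct")) {
    raw <- ts
    ts <- tryCatch(
      as.POSIXct(raw, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")),
      error = function(e) rep(as.POSIXct(NA), length(raw)))
    if (anyNA(ts)) {
      stop("unparseable timestamp(s): ",
           paste(utils::head(raw[is.na(ts)], 3), collapse = ", "))
    }
  }
  df$timestamp <- ts
  out <- lapply(split(df, df$individual), function(d) {
    d <- d[order(d$timestamp), ]
    if (anyDuplicated(d$timestamp)) {
      stop("non-increasing timestamps for individual ", d$individual[1])
    }
    list(individual = as.character(d$individual[1]),
         sex = if ("sex" %in% names(d)) as.character(d$sex[1]) else "unknown",
         fixes = d[, c("x", "y", "timestamp")])
  })
  class(out) <- "telemetry_tracks"
  out
}

#' Read telemetry fixes from CSV
#'
#' Expected header: `individual, sex, x, y, timestamp` (ISO 8601).
#'
#' @param path CSV path.
#' @return a [telemetry_tracks()] object.
#' @export
read_telemetry <- function(path) {
  telemetry_tracks(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Reference bandwidth for bivariate kernel density
#'
#' `h_ref = ((sd_x + sd_y) / 2) * n^(-1/6)`, the standard reference bandwidth
#' for bivariate data.
#'
#' @param x,y fix coordinates.
#' @return bandwidth in metres.
#' @export
h_ref <- function(x, y) {
  ((stats::sd(x) + stats::sd(y)) / 2) * length(x)^(-1 / 6)
}

#' Kernel utilization distribution and home-range area
#'
#' Bivariate Gaussian kernel density of an individual's fixes on a regular
#' grid (bounding box padded by `3h`, cell `h/4` by default), normalized to
#' integrate to 1.  The home range at a given isopleth level is the
#' smallest-density region containing that probability mass (volume contour);
#' its area is reported in hectares.
#'
#' @param track one element of a [telemetry_tracks()] list (>= 5 fixes, not
#'   all identical).
#' @param level isopleth probability level (default 0.95).
#' @param cell grid cell size in metres (default `h/4`).
#' @param h smoothing bandwidth (default [h_ref()]).
#' @return list of class `home_range`: `individual`, `sex`, `h`, `ud` (a
#'   [grid_surface()] of densities), `level`, `area_ha`, `contour_density`
#'   (density cut-off of the isopleth).
#' @export
kde_homerange <- function(track, level = 0.95, cell = NULL, h = NULL) {
  fx <- track$fixes
  if (nrow(fx) < 5) stop("home-range estimation needs >= 5 fixes")
  if (stats::sd(fx$x) == 0 && stats::sd(fx$y) == 0) {
    stop("all fixes identical: zero variance")
  }
  if (is.null(h)) h <- h_ref(fx$x, fx$y)
  if (h <= 0) stop("bandwidth must be positive")
  if (is.null(cell)) cell <- h / 4
  pad <- 3 * h
  x0 <- min(fx$x) - pad; x1 <- max(fx$x) + pad
  y0 <- min(fx$y) - pad; y1 <- max(fx$y) + pad
  nc <- max(2L, ceiling((x1 - x0) / cell))
  nr <- max(2L, ceiling((y1 - y0) / cell))
  cx <- x0 + (seq_len(nc) - 0.5) * cell
  cy <- y1 - (seq_len(nr) - 0.5) * cell        # row 1 = north
  dx2 <- outer(cx, fx$x, "-")^2                # nc x n
  dy2 <- outer(cy, fx$y, "-")^2                # nr x n
  dens <- matrix(0, nr, nc)
  for (i in seq_len(nrow(fx))) {
    dens <- dens + outer(exp(-dy2[, i] / (2 * h^2)),
                         exp(-dx2[, i] / (2 * h^2)))
  }
  dens <- dens / (nrow(fx) * 2 * pi * h^2)
  mass <- sum(dens) * cell^2
  dens <- dens / mass                          # enforce unit integral on grid
  ud <- grid_surface(dens, cell, origin = c(x0, y1))
  hr <- isopleth_area(ud, level)
  structure(list(individual = track$individual, sex = track$sex, h = h,
                 ud = ud, level = level, area_ha = hr$area_ha,
                 contour_density = hr$cut),
            class = "home_range")
}

# smallest-density region holding `level` probability mass
isopleth_area <- function(ud, level) {
  v <- as.vector(ud$values)
  o <- order(v, decreasing = TRUE)
  cellarea <- ud$cell_size^2
  cum <- cumsum(v[o]) * cellarea
  ncell <- which(cum >= level)[1]
  if (is.na(ncell)) ncell <- length(v)
  list(area_ha = ncell * cellarea / 1e4, cut = v[o][ncell])
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range %s (%s): %.0f%% isopleth area %.3f ha (h = %.2f m)\n",
              x$individual, x$sex, 100 * x$level, x$area_ha, x$h))
  invisible(x)
}

#' Home-range table for several individuals
#'
#' @param tracks a [telemetry_tracks()] object.
#' @inheritParams kde_homerange
#' @return data.frame `individual, sex, n_fixes, h, area_ha` plus the list of
#'   `home_range` objects as attribute `estimates`.
#' @export
homerange_table <- function(tracks, level = 0.95, cell = NULL) {
  est <- lapply(tracks, kde_homerange, level = level, cell = cell)
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    data.frame(individual = tracks[[i]]$individual, sex = tracks[[i]]$sex,
               n_fixes = nrow(tracks[[i]]$fixes), h = est[[i]]$h,
               area_ha = est[[i]]$area_ha, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "estimates") <- est
  out
}

#' Directed home-range overlap percentages
#'
#' `overlap(A -> B) = area(isopleth_A intersect isopleth_B) / area(isopleth_A)
#' * 100`; utilization distributions are re-rasterized onto a common grid.
#'
#' @param uds list of `home_range` objects (from [kde_homerange()]).
#' @param level isopleth level (defaults to each UD's own level).
#' @return square matrix of directed overlap percentages (rows = A).
#' @export
overlap_matrix <- function(uds, level = NULL) {
  n <- length(uds)
  nms <- vapply(uds, function(u) u$individual, "")
  # common grid covering all UDs at the finest cell size
  cells <- vapply(uds, function(u) u$ud$cell_size, 1.0)
  cell <- min(cells)
  xs <- range(unlist(lapply(uds, function(u)
    c(u$ud$origin[1], u$ud$origin[1] + ncol(u$ud$values) * u$ud$cell_size))))
  ys <- range(unlist(lapply(uds, function(u)
    c(u$ud$origin[2] - nrow(u$ud$values) * u$ud$cell_size, u$ud$origin[2]))))
  nc <- ceiling(diff(xs) / cell); nr <- ceiling(diff(ys) / cell)
  cx <- xs[1] + (seq_len(nc) - 0.5) * cell
  cy <- ys[2] - (seq_len(nr) - 0.5) * cell
  inside <- lapply(uds, function(u) {
    lv <- if (is.null(level)) u$level else level
    cut <- if (is.null(level)) u$contour_density else isopleth_area(u$ud, lv)$cut
    v <- u$ud$values
    ic <- pmin(pmax(floor((cx - u$ud$origin[1]) / u$ud$cell_size) + 1, 1), ncol(v))
    ir <- pmin(pmax(floor((u$ud$origin[2] - cy) / u$ud$cell_size) + 1, 1), nrow(v))
    on_grid_c <- cx >= u$ud$origin[1] &
      cx < u$ud$origin[1] + ncol(v) * u$ud$cell_size
    on_grid_r <- cy <= u$ud$origin[2] &
      cy > u$ud$origin[2] - nrow(v) * u$ud$cell_size
    m <- v[ir, ic, drop = FALSE] >= cut
    m[!on_grid_r, ] <- FALSE
    m[, !on_grid_c] <- FALSE
    m
  })
  out <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ai <- sum(inside[[i]])
    out[i, j] <- if (ai == 0) 0 else 100 * sum(inside[[i]] & inside[[j]]) / ai
  }
  out
}

#' Nightly activity metrics from consecutive fixes
#'
#' Euclidean distances between consecutive radiolocations, grouped into
#' activity nights (a night runs 12:00 local to 12:00 the next day) with the
#' per-night maximum step and its timestamp.
#'
#' @param track one element of a [telemetry_tracks()] list.
#' @return list with `steps` (data.frame `night, from, to, distance`) and
#'   `nightly_max` (data.frame `night, max_distance, at`).
#' @export
activity_metrics <- function(track) {
  fx <- track$fixes[order(track$fixes$timestamp), ]
  night <- as.Date(fx$timestamp - 12 * 3600, tz = "UTC")  # 12:00 -> 12:00 window
  steps <- NULL
  for (nt in unique(night)) {
    d <- fx[night == nt, ]
    if (nrow(d) < 2) next
    dist <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    steps <- rbind(steps, data.frame(
      night = as.Date(nt, origin = "1970-01-01"),
      from = d$timestamp[-nrow(d)], to = d$timestamp[-1], distance = dist))
  }
  if (is.null(steps)) {
    return(list(steps = data.frame(night = as.Date(character(0)),
                                   from = as.POSIXct(character(0)),
                                   to = as.POSIXct(character(0)),
                                   distance = numeric(0)),
                nightly_max = data.frame(night = as.Date(character(0)),
                                         max_distance = numeric(0),
                                         at = as.POSIXct(character(0)))))
  }
  nm <- do.call(rbind, lapply(split(steps, steps$night), function(d) {
    i <- which.max(d$distance)
    data.frame(night = d$night[1], max_distance = d$distance[i], at = d$to[i])
  }))
  rownames(nm) <- NULL
  list(steps = steps, nightly_max = nm)
}

#' Mann-Whitney U test
#'
#' Exact null distribution (via the Wilcoxon rank-sum distribution) when
#' `n_a * n_b <= 400` and there are no ties; normal approximation with tie
#' correction otherwise.  Reports both one-sided U statistics and their
#' minimum (the conventional test statistic).
#'
#' @param a,b numeric samples.
#' @return list of class `mwu_result`: `U` (min), `U_a`, `U_b`, `p`
#'   (two-sided), `exact`.
#' @export
mwu_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  ties <- anyDuplicated(c(a, b)) > 0
  if (na * nb <= 400 && !ties) {
    p <- 2 * stats::pwilcox(U, na, nb)
    # pwilcox is P(U <= u); two-sided doubles the lower tail (capped at 1)
    p <- min(1, p)
    exact <- TRUE
  } else {
    mu <- na * nb / 2
    tie_tab <- table(c(a, b))
    n <- na + nb
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (Ua - mu - sign(Ua - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(U = U, U_a = Ua, U_b = Ub, p = p, exact = exact),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (U_a = %g, U_b = %g), p = %.4g%s\n",
              x$U, x$U_a, x$U_b, x$p, if (x$exact) " (exact)" else ""))
  invisible(x)
}
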
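#' Resistance transformation specification
#'
#' A transformation maps an environmental surface onto resistance through one
#' of eight curves: the monomolecular (saturating) family `y = 1 - exp(-b*x)`
#' or the Ricker (hump-shaped) family `y = x * exp(-b*x)`, each in four modes.
#' "reverse" reflects the input axis (`x -> 10 - x` after the input rescale to
#' [0, 10]); "inverse" reflects the output vertically.  The transformed surface
#' is affinely rescaled to `[1, r]`, so `r` is the maximum resistance.
#'
#' @param family `"monomolecular"` or `"ricker"`.
#' @param mode one of `"plain"`, `"inverse"`, `"reverse"`, `"inverse-reverse"`.
#' @param b shape parameter, > 0.
#' @param r magnitude (maximum resistance), in `(1, r_cap]`.
#' @param r_cap cap on the magnitude (default 2500).
#' @return object of class `transform_spec`.
#' @export
transform_spec <- function(family = c("monomolecular", "ricker"),
                           mode = c("plain", "inverse", "reverse",
                                    "inverse-reverse"),
                           b, r, r_cap = 2500) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (!(b > 0)) stop("shape b must be > 0")
  if (!(r > 1 && r <= r_cap)) stop("magnitude r must lie in (1, r_cap]")
  structure(list(family = family, mode = mode, b = b, r = r, r_cap = r_cap),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("transform_spec: %s %s, b = %g, r = %g\n",
              x$mode, x$family, x$b, x$r))
  invisible(x)
}

#' @export
format.transform_spec <- function(x, ...) {
  sprintf("%s %s (b=%.4g, r=%.4g)", x$mode, x$family, x$b, x$r)
}

rescale01 <- function(v, lo, hi) {
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) stop("transformation undefined on zero range")
  lo + (v - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

# transformation curve on x in [0, 10], before output rescaling
transform_curve <- function(x, spec) {
  if (grepl("reverse", spec$mode)) x <- 10 - x
  y <- switch(spec$family,
              monomolecular = 1 - exp(-spec$b * x),
              ricker = x * exp(-spec$b * x))
  if (grepl("inverse", spec$mode)) {
    y <- (max(y, na.rm = TRUE) + min(y, na.rm = TRUE)) - y
  }
  y
}

#' Transform an environmental surface into a resistance surface
#'
#' Pipeline: rescale the surface to `[0, 10]`; apply the (possibly reversed)
#' base curve; optionally reflect vertically ("inverse"); rescale the result
#' to `[1, r]`.  The output minimum is exactly 1 and the maximum exactly `r`.
#'
#' @param s a [grid_surface()] (non-constant).
#' @param spec a [transform_spec()].
#' @return a `grid_surface` of resistances with attribute `spec`.
#' @export
transform_surface <- function(s, spec) {
  x <- rescale01(s$values, 0, 10)
  y <- transform_curve(x, spec)
  out <- rescale01(y, 1, spec$r)
  res <- grid_surface(out, s$cell_size, s$origin)
  attr(res, "spec") <- spec
  res
}

#' Composite resistance from several transformed surfaces
#'
#' Transforms each surface with its own spec, sums the transformed resistances
#' cell-wise and shifts the sum so its minimum is exactly 1.  Per-surface mean
#' contributions (% of the composite mean before shifting) are attached.
#'
#' @param surfaces list of [grid_surface()] objects on a common geometry.
#' @param specs list of [transform_spec()], one per surface.
#' @return a `grid_surface` with attributes `contributions` (named %, summing
#'   to 100) and `specs`.
#' @export
composite_surface <- function(surfaces, specs) {
  if (length(surfaces) < 2) stop("composite needs >= 2 surfaces")
  if (length(surfaces) != length(specs)) stop("one spec per surface required")
  tr <- Map(transform_surface, surfaces, specs)
  vals <- lapply(tr, function(t) t$values)
  total <- Reduce("+", vals)
  shifted <- total - min(total, na.rm = TRUE) + 1
  means <- vapply(vals, function(v) mean(v, na.rm = TRUE), 1.0)
  contrib <- 100 * means / sum(means)
  nms <- names(surfaces)
  if (is.null(nms)) nms <- paste0("surface", seq_along(surfaces))
  names(contrib) <- nms
  res <- grid_surface(shifted, surfaces[[1]]$cell_size, surfaces[[1]]$origin)
  attr(res, "contributions") <- contrib
  attr(res, "specs") <- specs
  res
}
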
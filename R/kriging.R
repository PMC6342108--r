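#' Variogram model
#'
#' Isotropic exponential or spherical semivariogram
#' `gamma(h) = nugget + psill * f(h / range)` with `f` the unit exponential
#' (`1 - exp(-h/range)`) or spherical form.
#'
#' @param family `"exponential"` or `"spherical"`.
#' @param nugget non-negative nugget variance.
#' @param psill positive partial sill.
#' @param range positive range parameter, metres.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical"),
                            nugget, psill, range) {
  family <- match.arg(family)
  if (nugget < 0 || psill <= 0 || range <= 0) {
    stop("require nugget >= 0, psill > 0, range > 0")
  }
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range),
            class = "variogram_model")
}

semivariance <- function(model, h) {
  u <- h / model$range
  f <- switch(model$family,
              exponential = 1 - exp(-u),
              spherical = ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3))
  ifelse(h == 0, 0, model$nugget + model$psill * f)
}

# covariance implied by the variogram (total sill minus gamma)
vgm_cov <- function(model, h) {
  sill <- model$nugget + model$psill
  sill - semivariance(model, h)
}

#' Fit a variogram by weighted least squares
#'
#' Empirical semivariances are computed in distance bins and the model fitted
#' by minimizing `sum(N_k * (gamma_hat_k - gamma_k)^2 / gamma_k^2)` (Cressie
#' weights) over (nugget, psill, range).
#'
#' @param pts data.frame with columns `x`, `y`, `value`.
#' @param family variogram family.
#' @param bin_width bin width in metres (default: 1/15 of the max distance).
#' @return a [variogram_model()] with attribute `empirical` (the binned cloud).
#' @export
fit_variogram <- function(pts, family = "exponential", bin_width = NULL) {
  d <- as.matrix(stats::dist(pts[, c("x", "y")]))
  dv <- d[lower.tri(d)]
  sq <- 0.5 * outer(pts$value, pts$value, "-")^2
  sv <- sq[lower.tri(sq)]
  if (is.null(bin_width)) bin_width <- max(dv) / 15
  bins <- floor(dv / bin_width)
  emp <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    data.frame(h = mean(dv[sel]), gamma = mean(sv[sel]), n = sum(sel))
  }))
  emp <- emp[emp$n >= 2 & emp$gamma > 0, ]
  obj <- function(par) {
    m <- list(family = family, nugget = exp(par[1]), psill = exp(par[2]),
              range = exp(par[3]))
    class(m) <- "variogram_model"
    gh <- semivariance(m, emp$h)
    sum(emp$n * (emp$gamma - gh)^2 / pmax(gh, 1e-12)^2)
  }
  s2 <- stats::var(pts$value)
  init <- log(c(max(s2 * 0.05, 1e-8), max(s2, 1e-6), max(emp$h) / 3))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  m <- variogram_model(family, nugget = exp(fit$par[1]),
                       psill = exp(fit$par[2]), range = exp(fit$par[3]))
  attr(m, "empirical") <- emp
  m
}

#' Ordinary kriging onto a grid
#'
#' Solves the full ordinary-kriging system (weights constrained to sum to 1)
#' with the covariance implied by the variogram.  With a zero nugget the
#' predictor interpolates the data exactly.
#'
#' @param pts data.frame with columns `x`, `y`, `value` (>= 3 points, no
#'   duplicate locations).
#' @param model a [variogram_model()], or `"auto"` to fit one by WLS
#'   ([fit_variogram()]).
#' @param grid a [grid_surface()] supplying the target geometry (its values
#'   are ignored), or a list with `n_rows`, `n_cols`, `cell_size`, `origin`.
#' @return a `grid_surface` of predictions, attribute `model` = variogram used.
#' @export
krige_surface <- function(pts, model = "auto", grid) {
  if (nrow(pts) < 3) stop("kriging needs >= 3 points")
  dmat <- as.matrix(stats::dist(pts[, c("x", "y")]))
  dup <- which(dmat == 0 & upper.tri(dmat), arr.ind = TRUE)
  if (nrow(dup)) {
    stop("duplicate point locations: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  }
  if (identical(model, "auto")) model <- fit_variogram(pts)
  if (!inherits(grid, "grid_surface")) {
    grid <- grid_surface(matrix(0, grid$n_rows, grid$n_cols), grid$cell_size,
                         grid$origin)
  }
  n <- nrow(pts)
  A <- rbind(cbind(vgm_cov(model, dmat), 1), c(rep(1, n), 0))
  Ainv <- solve(A)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- grid$origin[1] + (seq_len(nc) - 0.5) * grid$cell_size
  cy <- grid$origin[2] - (seq_len(nr) - 0.5) * grid$cell_size
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    dx <- outer(pts$x, cx, function(a, b) (a - b)^2)
    h <- sqrt(sweep(dx, 1, (pts$y - cy[i])^2, "+"))
    rhs <- rbind(vgm_cov(model, h), 1)
    w <- Ainv %*% rhs
    out[i, ] <- colSums(w[seq_len(n), , drop = FALSE] * pts$value)
  }
  res <- grid_surface(out, grid$cell_size, grid$origin)
  attr(res, "model") <- model
  res
}

#' Kriging prediction at arbitrary points
#'
#' Same system as [krige_surface()] but evaluated at the supplied locations;
#' used mainly to verify exact interpolation at the data points.
#'
#' @inheritParams krige_surface
#' @param newdata data.frame with columns `x`, `y`.
#' @return numeric vector of predictions, attribute `weights` (points x
#'   predictions matrix of kriging weights, columns summing to 1).
#' @export
krige_points <- function(pts, model, newdata) {
  n <- nrow(pts)
  dmat <- as.matrix(stats::dist(pts[, c("x", "y")]))
  A <- rbind(cbind(vgm_cov(model, dmat), 1), c(rep(1, n), 0))
  h <- sqrt(outer(pts$x, newdata$x, "-")^2 + outer(pts$y, newdata$y, "-")^2)
  rhs <- rbind(vgm_cov(model, h), 1)
  w <- solve(A, rhs)
  pred <- colSums(w[seq_len(n), , drop = FALSE] * pts$value)
  attr(pred, "weights") <- w[seq_len(n), , drop = FALSE]
  pred
}
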
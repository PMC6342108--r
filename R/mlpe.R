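#' Maximum-likelihood population effects (MLPE) regression of pairwise
#' distance matrices
#'
#' Fits the mixed model
#' \deqn{y_{ij} = \beta_0 + \sum_m \beta_m x_{m,ij} + u_i + u_j + \epsilon_{ij}}
#' to the lower triangles of pairwise distance matrices, where the
#' per-individual random effects \eqn{u_i \sim N(0, \sigma^2_u)} make pairs
#' sharing an individual correlated (the MLPE covariance of pairwise-distance
#' regressions).  Estimation maximizes the exact Gaussian likelihood with
#' covariance \eqn{\sigma^2_\epsilon I + \sigma^2_u Z Z^\top} (Z the
#' pair-to-individual incidence matrix) by profiling \eqn{\beta} and
#' \eqn{\sigma^2_\epsilon} out analytically and optimizing the variance ratio
#' on the log scale from several starts.
#'
#' Predictors are standardized (zero mean, unit variance over the pairs)
#' before fitting.  The parameter count `k` used for AIC/AICc follows the
#' convention of the resistance-optimization literature: null model 1,
#' Euclidean distance 2, binary feature surface (categories + 1), single
#' continuous surface 4, composite of s surfaces 2s + 1; `AIC = -2l + 2k` and
#' `AICc = AIC + 2k(k+1)/(n_ind - k - 1)` with the number of individuals as
#' the AICc sample size.
#'
#' @param formula a formula such as `dps ~ ndvi + humidity` or `dps ~ 1`
#'   (intercept-only null model); each term names an element of `data`.
#' @param data named list of symmetric pairwise matrices sharing identical
#'   labels (response and predictors).
#' @param k parameter count for the information criteria: a number, or one of
#'   `"auto"`, `"null"`, `"distance"`, `"continuous"`, `"feature"`,
#'   `"composite"`.  `"auto"` maps 0 predictors to 1 (null), one predictor to
#'   4 (single continuous surface) and m predictors to 2m + 1 (composite).
#' @param n_categories number of categories (only used with `k = "feature"`).
#' @param aicc_n `"individuals"` (default, the cited framework's convention)
#'   or `"pairs"`: sample size used in the AICc correction.
#' @return An object of class `mlpe` with components `beta` (named
#'   coefficients, raw standardized scale), `se`, `sigma2_u`, `sigma2_e`,
#'   `loglik`, `n_ind`, `n_pairs`, `k`, `AIC`, `AICc`, `fitted`, `y`, `X`,
#'   `labels`, `call`.
#' @seealso [mlpe_fit()] for the matrix interface, [model_comparison()] for
#'   AICc tables.
#' @examples
#' n <- 12
#' d <- as.matrix(dist(cbind(runif(n), runif(n))))
#' dimnames(d) <- list(letters[1:n], letters[1:n])
#' y <- 0.2 + 0.1 * d / sd(d[lower.tri(d)]) + 0.01 * matrix(rnorm(n * n), n)
#' y <- (y + t(y)) / 2; diag(y) <- 0; dimnames(y) <- dimnames(d)
#' fit <- mlpe(gen ~ dist, data = list(gen = y, dist = d), k = "distance")
#' coef(fit)
#' @export
mlpe <- function(formula, data, k = "auto", n_categories = NULL,
                 aicc_n = c("individuals", "pairs")) {
  aicc_n <- match.arg(aicc_n)
  vars <- all.vars(formula)
  yname <- vars[1]
  xnames <- setdiff(vars, yname)
  if (!yname %in% names(data)) stop("response '", yname, "' not found in data")
  missing_x <- setdiff(xnames, names(data))
  if (length(missing_x)) stop("predictor(s) not in data: ",
                              paste(missing_x, collapse = ", "))
  fit <- mlpe_fit(data[[yname]], data[xnames], k_override = k,
                  n_categories = n_categories, aicc_n = aicc_n)
  fit$call <- match.call()
  fit
}

#' MLPE fit, matrix interface
#'
#' @param y symmetric response matrix (e.g. Dps) with labelled dimnames.
#' @param X list (possibly empty) of symmetric predictor matrices with the
#'   same labels.
#' @param k_override see `k` in [mlpe()].
#' @inheritParams mlpe
#' @return see [mlpe()].
#' @export
mlpe_fit <- function(y, X = list(), k_override = "auto", n_categories = NULL,
                     aicc_n = "individuals") {
  labs <- rownames(y)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(y)))
  for (m in X) {
    ml <- rownames(m)
    if (!is.null(ml) && !identical(ml, labs)) {
      stop("predictor labels do not match the response labels")
    }
    if (!identical(dim(m), dim(y))) stop("matrix dimensions differ")
  }
  n_ind <- nrow(y)
  lt <- lower.tri(y)
  yy <- y[lt]
  n_pairs <- length(yy)
  idx <- which(lt, arr.ind = TRUE)       # (row = i, col = j), i > j
  Z <- Matrix::sparseMatrix(i = rep(seq_len(n_pairs), 2),
                            j = c(idx[, 1], idx[, 2]), x = 1,
                            dims = c(n_pairs, n_ind))
  p <- length(X)
  Xm <- matrix(1, n_pairs, 1)
  colnames(Xm) <- "(Intercept)"
  if (p) {
    xs <- sapply(X, function(m) {
      v <- m[lt]
      sdv <- stats::sd(v)
      if (sdv == 0) stop("constant predictor matrix")
      (v - mean(v)) / sdv
    })
    if (is.null(dim(xs))) xs <- matrix(xs, ncol = p)
    colnames(xs) <- if (!is.null(names(X))) names(X) else paste0("x", seq_len(p))
    if (p > 1 && qr(xs)$rank < p) stop("perfectly collinear predictors")
    Xm <- cbind(Xm, xs)
  }

  ZtZ <- as.matrix(Matrix::crossprod(Z))
  Zt <- Matrix::t(Z)
  Im <- diag(n_ind)

  # profiled -2 log-likelihood in lambda = sigma2_u / sigma2_e
  prof <- function(loglam) {
    lam <- exp(loglam)
    M <- Im / lam + ZtZ                    # (1/lam) I + Z'Z
    cM <- chol(M)
    logdetV <- determinant(Im + lam * ZtZ, logarithm = TRUE)$modulus
    vinv <- function(A) {
      ZtA <- as.matrix(Zt %*% A)
      A - as.matrix(Z %*% backsolve(cM, forwardsolve(t(cM), ZtA)))
    }
    ViX <- vinv(Xm); Viy <- vinv(yy)
    XtViX <- crossprod(Xm, ViX)
    beta <- solve(XtViX, crossprod(Xm, Viy))
    r <- yy - Xm %*% beta
    rss <- sum(r * vinv(r))
    s2e <- rss / n_pairs
    m2l <- n_pairs * log(2 * pi * s2e) + as.numeric(logdetV) + n_pairs
    list(m2l = m2l, beta = beta, s2e = s2e, XtViX = XtViX, vinv = vinv)
  }
  ols <- {
    qrX <- qr(Xm)
    beta <- qr.coef(qrX, yy)
    r <- yy - Xm %*% beta
    s2e <- sum(r^2) / n_pairs
    list(m2l = n_pairs * log(2 * pi * s2e) + n_pairs, beta = beta, s2e = s2e,
         XtViX = crossprod(Xm), vinv = identity)
  }
  # profile over log(lambda) on two brackets (guards rare bimodality), then
  # compare against the lambda -> 0 boundary (pure OLS)
  best <- list(m2l = Inf)
  best_lam <- 0
  for (iv in list(c(-15, 2), c(0, 12))) {
    opt <- stats::optimize(function(ll) prof(ll)$m2l, interval = iv,
                           tol = 1e-7)
    if (opt$objective < best$m2l - 1e-12) {
      best <- prof(opt$minimum)
      best_lam <- exp(opt$minimum)
    }
  }
  if (ols$m2l <= best$m2l + 1e-8) {       # boundary: no individual effect
    best <- ols
    best_lam <- 0
  }
  beta <- drop(best$beta)
  names(beta) <- colnames(Xm)
  s2e <- best$s2e
  s2u <- best_lam * s2e
  loglik <- -best$m2l / 2
  se <- sqrt(diag(solve(best$XtViX)) * s2e)
  names(se) <- colnames(Xm)

  k <- resolve_k(k_override, p, n_categories)
  aic <- -2 * loglik + 2 * k
  n_eff <- if (aicc_n == "individuals") n_ind else n_pairs
  aicc <- aic + 2 * k * (k + 1) / (n_eff - k - 1)
  structure(list(beta = beta, se = se, sigma2_u = s2u, sigma2_e = s2e,
                 loglik = loglik, n_ind = n_ind, n_pairs = n_pairs, k = k,
                 AIC = aic, AICc = aicc, fitted = drop(Xm %*% best$beta),
                 y = yy, X = Xm, Z = Z, labels = labs, call = sys.call()),
            class = "mlpe")
}

resolve_k <- function(k, p, n_categories) {
  if (is.numeric(k)) return(k)
  switch(k,
         auto = if (p == 0) 1 else if (p == 1) 4 else 2 * p + 1,
         null = 1,
         distance = 2,
         continuous = 4,
         feature = {
           if (is.null(n_categories)) stop("k = 'feature' needs n_categories")
           n_categories + 1
         },
         composite = 2 * p + 1,
         stop("unknown k convention: ", k))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.mlpe <- function(x, ...) {
  cat("MLPE mixed model:", x$n_ind, "individuals,", x$n_pairs, "pairs\n")
  print(round(x$beta, 5))
  cat(sprintf("sigma2_u = %.5g, sigma2_e = %.5g, logLik = %.4f\n",
              x$sigma2_u, x$sigma2_e, x$loglik))
  cat(sprintf("k = %d, AIC = %.4f, AICc = %.4f\n", x$k, x$AIC, x$AICc))
  invisible(x)
}

#' @export
summary.mlpe <- function(object, ...) {
  z <- object$beta / object$se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, sigma2_u = object$sigma2_u,
              sigma2_e = object$sigma2_e, loglik = object$loglik,
              AIC = object$AIC, AICc = object$AICc, k = object$k,
              n_ind = object$n_ind, n_pairs = object$n_pairs)
  class(out) <- "summary.mlpe"
  out
}

#' @export
print.summary.mlpe <- function(x, ...) {
  cat("MLPE mixed model\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Random effect: sigma2_u = %.5g; residual sigma2_e = %.5g\n",
              x$sigma2_u, x$sigma2_e))
  cat(sprintf("logLik %.4f; k = %d; AIC %.4f; AICc %.4f (n_ind = %d)\n",
              x$loglik, x$k, x$AIC, x$AICc, x$n_ind))
  invisible(x)
}

#' @export
coef.mlpe <- function(object, ...) object$beta

#' @export
logLik.mlpe <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_pairs,
            class = "logLik")
}

#' @export
fitted.mlpe <- function(object, ...) object$fitted

#' @export
residuals.mlpe <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "marginal") return(r)
  # subtract BLUPs of the individual effects
  if (object$sigma2_u == 0) return(r)
  Z <- object$Z
  n_ind <- object$n_ind
  lam <- object$sigma2_u / object$sigma2_e
  M <- diag(n_ind) / lam + as.matrix(Matrix::crossprod(Z))
  u <- lam * solve(M, as.numeric(Matrix::crossprod(Z, r)))
  # E[u|y] via Woodbury: sigma2_u Z' Sigma^{-1} r = lam (I/lam + Z'Z)^{-1} Z'r
  r - as.numeric(Z %*% u)
}

#' @export
predict.mlpe <- function(object, newX = NULL, ...) {
  if (is.null(newX)) return(object$fitted)
  Xm <- cbind(1, as.matrix(newX))
  drop(Xm %*% object$beta)
}

#' Simulate pairwise response matrices from a fitted (or specified) MLPE model
#'
#' @param object an `mlpe` fit.
#' @param nsim number of replicate matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of symmetric matrices with the fit's labels.
#' @export
simulate.mlpe <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_ind <- object$n_ind
  lt <- lower.tri(matrix(0, n_ind, n_ind))
  idx <- which(lt, arr.ind = TRUE)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    u <- stats::rnorm(n_ind, 0, sqrt(object$sigma2_u))
    e <- stats::rnorm(object$n_pairs, 0, sqrt(object$sigma2_e))
    v <- object$fitted + u[idx[, 1]] + u[idx[, 2]] + e
    m <- matrix(0, n_ind, n_ind, dimnames = list(object$labels, object$labels))
    m[lt] <- v
    m <- m + t(m)
    out[[s]] <- m
  }
  out
}

#' @export
plot.mlpe <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "fitted", ylab = "observed pairwise y",
                 pch = 16, col = "#00000055", ...)
  graphics::abline(0, 1, col = "red3")
  invisible(x)
}

# ---- model selection -------------------------------------------------------

#' AICc model comparison with Akaike weights
#'
#' Ranks a set of MLPE fits of the same response by AICc and reports delta
#' AICc and Akaike weights `w_m = exp(-delta_m/2) / sum(exp(-delta/2))`.
#'
#' @param fits named list of `mlpe` objects.
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @return data.frame `model, k, logLik, AIC, AICc, delta, weight, rank`,
#'   ordered by rank.
#' @export
model_comparison <- function(fits, criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) stop("empty model list")
  nms <- names(fits)
  if (is.null(nms)) nms <- paste0("model", seq_along(fits))
  crit <- vapply(fits, function(f) f[[criterion]], 1.0)
  delta <- crit - min(crit)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  d <- data.frame(model = nms,
                  k = vapply(fits, function(f) f$k, 1.0),
                  logLik = vapply(fits, function(f) f$loglik, 1.0),
                  AIC = vapply(fits, function(f) f$AIC, 1.0),
                  AICc = vapply(fits, function(f) f$AICc, 1.0),
                  delta = delta, weight = w,
                  rank = rank(crit, ties.method = "first"),
                  stringsAsFactors = FALSE)
  d[order(d$rank), ]
}
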
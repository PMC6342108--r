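#' Optimize the resistance transformation of a single continuous surface
#'
#' Genetic-algorithm search over (family, mode, b, r): each chromosome is
#' transformed into a resistance surface, commute distances between the sample
#' points are computed, and an MLPE model of the genetic distances on the
#' standardized commute distances is fitted; fitness is -AIC (the objective
#' used during optimization; AICc is reported for selection across optimized
#' surfaces).
#'
#' @param s a [grid_surface()] environmental surface.
#' @param y symmetric genetic-distance matrix (labels = individuals).
#' @param points two-column matrix/data.frame of sample coordinates, rows
#'   aligned with `y`'s labels.
#' @param cfg a [ga_config()].
#' @param refine polish (b, r) within every family/mode by Nelder-Mead after
#'   the GA (default TRUE); the categorical genes are poorly served by blend
#'   crossover alone, so the polish restores equation-choice accuracy at
#'   reduced GA settings.
#' @return object of class `optimized_model`: `spec` (best
#'   [transform_spec()]), `fit` (the final [mlpe()] fit, `k = "continuous"`),
#'   `objective` (AIC), `log` (best fitness per generation).
#' @export
optimize_single <- function(s, y, points, cfg = ga_config(), refine = TRUE) {
  fams <- c("monomolecular", "ricker")
  modes <- c("plain", "inverse", "reverse", "inverse-reverse")
  genes <- list(list(type = "cat", levels = 2L),
                list(type = "cat", levels = 4L),
                list(type = "log", lo = cfg$b_bounds[1], hi = cfg$b_bounds[2]),
                list(type = "log", lo = 1 + 1e-6, hi = cfg$r_cap))
  decode <- function(ch) {
    transform_spec(fams[ch[1]], modes[ch[2]], b = ch[3],
                   r = max(ch[4], 1 + 1e-6), r_cap = cfg$r_cap)
  }
  fitness <- function(ch) {
    spec <- decode(ch)
    cd <- commute_distance_matrix(transform_surface(s, spec), points)
    -mlpe_fit(y, list(cd = cd), k_override = "continuous")$AIC
  }
  res <- run_ga(genes, fitness, cfg)
  best <- res$best
  best_aic <- -res$fitness
  if (refine) {
    # Nelder-Mead polish of (b, r) within every family/mode, seeded from the
    # GA optimum: equation choice is decided by the best refitted AIC
    for (fi in 1:2) for (mi in 1:4) {
      obj <- function(p) {
        b <- min(max(exp(p[1]), cfg$b_bounds[1]), cfg$b_bounds[2])
        r <- min(1 + 1e-6 + exp(p[2]), cfg$r_cap)
        -fitness(c(fi, mi, b, r))
      }
      o <- stats::optim(c(log(best[3]), log(max(best[4] - 1, 1e-3))), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 30, reltol = 1e-6))
      if (o$value < best_aic - 1e-9) {
        best_aic <- o$value
        best <- c(fi, mi,
                  min(max(exp(o$par[1]), cfg$b_bounds[1]), cfg$b_bounds[2]),
                  min(1 + 1e-6 + exp(o$par[2]), cfg$r_cap))
      }
    }
  }
  spec <- decode(best)
  cd <- commute_distance_matrix(transform_surface(s, spec), points)
  fit <- mlpe_fit(y, list(cd = cd), k_override = "continuous")
  structure(list(type = "single", spec = spec, fit = fit,
                 objective = fit$AIC, log = res$log),
            class = "optimized_model")
}

#' Optimize per-category resistances of a categorical (binary) surface
#'
#' The first category's resistance is fixed at 1 for identifiability; the GA
#' searches the remaining category values.  `k = categories + 1`.
#'
#' @param s a categorical [grid_surface()] (integer-coded categories).
#' @inheritParams optimize_single
#' @return `optimized_model` with `category_values` (named, first = 1).
#' @export
optimize_categorical <- function(s, y, points, cfg = ga_config()) {
  cats <- sort(unique(as.vector(s$values)))
  cats <- cats[!is.na(cats)]
  if (length(cats) < 2) stop("categorical optimization needs >= 2 categories")
  genes <- rep(list(list(type = "log", lo = cfg$cat_bounds[1],
                         hi = cfg$cat_bounds[2])), length(cats) - 1)
  build <- function(ch) {
    vals <- c(1, ch)
    v <- s$values
    out <- v
    for (i in seq_along(cats)) out[v == cats[i]] <- vals[i]
    grid_surface(out, s$cell_size, s$origin)
  }
  fitness <- function(ch) {
    cd <- commute_distance_matrix(build(ch), points)
    -mlpe_fit(y, list(cd = cd), k_override = "feature",
              n_categories = length(cats))$AIC
  }
  res <- run_ga(genes, fitness, cfg)
  rs <- build(res$best)
  cd <- commute_distance_matrix(rs, points)
  fit <- mlpe_fit(y, list(cd = cd), k_override = "feature",
                  n_categories = length(cats))
  structure(list(type = "categorical",
                 category_values = stats::setNames(c(1, res$best),
                                                   paste0("cat", cats)),
                 fit = fit, objective = fit$AIC, log = res$log),
            class = "optimized_model")
}

#' Simultaneous optimization of several surfaces into a composite
#'
#' The chromosome concatenates each surface's (family, mode, b, r); the
#' composite resistance is the cell-wise sum of the individually transformed
#' surfaces shifted to minimum 1.  A surface's contribution (%) is its mean
#' transformed value over the composite mean.
#'
#' @param surfaces named list of >= 2 [grid_surface()] objects.
#' @inheritParams optimize_single
#' @return `optimized_model` with `specs` (per surface) and `contributions`.
#' @export
optimize_multi <- function(surfaces, y, points, cfg = ga_config()) {
  if (length(surfaces) < 2) stop("multisurface optimization needs >= 2 surfaces")
  fams <- c("monomolecular", "ricker")
  modes <- c("plain", "inverse", "reverse", "inverse-reverse")
  gene1 <- list(list(type = "cat", levels = 2L),
                list(type = "cat", levels = 4L),
                list(type = "log", lo = cfg$b_bounds[1], hi = cfg$b_bounds[2]),
                list(type = "log", lo = 1 + 1e-6, hi = cfg$r_cap))
  genes <- rep(gene1, length(surfaces))
  decode <- function(ch) {
    lapply(seq_along(surfaces), function(i) {
      g <- ch[(i - 1) * 4 + 1:4]
      transform_spec(fams[g[1]], modes[g[2]], b = g[3],
                     r = max(g[4], 1 + 1e-6), r_cap = cfg$r_cap)
    })
  }
  fitness <- function(ch) {
    comp <- composite_surface(surfaces, decode(ch))
    cd <- commute_distance_matrix(comp, points)
    -mlpe_fit(y, list(cd = cd), k_override = 2 * length(surfaces) + 1)$AIC
  }
  res <- run_ga(genes, fitness, cfg)
  specs <- decode(res$best)
  names(specs) <- names(surfaces)
  comp <- composite_surface(surfaces, specs)
  cd <- commute_distance_matrix(comp, points)
  fit <- mlpe_fit(y, list(cd = cd), k_override = 2 * length(surfaces) + 1)
  structure(list(type = "multi", specs = specs, fit = fit,
                 objective = fit$AIC,
                 contributions = attr(comp, "contributions"), log = res$log),
            class = "optimized_model")
}

#' @export
print.optimized_model <- function(x, ...) {
  cat("optimized_model (", x$type, "): AIC = ", round(x$objective, 4),
      ", AICc = ", round(x$fit$AICc, 4), "\n", sep = "")
  if (x$type == "single") cat(" ", format(x$spec), "\n")
  if (x$type == "categorical") print(round(x$category_values, 3))
  if (x$type == "multi") {
    for (n in names(x$specs)) {
      cat(sprintf("  %s: %s  (%.1f%%)\n", n, format(x$specs[[n]]),
                  x$contributions[n]))
    }
  }
  invisible(x)
}

#' Run several independent optimizations to confirm convergence
#'
#' @param n_runs number of independent GA runs (different seeds).
#' @inheritParams optimize_single
#' @return list of `optimized_model`s with attribute `agreement` (fraction of
#'   runs whose family/mode match the best run).
#' @export
optimize_single_runs <- function(s, y, points, cfg = ga_config(), n_runs = 3) {
  runs <- lapply(seq_len(n_runs), function(i) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + 1000 * (i - 1)
    optimize_single(s, y, points, cfg_i)
  })
  best <- runs[[which.min(vapply(runs, function(r) r$objective, 1.0))]]
  agree <- mean(vapply(runs, function(r) {
    r$spec$family == best$spec$family && r$spec$mode == best$spec$mode
  }, TRUE))
  attr(runs, "agreement") <- agree
  runs
}

#' Spearman correlation pre-filter between surfaces
#'
#' Cell-wise Spearman rank correlation over jointly unmasked cells of each
#' surface pair; pairs with `|rho| < threshold` are candidates for the
#' multisurface composite (the paper's "small to medium" Cohen cut-off).
#'
#' @param surfaces named list of [grid_surface()] objects, common geometry.
#' @param threshold retain pairs with `|rho|` below this (default 0.29).
#' @param on `"cells"` (default) or `"pairs"`: correlate raw cell values, or
#'   pairwise commute distances (requires `points`).
#' @param points sample coordinates, only for `on = "pairs"`.
#' @return list with `rho` (full correlation matrix) and `retained`
#'   (data.frame of surface pairs below the threshold).
#' @export
spearman_filter <- function(surfaces, threshold = 0.29,
                            on = c("cells", "pairs"), points = NULL) {
  on <- match.arg(on)
  nms <- names(surfaces)
  if (is.null(nms)) nms <- paste0("surface", seq_along(surfaces))
  n <- length(surfaces)
  vals <- if (on == "cells") {
    for (s in surfaces[-1]) {
      if (!identical(dim(s$values), dim(surfaces[[1]]$values))) {
        stop("surface shape mismatch")
      }
    }
    lapply(surfaces, function(s) as.vector(s$values))
  } else {
    lapply(surfaces, function(s) {
      cd <- commute_distance_matrix(s, points)
      cd[lower.tri(cd)]
    })
  }
  rho <- matrix(1, n, n, dimnames = list(nms, nms))
  ret <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(vals[[i]]) & !is.na(vals[[j]])
    r <- stats::cor(vals[[i]][ok], vals[[j]][ok], method = "spearman")
    rho[i, j] <- rho[j, i] <- r
    if (abs(r) < threshold) {
      ret <- rbind(ret, data.frame(a = nms[i], b = nms[j], rho = r,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(ret)) ret <- data.frame(a = character(0), b = character(0),
                                      rho = numeric(0))
  list(rho = rho, retained = ret)
}

#' Bootstrap model selection across optimized candidates
#'
#' Per iteration, a fixed fraction of the individuals is subsampled without
#' replacement, every candidate's already-optimized distance matrix is
#' subsetted and the MLPE refitted (no re-optimization), and the candidates
#' are ranked by AICc.  Reports the average rank, average Akaike weight and
#' top-model percentage over iterations.
#'
#' @param candidates named list describing each candidate model: each element
#'   is a list with `X` (the candidate's pairwise predictor matrix, or `NULL`
#'   for the null model) and `k` (its parameter-count convention, numeric or a
#'   string for [mlpe()]'s `k`), plus optional `n_categories`.
#' @param y full genetic-distance matrix.
#' @param iterations bootstrap iterations (paper scale 10000; default 500 for
#'   desk-scale runs).
#' @param fraction subsample fraction without replacement (default 0.75).
#' @param seed integer seed.
#' @return data.frame of class `bootstrap_summary`: `model, avg_weight,
#'   avg_rank, top_pct`, ordered by `top_pct`.
#' @export
bootstrap_selection <- function(candidates, y, iterations = 500,
                                fraction = 0.75, seed = 1) {
  n <- nrow(y)
  m <- ceiling(fraction * n)
  kmax <- max(vapply(candidates, function(cd) {
    resolve_k(cd$k, p = if (is.null(cd$X)) 0 else 1, cd$n_categories)
  }, 1.0))
  if (m < kmax + 2) stop("subsample too small for the largest model (k = ", kmax, ")")
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("model", seq_along(candidates))
  set.seed(seed)
  ranks <- weights <- matrix(0, iterations, length(candidates),
                             dimnames = list(NULL, nm))
  for (it in seq_len(iterations)) {
    keep <- sort(sample.int(n, m))
    ys <- y[keep, keep]
    fits <- lapply(candidates, function(cd) {
      X <- if (is.null(cd$X)) list() else list(x = cd$X[keep, keep])
      mlpe_fit(ys, X, k_override = cd$k, n_categories = cd$n_categories)
    })
    names(fits) <- nm
    cmp <- model_comparison(fits)
    ranks[it, cmp$model] <- cmp$rank
    weights[it, cmp$model] <- cmp$weight
  }
  out <- data.frame(model = nm, avg_weight = colMeans(weights),
                    avg_rank = colMeans(ranks),
                    top_pct = 100 * colMeans(ranks == 1),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$top_pct, out$avg_rank), ]
  rownames(out) <- NULL
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}
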
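#' Spatially autocorrelated Gaussian random field
#'
#' Gaussian-kernel smoothing of white noise on the grid, affinely rescaled to
#' the target mean and standard deviation.  `kind = "ndvi"` clips the result
#' to `[-1, 1]` after scaling.
#'
#' @param n_rows,n_cols grid shape.
#' @param cell_size cell edge, metres.
#' @param correlation_length smoothing length in metres (the Gaussian kernel
#'   sd); below one cell a warning is raised and white noise returned.
#' @param mean,sd target moments.
#' @param seed integer seed.
#' @param kind `"plain"` or `"ndvi"` (clip to `[-1, 1]`).
#' @param origin grid origin (top-left corner).
#' @return a [grid_surface()].
#' @export
gen_random_field <- function(n_rows, n_cols, cell_size = 5,
                             correlation_length = 50, mean = 0, sd = 1,
                             seed = 1, kind = c("plain", "ndvi"),
                             origin = c(0, 0)) {
  kind <- match.arg(kind)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  ell <- correlation_length / cell_size       # in cells
  if (ell < 1) {
    warning("correlation_length below cell size; returning white noise")
  } else {
    rad <- ceiling(3 * ell)
    k <- stats::dnorm(-rad:rad, sd = ell)
    k <- k / sum(k)
    # separable smoothing with reflected padding to avoid edge attenuation
    smooth1 <- function(m) {
      pad <- m[c(rev(seq_len(min(rad, nrow(m)))),
                 seq_len(nrow(m)),
                 nrow(m) + 1 - rev(seq_len(min(rad, nrow(m))))), , drop = FALSE]
      while (nrow(pad) < nrow(m) + 2 * rad) pad <- pad[c(1, seq_len(nrow(pad)), nrow(pad)), , drop = FALSE]
      out <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
      out[rad + seq_len(nrow(m)), , drop = FALSE]
    }
    z <- smooth1(z)
    z <- t(smooth1(t(z)))
  }
  if (sd == 0) {
    z[] <- mean
  } else {
    z <- (z - base::mean(z)) / stats::sd(as.vector(z)) * sd + mean
  }
  if (kind == "ndvi") z <- pmin(pmax(z, -1), 1)
  grid_surface(z, cell_size, origin)
}

#' Simulate pairwise genetic distances under the MLPE generative model
#'
#' `y_ij = beta0 + beta1 * standardized commute distance + u_i + u_j + eps`,
#' with the commute distances computed on the supplied resistance surface and
#' points; the result is clipped to `[0, 1]` (a Dps-like dissimilarity).
#'
#' @param rs resistance `grid_surface` (e.g. from [transform_surface()]).
#' @param points sample coordinates (rows = individuals, with rownames).
#' @param beta0,beta1 intercept and slope on the standardized distance.
#' @param sigma2_u,sigma2_e individual and residual variances (>= 0).
#' @param seed integer seed.
#' @return symmetric matrix with zero diagonal; attribute `commute` holds the
#'   standardized commute matrix used.
#' @export
sim_genetic_distances <- function(rs, points, beta0 = 0.5, beta1 = 0.1,
                                  sigma2_u = 0.002, sigma2_e = 0.002,
                                  seed = 1) {
  if (sigma2_u < 0 || sigma2_e < 0) stop("variances must be >= 0")
  cd <- commute_distance_matrix(rs, points)
  lt <- lower.tri(cd)
  xs <- (cd[lt] - mean(cd[lt])) / stats::sd(cd[lt])
  n <- nrow(cd)
  idx <- which(lt, arr.ind = TRUE)
  set.seed(seed)
  u <- stats::rnorm(n, 0, sqrt(sigma2_u))
  e <- stats::rnorm(length(xs), 0, sqrt(sigma2_e))
  v <- pmin(1, pmax(0, beta0 + beta1 * xs + u[idx[, 1]] + u[idx[, 2]] + e))
  y <- matrix(0, n, n, dimnames = dimnames(cd))
  y[lt] <- v
  y <- y + t(y)
  xmat <- matrix(0, n, n, dimnames = dimnames(cd))
  xmat[lt] <- xs
  attr(y, "commute") <- xmat + t(xmat)
  y
}

#' Simulate a family-structured microsatellite panel
#'
#' Per-locus allele frequencies are drawn from a symmetric Dirichlet; founders
#' are drawn in Hardy-Weinberg proportions and related dyads created by
#' Mendelian transmission: PO (parent + child), FS (two full siblings from a
#' new parental pair), HS (two half-siblings sharing one parent).  Remaining
#' individuals are unrelated founders.
#'
#' @param n_ind total individuals.
#' @param n_loci loci count.
#' @param n_alleles alleles per locus.
#' @param dirichlet concentration of the symmetric Dirichlet (1 = uniform).
#' @param n_po,n_fs,n_hs numbers of parent-offspring, full-sibling and
#'   half-sibling dyads to embed.
#' @param seed integer seed.
#' @param coords optional two-column matrix of coordinates to attach.
#' @return a [genotype_table()] with attribute `truth`: data.frame
#'   `id_a, id_b, relationship` for every embedded non-unrelated dyad.
#' @export
sim_microsat_families <- function(n_ind = 40, n_loci = 8, n_alleles = 10,
                                  dirichlet = 1, n_po = 3, n_fs = 3, n_hs = 3,
                                  seed = 1, coords = NULL) {
  need <- 2 * (n_po + n_fs + n_hs)
  if (need > n_ind) stop("design requests more related individuals (", need,
                         ") than available (", n_ind, ")")
  set.seed(seed)
  freqs <- lapply(seq_len(n_loci), function(j) {
    gam <- stats::rgamma(n_alleles, shape = dirichlet)
    gam / sum(gam)
  })
  draw_founder <- function() {
    sapply(freqs, function(f) sample.int(length(f), 2, replace = TRUE, prob = f))
  }  # 2 x n_loci
  transmit <- function(par) {
    vapply(seq_len(n_loci), function(j) par[sample.int(2, 1), j], 1L)
  }
  child_of <- function(p1, p2) rbind(transmit(p1), transmit(p2))
  genos <- vector("list", n_ind)
  truth <- NULL
  i <- 1
  add_dyad <- function(g1, g2, rel) {
    genos[[i]] <<- g1; genos[[i + 1]] <<- g2
    truth <<- rbind(truth, data.frame(id_a = sprintf("ind%02d", i),
                                      id_b = sprintf("ind%02d", i + 1),
                                      relationship = rel,
                                      stringsAsFactors = FALSE))
    i <<- i + 2
  }
  for (d in seq_len(n_po)) {
    par <- draw_founder()
    add_dyad(par, child_of(par, draw_founder()), "PO")
  }
  for (d in seq_len(n_fs)) {
    p1 <- draw_founder(); p2 <- draw_founder()
    add_dyad(child_of(p1, p2), child_of(p1, p2), "FS")
  }
  for (d in seq_len(n_hs)) {
    shared <- draw_founder()
    add_dyad(child_of(shared, draw_founder()), child_of(shared, draw_founder()),
             "HS")
  }
  while (i <= n_ind) {
    genos[[i]] <- draw_founder()
    i <- i + 1
  }
  A1 <- t(vapply(genos, function(g) pmin(g[1, ], g[2, ]), integer(n_loci)))
  A2 <- t(vapply(genos, function(g) pmax(g[1, ], g[2, ]), integer(n_loci)))
  ids <- sprintf("ind%02d", seq_len(n_ind))
  g <- genotype_table(ids, A1, A2, paste0("L", seq_len(n_loci)),
                      x = if (!is.null(coords)) coords[, 1],
                      y = if (!is.null(coords)) coords[, 2])
  attr(g, "truth") <- truth
  g
}

#' Simulate nightly radiolocation tracks
#'
#' Fixes are bivariate normal around each individual's centre; timestamps lie
#' on a 30-minute lattice in the 21:00-01:30 nightly activity window across
#' consecutive nights (10 slots per night).
#'
#' @param centers data.frame/matrix with columns `x`, `y` (one row per
#'   individual); rownames become individual ids.
#' @param sigma fix dispersion around the centre, metres.
#' @param n_fixes fixes per individual (>= 5; default 10).
#' @param nights number of nights to spread the fixes over.
#' @param seed integer seed.
#' @param sexes optional character vector of sexes per individual.
#' @param start_date first night's date.
#' @return a [telemetry_tracks()] object.
#' @export
sim_radiolocations <- function(centers, sigma = 10, n_fixes = 10, nights = 1,
                               seed = 1, sexes = NULL,
                               start_date = as.Date("2015-06-01")) {
  if (n_fixes < 5) stop("n_fixes must be >= 5")
  centers <- as.data.frame(centers)
  ids <- rownames(centers)
  if (is.null(ids)) ids <- sprintf("R%d", seq_len(nrow(centers)))
  set.seed(seed)
  slots <- seq(21 * 3600, 25.5 * 3600, by = 1800)   # 21:00 .. 01:30 next day
  rows <- NULL
  for (i in seq_len(nrow(centers))) {
    per_night <- ceiling(n_fixes / nights)
    ts <- as.POSIXct(character(0), tz = "UTC")
    for (nn in seq_len(nights)) {
      take <- min(per_night, n_fixes - length(ts))
      if (take <= 0) break
      base <- as.POSIXct(paste(start_date + (nn - 1), "00:00:00"), tz = "UTC")
      ts <- c(ts, base + sort(sample(slots, take)))
    }
    rows <- rbind(rows, data.frame(
      individual = ids[i],
      sex = if (is.null(sexes)) "unknown" else sexes[i],
      x = stats::rnorm(n_fixes, centers$x[i], sigma),
      y = stats::rnorm(n_fixes, centers$y[i], sigma),
      timestamp = ts, stringsAsFactors = FALSE))
  }
  telemetry_tracks(rows)
}

#' Bundled synthetic scenario
#'
#' `"mapimi-small"` emulates the study design at desk scale: a 60 x 60 cell
#' grid at 5 m resolution with four spatially autocorrelated environmental
#' surfaces (NDVI-like in [-1, 1] with roughly a third of cells below 0.1,
#' humidity %, temperature degC, elevation m), 40 individuals placed uniformly
#' at random, genetic distances generated from a known true transformation
#' (inverse monomolecular on the NDVI-like surface) under the MLPE model, a
#' family-structured microsatellite panel and nightly telemetry tracks.
#'
#' @param name scenario name (only `"mapimi-small"` is bundled).
#' @param seed integer master seed; every component seed derives from it.
#' @param n_ind number of individuals (default 40).
#' @param beta1 true effect of the standardized commute distance on genetic
#'   distance (default 0.08, a strong signal against the default noise).
#' @param sigma2_u,sigma2_e MLPE variance components of the generator.
#' @return list of class `synthetic_scenario` with `surfaces` (named list),
#'   `true_spec`, `true_surface` (name), `points`, `y` (genetic distances),
#'   `genotypes`, `tracks`, `params`.
#' @export
synthetic_scenario <- function(name = "mapimi-small", seed = 1, n_ind = 40,
                               beta1 = 0.08, sigma2_u = 5e-4, sigma2_e = 5e-4) {
  if (name != "mapimi-small") stop("unknown scenario: ", name)
  nr <- 60; nc <- 60; cs <- 5
  # NDVI-like: mean/sd chosen so ~30% of cells fall below 0.1 (bare soil)
  ndvi <- gen_random_field(nr, nc, cs, correlation_length = 60, mean = 0.18,
                           sd = 0.15, seed = seed + 11, kind = "ndvi")
  humidity <- gen_random_field(nr, nc, cs, correlation_length = 80, mean = 44,
                               sd = 8, seed = seed + 22)
  temperature <- gen_random_field(nr, nc, cs, correlation_length = 80,
                                  mean = 30, sd = 2.5, seed = seed + 33)
  elevation <- gen_random_field(nr, nc, cs, correlation_length = 120,
                                mean = 1152, sd = 12, seed = seed + 44)
  surfaces <- list(ndvi = ndvi, humidity = humidity,
                   temperature = temperature, elevation = elevation)
  set.seed(seed + 55)
  pts <- cbind(x = stats::runif(n_ind, 2 * cs, (nc - 2) * cs),
               y = -stats::runif(n_ind, 2 * cs, (nr - 2) * cs))
  rownames(pts) <- sprintf("ind%02d", seq_len(n_ind))
  true_spec <- transform_spec("monomolecular", "inverse", b = 0.5, r = 100)
  rs <- transform_surface(ndvi, true_spec)
  y <- sim_genetic_distances(rs, pts, beta0 = 0.55, beta1 = beta1,
                             sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                             seed = seed + 66)
  genotypes <- sim_microsat_families(n_ind = n_ind, n_loci = 8, n_alleles = 10,
                                     seed = seed + 77, coords = pts)
  idx <- seq_len(min(9, n_ind))
  tracks <- sim_radiolocations(data.frame(x = pts[idx, 1], y = pts[idx, 2],
                                          row.names = rownames(pts)[idx]),
                               sigma = 12, n_fixes = 10, nights = 1,
                               seed = seed + 88,
                               sexes = rep(c("M", "F"), length.out = length(idx)))
  structure(list(surfaces = surfaces, true_spec = true_spec,
                 true_surface = "ndvi", points = pts, y = y,
                 genotypes = genotypes, tracks = tracks,
                 params = list(seed = seed, n_ind = n_ind, beta1 = beta1,
                               beta0 = 0.55, sigma2_u = sigma2_u,
                               sigma2_e = sigma2_e, cell_size = cs,
                               n_rows = nr, n_cols = nc)),
            class = "synthetic_scenario")
}

#' Write a synthetic scenario to disk
#'
#' Rasters as ESRI ASCII grids, genotypes in both genepop and CSV dialects,
#' coordinates and telemetry as CSV, and a `truth.json` ledger of the true
#' generator parameters.
#'
#' @param sc a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (n in names(sc$surfaces)) {
    write_esri_ascii(sc$surfaces[[n]], file.path(dir, paste0(n, ".asc")))
  }
  write_genotypes(sc$genotypes, file.path(dir, "genotypes.gen"), "genepop")
  write_genotypes(sc$genotypes, file.path(dir, "genotypes.csv"), "csv")
  utils::write.csv(data.frame(id = rownames(sc$points), sc$points),
                   file.path(dir, "coordinates.csv"), row.names = FALSE)
  utils::write.csv(
    do.call(rbind, lapply(sc$tracks, function(t)
      data.frame(individual = t$individual, sex = t$sex, t$fixes))),
    file.path(dir, "telemetry.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sc$y), file.path(dir, "dps.csv"))
  truth <- c(sc$params,
             list(true_surface = sc$true_surface,
                  true_family = sc$true_spec$family,
                  true_mode = sc$true_spec$mode,
                  true_b = sc$true_spec$b, true_r = sc$true_spec$r))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
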
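# tiny programmatic fixtures shared across tests

# genotype table from a compact list: list(ind = list(c(a,b), c(a,b), ...))
make_genotypes <- function(calls, loci = NULL, x = NULL, y = NULL, sex = NULL) {
  ids <- names(calls)
  nl <- length(calls[[1]])
  grab <- function(fun) {
    matrix(unlist(lapply(calls, function(g) vapply(g, function(p) {
      if (is.null(p) || anyNA(p)) NA_integer_ else as.integer(fun(p))
    }, 1L))), nrow = length(calls), ncol = nl, byrow = TRUE)
  }
  a1 <- grab(min)
  a2 <- grab(max)
  if (is.null(loci)) loci <- paste0("L", seq_len(nl))
  genotype_table(ids, a1, a2, loci, x = x, y = y, sex = sex)
}

# random unrelated genotype table in HWE
random_genotypes <- function(n_ind, n_loci = 5, n_alleles = 6, seed = 1) {
  sim_microsat_families(n_ind, n_loci = n_loci, n_alleles = n_alleles,
                        n_po = 0, n_fs = 0, n_hs = 0, seed = seed)
}

# uniform small resistance raster + points in its extent
toy_raster <- function(nr = 5, nc = 5, cell = 1, values = NULL, seed = 1) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(runif(nr * nc, 1, 10), nr, nc)
  }
  grid_surface(values, cell)
}

toy_points <- function(s, n, seed = 1) {
  set.seed(seed)
  nr <- nrow(s$values); nc <- ncol(s$values)
  cbind(x = runif(n, 0.01, nc * s$cell_size - 0.01),
        y = -runif(n, 0.01, nr * s$cell_size - 0.01))
}

# dense effective-resistance oracle: commute = vol * R_eff from the
# Moore-Penrose pseudoinverse of the full graph Laplacian, built independently
# of the package's solver path (edges re-derived here).
commute_oracle <- function(rs, points) {
  v <- rs$values
  nr <- nrow(v); nc <- ncol(v)
  id <- matrix(seq_len(nr * nc), nr, nc)
  L <- matrix(0, nr * nc, nr * nc)
  vol <- 0
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    for (dd in list(c(0, 1, FALSE), c(1, 0, FALSE), c(1, 1, TRUE), c(1, -1, TRUE))) {
      r2 <- r + dd[1]; c2 <- cl + dd[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- (1 / v[r, cl] + 1 / v[r2, c2]) / 2
      if (dd[3]) w <- w / sqrt(2)
      i <- id[r, cl]; j <- id[r2, c2]
      L[i, j] <- L[j, i] <- L[i, j] - w
      L[i, i] <- L[i, i] + w; L[j, j] <- L[j, j] + w
      vol <- vol + 2 * w
    }
  }
  Lp <- MASS::ginv(L)
  cells <- cell_of(rs, points)
  vid <- id[cbind(cells[, "row"], cells[, "col"])]
  Reff <- outer(diag(Lp)[vid], diag(Lp)[vid], "+") - 2 * Lp[vid, vid]
  out <- vol * Reff
  diag(out) <- 0
  out
}
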
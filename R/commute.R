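#' Commute-time distances between points on a resistance raster
#'
#' Builds the 8-neighbour graph over unmasked cells: each cell is a vertex,
#' edges connect orthogonal and diagonal neighbours, and the conductance of an
#' edge is the mean of the two cell conductances (`1/R`), divided by `sqrt(2)`
#' for diagonal edges.  The commute distance between two vertices is
#' `vol(G) * R_eff(i, j)` with `vol(G) = 2 *` total edge conductance and
#' `R_eff` the effective resistance from the graph Laplacian.  This is the
#' circuit-theory (random-walk) connectivity measure.
#'
#' Effective resistances are obtained from a sparse Cholesky factor of the
#' grounded Laplacian (one solve per point), which agrees with the dense
#' pseudoinverse route to numerical precision; `method = "dense"` forces the
#' explicit pseudoinverse (small rasters only).
#'
#' @param rs a resistance `grid_surface` (values >= something positive).
#' @param points two-column matrix or data.frame of (x, y) sample coordinates;
#'   each point is snapped to its containing cell.
#' @param method `"sparse"` (grounded Laplacian solves, default) or `"dense"`
#'   (Moore-Penrose pseudoinverse).
#' @param conductance `"mean_conductance"` (default: arithmetic mean of cell
#'   conductances) or `"mean_resistance"` (reciprocal mean resistance).
#' @return symmetric matrix of commute distances, zero diagonal; row names
#'   from `points` row names if present.
#' @export
commute_distance_matrix <- function(rs, points,
                                    method = c("sparse", "dense"),
                                    conductance = c("mean_conductance",
                                                    "mean_resistance")) {
  method <- match.arg(method)
  conductance <- match.arg(conductance)
  v <- rs$values
  if (any(v[!is.na(v)] <= 0)) stop("resistances must be positive")
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  id <- matrix(NA_integer_, nr, nc)
  id[ok] <- seq_len(sum(ok))
  nv <- sum(ok)
  cond_cell <- 1 / v[ok]                      # conductance per vertex cell

  # enumerate edges to E/SE/S/SW neighbours (each undirected edge once)
  edges_i <- integer(0); edges_j <- integer(0); w <- numeric(0)
  add_edges <- function(dr, dc, diag) {
    r1 <- seq_len(nr); c1 <- seq_len(nc)
    rr <- r1[r1 + dr >= 1 & r1 + dr <= nr]
    cc <- c1[c1 + dc >= 1 & c1 + dc <= nc]
    if (!length(rr) || !length(cc)) return(NULL)
    a <- id[rr, cc, drop = FALSE]
    b <- id[rr + dr, cc + dc, drop = FALSE]
    sel <- !is.na(a) & !is.na(b)
    if (!any(sel)) return(NULL)
    ai <- a[sel]; bi <- b[sel]
    ca <- cond_cell[ai]; cb <- cond_cell[bi]
    cw <- if (conductance == "mean_conductance") (ca + cb) / 2
          else 1 / ((1 / ca + 1 / cb) / 2)
    if (diag) cw <- cw / sqrt(2)
    edges_i <<- c(edges_i, ai); edges_j <<- c(edges_j, bi); w <<- c(w, cw)
    NULL
  }
  add_edges(0, 1, FALSE); add_edges(1, 0, FALSE)
  add_edges(1, 1, TRUE); add_edges(1, -1, TRUE)
  if (!length(w)) stop("graph has no edges")

  cells <- cell_of(rs, points)
  vid <- id[cbind(cells[, "row"], cells[, "col"])]
  if (anyNA(vid)) {
    stop("point(s) in masked cells: ", paste(which(is.na(vid)), collapse = ", "))
  }
  # connectivity check from the first point via BFS on the adjacency structure
  A <- Matrix::sparseMatrix(i = c(edges_i, edges_j), j = c(edges_j, edges_i),
                            x = 1, dims = c(nv, nv))
  reach <- rep(FALSE, nv); reach[vid[1]] <- TRUE
  frontier <- vid[1]
  cnts <- diff(A@p)
  while (length(frontier)) {
    k <- cnts[frontier]
    idx <- rep(A@p[frontier], k) + sequence(k)
    nb <- unique(A@i[idx] + 1L)
    frontier <- nb[!reach[nb]]
    reach[frontier] <- TRUE
  }
  if (!all(reach[vid])) {
    stop("disconnected point pair(s): points ",
         paste(which(!reach[vid]), collapse = ", "), " unreachable from point 1")
  }

  vol <- 2 * sum(w)
  npts <- nrow(cells)
  uvid <- unique(vid)

  L <- Matrix::sparseMatrix(i = c(edges_i, edges_j), j = c(edges_j, edges_i),
                            x = c(-w, -w), dims = c(nv, nv))
  Matrix::diag(L) <- -Matrix::rowSums(L)

  if (method == "dense") {
    if (nv > 3000) stop("dense method limited to <= 3000 vertices")
    Lp <- MASS::ginv(as.matrix(L))
    G <- Lp[uvid, uvid, drop = FALSE]
  } else {
    ground <- uvid[1]
    keep <- setdiff(seq_len(nv), ground)
    Lg <- Matrix::forceSymmetric(L[keep, keep, drop = FALSE])
    pos <- match(setdiff(uvid, ground), keep)
    rhs <- Matrix::sparseMatrix(i = pos, j = seq_along(pos),
                                x = 1, dims = c(nv - 1, length(pos)))
    ch <- Matrix::Cholesky(Lg, LDL = FALSE, perm = TRUE)
    X <- as.matrix(Matrix::solve(ch, rhs, system = "A"))
    # grounded inverse entries for the point vertices (ground row/col = 0)
    G <- matrix(0, length(uvid), length(uvid))
    G[-1, -1] <- X[pos, , drop = FALSE]
  }
  gidx <- match(vid, uvid)
  dG <- diag(G)
  Reff <- outer(dG[gidx], dG[gidx], "+") - 2 * G[gidx, gidx, drop = FALSE]
  out <- vol * Reff
  diag(out) <- 0
  out <- (out + t(out)) / 2
  labs <- rownames(points)
  if (is.null(labs) && is.data.frame(points)) labs <- as.character(seq_len(npts))
  dimnames(out) <- list(labs, labs)
  out
}
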
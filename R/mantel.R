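#' Simple Mantel test between two pairwise matrices
#'
#' Correlates the lower triangles (Pearson or Spearman) and assesses
#' significance by simultaneous row/column permutation of one matrix; the
#' two-tailed p-value is `(count(|r_perm| >= |r_obs|) + 1) / (n_perm + 1)`.
#'
#' @param a,b symmetric matrices with matching labels.
#' @param n_perm number of permutations (default 10000).
#' @param method `"pearson"` or `"spearman"`.
#' @param seed integer seed.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `method`.
#' @export
mantel_test <- function(a, b, n_perm = 10000, method = c("pearson", "spearman"),
                        seed = 1) {
  method <- match.arg(method)
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop("matrix labels do not match")
  }
  if (!identical(dim(a), dim(b))) stop("matrix dimensions differ")
  lt <- lower.tri(a)
  r_obs <- stats::cor(a[lt], b[lt], method = method)
  set.seed(seed)
  n <- nrow(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    pm <- sample.int(n)
    r_p <- stats::cor(a[lt], b[pm, pm][lt], method = method)
    if (abs(r_p) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
                 method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$r, x$p, x$n_perm))
  invisible(x)
}

#' Mantel correlogram over fixed-width distance classes
#'
#' For each geographic distance class, the class-membership indicator matrix
#' is Mantel-correlated with the genetic-distance matrix; p-values are
#' Holm-corrected across classes.  Classes with fewer than 20 pairs are
#' flagged low-power.
#'
#' @param g symmetric genetic-distance matrix.
#' @param coords two-column matrix of coordinates aligned with `g`'s rows.
#' @param class_width class width in metres (default 50).
#' @param n_perm permutations per class.
#' @param method correlation method.
#' @param seed integer seed.
#' @return data.frame of class `mantel_correlogram`: `lower, upper, midpoint,
#'   n_pairs, r, p, p_adj, low_power`.
#' @export
mantel_correlogram <- function(g, coords, class_width = 50, n_perm = 1000,
                               method = "pearson", seed = 1) {
  if (class_width <= 0) stop("class width must be > 0")
  d <- as.matrix(stats::dist(coords))
  lt <- lower.tri(d)
  maxd <- max(d[lt])
  edges <- seq(0, maxd + class_width, by = class_width)
  rows <- list()
  for (ci in seq_len(length(edges) - 1)) {
    lo <- edges[ci]; hi <- edges[ci + 1]
    ind <- (d >= lo & d < hi) * 1
    diag(ind) <- 0
    dimnames(ind) <- dimnames(g)
    np <- sum(ind[lt])
    if (np == 0) {
      rows[[ci]] <- data.frame(lower = lo, upper = hi,
                               midpoint = (lo + hi) / 2, n_pairs = 0,
                               r = NA_real_, p = NA_real_)
      next
    }
    if (stats::sd(ind[lt]) == 0) {
      # every pair in one class: r of a constant indicator is undefined
      rows[[ci]] <- data.frame(lower = lo, upper = hi,
                               midpoint = (lo + hi) / 2, n_pairs = np,
                               r = NA_real_, p = NA_real_)
      next
    }
    mt <- mantel_test(g, ind, n_perm = n_perm, method = method,
                      seed = seed + ci)
    rows[[ci]] <- data.frame(lower = lo, upper = hi, midpoint = (lo + hi) / 2,
                             n_pairs = np, r = mt$r, p = mt$p)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "holm")
  out$low_power <- out$n_pairs < 20
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
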
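#' One-hot allele-count encoding of genotypes
#'
#' Each individual becomes a row of per-(locus, allele) counts in 0/1/2;
#' missing calls are replaced by the locus-mean counts so that every row is
#' complete (standard practice for PCA of genotype matrices).
#'
#' @param g a [genotype_table()].
#' @param center subtract column means (default TRUE).
#' @return numeric matrix, individuals x (locus, allele) columns.
#' @export
genotype_counts <- function(g, center = TRUE) {
  cols <- list()
  for (j in seq_along(g$loci)) {
    alleles <- sort(unique(c(g$a1[, j], g$a2[, j])))
    alleles <- alleles[!is.na(alleles)]
    cj <- sapply(alleles, function(al)
      (g$a1[, j] == al) + (g$a2[, j] == al))
    if (is.null(dim(cj))) cj <- matrix(cj, nrow = length(g$ids))
    colnames(cj) <- paste0(g$loci[j], ".", alleles)
    for (cidx in seq_len(ncol(cj))) {
      v <- cj[, cidx]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cj[, cidx] <- v
    }
    cols[[j]] <- cj
  }
  m <- do.call(cbind, cols)
  rownames(m) <- g$ids
  if (center) m <- scale(m, center = TRUE, scale = FALSE)
  m
}

#' K-means cluster scan scored by BIC
#'
#' PCA of the centered allele-count matrix retains `n_pcs` components; for
#' each K in `1:K_max`, K-means (with restarts) is run on the retained PCs and
#' scored with the K-means BIC used by the DAPC literature,
#' `BIC(K) = n * log(WSS_K / n) + K * log(n)`, where `WSS_K` is the total
#' within-cluster sum of squares.  The best K minimizes BIC.
#'
#' @param g a [genotype_table()].
#' @param K_max largest K to test (must be < number of individuals).
#' @param n_pcs number of principal components retained (default all).
#' @param seed integer seed (restarts are deterministic given it).
#' @param nstart K-means restarts per K.
#' @return list of class `cluster_scan`: `K`, `BIC`, `best_K`, `assignments`
#'   (for best K), `pcs` (retained scores).
#' @export
kmeans_bic_scan <- function(g, K_max = 10, n_pcs = NULL, seed = 1, nstart = 20) {
  n <- length(g$ids)
  if (K_max >= n) stop("K_max must be smaller than the number of individuals")
  m <- genotype_counts(g)
  pc <- stats::prcomp(m, center = FALSE)
  if (is.null(n_pcs)) n_pcs <- ncol(pc$x)
  n_pcs <- min(n_pcs, ncol(pc$x))
  sc <- pc$x[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  bic <- numeric(K_max)
  assign_list <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    if (K == 1) {
      wss <- sum(scale(sc, center = TRUE, scale = FALSE)^2)
      assign_list[[K]] <- rep(1L, n)
    } else {
      km <- suppressWarnings(stats::kmeans(sc, centers = K, nstart = nstart,
                                           iter.max = 200))
      wss <- km$tot.withinss
      assign_list[[K]] <- km$cluster
    }
    bic[K] <- n * log(wss / n) + K * log(n)
  }
  best <- which.min(bic)
  structure(list(K = seq_len(K_max), BIC = bic, best_K = best,
                 assignments = stats::setNames(assign_list[[best]], g$ids),
                 pcs = sc, eig = pc$sdev^2),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat("cluster_scan: K =", min(x$K), "..", max(x$K), "; best K =", x$best_K, "\n")
  print(data.frame(K = x$K, BIC = round(x$BIC, 2)), row.names = FALSE)
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' PCA of the centered allele-count matrix retains `n_pcs` components, then a
#' linear discriminant analysis of the retained scores on the given group
#' labels yields discriminant axes and per-individual posterior assignment
#' probabilities.
#'
#' @param g a [genotype_table()].
#' @param groups group labels aligned with `g$ids` (or named by id); >= 2
#'   groups.
#' @param n_pcs retained principal components; must be smaller than
#'   `n - n_groups`.
#' @return list of class `dapc_fit`: `n_pcs`, `var_fraction` (variance share
#'   of the retained PCs), `lda` (the underlying fit), `scores` (discriminant
#'   coordinates), `posterior`, `assigned`.
#' @export
dapc_fit <- function(g, groups, n_pcs) {
  if (!is.null(names(groups))) groups <- groups[g$ids]
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("discrimination undefined for K=1")
  n <- length(g$ids)
  if (n_pcs >= n - nlevels(groups)) {
    stop("n_pcs must be < n individuals - number of groups")
  }
  m <- genotype_counts(g)
  pc <- stats::prcomp(m, center = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  sc <- pc$x[, seq_len(n_pcs), drop = FALSE]
  var_fraction <- sum(pc$sdev[seq_len(n_pcs)]^2) / sum(pc$sdev^2)
  fit <- MASS::lda(sc, grouping = groups)
  pred <- stats::predict(fit, sc)
  structure(list(n_pcs = n_pcs, var_fraction = var_fraction, lda = fit,
                 scores = pred$x, posterior = pred$posterior,
                 assigned = stats::setNames(as.character(pred$class), g$ids),
                 groups = stats::setNames(as.character(groups), g$ids)),
            class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  acc <- mean(x$assigned == x$groups)
  cat(sprintf("dapc_fit: %d PCs (%.1f%% variance), %d groups, re-assignment %.1f%%\n",
              x$n_pcs, 100 * x$var_fraction, length(unique(x$groups)), 100 * acc))
  invisible(x)
}
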
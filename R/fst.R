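#' Pairwise Weir-Cockerham FST between groups
#'
#' Multilocus theta from the variance-components estimator: for each pair of
#' groups, components a (among populations), b (among individuals within
#' populations) and c (within individuals) are accumulated over all alleles and
#' loci, and theta = sum(a) / sum(a + b + c).  Slightly negative estimates are
#' reported as computed.
#'
#' @param g a [genotype_table()].
#' @param groups named vector (names = individual ids) or vector aligned with
#'   `g$ids` giving group labels; >= 2 groups each with >= 2 individuals.
#' @return A symmetric matrix of pairwise theta over groups (diagonal `NA`).
#' @export
pairwise_fst <- function(g, groups) {
  if (!is.null(names(groups))) groups <- groups[g$ids]
  if (length(groups) != length(g$ids)) stop("groups do not align with individuals")
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 individuals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  m <- matrix(NA_real_, length(glev), length(glev), dimnames = list(glev, glev))
  for (i in seq_along(glev)) for (k in seq_along(glev)) if (i < k) {
    th <- wc_theta(g, which(groups == glev[i]), which(groups == glev[k]))
    m[i, k] <- m[k, i] <- th
  }
  m
}

# Weir & Cockerham (1984) theta for two samples, summed components over
# alleles and loci.
wc_theta <- function(g, idx1, idx2) {
  r <- 2
  num <- 0; den <- 0; any_locus <- FALSE
  for (j in seq_along(g$loci)) {
    sub <- list(idx1, idx2)
    n_i <- vapply(sub, function(ix) sum(!is.na(g$a1[ix, j])), 1.0)
    if (any(n_i < 2)) next
    any_locus <- TRUE
    alleles <- sort(unique(c(g$a1[c(idx1, idx2), j], g$a2[c(idx1, idx2), j])))
    alleles <- alleles[!is.na(alleles)]
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(sub, function(ix) {
        a <- c(g$a1[ix, j], g$a2[ix, j]); a <- a[!is.na(a)]
        mean(a == al)
      }, 1.0)
      h_i <- vapply(sub, function(ix) {
        t1 <- g$a1[ix, j]; t2 <- g$a2[ix, j]
        ok <- !is.na(t1)
        mean((t1[ok] == al) != (t2[ok] == al))
      }, 1.0)
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                            (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (!any_locus) stop("no locus with >= 2 typed individuals in both groups")
  if (den == 0) return(0)
  num / den
}

#' Proportion-of-shared-alleles genetic distance (Dps)
#'
#' For each dyad, only loci typed in both individuals contribute:
#' `Dps = 1 - sum(shared_l) / (2 * L_typed)` where `shared_l` in 0..2 is the
#' number of alleles matched under the optimal pairing of the two diploid
#' calls.
#'
#' @param g a [genotype_table()].
#' @return Symmetric numeric matrix (individuals x individuals) with zero
#'   diagonal, values in `[0, 1]`.
#' @export
dps_matrix <- function(g) {
  n <- length(g$ids)
  m <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    typed <- !is.na(g$a1[i, ]) & !is.na(g$a1[k, ])
    if (!any(typed)) stop("dyad (", g$ids[i], ", ", g$ids[k], ") has no co-typed loci")
    sh <- shared_alleles(g$a1[i, typed], g$a2[i, typed],
                         g$a1[k, typed], g$a2[k, typed])
    m[i, k] <- m[k, i] <- 1 - sum(sh) / (2 * sum(typed))
  }
  m
}

# per-locus matched allele count (0,1,2) under optimal pairing; vectorized
shared_alleles <- function(x1, x2, y1, y2) {
  # both calls sorted (a1 <= a2) by construction
  two <- (x1 == y1 & x2 == y2)
  one <- !two & (x1 == y1 | x1 == y2 | x2 == y1 | x2 == y2)
  # a homozygote vs heterozygote containing that allele shares exactly 1;
  # heterozygotes sharing both alleles are the `two` case above.
  as.integer(two) * 2L + as.integer(one)
}
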
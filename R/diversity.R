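#' Microsatellite diversity summary
#'
#' Per-locus allele counts (Na), effective alleles (Ne = 1/sum(p^2)), observed
#' heterozygosity (Ho), unbiased expected heterozygosity
#' (uHe = 2n/(2n-1) * (1 - sum(p^2))) and inbreeding coefficient
#' (FIS = 1 - Ho/uHe), plus across-locus means.  The overall FIS is defined as
#' `1 - mean(Ho)/mean(uHe)`; monomorphic loci have uHe = 0 and undefined FIS
#' (NA, excluded from the FIS mean).
#'
#' @param g a [genotype_table()] with at least two individuals.
#' @return A data.frame with one row per locus plus a `MEAN` row and columns
#'   `locus, n, Na, Ne, Ho, uHe, FIS`.
#' @export
diversity_summary <- function(g) {
  if (length(g$ids) < 2) stop("diversity summary needs at least 2 individuals")
  freqs <- allele_frequencies(g)
  rows <- lapply(seq_along(g$loci), function(j) {
    f <- freqs[[j]]
    n <- attr(f, "n_typed")
    sp2 <- sum(f^2)
    typed <- !is.na(g$a1[, j])
    ho <- mean(g$a1[typed, j] != g$a2[typed, j])
    uhe <- if (n > 0) (2 * n) / (2 * n - 1) * (1 - sp2) else NA_real_
    data.frame(locus = g$loci[j], n = n, Na = length(f), Ne = 1 / sp2,
               Ho = ho, uHe = uhe,
               FIS = if (uhe > 0) 1 - ho / uhe else NA_real_,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  mean_row <- data.frame(locus = "MEAN", n = mean(d$n), Na = mean(d$Na),
                         Ne = mean(d$Ne), Ho = mean(d$Ho), uHe = mean(d$uHe),
                         FIS = if (mean(d$uHe) > 0) 1 - mean(d$Ho) / mean(d$uHe)
                               else NA_real_,
                         stringsAsFactors = FALSE)
  rbind(d, mean_row)
}

# log conditional probability of a diploid genotype table given its allele
# counts (Levene): log[ n! * prod(n_a!) * 2^H / ((2n)! * prod(n_ab!)) ]
log_levene_prob <- function(a1, a2) {
  n <- length(a1)
  alleles <- c(a1, a2)
  acounts <- table(alleles)
  gt <- paste(pmin(a1, a2), pmax(a1, a2))
  gcounts <- table(gt)
  H <- sum(a1 != a2)
  lfactorial(n) + sum(lfactorial(acounts)) + H * log(2) -
    lfactorial(2 * n) - sum(lfactorial(gcounts))
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, genotype tables are generated by
#' randomly pairing the observed allele list; the p-value is the proportion of
#' tables (including the observed one) whose Levene conditional probability is
#' less than or equal to the observed table's.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @param reps number of Monte-Carlo shuffles (>= 1000; default 100000).
#' @param seed integer RNG seed.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(g, locus, reps = 100000, seed = 1) {
  j <- match(locus, g$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  if (reps < 1000) stop("reps must be >= 1000")
  typed <- !is.na(g$a1[, j])
  a1 <- g$a1[typed, j]; a2 <- g$a2[typed, j]
  if (length(unique(c(a1, a2))) < 2) {
    warning("locus ", locus, " is monomorphic; HWE p = 1")
    return(1)
  }
  obs <- log_levene_prob(a1, a2)
  pool <- c(a1, a2)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(reps)) {
    s <- sample(pool)
    half <- length(s) / 2
    if (log_levene_prob(s[seq_len(half)], s[half + seq_len(half)]) <= obs + 1e-9)
      hits <- hits + 1L
  }
  (hits + 1) / (reps + 1)
}

#' HWE tests across all loci with Bonferroni correction
#'
#' @inheritParams hwe_exact_test
#' @param alpha familywise significance level for the Bonferroni flag.
#' @return data.frame `locus, p, p_bonferroni, significant`.
#' @export
hwe_test_all <- function(g, reps = 10000, seed = 1, alpha = 0.05) {
  p <- vapply(seq_along(g$loci), function(j) {
    suppressWarnings(hwe_exact_test(g, g$loci[j], reps = reps, seed = seed + j))
  }, 1.0)
  padj <- pmin(1, p * length(p))
  data.frame(locus = g$loci, p = p, p_bonferroni = padj,
             significant = padj < alpha, stringsAsFactors = FALSE)
}

# exact enumeration of the HWE test for small cases (test oracle, exported for
# reuse): enumerate all genotype tables compatible with the allele counts via
# recursive pairing of the allele multiset, deduplicated by genotype counts.
#' Exhaustive exact HWE p-value (small problems only)
#'
#' Enumerates every distinguishable genotype table compatible with the observed
#' allele counts and sums Levene probabilities over tables at most as probable
#' as the observed one.  Feasible only for few alleles; used as an independent
#' check of [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return exact p-value.
#' @export
hwe_exact_enumeration <- function(g, locus) {
  j <- match(locus, g$loci)
  typed <- !is.na(g$a1[, j])
  a1 <- g$a1[typed, j]; a2 <- g$a2[typed, j]
  if (length(unique(c(a1, a2))) < 2) return(1)
  obs <- log_levene_prob(a1, a2)
  counts <- table(c(a1, a2))
  alleles <- as.integer(names(counts))
  counts <- as.integer(counts)
  n <- length(a1)
  K <- length(alleles)
  # genotype categories: (i,j) with i<=j
  cats <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  results <- new.env()
  recurse <- function(idx, remaining, ngen, acc) {
    if (idx > nrow(cats)) {
      if (all(remaining == 0)) {
        key <- paste(acc, collapse = ",")
        assign(key, acc, envir = results)
      }
      return(invisible(NULL))
    }
    i <- cats[idx, 1]; k <- cats[idx, 2]
    maxc <- if (i == k) remaining[i] %/% 2 else min(remaining[i], remaining[k])
    for (cnt in 0:maxc) {
      rem <- remaining
      if (i == k) rem[i] <- rem[i] - 2 * cnt
      else { rem[i] <- rem[i] - cnt; rem[k] <- rem[k] - cnt }
      recurse(idx + 1, rem, ngen + cnt, c(acc, cnt))
    }
  }
  recurse(1, counts, 0, integer(0))
  tabs <- as.list(results)
  p <- 0
  for (tb in tabs) {
    ga <- rep(alleles[cats[, 1]], tb)
    gb <- rep(alleles[cats[, 2]], tb)
    lp <- log_levene_prob(ga, gb)
    if (lp <= obs + 1e-9) p <- p + exp(lp)
  }
  min(p, 1)
}
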
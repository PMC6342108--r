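#' Maximum-likelihood relationship classification for a dyad
#'
#' Multilocus likelihood of the dyad's genotypes under the four standard
#' IBD-coefficient vectors (k0, k1, k2): unrelated U = (1,0,0), half-sibling
#' HS = (0.5,0.5,0), full-sibling FS = (0.25,0.5,0.25) and parent-offspring
#' PO = (0,1,0).  Loci are treated as independent and allele frequencies as
#' known.  The PO log-likelihood is `-Inf` whenever some co-typed locus shares
#' no allele (Mendelian exclusion).
#'
#' @param g a [genotype_table()].
#' @param freqs an [allele_frequencies()] table for `g`.
#' @param dyad character vector of two individual ids.
#' @return A list of class `relationship_call` with fields `dyad`, `loglik`
#'   (named vector over U/HS/FS/PO), `best` and `first_order`.
#' @export
relationship_classify <- function(g, freqs, dyad) {
  i <- match(dyad[1], g$ids); k <- match(dyad[2], g$ids)
  if (is.na(i) || is.na(k)) stop("unknown id in dyad: ", paste(dyad, collapse = ", "))
  kvec <- list(U = c(1, 0, 0), HS = c(0.5, 0.5, 0),
               FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))
  ll <- c(U = 0, HS = 0, FS = 0, PO = 0)
  for (j in seq_along(g$loci)) {
    if (is.na(g$a1[i, j]) || is.na(g$a1[k, j])) next
    f <- freqs[[j]]
    pr <- function(al) {
      p <- f[as.character(al)]
      if (is.na(p)) stop("allele ", al, " absent from frequency table at locus ",
                         g$loci[j])
      as.numeric(p)
    }
    a <- g$a1[i, j]; b <- g$a2[i, j]       # G1 (sorted pair)
    cc <- g$a1[k, j]; d <- g$a2[k, j]      # G2
    pG1 <- if (a == b) pr(a)^2 else 2 * pr(a) * pr(b)
    pG2 <- if (cc == d) pr(cc)^2 else 2 * pr(cc) * pr(d)
    # P(G2 | G1, exactly one pair IBD), Thompson transition probabilities
    t1 <- if (a == b) {
      if (cc == d) { if (cc == a) pr(a) else 0 }
      else if (cc == a) pr(d) else if (d == a) pr(cc) else 0
    } else {
      if (cc == d) { if (cc == a) pr(a) / 2 else if (cc == b) pr(b) / 2 else 0 }
      else if (cc == a && d == b) (pr(a) + pr(b)) / 2
      else if (cc == a || d == a) { if (cc == a) pr(d) / 2 else pr(cc) / 2 }
      else if (cc == b || d == b) { if (cc == b) pr(d) / 2 else pr(cc) / 2 }
      else 0
    }
    t2 <- as.numeric(cc == a && d == b)    # both pairs IBD: same genotype
    for (rel in names(kvec)) {
      kk <- kvec[[rel]]
      L <- pG1 * (kk[1] * pG2 + kk[2] * t1 + kk[3] * t2)
      ll[rel] <- ll[rel] + log(L)          # log(0) = -Inf propagates
    }
  }
  best <- names(ll)[which.max(ll)]
  structure(list(dyad = as.character(dyad), loglik = ll, best = best,
                 first_order = best %in% c("FS", "PO")),
            class = "relationship_call")
}

#' @export
print.relationship_call <- function(x, ...) {
  cat("dyad", x$dyad[1], "-", x$dyad[2], ": best =", x$best,
      if (x$first_order) "(first-order)" else "", "\n")
  print(round(x$loglik, 3))
  invisible(x)
}

#' Classify every dyad of a genotype table
#'
#' @inheritParams relationship_classify
#' @return data.frame `id_a, id_b, logL_U, logL_HS, logL_FS, logL_PO, best,
#'   first_order`, one row per unordered dyad.
#' @export
relationship_classify_all <- function(g, freqs = allele_frequencies(g)) {
  n <- length(g$ids)
  rows <- list()
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    rc <- relationship_classify(g, freqs, c(g$ids[i], g$ids[k]))
    rows[[length(rows) + 1]] <- data.frame(
      id_a = g$ids[i], id_b = g$ids[k],
      logL_U = rc$loglik["U"], logL_HS = rc$loglik["HS"],
      logL_FS = rc$loglik["FS"], logL_PO = rc$loglik["PO"],
      best = rc$best, first_order = rc$first_order, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove first-order relatives by greedy vertex cover
#'
#' Builds a graph on individuals whose edges are the first-order dyads and
#' iteratively removes the highest-degree vertex (ties broken by
#' lexicographically smallest id) until no edge remains, so that the retained
#' individuals contain no first-order pair.
#'
#' @param g a [genotype_table()].
#' @param calls either the data.frame of [relationship_classify_all()] or a
#'   list of `relationship_call` objects.
#' @return The pruned `genotype_table`, with attribute `removed` giving the
#'   removal order.
#' @export
prune_first_order <- function(g, calls) {
  if (is.data.frame(calls)) {
    ed <- calls[calls$first_order, c("id_a", "id_b"), drop = FALSE]
  } else {
    fo <- Filter(function(x) isTRUE(x$first_order), calls)
    ed <- do.call(rbind, lapply(fo, function(x)
      data.frame(id_a = x$dyad[1], id_b = x$dyad[2], stringsAsFactors = FALSE)))
    if (is.null(ed)) ed <- data.frame(id_a = character(0), id_b = character(0))
  }
  removed <- character(0)
  while (nrow(ed) > 0) {
    deg <- sort(table(c(ed$id_a, ed$id_b)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- sort(top)[1]
    removed <- c(removed, victim)
    ed <- ed[ed$id_a != victim & ed$id_b != victim, , drop = FALSE]
  }
  out <- subset_individuals(g, setdiff(g$ids, removed))
  attr(out, "removed") <- removed
  out
}
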
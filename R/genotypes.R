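#' Diploid microsatellite genotype table
#'
#' A `genotype_table` stores diploid allele calls for a set of individuals at a
#' set of loci, together with optional coordinates (planar metres) and sex.
#' Allele calls are opaque positive integer codes; a call is either a complete
#' unordered pair or wholly missing (`NA`).
#'
#' Internally the calls live in two integer matrices `a1`, `a2` (individuals x
#' loci); `a1 <= a2` is enforced so that unordered pairs compare cheaply.
#'
#' @param ids character vector of unique individual labels.
#' @param a1,a2 integer matrices (individuals x loci) of allele codes; `NA`
#'   marks missing calls and must occur in both matrices simultaneously.
#' @param loci character vector of locus names.
#' @param x,y optional numeric coordinate vectors (metres).
#' @param sex optional character vector, values in `c("M", "F", "unknown")`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, a1, a2, loci = colnames(a1), x = NULL, y = NULL,
                           sex = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2))) stop("allele matrices differ in shape")
  if (nrow(a1) != length(ids)) stop("ids do not match allele matrix rows")
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (length(loci) != ncol(a1)) stop("loci do not match allele matrix columns")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing call (one allele of two) for individual ",
         ids[w[1]], " at locus ", loci[w[2]])
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (!is.null(sex)) {
    sex <- as.character(sex)
    sex[is.na(sex) | !sex %in% c("M", "F")] <- "unknown"
  }
  structure(list(ids = ids, loci = as.character(loci), a1 = a1, a2 = a2,
                 x = if (!is.null(x)) as.numeric(x), y = if (!is.null(y)) as.numeric(y),
                 sex = sex),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", length(x$ids), " individuals x ", length(x$loci),
      " loci\n", sep = "")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%; coordinates: %s; sex: %s\n",
              100 * miss, if (is.null(x$x)) "no" else "yes",
              if (is.null(x$sex)) "no" else "yes"))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$ids), length(x$loci))

#' Subset a genotype table by individuals
#'
#' @param g a [genotype_table()].
#' @param keep character vector of ids (or logical/integer index) to retain.
#' @return A `genotype_table` with the selected individuals, original order.
#' @export
subset_individuals <- function(g, keep) {
  idx <- if (is.character(keep)) match(keep, g$ids) else seq_along(g$ids)[keep]
  if (anyNA(idx)) stop("unknown id(s): ", paste(keep[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  genotype_table(g$ids[idx], g$a1[idx, , drop = FALSE], g$a2[idx, , drop = FALSE],
                 g$loci, x = g$x[idx], y = g$y[idx], sex = g$sex[idx])
}

# ---- I/O -------------------------------------------------------------------

#' Read genotypes from genepop or CSV text
#'
#' Genepop dialect: title line, one locus name per line (or a single
#' comma-separated line), `POP` markers, then `id ,  aabb aabb ...` rows with
#' 2- or 3-digit allele codes per allele (4- or 6-digit genotype fields);
#' `00`/`000` codes a missing allele.  CSV dialect: header
#' `id,x,y,sex,<locus>.1,<locus>.2,...`; blank cells code missing alleles.
#'
#' @param path file path.
#' @param dialect `"genepop"` or `"csv"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("genepop", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (dialect == "genepop") read_genepop(path) else read_genotypes_csv(path)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3) stop("genepop file too short: ", path)
  body <- lines[-1]                              # drop title
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_at)) stop("no POP marker in genepop file: ", path)
  locus_lines <- body[seq_len(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  rows <- body[-seq_len(pop_at[1])]
  rows <- rows[!grepl("^\\s*pop\\s*$", rows, ignore.case = TRUE)]
  ids <- character(0); A1 <- NULL; A2 <- NULL
  for (r in rows) {
    parts <- strsplit(r, ",")[[1]]
    if (length(parts) < 2) stop("malformed genepop row: ", r)
    id <- trimws(parts[1])
    fields <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(fields) != length(loci)) {
      stop("individual ", id, " has ", length(fields), " genotype fields for ",
           length(loci), " loci")
    }
    w <- nchar(fields)
    if (any(w != w[1] | !w %in% c(4L, 6L))) {
      stop("individual ", id, ": genotype fields must be uniformly 4 or 6 digits")
    }
    d <- w[1] / 2
    al1 <- as.integer(substr(fields, 1, d))
    al2 <- as.integer(substr(fields, d + 1, 2 * d))
    al1[al1 == 0L] <- NA; al2[al2 == 0L] <- NA
    bad <- xor(is.na(al1), is.na(al2))
    if (any(bad)) al1[bad] <- al2[bad] <- NA   # partial genotype treated missing
    ids <- c(ids, id); A1 <- rbind(A1, al1); A2 <- rbind(A2, al2)
  }
  genotype_table(ids, A1, A2, loci)
}

read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(d)) stop("csv genotype file lacks an 'id' column: ", path)
  meta <- intersect(c("id", "x", "y", "sex"), names(d))
  gcols <- setdiff(names(d), meta)
  if (length(gcols) %% 2 != 0 || !length(gcols)) {
    stop("expected two columns per locus (<locus>.1, <locus>.2), got ",
         length(gcols), " genotype columns")
  }
  base <- sub("\\.[12]$", "", gcols)
  loci <- unique(base)
  for (l in loci) {
    if (!all(paste0(l, c(".1", ".2")) %in% gcols)) {
      stop("locus ", l, " lacks paired columns ", l, ".1 and ", l, ".2")
    }
  }
  to_int <- function(v) {
    v[v %in% c("", "NA")] <- NA
    as.integer(v)
  }
  A1 <- sapply(loci, function(l) to_int(as.character(d[[paste0(l, ".1")]])))
  A2 <- sapply(loci, function(l) to_int(as.character(d[[paste0(l, ".2")]])))
  if (is.null(dim(A1))) { A1 <- matrix(A1, nrow = nrow(d)); A2 <- matrix(A2, nrow = nrow(d)) }
  bad <- xor(is.na(A1), is.na(A2))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("odd allele count for individual ", d$id[w[1]], " at locus ", loci[w[2]])
  }
  genotype_table(d$id, A1, A2, loci,
                 x = if ("x" %in% names(d)) d$x, y = if ("y" %in% names(d)) d$y,
                 sex = if ("sex" %in% names(d)) d$sex)
}

#' Write genotypes to genepop or CSV text
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(g, f), d)`
#' reproduces `g`'s ids, loci and calls exactly.
#'
#' @param g a [genotype_table()].
#' @param path output file path.
#' @param dialect `"genepop"` or `"csv"`.
#' @param title genepop title line.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("genepop", "csv"),
                            title = "resgen genotype export") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    d <- data.frame(id = g$ids, stringsAsFactors = FALSE)
    if (!is.null(g$x)) d$x <- g$x
    if (!is.null(g$y)) d$y <- g$y
    if (!is.null(g$sex)) d$sex <- g$sex
    for (j in seq_along(g$loci)) {
      d[[paste0(g$loci[j], ".1")]] <- g$a1[, j]
      d[[paste0(g$loci[j], ".2")]] <- g$a2[, j]
    }
    utils::write.csv(d, path, row.names = FALSE, na = "")
  } else {
    digits <- if (max(c(g$a1, g$a2), 1L, na.rm = TRUE) > 99) 3L else 2L
    fmt <- function(a) {
      a[is.na(a)] <- 0L
      formatC(a, width = digits, flag = "0")
    }
    geno <- matrix(paste0(fmt(g$a1), fmt(g$a2)), nrow = length(g$ids))
    rows <- paste0(g$ids, " ,  ", apply(geno, 1, paste, collapse = " "))
    writeLines(c(title, g$loci, "POP", rows), path)
  }
  invisible(path)
}

# ---- allele frequencies ----------------------------------------------------

#' Per-locus allele relative frequencies
#'
#' Frequencies are computed over typed individuals only (pairwise deletion);
#' each diploid call contributes two gametes.
#'
#' @param g a [genotype_table()].
#' @return An object of class `allele_freqs`: a list with one element per
#'   locus, each a named numeric vector of frequencies (names are allele
#'   codes), with attribute `n_typed` (individuals typed at that locus).
#' @export
allele_frequencies <- function(g) {
  out <- lapply(seq_along(g$loci), function(j) {
    a <- c(g$a1[, j], g$a2[, j])
    a <- a[!is.na(a)]
    if (!length(a)) stop("all calls missing at locus ", g$loci[j])
    tab <- table(a)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    attr(f, "n_typed") <- sum(!is.na(g$a1[, j]))
    f
  })
  names(out) <- g$loci
  class(out) <- "allele_freqs"
  out
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs over", length(x), "loci; alleles per locus:",
      paste(vapply(x, length, 1L), collapse = " "), "\n")
  invisible(x)
}
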
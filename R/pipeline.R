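#' Analysis configuration for the full pipeline
#'
#' @param genotypes a [genotype_table()] (or path to a genotype file plus
#'   `dialect`).
#' @param surfaces named list of [grid_surface()] environmental surfaces.
#' @param points sample coordinates aligned with the genotype ids.
#' @param tracks optional [telemetry_tracks()] for the home-range stage.
#' @param dialect genotype file dialect if `genotypes` is a path.
#' @param prune_related remove one member of each first-order dyad before the
#'   landscape-genetics stages (default TRUE; switching it off is logged
#'   prominently in the report).
#' @param ga a [ga_config()] for the optimization stages.
#' @param bootstrap_iterations,bootstrap_fraction bootstrap model-selection
#'   settings.
#' @param mantel_permutations permutations for the Mantel test/correlogram.
#' @param correlogram_width distance-class width, metres.
#' @param isopleth home-range isopleth level.
#' @param spearman_threshold correlation cut-off for composite candidates.
#' @param seed master seed; stage seeds derive deterministically from it.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(genotypes, surfaces, points, tracks = NULL,
                            dialect = "csv", prune_related = TRUE,
                            ga = ga_config(), bootstrap_iterations = 100,
                            bootstrap_fraction = 0.75,
                            mantel_permutations = 999,
                            correlogram_width = 50, isopleth = 0.95,
                            spearman_threshold = 0.29, seed = 1) {
  if (is.character(genotypes)) {
    if (!file.exists(genotypes)) stop("genotype file not found: ", genotypes)
    genotypes <- read_genotypes(genotypes, dialect)
  }
  structure(list(genotypes = genotypes, surfaces = surfaces, points = points,
                 tracks = tracks, prune_related = prune_related, ga = ga,
                 bootstrap_iterations = bootstrap_iterations,
                 bootstrap_fraction = bootstrap_fraction,
                 mantel_permutations = mantel_permutations,
                 correlogram_width = correlogram_width, isopleth = isopleth,
                 spearman_threshold = spearman_threshold, seed = seed),
            class = "analysis_config")
}

#' Run the full landscape-genetics pipeline
#'
#' Stage order: diversity -> HWE -> relatedness -> pruning -> Dps ->
#' clustering -> Mantel test/correlogram -> single-surface optimization ->
#' Spearman filter -> multisurface optimization -> bootstrap model selection
#' -> home range (if telemetry present).  All landscape-genetics stages use
#' the pruned (unrelated) dataset.  Every output table is written as CSV to
#' `out_dir` together with a machine-readable `summary.json`.
#'
#' @param cfg an [analysis_config()].
#' @param out_dir report directory (created).
#' @return list of stage results, invisibly (also written to `out_dir`).
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("resgen_report_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  g <- cfg$genotypes

  res$diversity <- stage("diversity", diversity_summary(g))
  utils::write.csv(res$diversity, file.path(out_dir, "diversity.csv"),
                   row.names = FALSE)
  res$hwe <- stage("hwe", hwe_test_all(g, reps = 2000, seed = cfg$seed))
  utils::write.csv(res$hwe, file.path(out_dir, "hwe.csv"), row.names = FALSE)

  res$relationships <- stage("relatedness", relationship_classify_all(g))
  utils::write.csv(res$relationships, file.path(out_dir, "relationships.csv"),
                   row.names = FALSE)
  if (cfg$prune_related) {
    gu <- stage("prune", prune_first_order(g, res$relationships))
    res$removed <- attr(gu, "removed")
  } else {
    message("NOTE: first-order pruning disabled; related individuals retained")
    gu <- g
    res$removed <- character(0)
  }
  res$n_unrelated <- length(gu$ids)

  res$dps <- stage("dps", dps_matrix(gu))
  utils::write.csv(as.data.frame(res$dps), file.path(out_dir, "dps.csv"))

  res$cluster_scan <- stage("clustering",
                            kmeans_bic_scan(gu, K_max = min(8, length(gu$ids) - 1),
                                            seed = cfg$seed))
  utils::write.csv(data.frame(K = res$cluster_scan$K, BIC = res$cluster_scan$BIC),
                   file.path(out_dir, "bic_by_k.csv"), row.names = FALSE)

  pts <- cfg$points[gu$ids, , drop = FALSE]
  eu <- as.matrix(stats::dist(pts))
  dimnames(eu) <- list(gu$ids, gu$ids)
  res$mantel <- stage("mantel",
                      mantel_test(res$dps, eu, n_perm = cfg$mantel_permutations,
                                  method = "spearman", seed = cfg$seed))
  res$correlogram <- stage("correlogram",
                           mantel_correlogram(res$dps, pts,
                                              class_width = cfg$correlogram_width,
                                              n_perm = cfg$mantel_permutations,
                                              seed = cfg$seed))
  utils::write.csv(as.data.frame(res$correlogram),
                   file.path(out_dir, "correlogram.csv"), row.names = FALSE)

  res$single <- stage("optimize_single", {
    out <- list()
    for (n in names(cfg$surfaces)) {
      ga_n <- cfg$ga
      ga_n$seed <- cfg$seed + match(n, names(cfg$surfaces))
      out[[n]] <- optimize_single(cfg$surfaces[[n]], res$dps, pts, ga_n)
    }
    out
  })
  res$spearman <- stage("spearman_filter",
                        spearman_filter(cfg$surfaces, cfg$spearman_threshold))
  res$multi <- NULL
  if (nrow(res$spearman$retained) > 0) {
    res$multi <- stage("optimize_multi", {
      pair <- res$spearman$retained[1, ]
      ga_m <- cfg$ga; ga_m$seed <- cfg$seed + 100
      optimize_multi(cfg$surfaces[c(pair$a, pair$b)], res$dps, pts, ga_m)
    })
  }

  res$bootstrap <- stage("bootstrap", {
    cands <- list(null = list(X = NULL, k = "null"),
                  distance = list(X = eu, k = "distance"))
    for (n in names(res$single)) {
      cd <- commute_distance_matrix(
        transform_surface(cfg$surfaces[[n]], res$single[[n]]$spec), pts)
      cands[[n]] <- list(X = cd, k = "continuous")
    }
    if (!is.null(res$multi)) {
      comp <- composite_surface(cfg$surfaces[names(res$multi$specs)],
                                res$multi$specs)
      cands$composite <- list(X = commute_distance_matrix(comp, pts),
                              k = 2 * length(res$multi$specs) + 1)
    }
    bootstrap_selection(cands, res$dps, iterations = cfg$bootstrap_iterations,
                        fraction = cfg$bootstrap_fraction, seed = cfg$seed)
  })
  utils::write.csv(res$bootstrap, file.path(out_dir, "model_selection.csv"),
                   row.names = FALSE)

  if (!is.null(cfg$tracks)) {
    res$homerange <- stage("homerange",
                           homerange_table(cfg$tracks, level = cfg$isopleth))
    utils::write.csv(res$homerange, file.path(out_dir, "homerange.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    seed = cfg$seed,
    n_individuals = length(g$ids),
    n_unrelated = res$n_unrelated,
    n_removed = length(res$removed),
    mean_Ho = res$diversity$Ho[res$diversity$locus == "MEAN"],
    mean_uHe = res$diversity$uHe[res$diversity$locus == "MEAN"],
    best_K = res$cluster_scan$best_K,
    mantel_r = res$mantel$r, mantel_p = res$mantel$p,
    top_model = res$bootstrap$model[1],
    top_model_pct = res$bootstrap$top_pct[1],
    single_specs = lapply(res$single, function(o) {
      list(family = o$spec$family, mode = o$spec$mode, b = o$spec$b,
           r = o$spec$r, AIC = o$fit$AIC, AICc = o$fit$AICc)
    }),
    homerange_mean_ha = if (!is.null(res$homerange)) mean(res$homerange$area_ha))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  res$out_dir <- out_dir
  invisible(res)
}
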
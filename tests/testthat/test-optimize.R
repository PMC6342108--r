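# small shared scenario for optimization tests (coarse grid keeps GA cheap)
opt_scenario <- function(seed = 1, beta1 = 0.08, n_ind = 25, nr = 20) {
  surf <- gen_random_field(nr, nr, cell_size = 5, correlation_length = 30,
                           mean = 0.2, sd = 0.15, seed = seed, kind = "ndvi")
  decoy <- gen_random_field(nr, nr, cell_size = 5, correlation_length = 30,
                            mean = 44, sd = 8, seed = seed + 1)
  set.seed(seed + 2)
  pts <- cbind(x = runif(n_ind, 1, nr * 5 - 1), y = -runif(n_ind, 1, nr * 5 - 1))
  rownames(pts) <- sprintf("i%02d", seq_len(n_ind))
  spec <- transform_spec("monomolecular", "inverse", b = 0.5, r = 100)
  y <- sim_genetic_distances(transform_surface(surf, spec), pts,
                             beta0 = 0.55, beta1 = beta1,
                             sigma2_u = 5e-4, sigma2_e = 5e-4, seed = seed + 3)
  list(surf = surf, decoy = decoy, pts = pts, y = y, spec = spec)
}

fast_cfg <- function(seed) {
  ga_config(pop_size = 10, max_generations = 6, stagnation = 4, seed = seed)
}

test_that("GA optimization is deterministic given the seed", {
  sc <- opt_scenario(seed = 5)
  a <- optimize_single(sc$surf, sc$y, sc$pts, fast_cfg(3))
  b <- optimize_single(sc$surf, sc$y, sc$pts, fast_cfg(3))
  expect_identical(a$spec, b$spec)
  expect_identical(a$objective, b$objective)
  # elitism: best fitness is non-decreasing over generations
  expect_true(all(diff(a$log) >= -1e-12))
})

test_that("single-surface optimization finds a strong planted signal", {
  sc <- opt_scenario(seed = 7)
  om <- optimize_single(sc$surf, sc$y, sc$pts,
                        ga_config(pop_size = 12, max_generations = 8,
                                  stagnation = 5, seed = 11))
  null_fit <- mlpe_fit(sc$y, list(), k_override = "null")
  expect_lt(om$fit$AICc, null_fit$AICc - 2)
  expect_s3_class(om$spec, "transform_spec")
})

test_that("categorical optimization fixes the first category at 1", {
  sc <- opt_scenario(seed = 9)
  feat <- reclassify_binary(sc$surf, 0.1)
  om <- optimize_categorical(feat, sc$y, sc$pts, fast_cfg(2))
  expect_equal(unname(om$category_values[1]), 1)
  expect_equal(om$fit$k, 3)
  flat <- grid_surface(matrix(1, 4, 4), 5)
  expect_error(optimize_categorical(flat, sc$y, sc$pts, fast_cfg(1)),
               ">= 2 categories")
})

test_that("multisurface composites report contributions summing to 100", {
  sc <- opt_scenario(seed = 13, n_ind = 20)
  om <- optimize_multi(list(a = sc$surf, b = sc$decoy), sc$y, sc$pts,
                       fast_cfg(4))
  expect_equal(sum(om$contributions), 100, tolerance = 1e-6)
  expect_equal(om$fit$k, 5)
  expect_named(om$specs, c("a", "b"))
  expect_error(optimize_multi(list(a = sc$surf), sc$y, sc$pts, fast_cfg(1)),
               ">= 2 surfaces")
})

test_that("spearman filter retains weakly correlated surface pairs", {
  set.seed(15)
  a <- grid_surface(matrix(rnorm(10000), 100, 100), 5)
  b <- grid_surface(matrix(rnorm(10000), 100, 100), 5)
  res <- spearman_filter(list(a = a, b = b), threshold = 0.29)
  expect_lt(abs(res$rho["a", "b"]), 0.05)
  expect_equal(nrow(res$retained), 1)
  # a surface against a monotone transform of itself: rho = 1, excluded
  c_ <- grid_surface(exp(a$values), 5)
  res2 <- spearman_filter(list(a = a, c = c_))
  expect_equal(res2$rho["a", "c"], 1)
  expect_equal(nrow(res2$retained), 0)
  expect_error(spearman_filter(list(a = a, d = grid_surface(matrix(1, 2, 2), 5))),
               "mismatch")
})

test_that("bootstrap selection summarizes ranks, weights and top models", {
  sc <- opt_scenario(seed = 17, n_ind = 20)
  eu <- as.matrix(stats::dist(sc$pts))
  dimnames(eu) <- dimnames(sc$y)
  cd <- commute_distance_matrix(transform_surface(sc$surf, sc$spec), sc$pts)
  # single candidate: trivially always top
  one <- bootstrap_selection(list(m = list(X = cd, k = "continuous")), sc$y,
                             iterations = 5, seed = 1)
  expect_equal(one$top_pct, 100)
  expect_equal(one$avg_rank, 1)

  cands <- list(null = list(X = NULL, k = "null"),
                distance = list(X = eu, k = "distance"),
                truth = list(X = cd, k = "continuous"))
  bs <- bootstrap_selection(cands, sc$y, iterations = 20, fraction = 0.75,
                            seed = 2)
  expect_true(all(bs$avg_weight >= 0 & bs$avg_weight <= 1))
  expect_true(all(bs$avg_rank >= 1 & bs$avg_rank <= 3))
  expect_lte(sum(bs$top_pct), 100 + 1e-9)
  expect_equal(bs$model[1], "truth")  # strong signal wins
  # determinism
  bs2 <- bootstrap_selection(cands, sc$y, iterations = 20, fraction = 0.75,
                             seed = 2)
  expect_identical(bs, bs2)
})

test_that("full-fraction single-iteration bootstrap equals the full comparison", {
  sc <- opt_scenario(seed = 19, n_ind = 18)
  eu <- as.matrix(stats::dist(sc$pts))
  dimnames(eu) <- dimnames(sc$y)
  cands <- list(null = list(X = NULL, k = "null"),
                distance = list(X = eu, k = "distance"))
  bs <- bootstrap_selection(cands, sc$y, iterations = 1, fraction = 1, seed = 3)
  full <- model_comparison(list(
    null = mlpe_fit(sc$y, list(), k_override = "null"),
    distance = mlpe_fit(sc$y, list(x = eu), k_override = "distance")))
  for (m in full$model) {
    expect_equal(bs$avg_rank[bs$model == m], full$rank[full$model == m])
    expect_equal(bs$avg_weight[bs$model == m], full$weight[full$model == m],
                 tolerance = 1e-9)
  }
})

test_that("three independent runs report convergence agreement", {
  sc <- opt_scenario(seed = 23, n_ind = 18, nr = 15)
  runs <- optimize_single_runs(sc$surf, sc$y, sc$pts, fast_cfg(5), n_runs = 2)
  expect_length(runs, 2)
  expect_true(attr(runs, "agreement") >= 0 && attr(runs, "agreement") <= 1)
})
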
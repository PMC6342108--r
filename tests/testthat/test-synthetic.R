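test_that("random fields are reproducible with decaying autocorrelation", {
  a <- gen_random_field(40, 40, 5, correlation_length = 50, mean = 10, sd = 2,
                        seed = 3)
  b <- gen_random_field(40, 40, 5, correlation_length = 50, mean = 10, sd = 2,
                        seed = 3)
  expect_identical(a$values, b$values)
  expect_equal(mean(a$values), 10, tolerance = 1e-9)
  expect_equal(sd(as.vector(a$values)), 2, tolerance = 1e-9)
  # lag-1 autocorrelation exceeds lag-10 (Moran-style decay)
  v <- a$values
  lag_cor <- function(k) cor(as.vector(v[, 1:(40 - k)]), as.vector(v[, (k + 1):40]))
  expect_gt(lag_cor(1), lag_cor(10))
  expect_warning(gen_random_field(10, 10, 5, correlation_length = 2, seed = 1),
                 "white noise")
  flat <- gen_random_field(10, 10, 5, correlation_length = 20, mean = 4, sd = 0,
                           seed = 1)
  expect_true(all(flat$values == 4))
  nd <- gen_random_field(30, 30, 5, correlation_length = 30, mean = 0.2,
                         sd = 0.6, seed = 5, kind = "ndvi")
  expect_true(all(nd$values >= -1 & nd$values <= 1))
})

test_that("noise-free genetic distances track commute distances perfectly", {
  s <- gen_random_field(15, 15, 5, correlation_length = 25, seed = 7)
  set.seed(8)
  pts <- cbind(x = runif(10, 1, 74), y = -runif(10, 1, 74))
  rownames(pts) <- paste0("i", 1:10)
  rs <- transform_surface(s, transform_spec("monomolecular", "plain", 1, 50))
  y <- sim_genetic_distances(rs, pts, beta0 = 0.5, beta1 = 0.05,
                             sigma2_u = 0, sigma2_e = 0, seed = 1)
  cd <- commute_distance_matrix(rs, pts)
  lt <- lower.tri(y)
  expect_equal(cor(y[lt], cd[lt], method = "spearman"), 1)
  y2 <- sim_genetic_distances(rs, pts, seed = 4)
  y3 <- sim_genetic_distances(rs, pts, seed = 4)
  expect_identical(y2, y3)
  expect_error(sim_genetic_distances(rs, pts, sigma2_u = -1), "variances")
})

test_that("family simulation respects Mendelian transmission", {
  g <- sim_microsat_families(30, n_po = 5, n_fs = 5, n_hs = 3, seed = 11)
  tr <- attr(g, "truth")
  po <- tr[tr$relationship == "PO", ]
  for (i in seq_len(nrow(po))) {
    ia <- match(po$id_a[i], g$ids); ib <- match(po$id_b[i], g$ids)
    share <- shared_alleles(g$a1[ia, ], g$a2[ia, ], g$a1[ib, ], g$a2[ib, ])
    expect_true(all(share >= 1))   # a parent and child always share an allele
  }
  expect_error(sim_microsat_families(5, n_po = 3, n_fs = 3, n_hs = 0),
               "more related")
})

test_that("full siblings are genetically closer than unrelated pairs", {
  fs_d <- c(); u_d <- c()
  for (s in 1:5) {
    g <- sim_microsat_families(40, n_po = 0, n_fs = 10, n_hs = 0,
                               seed = 1300 + s)
    dm <- dps_matrix(g)
    tr <- attr(g, "truth")
    for (i in seq_len(nrow(tr))) fs_d <- c(fs_d, dm[tr$id_a[i], tr$id_b[i]])
    others <- setdiff(g$ids, c(tr$id_a, tr$id_b))
    u_d <- c(u_d, dm[others, others][lower.tri(diag(length(others)))])
  }
  expect_lt(mean(fs_d), mean(u_d))
})

test_that("relationship classification recovers most simulated first-order dyads", {
  hits <- 0; tot <- 0
  for (s in 1:4) {
    g <- sim_microsat_families(24, n_loci = 8, n_alleles = 10, n_po = 4,
                               n_fs = 4, n_hs = 0, seed = 1400 + s)
    f <- allele_frequencies(g)
    tr <- attr(g, "truth")
    for (i in seq_len(nrow(tr))) {
      rc <- relationship_classify(g, f, c(tr$id_a[i], tr$id_b[i]))
      hits <- hits + rc$first_order; tot <- tot + 1
    }
  }
  expect_gte(hits / tot, 0.8)
})

test_that("telemetry simulation stays in the nightly window", {
  centers <- data.frame(x = c(0, 100), y = c(0, -100),
                        row.names = c("R1", "R2"))
  tk <- sim_radiolocations(centers, sigma = 8, n_fixes = 10, seed = 21,
                           sexes = c("M", "F"))
  expect_length(tk, 2)
  for (t in tk) {
    expect_equal(nrow(t$fixes), 10)
    hrs <- as.numeric(format(t$fixes$timestamp, "%H")) +
      as.numeric(format(t$fixes$timestamp, "%M")) / 60
    expect_true(all(hrs >= 21 | hrs <= 1.5))
  }
  tk2 <- sim_radiolocations(centers, sigma = 8, n_fixes = 10, seed = 21,
                            sexes = c("M", "F"))
  expect_identical(tk[[1]]$fixes, tk2[[1]]$fixes)
  expect_error(sim_radiolocations(centers, n_fixes = 3), ">= 5")
})

test_that("home-range area grows with simulated dispersion", {
  areas <- vapply(c(5, 10, 20), function(sg) {
    mean(vapply(1:3, function(s) {
      tk <- sim_radiolocations(data.frame(x = 0, y = 0), sigma = sg,
                               n_fixes = 10, seed = 1500 + s)
      kde_homerange(tk[[1]])$area_ha
    }, 1.0))
  }, 1.0)
  expect_true(all(diff(areas) > 0))
})

test_that("the bundled scenario is reproducible and exports cleanly", {
  sc1 <- synthetic_scenario(seed = 5)
  sc2 <- synthetic_scenario(seed = 5)
  expect_identical(sc1$y, sc2$y)
  expect_identical(sc1$surfaces$ndvi$values, sc2$surfaces$ndvi$values)
  # roughly a third of NDVI cells read as bare soil
  frac <- mean(sc1$surfaces$ndvi$values < 0.1)
  expect_gt(frac, 0.15); expect_lt(frac, 0.45)
  dir <- tempfile("scenario_")
  write_scenario(sc1, dir)
  expect_true(all(file.exists(file.path(dir, c("ndvi.asc", "genotypes.gen",
                                               "genotypes.csv", "truth.json",
                                               "telemetry.csv", "dps.csv")))))
  back <- read_esri_ascii(file.path(dir, "ndvi.asc"))
  expect_equal(back$values, sc1$surfaces$ndvi$values, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$true_surface, "ndvi")
  expect_equal(truth$true_mode, "inverse")
})
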
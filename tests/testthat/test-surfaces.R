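test_that("NDVI follows its defining formula and masks degenerate cells", {
  red <- grid_surface(matrix(c(0.3, 0.2, 0, 0.5), 2, 2), 5)
  nir <- grid_surface(matrix(c(0.5, 0.2, 0.4, 0), 2, 2), 5)
  nd <- compute_ndvi(red, nir)
  expect_equal(nd$values[1, 1], 0.25)        # (0.5-0.3)/(0.8)
  expect_equal(nd$values[2, 1], 0)           # NIR = Red
  expect_equal(nd$values[1, 2], 1)           # Red = 0
  expect_equal(nd$values[2, 2], -1)          # NIR = 0
  z <- grid_surface(matrix(0, 2, 2), 5)
  expect_true(all(is.na(compute_ndvi(z, z)$values)))  # 0/0 masked
  expect_error(compute_ndvi(red, grid_surface(matrix(1, 3, 3), 5)),
               "co-registered")
})

test_that("binary reclassification thresholds and is idempotent", {
  v <- matrix(c(0.05, 0.1, 0.3, -0.2, 0.12, 0.09, 0.5, 0.08, 0.11,
                0.2, 0.02, 0.15, 0.1, 0.07, 0.25, -0.1, 0.3, 0.18,
                0.04, 0.22, 0.13, 0.06, 0.09, 0.4, 0.1), 5, 5)
  s <- grid_surface(v, 5)
  b <- reclassify_binary(s, 0.1)
  expect_equal(sum(b$values), sum(v >= 0.1))   # direct cell count
  expect_true(all(b$values %in% c(0, 1)))
  b2 <- reclassify_binary(b, 0.1)
  expect_identical(b2$values, b$values)
  low <- grid_surface(matrix(0.01, 3, 3), 5)
  expect_true(all(reclassify_binary(low, 0.1)$values == 0))
  s$values[1, 1] <- NA
  expect_true(is.na(reclassify_binary(s, 0.1)$values[1, 1]))
})

test_that("ESRI ASCII grids round-trip including nodata", {
  set.seed(5)
  s <- grid_surface(matrix(rnorm(12), 3, 4), 2.5, origin = c(100, 250))
  s$values[2, 3] <- NA
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(s, f)
  back <- read_esri_ascii(f)
  expect_equal(back$values, s$values)
  expect_equal(back$cell_size, s$cell_size)
  expect_equal(back$origin, s$origin)
})

test_that("ordinary kriging interpolates exactly with zero nugget", {
  set.seed(6)
  pts <- data.frame(x = runif(10, 0, 100), y = runif(10, 0, 100),
                    value = rnorm(10))
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 30)
  pr <- krige_points(pts, m, pts[, c("x", "y")])
  expect_lt(max(abs(pr - pts$value)), 1e-6)
  w <- attr(pr, "weights")
  expect_true(all(abs(colSums(w) - 1) < 1e-9))

  # constant data -> constant surface (weights sum to 1)
  cpts <- data.frame(x = c(0, 50, 100, 30), y = c(0, 80, 10, 40), value = 7)
  ks <- krige_surface(cpts, m, list(n_rows = 5, n_cols = 5, cell_size = 20,
                                    origin = c(0, 100)))
  expect_true(all(abs(ks$values - 7) < 1e-9))
})

test_that("two-point kriging matches the 3x3 linear system solved longhand", {
  pts <- data.frame(x = c(0, 10), y = c(0, 0), value = c(1, 3))
  m <- variogram_model("exponential", nugget = 0.1, psill = 2, range = 5)
  target <- data.frame(x = 4, y = 3)
  cv <- function(h) {
    sill <- 2.1
    ifelse(h == 0, sill, sill - (0.1 + 2 * (1 - exp(-h / 5))))
  }
  A <- rbind(c(cv(0), cv(10), 1), c(cv(10), cv(0), 1), c(1, 1, 0))
  b <- c(cv(5), cv(sqrt(45)), 1)
  sol <- solve(A, b)
  hand <- sol[1] * 1 + sol[2] * 3
  expect_equal(unname(krige_points(pts, m, target))[1], hand, tolerance = 1e-10)
})

test_that("kriging smooths to the data mean far from all points", {
  set.seed(8)
  pts <- data.frame(x = runif(8, 0, 10), y = runif(8, 0, 10),
                    value = rnorm(8, 5, 1))
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 1)
  far <- krige_points(pts, m, data.frame(x = 5000, y = 5000))
  expect_lt(abs(far - mean(pts$value)) / abs(mean(pts$value)), 0.01)
})

test_that("auto variogram fitting recovers a sensible model", {
  set.seed(9)
  truth <- variogram_model("exponential", nugget = 0, psill = 4, range = 20)
  pts <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  # draw one realization of the Gaussian process the variogram describes
  d <- as.matrix(stats::dist(pts))
  S <- 4 * exp(-d / 20)
  pts$value <- drop(chol(S + 1e-8 * diag(nrow(S))) %*% rnorm(nrow(S)))
  fit <- fit_variogram(pts)
  expect_s3_class(fit, "variogram_model")
  expect_gt(fit$psill, 0)
  pr <- krige_points(pts, fit, data.frame(x = 33, y = 47))
  expect_true(is.finite(pr))
  expect_error(krige_surface(rbind(pts, pts[1, ]), fit,
                             list(n_rows = 2, n_cols = 2, cell_size = 50,
                                  origin = c(0, 100))),
               "duplicate")
})

test_that("resampling preserves range and majority semantics", {
  set.seed(10)
  s <- grid_surface(matrix(runif(64), 8, 8), 5)
  fine <- resample_surface(s, 2.5, "bilinear")
  expect_true(min(fine$values) >= min(s$values) - 1e-12)
  expect_true(max(fine$values) <= max(s$values) + 1e-12)
  b <- reclassify_binary(s, 0.5)
  coarse <- resample_surface(b, 10, "majority")
  expect_true(all(coarse$values %in% c(0, 1)))
  expect_equal(dim(coarse$values), c(4L, 4L))
})
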
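norm_track <- function(n, sigma = 10, seed = 1) {
  set.seed(seed)
  list(individual = "t1", sex = "M",
       fixes = data.frame(x = rnorm(n, 0, sigma), y = rnorm(n, 0, sigma),
                          timestamp = as.POSIXct("2015-06-01 21:00:00",
                                                 tz = "UTC") + seq_len(n) * 60))
}

test_that("the utilization distribution integrates to one", {
  hr <- kde_homerange(norm_track(60), level = 0.95)
  expect_equal(sum(hr$ud$values) * hr$ud$cell_size^2, 1, tolerance = 1e-6)
  expect_true(all(hr$ud$values >= 0))
})

test_that("the 95% area approaches the bivariate-normal closed form", {
  hr <- kde_homerange(norm_track(1000, sigma = 10, seed = 3), level = 0.95)
  analytic <- 5.991 * pi * 100          # chi^2_2 95% quantile * pi * sigma^2
  expect_lt(abs(hr$area_ha * 1e4 - analytic) / analytic, 0.15)
})

test_that("h_ref follows the reference-bandwidth formula", {
  set.seed(4)
  x <- rnorm(64); x <- (x - mean(x)) / sd(x) * 4
  y <- rnorm(64); y <- (y - mean(y)) / sd(y) * 4
  expect_equal(h_ref(x, y), 4 * 64^(-1 / 6))
  expect_equal(4 * 64^(-1 / 6), 2, tolerance = 1e-12)
})

test_that("isopleth areas are monotone in the level", {
  tr <- norm_track(200, seed = 5)
  a95 <- kde_homerange(tr, level = 0.95)$area_ha
  a50 <- kde_homerange(tr, level = 0.50)$area_ha
  expect_lt(a50, a95)
  expect_error(kde_homerange(norm_track(4)), ">= 5 fixes")
  same <- norm_track(10)
  same$fixes$x <- 1; same$fixes$y <- 2
  expect_error(kde_homerange(same), "zero variance")
})

test_that("overlap percentages behave on constructed ranges", {
  a <- kde_homerange(norm_track(200, sigma = 10, seed = 6))
  ov <- overlap_matrix(list(a, a))
  expect_equal(unname(ov[1, 2]), 100)
  expect_equal(unname(ov[2, 1]), 100)
  far <- norm_track(200, sigma = 10, seed = 7)
  far$fixes$x <- far$fixes$x + 10000
  far$individual <- "t2"
  b <- kde_homerange(far)
  ov2 <- overlap_matrix(list(a, b))
  expect_equal(unname(ov2[1, 2]), 0)
  expect_equal(unname(ov2[2, 1]), 0)
  # B nested inside A with roughly half the spread: overlap(B->A) = 100
  inner <- norm_track(400, sigma = 4, seed = 8)
  inner$individual <- "t3"
  cc <- kde_homerange(inner)
  ov3 <- overlap_matrix(list(a, cc))
  expect_gt(unname(ov3[2, 1]), 95)          # B -> A
  expect_lt(unname(ov3[1, 2]), 60)          # A -> B covers only part of A
})

test_that("activity metrics compute consecutive steps per night", {
  ts <- as.POSIXct(c("2015-06-01 21:00:00", "2015-06-01 23:00:00",
                     "2015-06-02 01:00:00"), tz = "UTC")
  tr <- list(individual = "a", sex = "M",
             fixes = data.frame(x = c(0, 30, 30), y = c(0, 40, 40),
                                timestamp = ts))
  am <- activity_metrics(tr)
  expect_equal(am$steps$distance, c(50, 0))   # 3-4-5 triangle then no move
  expect_equal(nrow(am$nightly_max), 1)       # 01:00 belongs to the same night
  expect_equal(am$nightly_max$max_distance, 50)
  expect_equal(am$nightly_max$at, ts[2])

  # collinear fixes at 5 m spacing
  tr2 <- list(individual = "b", sex = "F",
              fixes = data.frame(x = seq(0, 20, 5), y = 0,
                                 timestamp = ts[1] + 0:4 * 1800))
  expect_true(all(activity_metrics(tr2)$steps$distance == 5))

  # single fix in a night: no step
  tr3 <- list(individual = "c", sex = "F",
              fixes = data.frame(x = 0, y = 0, timestamp = ts[1]))
  expect_equal(nrow(activity_metrics(tr3)$steps), 0)
  expect_error(telemetry_tracks(data.frame(individual = "x", sex = "M", x = 1,
                                           y = 1, timestamp = "yesterday")),
               "unparseable")
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  a <- c(5, 7, 9); b <- c(1, 2)
  mw <- mwu_test(a, b)
  expect_equal(mw$U_a, 6)    # all of a exceed all of b
  expect_equal(mw$U, 0)
  # enumeration oracle on a small untied case
  set.seed(9)
  a2 <- rnorm(4); b2 <- rnorm(3)
  mw2 <- mwu_test(a2, b2)
  U_count <- sum(outer(a2, b2, ">"))
  expect_equal(mw2$U_a, U_count)
  # exact p equals enumeration over all rank assignments
  pool <- c(a2, b2)
  combos <- utils::combn(7, 4)
  U_null <- apply(combos, 2, function(ix) {
    ra <- rank(pool)[ix]
    sum(ra) - 4 * 5 / 2
  })
  # two-sided exact p: 2 * P(U <= observed min U)
  p2 <- min(1, 2 * mean(U_null <= mw2$U))
  expect_equal(mw2$p, p2, tolerance = 1e-12)
  expect_error(mwu_test(numeric(0), b), "empty")
})

test_that("published home-range cells reproduce the sex contrast", {
  tab <- utils::read.csv(system.file("extdata",
                                     "homerange_areas_published.csv",
                                     package = "resgen"))
  males <- tab$area_ha[tab$sex == "M"]
  females <- tab$area_ha[tab$sex == "F"]
  expect_equal(length(males), 6)
  expect_equal(length(females), 2)
  mw <- mwu_test(males, females)
  expect_equal(mw$U_a, 8)    # exhaustive pair count over the 12 pairs
  # the printed U = 45 is impossible for 6 vs 2 samples (max U = 12)
  expect_lte(max(mw$U_a, mw$U_b), 12)
})
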
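# build a pairwise scenario with known parameters; returns matrices + truth
mlpe_sim <- function(n = 25, beta1 = 0.5, s2u = 0.09, s2e = 0.16, seed = 1) {
  set.seed(seed)
  pts <- cbind(runif(n), runif(n))
  d <- as.matrix(stats::dist(pts))
  ids <- paste0("i", seq_len(n))
  dimnames(d) <- list(ids, ids)
  lt <- lower.tri(d)
  xs <- (d[lt] - mean(d[lt])) / sd(d[lt])
  idx <- which(lt, arr.ind = TRUE)
  u <- rnorm(n, 0, sqrt(s2u))
  yv <- 0.2 + beta1 * xs + u[idx[, 1]] + u[idx[, 2]] +
    rnorm(length(xs), 0, sqrt(s2e))
  y <- matrix(0, n, n, dimnames = dimnames(d))
  y[lt] <- yv
  list(y = y + t(y), d = d)
}

test_that("with no individual variance the fit reduces to OLS", {
  sim <- mlpe_sim(n = 30, s2u = 0, s2e = 0.09, seed = 11)
  fit <- mlpe(gen ~ dist, data = list(gen = sim$y, dist = sim$d),
              k = "continuous")
  lt <- lower.tri(sim$y)
  xs <- scale(sim$d[lt])[, 1]
  ols <- stats::lm(sim$y[lt] ~ xs)
  expect_lt(max(abs(coef(fit) - coef(ols))) / max(abs(coef(ols))), 1e-4)
  expect_equal(fit$sigma2_u, 0)
  # -2l equals the OLS Gaussian deviance exactly at the boundary
  n <- length(xs)
  s2 <- sum(residuals(ols)^2) / n
  expect_equal(-2 * fit$loglik, n * log(2 * pi * s2) + n, tolerance = 1e-8)
})

test_that("the profiled likelihood equals a dense-covariance oracle", {
  sim <- mlpe_sim(seed = 21)
  fit <- mlpe_fit(sim$y, list(d = sim$d), k_override = "continuous")
  lt <- lower.tri(sim$y)
  idx <- which(lt, arr.ind = TRUE)
  n <- nrow(sim$y)
  np <- sum(lt)
  Z <- matrix(0, np, n)
  Z[cbind(seq_len(np), idx[, 1])] <- 1
  Z[cbind(seq_len(np), idx[, 2])] <- 1
  X <- cbind(1, scale(sim$d[lt])[, 1])
  yv <- sim$y[lt]
  negll <- function(p) {
    S <- exp(p[2]) * diag(np) + exp(p[1]) * tcrossprod(Z)
    b <- solve(crossprod(X, solve(S, X)), crossprod(X, solve(S, yv)))
    r <- yv - X %*% b
    0.5 * (determinant(S)$modulus + crossprod(r, solve(S, r)) +
             np * log(2 * pi))
  }
  o <- stats::optim(log(c(0.09, 0.16)), function(p) as.numeric(negll(p)))
  expect_equal(fit$loglik, -o$value, tolerance = 1e-5)
})

test_that("parameters are recovered within estimated uncertainty", {
  ok <- vapply(1:25, function(s) {
    sim <- mlpe_sim(n = 30, beta1 = 0.5, s2u = 0.3, s2e = 0.2, seed = 3000 + s)
    fit <- mlpe_fit(sim$y, list(d = sim$d), k_override = "continuous")
    abs(fit$beta[["d"]] - 0.5) <= 3 * fit$se[["d"]]
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("information criteria follow the stated conventions", {
  sim <- mlpe_sim(seed = 31)
  null <- mlpe(gen ~ 1, data = list(gen = sim$y), k = "null")
  expect_equal(null$k, 1)
  dist <- mlpe(gen ~ d, data = list(gen = sim$y, d = sim$d), k = "distance")
  expect_equal(dist$k, 2)
  expect_equal(dist$AIC, -2 * dist$loglik + 4)
  expect_equal(dist$AICc,
               dist$AIC + 2 * 2 * 3 / (dist$n_ind - 3))
  expect_gte(dist$AICc, dist$AIC)
  # k conventions: continuous 4, feature ncat+1, composite 2s+1
  expect_equal(mlpe_fit(sim$y, list(d = sim$d), k_override = "continuous")$k, 4)
  expect_equal(mlpe_fit(sim$y, list(d = sim$d), k_override = "feature",
                        n_categories = 2)$k, 3)
  expect_equal(mlpe_fit(sim$y, list(a = sim$d, b = sim$d + sim$d^2),
                        k_override = "composite")$k, 5)
  # AICc -> AIC as the number of individuals grows
  k <- 4
  corr_n <- function(n) 2 * k * (k + 1) / (n - k - 1)
  expect_lt(corr_n(1e8), 1e-6)
  expect_true(all(diff(corr_n(10^(2:8))) < 0))
})

test_that("model comparison computes Akaike weights and ranks", {
  sim <- mlpe_sim(seed = 41)
  f1 <- mlpe_fit(sim$y, list(d = sim$d), k_override = "continuous")
  f2 <- f1; f2$AICc <- f1$AICc + 2; f2$AIC <- f1$AIC + 2
  cmp <- model_comparison(list(a = f1, b = f2))
  expect_equal(cmp$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-9)
  expect_equal(round(cmp$weight, 3), c(0.731, 0.269))
  expect_equal(cmp$rank, c(1, 2))
  single <- model_comparison(list(only = f1))
  expect_equal(single$weight, 1)
  expect_equal(single$rank, 1)
  # weights invariant to a constant shift in AICc
  f3 <- f1; f3$AICc <- f1$AICc + 100
  f4 <- f2; f4$AICc <- f2$AICc + 100
  cmp2 <- model_comparison(list(a = f3, b = f4))
  expect_equal(cmp2$weight, cmp$weight)
  expect_error(model_comparison(list()), "empty")
})

test_that("degenerate designs are rejected", {
  sim <- mlpe_sim(seed = 51)
  bad <- sim$d
  rownames(bad) <- colnames(bad) <- rev(rownames(sim$d))
  expect_error(mlpe_fit(sim$y, list(d = bad)), "labels")
  expect_error(mlpe_fit(sim$y, list(a = sim$d, b = 2 * sim$d)), "collinear")
})

test_that("simulate() round-trips the generative model", {
  sim <- mlpe_sim(n = 30, seed = 61)
  fit <- mlpe_fit(sim$y, list(d = sim$d), k_override = "continuous")
  reps <- simulate(fit, nsim = 3, seed = 9)
  expect_length(reps, 3)
  for (m in reps) {
    expect_identical(dim(m), dim(sim$y))
    expect_true(isSymmetric(m))
    refit <- mlpe_fit(m, list(d = sim$d), k_override = "continuous")
    expect_lt(abs(refit$beta[["d"]] - fit$beta[["d"]]),
              6 * sqrt(fit$se[["d"]]^2 + refit$se[["d"]]^2))
  }
  # residual methods return pair-level vectors
  expect_length(residuals(fit), fit$n_pairs)
  expect_length(residuals(fit, "conditional"), fit$n_pairs)
  expect_lt(sd(residuals(fit, "conditional")), sd(residuals(fit)) + 1e-12)
})
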
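ctrl_mv <- mcmc_control(n_iter = 2500, burnin = 500, thin = 2)

## 4x4 among-individual covariance with one planted correlation
sigma_with_cor <- function(r, v = c(0.3, 0.25, 0.2, 0.25), i = 1, j = 2) {
  S <- diag(v)
  S[i, j] <- S[j, i] <- r * sqrt(v[i] * v[j])
  S
}

test_that("planted among-individual correlation is recovered", {
  sim <- simulate_behavior_table(
    n_ind = 96, n_months = 18, n_regions = 7,
    beta = matrix(0.5, 1, 4, dimnames = list("sex", NULL)),
    Sigma_I = sigma_with_cor(0.6), V_region = 0.05, V_month = 0.1,
    Sigma_resid = diag(0.6, 4), seed = 21)
  fit <- fit_multivariate(sim$table,
                          traits = c("distance", "home_range", "diurnality",
                                     "exploratory"),
                          fixed = "sex",
                          random = c("individual_id", "region", "window"),
                          control = ctrl_mv, seed = 1)
  ai <- among_individual_correlations(fit)
  expect_lt(abs(ai$estimate[1, 2] - 0.6), 0.15)
  expect_gt(ai$lower[1, 2], 0)                    # CI excludes zero
  ## diagonal carries the among-individual variances (standardized scale)
  tot <- 0.3 + 0.05 + 0.1 + 0.6
  expect_lt(abs(ai$estimate[1, 1] - 0.3 / tot), 0.1)

  ## fixed effects recovered per trait (standardized scale), CI sane
  fe <- fixed_effect_summary(fit)
  sexrows <- fe[grepl("sexmale", fe$coefficient), ]
  expect_equal(nrow(sexrows), 4L)
  expect_true(all(sexrows$lower < sexrows$mean & sexrows$mean < sexrows$upper))

  ## determinism
  fit2 <- fit_multivariate(sim$table,
                           traits = c("distance", "home_range", "diurnality",
                                      "exploratory"),
                           fixed = "sex",
                           random = c("individual_id", "region", "window"),
                           control = ctrl_mv, seed = 1)
  expect_identical(fit$cov_draws[[1]], fit2$cov_draws[[1]])
})

test_that("diagonal truth yields correlations whose CIs cover zero", {
  sim <- simulate_behavior_table(
    n_ind = 96, n_months = 18, n_regions = 7, beta = NULL,
    Sigma_I = diag(c(0.3, 0.25, 0.2, 0.25)), V_region = 0.05,
    V_month = 0.1, Sigma_resid = diag(0.6, 4), seed = 22)
  fit <- fit_multivariate(sim$table,
                          traits = c("distance", "home_range", "diurnality",
                                     "exploratory"), fixed = character(0),
                          random = c("individual_id", "region", "window"),
                          control = ctrl_mv, seed = 2)
  ai <- among_individual_correlations(fit)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lte(ai$lower[i, j], 0)
    expect_gte(ai$upper[i, j], 0)
  }
})

test_that("residual and among-individual covariance levels separate", {
  Sr <- diag(0.6, 4)
  Sr[1, 2] <- Sr[2, 1] <- 0.5 * 0.6        # residual-level correlation 0.5
  sim <- simulate_behavior_table(
    n_ind = 96, n_months = 18, n_regions = 7, beta = NULL,
    Sigma_I = diag(0.05, 4), V_region = 0.02, V_month = 0.05,
    Sigma_resid = Sr, seed = 23)
  fit <- fit_multivariate(sim$table,
                          traits = c("distance", "home_range", "diurnality",
                                     "exploratory"), fixed = character(0),
                          random = c("individual_id", "region", "window"),
                          control = ctrl_mv, seed = 3)
  ai <- among_individual_correlations(fit)
  expect_true(ai$lower[1, 2] <= 0 & ai$upper[1, 2] >= 0)
  rr <- fit$cov_draws$residual
  r_resid <- rr[, 1, 2] / sqrt(rr[, 1, 1] * rr[, 2, 2])
  expect_gt(quantile(r_resid, 0.025), 0)          # residual CI excludes 0
  expect_lt(abs(mean(r_resid) - 0.5), 0.1)
})

test_that("correlation summaries respect exact invariances", {
  ## correlations from draws are invariant to rescaling one trait
  set.seed(30)
  arr <- array(NA_real_, c(100, 3, 3))
  for (d in 1:100) {
    A <- matrix(rnorm(9), 3)
    arr[d, , ] <- crossprod(A) + diag(0.5, 3)
  }
  ai <- among_individual_correlations(arr)
  arr2 <- arr
  arr2[, 1, ] <- arr2[, 1, ] * 3; arr2[, , 1] <- arr2[, , 1] * 3
  ai2 <- among_individual_correlations(arr2)
  expect_equal(ai2$estimate[1, 2], ai$estimate[1, 2], tolerance = 1e-12)
  expect_equal(ai2$estimate[2, 3], ai$estimate[2, 3], tolerance = 1e-12)
  ## diagonal (variances) scales by 9
  expect_equal(ai2$estimate[1, 1], 9 * ai$estimate[1, 1], tolerance = 1e-12)

  ## diagonal covariance -> all off-diagonal correlations 0
  arr0 <- array(0, c(50, 2, 2))
  arr0[, 1, 1] <- runif(50, 0.5, 1); arr0[, 2, 2] <- runif(50, 0.5, 1)
  ai0 <- among_individual_correlations(arr0)
  expect_equal(ai0$estimate[1, 2], 0)
})

test_that("eigen axes reduce to closed forms and stay aligned", {
  ## identity matrix in all draws: equal shares of 0.25
  arrI <- array(0, c(40, 4, 4))
  for (d in 1:40) arrI[d, , ] <- diag(4)
  expect_warning(sI <- eigen_syndrome(arrI), "overlap")  # degenerate axes
  expect_equal(sI$shares, rep(0.25, 4))

  ## rank-1 matrix v v': first share 1, PC1 proportional to v
  v <- c(2, 1, -1, 0.5); v <- v / sqrt(sum(v^2))
  arr1 <- array(0, c(30, 4, 4))
  for (d in 1:30) arr1[d, , ] <- 3 * outer(v, v)
  s1 <- suppressWarnings(eigen_syndrome(arr1))
  expect_equal(s1$shares[1], 1)
  expect_equal(abs(sum(s1$loadings[, 1] * v)), 1, tolerance = 1e-10)

  ## 2x2 oracle: eigenvalues from the characteristic polynomial
  M <- matrix(c(0.3, 0.12, 0.12, 0.2), 2, 2)
  tr <- sum(diag(M)); dt <- det(M)
  lam <- (tr + c(1, -1) * sqrt(tr^2 - 4 * dt)) / 2
  arr2 <- array(0, c(10, 2, 2))
  for (d in 1:10) arr2[d, , ] <- M
  s2 <- suppressWarnings(eigen_syndrome(arr2))
  expect_equal(s2$values, lam, tolerance = 1e-10)

  ## shares sum to 1 and descend, in every draw
  set.seed(31)
  arr <- array(NA_real_, c(60, 4, 4))
  for (d in 1:60) {
    A <- matrix(rnorm(16), 4)
    arr[d, , ] <- crossprod(A)
  }
  s <- eigen_syndrome(arr)
  expect_equal(rowSums(s$share_draws), rep(1, 60), tolerance = 1e-12)
  expect_true(all(apply(s$share_draws, 1, function(z) all(diff(z) <= 1e-12))))
  ## loadings unit norm; per-draw sign alignment to the point axes
  expect_equal(colSums(s$loadings^2), rep(1, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in 1:4)
    expect_true(all(apply(s$loading_draws[, , j], 1,
                          function(w) sum(w * s$loadings[, j])) >= 0))
})

test_that("a planted dominant axis is recovered through the model", {
  v <- c(1, 0.9, 0, 1)                    # distance, home range, exploratory
  v <- v / sqrt(sum(v^2))
  S <- 0.35 * outer(v, v) + diag(0.03, 4)
  sim <- simulate_behavior_table(
    n_ind = 96, n_months = 18, n_regions = 7, beta = NULL,
    Sigma_I = S, V_region = 0.05, V_month = 0.1,
    Sigma_resid = diag(0.6, 4), seed = 24)
  fit <- fit_multivariate(sim$table,
                          traits = c("distance", "home_range", "diurnality",
                                     "exploratory"), fixed = character(0),
                          random = c("individual_id", "region", "window"),
                          control = ctrl_mv, seed = 4)
  s <- eigen_syndrome(fit)
  expect_gt(abs(sum(s$loadings[, 1] * v)), 0.9)   # |cos angle| > 0.9
  expect_gt(s$shares[1], 2 * s$shares[2])         # dominant axis
  ai <- among_individual_correlations(fit)
  for (pair in list(c(1, 2), c(1, 4), c(2, 4)))
    expect_gt(ai$lower[pair[1], pair[2]], 0)
})
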
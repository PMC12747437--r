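test_that("goal variances reduce to empirical variances when the error is zero", {
  ts <- make_chain_gt(L = 5, N = 120, step = 40, seed = 11)$truth
  gvt <- compute_goal_variances(ts, known_error_model(ts, 0), dim = 1,
                                min_n = 50)
  expect_equal(gvt$mu, gvt$emp_var)
  expect_true(all(gvt$usable))
})

test_that("goal table matches a brute-force recomputation from raw differences", {
  ts <- add_localization_error(make_chain_gt(L = 5, N = 150, step = 40,
                                             seed = 12, dropout = 0.1),
                               35, seed = 13)$observed
  em <- known_error_model(ts, 35)
  gvt <- compute_goal_variances(ts, em, dim = 2, min_n = 50)
  for (k in sample(nrow(gvt), 6)) {
    a <- gvt$alpha[k]; b <- gvt$beta[k]
    d <- ts$positions[, a, 2] - ts$positions[, b, 2]
    d <- d[!is.na(d)]
    expect_equal(gvt$n[k], length(d))
    expect_equal(gvt$emp_var[k], var(d))
    expect_equal(gvt$mu[k], max(var(d) - 35^2, 1))
    m2 <- mean((d - mean(d))^2); m4 <- mean((d - mean(d))^4)
    expect_equal(gvt$sd[k], max(sqrt((m4 - m2^2) / length(d)), 0.1))
  }
})

test_that("displacement-variance inflation equals the injected error variance", {
  # conservation check at N = 2000: Var(O^a - O^b) - Var(T^a - O^b) ~ sigma^2
  gt <- make_chain_gt(L = 6, N = 2000, step = 30, seed = 14)
  for (sigma in c(25, 50)) {
    noisy <- add_localization_error(gt, sigma, seed = 15)
    em <- known_error_model(noisy$observed, sigma)
    gvt <- compute_goal_variances(noisy$observed, em, dim = 1, min_n = 50)
    for (k in sample(nrow(gvt), 5)) {
      a <- gvt$alpha[k]; b <- gvt$beta[k]
      d_true <- gt$truth$positions[, a, 1] - noisy$observed$positions[, b, 1]
      inflation <- gvt$emp_var[k] - var(d_true, na.rm = TRUE)
      expect_lt(abs(inflation - sigma^2), 4 * gvt$sd[k])
    }
  }
})

test_that("the goal-variance density has its closed form and symmetry", {
  expect_equal(goal_variance_logdensity(0, 0, 1), log(1 / sqrt(2 * pi)))
  expect_equal(goal_variance_logdensity(1, 0, 1), log(exp(-0.5) / sqrt(2 * pi)))
  expect_equal(goal_variance_logdensity(5 + 2.3, 5, 1.7),
               goal_variance_logdensity(5 - 2.3, 5, 1.7))
  expect_error(goal_variance_logdensity(1, 0, 0), "sigma")
})

test_that("locus likelihood equals a term-by-term brute-force evaluation", {
  ts <- add_localization_error(make_chain_gt(L = 3, N = 5, step = 40, seed = 16),
                               20, seed = 17)$observed
  em <- known_error_model(ts, 20)
  gvt <- suppressWarnings(compute_goal_variances(ts, em, dim = 1, min_n = 2))
  a <- 1
  A <- ts$positions[, a, 1] + rnorm(5, 0, 10)
  ref <- 0
  for (b in 2:3) {
    row <- gvt[gvt$alpha == a & gvt$beta == b, ]
    v <- var(A - ts$positions[, b, 1])
    ref <- ref + dnorm(v, row$mu, row$sd, log = TRUE)
  }
  expect_equal(locus_log_likelihood(A, ts, gvt, alpha = a), ref)

  # translation invariance of the likelihood
  expect_equal(locus_log_likelihood(A + 1234.5, ts, gvt, alpha = a),
               locus_log_likelihood(A, ts, gvt, alpha = a))
})

test_that("with zero error the observed data already maximize the likelihood", {
  ts <- make_chain_gt(L = 4, N = 100, step = 40, seed = 18)$truth
  gvt <- compute_goal_variances(ts, known_error_model(ts, 0), dim = 1,
                                min_n = 50)
  ll0 <- locus_log_likelihood(ts$positions[, 1, 1], ts, gvt, alpha = 1)
  set.seed(1)
  for (r in 1:10) {
    ll <- locus_log_likelihood(ts$positions[, 1, 1] + rnorm(100, 0, 5),
                               ts, gvt, alpha = 1)
    expect_lte(ll, ll0)
  }
  # and the optimizer leaves such data essentially untouched
  fit <- optimize_locus(1, ts, gvt, optimizer_config(seed = 2, min_n = 50),
                        known_error_model(ts, 0))
  expect_true(all(abs(fit$C) < 1e-12))
})

test_that("accepted-step likelihood is non-decreasing and final >= initial", {
  ts <- add_localization_error(make_chain_gt(L = 8, N = 120, step = 30, seed = 19),
                               40, seed = 20)$observed
  em <- known_error_model(ts, 40)
  gvt <- compute_goal_variances(ts, em, dim = 1, min_n = 50)
  set.seed(99)
  fit <- optimize_locus(3, ts, gvt, optimizer_config(seed = 99, sweeps = 40), em)
  expect_true(all(diff(fit$loglik) > -1e-6))
  expect_gte(fit$loglik[length(fit$loglik)], fit$loglik[1])
  # corrections are mean-centered over localized spots
  expect_lt(abs(mean(fit$C)), 1e-9)
})

run_small_lear <- function(sigma, seed_data = 23, seed_opt = 7, L = 30,
                           N = 250, sweeps = 60) {
  gt <- make_chain_gt(L = L, N = N, step = 30, seed = seed_data)
  noisy <- add_localization_error(gt, sigma, seed = seed_data + 1)
  em <- known_error_model(noisy$observed, sigma)
  cfg <- optimizer_config(seed = seed_opt, sweeps = sweeps)
  fit <- suppressWarnings(run_lear(noisy$observed, em, cfg))
  list(gt = gt, noisy = noisy, fit = fit)
}

test_that("correction is deterministic under a fixed seed", {
  a <- run_small_lear(50, L = 8, N = 120, sweeps = 15)
  b <- run_small_lear(50, L = 8, N = 120, sweeps = 15)
  expect_identical(a$fit$adjusted$positions, b$fit$adjusted$positions)
  expect_identical(a$fit$corrections, b$fit$corrections)
})

test_that("adding a constant offset to a locus shifts its adjusted column by the same constant", {
  base <- run_small_lear(40, L = 8, N = 120, sweeps = 15)
  shifted_obs <- base$noisy$observed
  shifted_obs$positions[, 4, 1] <- shifted_obs$positions[, 4, 1] + 500
  em <- known_error_model(shifted_obs, 40)
  fit2 <- suppressWarnings(run_lear(shifted_obs, em,
                                    optimizer_config(seed = 7, sweeps = 15)))
  expect_equal(fit2$adjusted$positions[, 4, 1],
               base$fit$adjusted$positions[, 4, 1] + 500, tolerance = 1e-9)
  expect_equal(fit2$adjusted$positions[, 2, 2],
               base$fit$adjusted$positions[, 2, 2], tolerance = 1e-9)
})

test_that("relative error after correction shrinks as the injected error grows", {
  rel <- sapply(c(25, 50, 100), function(sigma) {
    r <- run_small_lear(sigma)
    mean(relative_error_per_locus(r$fit$adjusted, r$noisy$observed, r$gt$truth))
  })
  expect_true(all(rel < 1))
  expect_true(all(diff(rel) < 0))
})

test_that("corrections oppose the injected noise at the single-spot level", {
  r <- run_small_lear(50)
  cc <- cor(as.vector(r$fit$corrections), as.vector(r$noisy$noise))
  expect_lt(cc, -0.3)
})

test_that("noise-free input with a zero error model passes through unchanged", {
  gt <- make_chain_gt(L = 6, N = 120, step = 40, seed = 29)
  em <- known_error_model(gt$truth, 0)
  fit <- run_lear(gt$truth, em, optimizer_config(seed = 1, sweeps = 10))
  expect_equal(fit$adjusted$positions, gt$truth$positions, tolerance = 1e-12)
})

test_that("loci without a usable partner are passed through with a warning", {
  gt <- make_chain_gt(L = 4, N = 120, step = 40, seed = 30)
  noisy <- add_localization_error(gt, 30, seed = 31)
  obs <- noisy$observed
  obs$positions[6:120, 2, ] <- NA  # locus 2 nearly unobserved
  em <- known_error_model(obs, 30)
  w <- capture_warnings(fit <- run_lear(obs, em,
                                        optimizer_config(seed = 1, sweeps = 5)))
  expect_true(any(grepl("no usable partner", w)))
  expect_equal(fit$adjusted$positions[, 2, ], obs$positions[, 2, ])
})
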
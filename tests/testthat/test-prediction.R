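sim_design <- function(n = 60L, p = 12L, k = 3L, snr = 10, seed = 1L) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
    beta <- c(rep(2, k), rep(0, p - k))
    mu <- drop(x %*% beta)
    y <- mu + rnorm(n, 0, sd(mu) / snr)
    list(x = x, y = y, beta = beta)
  })
}

test_that("the elastic net at vanishing penalty matches least squares", {
  d <- sim_design(n = 50, p = 8, seed = 2)
  fit <- fit_enet(d$x, d$y, alpha = 0.5, lambda = 1e-10)
  ols <- coef(lm(d$y ~ d$x))
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - ols)), 1e-4)
})

test_that("the coordinate-descent solution matches glmnet on a shared scale", {
  # glmnet internally rescales the response, which changes the effective
  # ridge weight; on a unit-variance response both solve the same objective
  d <- sim_design(n = 50, p = 8, seed = 3)
  xs <- scale(d$x)
  ys <- d$y / sqrt(mean((d$y - mean(d$y))^2))
  for (alpha in c(0.3, 0.7, 1)) {
    g <- glmnet::glmnet(xs, ys, alpha = alpha, standardize = FALSE,
                        lambda = c(0.8, 0.4, 0.2, 0.1, 0.05), thresh = 1e-14)
    ref <- as.numeric(coef(g, s = 0.1))
    fit <- fit_enet(xs, ys, alpha = alpha, lambda = 0.1)
    expect_lt(max(abs(fit$coefficients - ref[-1])), 1e-6)
  }
})

test_that("full shrinkage beyond lambda_max and support recovery both hold", {
  d <- sim_design(n = 100, p = 20, k = 3, snr = 10, seed = 4)
  lmax <- lambda_max(d$x, d$y, 0.9)
  expect_equal(fit_enet(d$x, d$y, 0.9, 10 * lmax)$df, 0L)
  # some lambda on the path (the oracle choice) recovers the support exactly
  supports <- lapply(exp(seq(log(lmax), log(0.01 * lmax), length.out = 20)),
                     function(l) {
                       unname(which(fit_enet(d$x, d$y, 0.9, l)$coefficients != 0))
                     })
  expect_true(any(vapply(supports, identical, logical(1L),
                         y = which(d$beta != 0))))
  expect_error(fit_enet(d$x, c(d$y[-1], NA), 0.5, 1),
               class = "pdmotor_validation_error")
})

test_that("the penalized objective never increases across sweeps", {
  d <- sim_design(seed = 5)
  for (alpha in c(0.2, 1)) {
    fit <- fit_enet(d$x, d$y, alpha, lambda_max(d$x, d$y, alpha) * 0.05)
    expect_true(all(diff(fit$objective) <= 1e-12))
  }
})

test_that("loocv equals brute-force per-fold refits", {
  d <- sim_design(n = 25, p = 6, seed = 6)
  cv <- loocv(d$x, d$y, alpha = 0.5, lambda = 0.2)
  brute <- vapply(seq_along(d$y), function(i) {
    f <- fit_enet(d$x[-i, ], d$y[-i], alpha = 0.5, lambda = 0.2)
    predict(f, d$x[i, , drop = FALSE])
  }, numeric(1L))
  expect_lt(max(abs(cv$predictions$predicted - brute)), 1e-8)
  # intercept-only model predicts the fold mean, exactly
  big <- 100 * lambda_max(d$x, d$y, 0.5)
  cv0 <- loocv(d$x, d$y, alpha = 0.5, lambda = big)
  means <- vapply(seq_along(d$y), function(i) mean(d$y[-i]), numeric(1L))
  expect_equal(cv0$predictions$predicted, means, tolerance = 1e-10)
  expect_equal(cv0$mae, mean(abs(d$y - means)), tolerance = 1e-10)
  # a perfect linear signal with no penalty is predicted perfectly
  y_lin <- drop(d$x %*% c(1, -2, rep(0, 4)))
  cv1 <- loocv(d$x, y_lin, alpha = 0.5, lambda = 1e-10)
  expect_gt(cv1$r2, 0.999)
  expect_lt(cv1$mae, 1e-4)
})

test_that("grid search respects the df cap and dominates the mean predictor", {
  d <- sim_design(n = 40, p = 15, seed = 7)
  gs <- enet_grid_search(d$x, d$y, alpha_grid = c(0.3, 0.6, 1),
                         n_lambda = 25L)
  expect_true(all(gs$grid$df[gs$grid$accepted] <= 20L))
  expect_lte(gs$fit$df, 20L)
  expect_gt(gs$cv$r2, 0)  # selection dominates the mean predictor
  # a grid with only an over-shrunk lambda gives the null model
  gs0 <- enet_grid_search(d$x, d$y, alpha_grid = 1, n_lambda = 1L,
                          lambda_ratio = 1)
  expect_equal(gs0$fit$df, 0L)
  expect_lte(gs0$cv$r2, 0)
})

test_that("transfer predictions freeze the day-1 model", {
  d <- sim_design(n = 30, p = 6, seed = 8)
  fit <- fit_enet(d$x, d$y, 0.5, 0.1)
  rep1 <- transfer_predict(fit, d$x, d$y)
  expect_equal(rep1$predictions$predicted, unname(predict(fit, d$x)))
  x2 <- d$x[, c(3, 1, 2, 4, 5, 6)]  # column order must not matter
  rep2 <- transfer_predict(fit, x2, d$y)
  expect_equal(rep2$mae, rep1$mae)
  bad <- d$x[, 1:3]
  expect_error(transfer_predict(fit, bad, d$y),
               class = "pdmotor_validation_error")
})

test_that("cluster indicators only help when they carry signal", {
  d <- sim_design(n = 36, p = 6, seed = 9)
  base <- enet_grid_search(d$x, d$y, alpha_grid = c(0.5, 1), n_lambda = 20L)
  # all-same label reduces to the plain model
  same <- cluster_augmented_fit(d$x, d$y, rep(1L, 36), alpha_grid = c(0.5, 1),
                                n_lambda = 20L)
  expect_equal(same$cv$r2, base$cv$r2, tolerance = 1e-9)
  # planted groups whose additive y offsets are non-monotone in X: a linear
  # model cannot represent them, but indicators (recoverable from X by the
  # leakage-free held-out assignment) can
  withr::with_seed(71, {
    groups <- rep(1:3, each = 12)
    xg <- cbind(matrix(rnorm(36 * 4), 36, 4), grp = c(-8, 0, 8)[groups] +
                  rnorm(36, 0, 0.3))
    colnames(xg) <- paste0("f", 1:5)
    yg <- drop(xg[, 1:4] %*% c(1, -1, 0.5, 0)) +
      c(6, 0, 6)[groups] + rnorm(36, 0, 0.5)
    plain <- enet_grid_search(xg, yg, alpha_grid = c(0.5, 1), n_lambda = 20L)
    aug <- cluster_augmented_fit(xg, yg, groups, alpha_grid = c(0.5, 1),
                                 n_lambda = 20L)
    expect_gt(aug$cv$r2, plain$cv$r2)
  })
  # random labels do not systematically help
  deltas <- vapply(1:10, function(s) {
    withr::with_seed(700 + s, {
      rnd <- sample(1:3, 36, replace = TRUE)
      cluster_augmented_fit(d$x, d$y, rnd, alpha_grid = 1,
                            n_lambda = 15L)$cv$r2 - base$cv$r2
    })
  }, numeric(1L))
  expect_lte(mean(deltas), 0.05)
})

test_that("day-1 models transfer to drifted day-2 sessions", {
  ratios <- vapply(1:10, function(s) {
    cc <- cached_cohort(n = 12L, seed = 40L + s, day2 = TRUE)
    m <- cc$metrics
    u <- cc$updrs
    x1 <- impute_median(metric_cols(m[m$visit_day == 1, ]))
    x2 <- impute_median(metric_cols(m[m$visit_day == 2, ]))
    gs <- enet_grid_search(x1, u$total[u$visit_day == 1],
                           alpha_grid = c(0.5, 1), n_lambda = 15L)
    day2 <- transfer_predict(gs$fit, x2, u$total[u$visit_day == 2])
    in_sample <- mean(abs(u$total[u$visit_day == 1] -
                            predict(gs$fit, x1)))
    day2$mae / max(gs$cv$mae, in_sample, 1)
  }, numeric(1L))
  expect_gte(sum(ratios <= 2), 9L)
})

test_that("enet tidiers expose coefficients and fit summaries", {
  d <- sim_design(n = 30, p = 5, seed = 10)
  fit <- fit_enet(d$x, d$y, 0.5, 0.2)
  td <- tidy(fit)
  expect_equal(nrow(td), 6L)
  expect_named(glance(fit), c("alpha", "lambda", "df", "sweeps"))
  cv <- loocv(d$x, d$y, 0.5, 0.2)
  expect_named(glance(cv), c("mae", "r2", "scheme", "n"))
  expect_equal(nrow(tidy(cv)), 30L)
})
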
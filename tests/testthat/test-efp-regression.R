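test_that("design matrix embeds 12 s of band history per BOLD point", {
  q <- quick_session(duration_s = 100, seed = 1)
  dm <- build_design_matrix(q$ds)
  expect_equal(dim(dm$X), c(353, 480))
  expect_length(dm$y, 353)
  # constant band powers give identical rows
  bands <- matrix(5, 10, 60)
  X <- cefp:::design_from_bands(bands)
  expect_true(all(X == 5))
  expect_equal(dim(X), c(13, 480))
  # one-hot at (band 1, t = 48) appears only at column (band 1, delay 0)
  bands <- matrix(0, 10, 48)
  bands[1, 48] <- 1
  X <- cefp:::design_from_bands(bands)
  expect_equal(X[1, 1], 1)
  expect_equal(sum(X), 1)
  # row counts follow n - 47 for a range of lengths
  for (n4 in c(48, 100, 241)) {
    expect_equal(nrow(cefp:::design_from_bands(matrix(0, 10, n4))), n4 - 47)
  }
  expect_error(cefp:::design_from_bands(matrix(0, 10, 40)), "short")
})

test_that("ridge matches the dense normal-equation oracle and its limits", {
  # interpolation at lambda = 0 (centering a 2x2 identity leaves rank 1,
  # hence the minimum-norm warning)
  f <- suppressWarnings(ridge_fit(diag(2), c(1, 0), 0))
  expect_equal(diag(2) %*% f$weights + f$intercept, matrix(c(1, 0)),
               tolerance = 1e-10)
  set.seed(2)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- rnorm(50)
  # infinite shrinkage: weights vanish, intercept -> mean(y)
  big <- ridge_fit(X, y, 1e12)
  expect_lt(sqrt(sum(big$weights^2)), 1e-6)
  expect_equal(big$intercept, mean(y), tolerance = 1e-6)
  # dense-solve oracle
  fit <- ridge_fit(X, y, 0.7)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w <- solve(crossprod(Xc) + 0.7 * diag(8), crossprod(Xc, yc))
  expect_equal(fit$weights, as.numeric(w), tolerance = 1e-8)
  # rank-deficient + lambda = 0 warns and returns a solution
  Xr <- cbind(X, X[, 1])
  expect_warning(fr <- ridge_fit(Xr, y, 0), "rank-deficient")
  expect_true(all(is.finite(fr$weights)))
  # penalty path: weight norm is non-increasing in lambda
  norms <- vapply(10^seq(-3, 3, length.out = 13), function(l) {
    sqrt(sum(ridge_fit(X, y, l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("nmse is mse over population variance", {
  y <- c(1, 2, 3, 4)
  expect_equal(nmse(y, y), 0)
  expect_equal(nmse(y, rep(mean(y), 4)), 1)
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(nmse(a, b), mean((a - b)^2) / mean((a - mean(a))^2))
  expect_error(nmse(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("inner CV picks small penalties for clean fits, large for noise", {
  q <- quick_session(duration_s = 150, snr = 1e12, seed = 4)
  dm <- build_design_matrix(q$ds)
  grid <- 10^seq(-2, 4, length.out = 7)
  cfg <- cv_config(n_inner_splits = 8, lambda_grid = grid, seed = 1)
  sel <- inner_cv_select(dm$X, dm$y, cfg)
  expect_equal(sel$lambda, min(grid))
  # pure-noise target: maximal shrinkage wins (tie rule toward larger lambda)
  set.seed(5)
  ynoise <- rnorm(nrow(dm$X))
  seln <- inner_cv_select(dm$X, ynoise, cfg)
  expect_equal(seln$lambda, max(grid))
  # seeded determinism
  sel2 <- inner_cv_select(dm$X, dm$y, cfg)
  expect_identical(sel$cv_table, sel2$cv_table)
  expect_equal(nrow(sel$cv_table), 8 * length(grid))
})

test_that("individual fingerprints recover planted structure", {
  q <- quick_session(duration_s = 300, snr = 10, seed = 6)
  model <- fit_individual_efp(q$ds, light_cfg())
  expect_s3_class(model, "efp_model")
  expect_equal(dim(model$coeffs), c(10, 48))
  expect_gte(cor(as.numeric(model$coeffs), as.numeric(q$truth$coeffs)), 0.8)
  # determinism on a duplicate session
  model2 <- fit_individual_efp(q$ds, light_cfg())
  expect_identical(model$coeffs, model2$coeffs)
  # a single active band captures most of the fitted energy
  sc <- uniform_scheme()
  co <- matrix(0, 10, 48)
  co[4, ] <- exp(-(0:47) / 10)
  spec <- sim_spec(1, 1, duration_s = 300, seed = 7, snr = 10)
  env <- cefp:::sim_envelopes(10, 1200, 11)
  bold <- simulate_bold(env, ground_truth(co, sc), snr = 10, seed = 8)
  ds <- session_dataset(cefp:::zscore_rows(env), as.numeric(bold), sc,
                        session_id = "oneband")
  m <- fit_individual_efp(ds, light_cfg())
  energy <- rowSums(m$coeffs^2)
  expect_gte(energy[4] / sum(energy), 0.7)
})

test_that("prediction evaluation handles self-fits, zero and flipped models", {
  q <- quick_session(duration_s = 200, snr = 1e12, seed = 9)
  dm <- build_design_matrix(q$ds)
  fit <- suppressWarnings(ridge_fit(dm$X, dm$y, 1e-8))
  model <- efp_model(matrix(fit$weights, 10, byrow = TRUE), fit$intercept,
                     q$ds$scheme, 0)
  expect_gt(evaluate_prediction(model, q$ds), 0.99)
  zero <- efp_model(matrix(0, 10, 48), 0, q$ds$scheme)
  expect_warning(r0 <- evaluate_prediction(zero, q$ds), "constant")
  expect_equal(r0, 0)
  flipped <- model
  flipped$coeffs <- -model$coeffs
  expect_equal(evaluate_prediction(flipped, q$ds),
               -evaluate_prediction(model, q$ds), tolerance = 1e-12)
})
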
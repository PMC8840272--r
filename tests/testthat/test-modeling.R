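test_that("PCA transform: standardization, rank handling, closed-form loadings", {
  # exactly collinear duplicated columns: retained count collapses to the
  # distinct-signal count at full variance target
  set.seed(1)
  base <- matrix(rnorm(40), 20, 2)
  x <- cbind(base, base)
  colnames(x) <- paste0("c", 1:4)
  p <- fit_pca(x, variance_target = 0.999)
  expect_lte(p$k, 2)

  # variance_target = 1 keeps everything: an invertible rotation of the
  # standardized data
  pfull <- fit_pca(base, variance_target = 1)
  expect_equal(pfull$k, 2)
  sc <- predict(pfull, base)
  back <- sc %*% t(pfull$rotation)
  xs <- scale(base)
  expect_equal(back, xs, ignore_attr = TRUE, tolerance = 1e-10)

  # known covariance [[2,1],[1,2]]: eigenvectors are (1,1)/sqrt2, (1,-1)/sqrt2
  set.seed(7)
  z <- matrix(rnorm(4000), 2000, 2)
  y <- z %*% chol(matrix(c(2, 1, 1, 2), 2))
  p2 <- fit_pca(y, variance_target = 1)
  v1 <- p2$rotation[, 1]
  expect_equal(abs(sum(v1 * c(1, 1) / sqrt(2))), 1, tolerance = 0.05)

  # zero-variance columns are dropped with a warning
  xz <- cbind(base, flat = 1)
  expect_warning(pz <- fit_pca(xz), "zero-variance")
  expect_false("flat" %in% pz$cols)
  expect_error(fit_pca(base[1:2, ]), "3 training rows")
})

test_that("a linear learner recovers a noiseless linear anomaly exactly", {
  tbl <- linear_anomaly_table()
  sp <- stratified_split(tbl[c("year", "anomaly")], 0.2, 5, seed = 1)
  fit <- tune_and_fit(tbl, sp, method = "linear", use_pca = FALSE)
  pred <- predict(fit, tbl, years = test_years(sp))
  actual <- tbl$anomaly[match(test_years(sp), tbl$year)]
  expect_lte(compute_metrics(pred$yield, actual)$rmse, 1e-6)
})

test_that("the leave-one-out score matches a brute-force oracle", {
  tbl <- linear_anomaly_table(noise = 0.5)
  sp <- stratified_split(tbl[c("year", "anomaly")], 0.2, 5, seed = 2)
  fit <- tune_and_fit(tbl, sp, method = "linear", use_pca = FALSE)
  tr_y <- sort(train_years(sp))
  x <- as.matrix(tbl[match(tr_y, tbl$year), c("x1", "x2", "x3")])
  y <- tbl$anomaly[match(tr_y, tbl$year)]
  errs <- vapply(seq_along(y), function(i) {
    cf <- coef(lm(y[-i] ~ x[-i, , drop = FALSE]))
    unname(cf[1] + sum(cf[-1] * x[i, ])) - y[i]
  }, numeric(1))
  expect_equal(fit$loocv_rmse, sqrt(mean(errs^2)), tolerance = 1e-8)
  expect_equal(length(tr_y), 20) # one fold per training year
})

test_that("the LOOCV score ignores training-row order and seeds reproduce fits", {
  tbl <- linear_anomaly_table(noise = 0.3)
  sp <- stratified_split(tbl[c("year", "anomaly")], 0.2, 5, seed = 4)
  shuffled <- tbl[sample(nrow(tbl)), ]
  f1 <- tune_and_fit(tbl, sp, method = "boosted_tree", seed = 9,
                     grid = tibble::tibble(nrounds = 50L,
                                           learning_rate = 0.1,
                                           max_depth = 2L))
  f2 <- tune_and_fit(shuffled, sp, method = "boosted_tree", seed = 9,
                     grid = tibble::tibble(nrounds = 50L,
                                           learning_rate = 0.1,
                                           max_depth = 2L))
  expect_equal(f1$loocv_rmse, f2$loocv_rmse)
  p1 <- predict(f1, tbl)
  p2 <- predict(f2, tbl)
  expect_equal(p1$yield, p2$yield)
})

test_that("full-rank PCA leaves least-squares predictions unchanged", {
  tbl <- linear_anomaly_table(noise = 0.2)
  sp <- stratified_split(tbl[c("year", "anomaly")], 0.2, 5, seed = 1)
  f0 <- tune_and_fit(tbl, sp, method = "linear", use_pca = FALSE)
  f1 <- tune_and_fit(tbl, sp, method = "linear", use_pca = TRUE,
                     variance_target = 1.0)
  p0 <- predict(f0, tbl)
  p1 <- predict(f1, tbl)
  expect_equal(p0$yield, p1$yield, tolerance = 1e-8)
})

test_that("every learner in the menu trains and predicts", {
  tbl <- linear_anomaly_table(noise = 0.3)
  sp <- stratified_split(tbl[c("year", "anomaly")], 0.2, 5, seed = 6)
  small_grids <- list(
    linear = NULL,
    boosted_linear = tibble::tibble(nrounds = 50L, reg_lambda = 0.1),
    svr_linear = tibble::tibble(cost = 1),
    svr_quadratic = tibble::tibble(cost = 1),
    svr_cubic = tibble::tibble(cost = 1),
    svr_gaussian = tibble::tibble(cost = 1, gamma = 1 / 3),
    tree = tibble::tibble(cp = 0.01, maxdepth = 3L),
    boosted_tree = tibble::tibble(nrounds = 50L, learning_rate = 0.1,
                                  max_depth = 2L),
    bagged_tree = tibble::tibble(ntree = 100L, nodesize = 3L))
  for (m in vh_methods()) {
    fit <- tune_and_fit(tbl, sp, method = m, use_pca = TRUE, seed = 3,
                        grid = small_grids[[m]])
    pred <- predict(fit, tbl, years = test_years(sp))
    expect_true(all(is.finite(pred$yield)), info = m)
    expect_s3_class(glance(fit), "tbl_df")
  }
})

test_that("yield predictions are trend plus modelled anomaly", {
  # a constant-anomaly response: model predicts ~0 anomaly, predictions
  # follow the training-year trend line
  yrs <- 1995:2019
  tbl <- tibble::tibble(year = yrs, yield = 4 + 0.05 * (yrs - 1995),
                        x1 = rnorm(25), x2 = rnorm(25))
  ys <- detrend_yield(tbl[c("year", "yield")])
  sp <- stratified_split(ys, 0.2, 5, seed = 8)
  fit <- tune_and_fit(tbl, sp, method = "linear", use_pca = FALSE)
  pred <- predict(fit, tbl, years = test_years(sp))
  expect_equal(pred$yield, 4 + 0.05 * (test_years(sp) - 1995),
               tolerance = 1e-6)
  expect_equal(pred$yield, pred$trend + pred$anomaly)
  expect_error(predict(fit, tbl, years = 1890), "no predictor rows")
})

test_that("hyperparameter search reports the whole grid and the winner", {
  tbl <- linear_anomaly_table(noise = 0.4)
  sp <- stratified_split(tbl[c("year", "anomaly")], 0.2, 5, seed = 5)
  grid <- tidyr::expand_grid(nrounds = c(25L, 50L), learning_rate = 0.1,
                             max_depth = c(1L, 2L))
  fit <- tune_and_fit(tbl, sp, method = "boosted_tree", grid = grid, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$selected), 1)
  expect_equal(min(td$loocv_rmse), fit$loocv_rmse)
  expect_error(tune_and_fit(tbl, sp, method = "boosted_tree",
                            grid = grid[0, ]), "empty")
})

test_that("training demands enough years", {
  tbl <- linear_anomaly_table(n = 25)
  sp <- stratified_split(tbl[c("year", "anomaly")], 0.2, 5, seed = 1)
  expect_error(tune_and_fit(tbl[1:5, ], sp, method = "linear"),
               "8 training years")
})
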
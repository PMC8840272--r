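#' Principal-component transform of a predictor table
#'
#' Standardizes the columns (zero-variance columns are dropped with a
#' warning), fits principal components on the supplied rows only, and
#' retains the smallest number of components whose cumulative explained
#' variance reaches `variance_target` (or exactly `rank` components when
#' given). Used to decorrelate the strongly collinear weekly VCI/TCI
#' predictors before a learner is trained.
#'
#' @param x numeric matrix or data frame of training predictors (>= 3 rows).
#' @param variance_target fraction of variance to retain, in (0, 1].
#' @param rank optional fixed number of retained components (overrides
#'   `variance_target`).
#' @return An object of class `vh_pca`: list with `center`, `scale`,
#'   `rotation` (full), `k`, `var_explained`, `dropped` (column names).
#' @export
fit_pca <- function(x, variance_target = 0.95, rank = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) < 3L) stop("PCA needs at least 3 training rows")
  if (variance_target <= 0 || variance_target > 1) {
    stop("`variance_target` must be in (0, 1]")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[scl == 0] %||% character(0)
  keep <- scl > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " zero-variance column(s)")
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]), 2L,
              scl[keep], "/")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (!is.null(rank)) {
    min(as.integer(rank), ncol(pc$rotation))
  } else {
    which(cumsum(ve) >= variance_target - 1e-12)[1]
  }
  structure(
    list(center = ctr[keep], scale = scl[keep], rotation = pc$rotation,
         k = as.integer(k), var_explained = ve,
         dropped = dropped, cols = colnames(x)[keep]),
    class = "vh_pca"
  )
}

#' @rdname fit_pca
#' @param object a `vh_pca`.
#' @param newdata matrix/data frame with the training columns.
#' @param ... unused.
#' @export
predict.vh_pca <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x <- x[, object$cols, drop = FALSE]
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  xs %*% object$rotation[, seq_len(object$k), drop = FALSE]
}

#' Default hyperparameter grids
#'
#' One tibble row per candidate setting; all grids are deliberately small
#' because they are evaluated by leave-one-out cross-validation on short
#' annual series. Pass your own tibble to [tune_and_fit()] to override.
#'
#' @param method a method name from [vh_methods()].
#' @param p number of predictor columns (sets the Gaussian-kernel width
#'   scale).
#' @return A tibble of hyperparameter combinations.
#' @export
default_grid <- function(method, p = 104L) {
  switch(method,
    linear = tibble::tibble(.setting = 1L),
    boosted_linear = tidyr::expand_grid(nrounds = c(50L, 100L, 200L),
                                        reg_lambda = c(0, 0.1, 1)),
    svr_linear = ,
    svr_quadratic = ,
    svr_cubic = tidyr::expand_grid(cost = c(0.1, 1, 10)),
    svr_gaussian = tidyr::expand_grid(cost = 10^(-1:2),
                                      gamma = 2^(-2:2) / p),
    tree = tidyr::expand_grid(cp = c(0.001, 0.01, 0.1),
                              maxdepth = c(2L, 3L, 5L)),
    boosted_tree = tidyr::expand_grid(nrounds = c(50L, 100L, 200L),
                                      learning_rate = c(0.05, 0.1),
                                      max_depth = c(1L, 2L, 3L)),
    bagged_tree = tidyr::expand_grid(ntree = c(100L, 300L),
                                     nodesize = c(1L, 3L)),
    stop("unknown method: ", method)
  )
}

#' Supported learner names
#'
#' Linear regression (plain and boosted), support vector regression with
#' linear/quadratic/cubic/Gaussian kernels, and single, boosted and bagged
#' regression trees.
#'
#' @return Character vector of method names.
#' @export
vh_methods <- function() {
  c("linear", "boosted_linear", "svr_linear", "svr_quadratic", "svr_cubic",
    "svr_gaussian", "tree", "boosted_tree", "bagged_tree")
}

# Fit one learner on an (x, y) training set with one grid row of
# hyperparameters; returns an object predict_learner() understands.
fit_learner <- function(method, x, y, params, seed) {
  x <- as.matrix(x)
  withr::with_seed(as.integer(seed), {
    model <- switch(method,
      linear = {
        fit <- stats::lm.fit(cbind(1, x), y)
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        list(coef = cf)
      },
      boosted_linear = xgboost::xgboost(
        x = x, y = y, nrounds = params$nrounds, booster = "gblinear",
        reg_lambda = params$reg_lambda, nthreads = 1L, verbosity = 0L),
      svr_linear = e1071::svm(x, y, type = "eps-regression",
                              kernel = "linear", cost = params$cost),
      svr_quadratic = e1071::svm(x, y, type = "eps-regression",
                                 kernel = "polynomial", degree = 2,
                                 coef0 = 1, cost = params$cost),
      svr_cubic = e1071::svm(x, y, type = "eps-regression",
                             kernel = "polynomial", degree = 3,
                             coef0 = 1, cost = params$cost),
      svr_gaussian = e1071::svm(x, y, type = "eps-regression",
                                kernel = "radial", cost = params$cost,
                                gamma = params$gamma),
      tree = {
        df <- data.frame(y = y, x)
        rpart::rpart(y ~ ., data = df, method = "anova",
                     control = rpart::rpart.control(
                       minsplit = 2L, minbucket = 1L, xval = 0L,
                       cp = params$cp, maxdepth = params$maxdepth))
      },
      boosted_tree = xgboost::xgboost(
        x = x, y = y, nrounds = params$nrounds,
        learning_rate = params$learning_rate, max_depth = params$max_depth,
        nthreads = 1L, verbosity = 0L),
      bagged_tree = randomForest::randomForest(
        x = x, y = y, ntree = params$ntree, mtry = ncol(x),
        nodesize = params$nodesize),
      stop("unknown method: ", method)
    )
    list(method = method, model = model, xnames = colnames(x))
  })
}

predict_learner <- function(learner, x) {
  x <- as.matrix(x)
  m <- learner$model
  switch(learner$method,
    linear = as.numeric(cbind(1, x) %*% m$coef),
    tree = as.numeric(stats::predict(m, newdata = as.data.frame(x))),
    boosted_linear = ,
    boosted_tree = as.numeric(stats::predict(m, x)),
    as.numeric(stats::predict(m, x))
  )
}

# Predictor columns of a modelling table: every numeric column that is not
# bookkeeping.
predictor_cols <- function(table, predictors = NULL) {
  if (!is.null(predictors)) return(predictors)
  drop <- c("year", "yield", "trend", "anomaly", "stratum", "set",
            "season", "subregion", "region")
  nm <- setdiff(names(table), drop)
  nm[vapply(table[nm], is.numeric, logical(1))]
}

#' Tune and fit a yield-anomaly model
#'
#' Trains one learner for a (subregion, season) table. The response is the
#' weather-driven yield anomaly: when the table carries a `yield` column,
#' a trend (default OLS line) is fitted on the *training years only* and
#' the model learns `yield - trend`; a table with an `anomaly` column and
#' no `yield` is modelled directly (zero trend). Hyperparameters are chosen
#' by leave-one-out cross-validation over `grid` on the training years;
#' when `use_pca` is set, the principal-component transform is refit inside
#' every fold (and on the full training set for the final model) so no test
#' or validation information leaks into the rotation.
#'
#' @param table a modelling table: `year`, predictors (by default all other
#'   numeric columns, typically `vci_w*`/`tci_w*`), and `yield` and/or
#'   `anomaly`.
#' @param split a [stratified_split()] result; only its training years are
#'   used here.
#' @param method one of [vh_methods()].
#' @param use_pca apply [fit_pca()] predictor reduction?
#' @param grid hyperparameter tibble (default [default_grid()]).
#' @param seed integer seed controlling all stochastic fits.
#' @param variance_target retained-variance target for the PCA step.
#' @param pca_rank optional fixed PCA rank (overrides `variance_target`).
#' @param trend_method trend for the yield decomposition
#'   (see [detrend_yield()]).
#' @param predictors optional character vector naming predictor columns.
#' @return An object of class `vh_fit`.
#' @export
tune_and_fit <- function(table, split, method = "boosted_tree",
                         use_pca = TRUE, grid = NULL, seed = 1L,
                         variance_target = 0.95, pca_rank = NULL,
                         trend_method = "ols_linear", predictors = NULL) {
  method <- match.arg(method, vh_methods())
  table <- tibble::as_tibble(table)
  pcols <- predictor_cols(table, predictors)
  if (length(pcols) == 0L) stop("no predictor columns found")
  tr_years <- sort(intersect(train_years(split), table$year))
  if (length(tr_years) < 8L) stop("need at least 8 training years")
  tr <- table[match(tr_years, table$year), , drop = FALSE]

  trend_fit <- NULL
  if ("yield" %in% names(table)) {
    ys <- detrend_yield(tr[, c("year", "yield")], method = trend_method)
    trend_fit <- attr(ys, "trend_fit")
    y <- ys$anomaly
  } else if ("anomaly" %in% names(table)) {
    y <- tr$anomaly
  } else {
    stop("table needs a `yield` or `anomaly` column")
  }
  x <- as.matrix(tr[, pcols, drop = FALSE])
  grid <- grid %||% default_grid(method, p = ncol(x))
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")

  n <- nrow(x)
  loocv <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    errs <- vapply(seq_len(n), function(i) {
      xi <- x[-i, , drop = FALSE]
      yi <- y[-i]
      xo <- x[i, , drop = FALSE]
      if (use_pca) {
        pca <- suppressWarnings(
          fit_pca(xi, variance_target = variance_target, rank = pca_rank))
        xi <- stats::predict(pca, xi)
        xo <- stats::predict(pca, xo)
      }
      fit <- tryCatch(
        fit_learner(method, xi, yi, params, seed = seed + tr_years[i] %% 1000L),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      predict_learner(fit, xo) - y[i]
    }, numeric(1))
    if (all(is.na(errs))) return(Inf) # grid point failed on every fold
    sqrt(mean(errs^2, na.rm = TRUE))
  }, numeric(1))

  if (all(!is.finite(loocv))) stop("no hyperparameter setting could be fit")
  best <- which.min(loocv)
  best_params <- as.list(grid[best, , drop = FALSE])

  pca <- NULL
  xf <- x
  if (use_pca) {
    pca <- suppressWarnings(
      fit_pca(x, variance_target = variance_target, rank = pca_rank))
    xf <- stats::predict(pca, x)
  }
  learner <- fit_learner(method, xf, y, best_params, seed = seed + 777L)

  structure(
    list(method = method, use_pca = use_pca, params = best_params,
         grid_results = dplyr::bind_cols(grid, tibble::tibble(loocv_rmse = loocv)),
         loocv_rmse = loocv[best], learner = learner, pca = pca,
         trend_fit = trend_fit, predictors = pcols,
         train_years = tr_years, seed = seed,
         season = attr(table, "season"), subregion = attr(table, "subregion")),
    class = "vh_fit"
  )
}

#' @export
print.vh_fit <- function(x, ...) {
  cat(sprintf("<vh_fit> %s (%s), %d training years, LOOCV RMSE %.4g\n",
              x$method, if (x$use_pca) "PCA-ML" else "ML-only",
              length(x$train_years), x$loocv_rmse))
  invisible(x)
}

#' Predict yields from a fitted model
#'
#' Reassembles the yield as trend plus predicted anomaly:
#' `Yhat_i = T(year_i) + model(predictors_i)`, where the trend is the one
#' fitted on the training years (extrapolated for test years). A fit
#' trained directly on anomalies has zero trend, so `yield` equals the
#' predicted anomaly.
#'
#' @param object a `vh_fit`.
#' @param newdata a table carrying `year` and the fit's predictor columns.
#' @param years which years to predict (default: all rows of `newdata`).
#' @param ... unused.
#' @return A tibble (`year`, `anomaly`, `trend`, `yield`).
#' @export
predict.vh_fit <- function(object, newdata, years = NULL, ...) {
  newdata <- tibble::as_tibble(newdata)
  years <- years %||% newdata$year
  idx <- match(years, newdata$year)
  if (anyNA(idx)) {
    stop("no predictor rows for year(s): ",
         paste(years[is.na(idx)], collapse = ", "))
  }
  x <- as.matrix(newdata[idx, object$predictors, drop = FALSE])
  if (!is.null(object$pca)) x <- stats::predict(object$pca, x)
  anom <- predict_learner(object$learner, x)
  trend <- eval_trend(object$trend_fit, years)
  tibble::tibble(year = years, anomaly = anom, trend = trend,
                 yield = trend + anom)
}

#' @rdname tune_and_fit
#' @param x a `vh_fit`.
#' @param ... unused.
#' @method tidy vh_fit
#' @export
tidy.vh_fit <- function(x, ...) {
  grid <- x$grid_results
  grid$selected <- seq_len(nrow(grid)) ==
    which.min(replace(grid$loocv_rmse, !is.finite(grid$loocv_rmse), Inf))
  tibble::as_tibble(grid)
}

#' @rdname tune_and_fit
#' @method glance vh_fit
#' @export
glance.vh_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    use_pca = x$use_pca,
    n_train = length(x$train_years),
    loocv_rmse = x$loocv_rmse,
    pca_rank = if (is.null(x$pca)) NA_integer_ else x$pca$k,
    subregion = x$subregion %||% NA,
    season = x$season %||% NA_character_
  )
}
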
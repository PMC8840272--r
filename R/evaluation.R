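#' Prediction error metrics
#'
#' Root-mean-square error and mean absolute error of predictions against
#' actuals. The RMSE emphasises large errors (they are squared before
#' averaging) and is never smaller than the MAE.
#'
#' @param pred,actual equal-length numeric vectors (length >= 1).
#' @return A one-row tibble (`n`, `rmse`, `mae`).
#' @export
compute_metrics <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) == 0L) {
    stop("`pred` and `actual` must be non-empty and of equal length")
  }
  e <- pred - actual
  tibble::tibble(n = length(e),
                 rmse = sqrt(mean(e^2)),
                 mae = mean(abs(e)))
}

#' Error as a percentage of the mean yield
#'
#' @param value an RMSE or MAE (same units as the yields).
#' @param actual the actual yields whose mean scales the indicator.
#' @return `value / mean(actual) * 100`.
#' @export
percent_of_mean <- function(value, actual) {
  m <- mean(actual)
  if (!is.finite(m) || m <= 0) stop("mean of `actual` must be positive")
  value / m * 100
}

#' Relative improvement of a candidate over a baseline error
#'
#' `(baseline - candidate) / baseline * 100`: positive when the candidate
#' model has the smaller error. This is the percentage used both for
#' PCA-ML vs ML-only and for subregional vs one-fits-all comparisons.
#'
#' @param candidate,baseline error values (baseline > 0).
#' @return Percentage improvement (vectorized).
#' @export
improvement_pct <- function(candidate, baseline) {
  if (any(baseline <= 0)) stop("`baseline` must be positive")
  (baseline - candidate) / baseline * 100
}

#' Test-set evaluation of a fitted model
#'
#' Predicts the test years of `split` from `table` and scores them against
#' the actual yields (or anomalies, for a fit trained without a trend).
#'
#' @param fit a [tune_and_fit()] result.
#' @param table the modelling table the fit was trained from (must cover
#'   the test years).
#' @param split the [stratified_split()] used for training.
#' @return A one-row tibble: `n_test`, `rmse`, `mae`, `rmse_pct`,
#'   `mae_pct` (percent of mean actual on the test years).
#' @export
evaluate_fit <- function(fit, table, split) {
  yrs <- sort(intersect(test_years(split), table$year))
  if (length(yrs) == 0L) stop("no test years available in `table`")
  pred <- stats::predict(fit, table, years = yrs)
  actual <- if (is.null(fit$trend_fit) && !"yield" %in% names(table)) {
    table$anomaly[match(yrs, table$year)]
  } else {
    table$yield[match(yrs, table$year)]
  }
  m <- compute_metrics(pred$yield, actual)
  pct_ok <- mean(actual) > 0
  tibble::tibble(
    n_test = m$n, rmse = m$rmse, mae = m$mae,
    rmse_pct = if (pct_ok) percent_of_mean(m$rmse, actual) else NA_real_,
    mae_pct = if (pct_ok) percent_of_mean(m$mae, actual) else NA_real_)
}

#' Compare PCA-ML against ML-only on one table
#'
#' Trains the same learner twice (with and without the principal-component
#' predictor reduction) under identical splits and seeds, scores both on
#' the test years, and reports the PCA-ML improvement percentage.
#'
#' @inheritParams tune_and_fit
#' @param ... further arguments passed to [tune_and_fit()].
#' @return A one-row tibble with `rmse_pca_ml`, `rmse_ml_only`, the MAE
#'   analogues, and `improvement_rmse_pct` / `improvement_mae_pct`
#'   (positive = PCA-ML better).
#' @export
compare_pca_ml <- function(table, split, method = "boosted_tree", seed = 1L,
                           ...) {
  f1 <- tune_and_fit(table, split, method = method, use_pca = TRUE,
                     seed = seed, ...)
  f0 <- tune_and_fit(table, split, method = method, use_pca = FALSE,
                     seed = seed, ...)
  e1 <- evaluate_fit(f1, table, split)
  e0 <- evaluate_fit(f0, table, split)
  tibble::tibble(
    n_test = e1$n_test,
    rmse_pca_ml = e1$rmse, rmse_ml_only = e0$rmse,
    mae_pca_ml = e1$mae, mae_ml_only = e0$mae,
    improvement_rmse_pct = improvement_pct(e1$rmse, e0$rmse),
    improvement_mae_pct = improvement_pct(e1$mae, e0$mae))
}

#' Subregional models versus a one-fits-all model
#'
#' For every (subregion, season) pair, trains the subregional model on the
#' subregion's own averaged predictors and yields, trains a single
#' whole-region ("one-fits-all") model per season on the region-wide
#' averages, applies both to the subregion's test years (the one-fits-all
#' model sees the subregion's predictor rows but keeps its region-wide
#' trend), and reports both errors plus the subregional improvement
#' percentage. A season absent from the region tables is skipped with a
#' message; a subregion simply contributes rows only for the seasons it
#' grows.
#'
#' @param subregion_tables tibble with columns `subregion`, `season`,
#'   `table` (list of modelling tables with `year`, predictors, `yield`)
#'   and `split` (list of [stratified_split()] results).
#' @param region_tables tibble with columns `season`, `table`, `split` for
#'   the whole-region averages.
#' @param method,use_pca,seed,... forwarded to [tune_and_fit()].
#' @return A tibble of class `vh_eval`: one row per (subregion, season)
#'   with `rmse_sub`, `mae_sub`, `rmse_ofa`, `mae_ofa`, `rmse_pct_sub`,
#'   `improvement_rmse_pct`, `improvement_mae_pct`. Attribute `summary`
#'   holds the across-case average improvements.
#' @export
one_fits_all_comparison <- function(subregion_tables, region_tables,
                                    method = "boosted_tree", use_pca = TRUE,
                                    seed = 1L, ...) {
  region_fits <- list()
  for (i in seq_len(nrow(region_tables))) {
    s <- region_tables$season[i]
    region_fits[[s]] <- tune_and_fit(region_tables$table[[i]],
                                     region_tables$split[[i]],
                                     method = method, use_pca = use_pca,
                                     seed = seed, ...)
  }

  rows <- purrr::map_dfr(seq_len(nrow(subregion_tables)), function(i) {
    sub <- subregion_tables$subregion[i]
    ssn <- subregion_tables$season[i]
    tbl <- subregion_tables$table[[i]]
    spl <- subregion_tables$split[[i]]
    if (!ssn %in% names(region_fits)) {
      message("season '", ssn, "' has no one-fits-all model; skipping ",
              sub)
      return(NULL)
    }
    fit_sub <- tune_and_fit(tbl, spl, method = method, use_pca = use_pca,
                            seed = seed, ...)
    yrs <- sort(intersect(test_years(spl), tbl$year))
    actual <- tbl$yield[match(yrs, tbl$year)]
    pred_sub <- stats::predict(fit_sub, tbl, years = yrs)$yield
    pred_ofa <- stats::predict(region_fits[[ssn]], tbl, years = yrs)$yield
    ms <- compute_metrics(pred_sub, actual)
    mo <- compute_metrics(pred_ofa, actual)
    tibble::tibble(
      subregion = sub, season = ssn, n_test = length(yrs),
      rmse_sub = ms$rmse, mae_sub = ms$mae,
      rmse_ofa = mo$rmse, mae_ofa = mo$mae,
      rmse_pct_sub = percent_of_mean(ms$rmse, actual),
      improvement_rmse_pct = improvement_pct(ms$rmse, mo$rmse),
      improvement_mae_pct = improvement_pct(ms$mae, mo$mae))
  })
  summary <- tibble::tibble(
    mean_improvement_rmse_pct = mean(rows$improvement_rmse_pct),
    max_improvement_rmse_pct = max(rows$improvement_rmse_pct),
    mean_improvement_mae_pct = mean(rows$improvement_mae_pct),
    mean_rmse_pct_sub = mean(rows$rmse_pct_sub))
  structure(rows, class = c("vh_eval", class(rows)), summary = summary)
}

#' Write an evaluation report
#'
#' @param report a `vh_eval` (or any data frame).
#' @param csv_path,json_path output paths (either may be `NULL`). JSON
#'   output requires the `jsonlite` package.
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("JSON output requires the `jsonlite` package")
    }
    jsonlite::write_json(as.data.frame(report), json_path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
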
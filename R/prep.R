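#' Fill missing weeks with long-term weekly means
#'
#' Each missing (year, week) value in a weekly series is replaced by the
#' mean of that calendar week over the years where it is observed. Rows
#' absent from the input (e.g. a record that starts mid-year) are treated
#' as missing for every year within the series' year range.
#'
#' @param series data frame with columns `year`, `week` (1--52) and `value`.
#' @return A tibble (`year`, `week`, `value`, `filled`) covering every week
#'   1--52 of every year present, with `filled = TRUE` where the long-term
#'   weekly mean was substituted. Errors if some week is missing in all
#'   years.
#' @export
fill_missing_weeks <- function(series) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("year", "week", "value") %in% names(series)))
  full <- tidyr::expand_grid(year = sort(unique(series$year)),
                             week = 1:52)
  out <- dplyr::left_join(full, series[c("year", "week", "value")],
                          by = c("year", "week"))
  wk_mean <- dplyr::summarise(
    dplyr::group_by(out, .data$week),
    wmean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (any(!is.finite(wk_mean$wmean))) {
    bad <- wk_mean$week[!is.finite(wk_mean$wmean)]
    stop("week(s) missing in every year: ", paste(bad, collapse = ", "))
  }
  out <- dplyr::left_join(out, wk_mean, by = "week")
  out$filled <- is.na(out$value)
  out$value <- ifelse(out$filled, out$wmean, out$value)
  dplyr::arrange(dplyr::select(out, -"wmean"), .data$year, .data$week)
}

#' Spatially averaged weekly series per subregion
#'
#' Unweighted mean over the valid cells of each subregion at each week. An
#' optional cosine-latitude weighting is available for grids whose `row`
#' coordinate maps to latitude.
#'
#' @param stack a [vh_stack].
#' @param regions a `vh_subregions` (or any data frame with columns `cell`
#'   and `subregion`) covering the stack's cells.
#' @param weights `"equal"` (default) or `"cos_lat"`; the latter needs a
#'   `lat` column in `regions`.
#' @return A tibble (`subregion`, `year`, `week`, `value`); weeks where a
#'   subregion has no valid cell give `NA` (fill with
#'   [fill_missing_weeks()]).
#' @export
spatial_average <- function(stack, regions, weights = c("equal", "cos_lat")) {
  weights <- match.arg(weights)
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("cell", "subregion") %in% names(regions)))
  idx <- match(regions$cell, stack$cells$cell)
  if (anyNA(idx)) stop("`regions` refers to cells absent from the stack")

  w <- rep(1, nrow(regions))
  if (weights == "cos_lat") {
    if (!"lat" %in% names(regions)) stop("cos_lat weighting needs a `lat` column")
    w <- cos(regions$lat * pi / 180)
  }

  subs <- sort(unique(regions$subregion))
  out <- purrr::map_dfr(subs, function(s) {
    cols <- idx[regions$subregion == s]
    if (length(cols) == 0L) stop("subregion ", s, " has no cells")
    v <- stack$values[, cols, drop = FALSE]
    m <- stack$mask[, cols, drop = FALSE]
    ww <- matrix(rep(w[regions$subregion == s], each = n_times(stack)),
                 nrow = n_times(stack))
    ww[!m] <- 0
    num <- rowSums(v * ww, na.rm = TRUE)
    den <- rowSums(ww)
    tibble::tibble(subregion = s,
                   year = stack$times$year,
                   week = stack$times$week,
                   value = ifelse(den > 0, num / den, NA_real_))
  })
  out
}

#' Re-index weekly series to crop years
#'
#' A crop year for a season with harvest-end week `w` spans week `w + 1` of
#' the preceding calendar year through week `w` of the harvest year: the
#' window starts the first week after the previous harvest and ends at the
#' last week of the current harvest. Each crop year therefore carries
#' exactly 52 weekly VCI and 52 weekly TCI values, ordered from the first
#' week after the previous harvest (`*_w01`) to the harvest-end week
#' (`*_w52`).
#'
#' @param vci,tci weekly series for one subregion: data frames with columns
#'   `year`, `week`, `value` covering every needed week (gap-fill first).
#' @param harvest_end_week last week (1--52) of the harvest season.
#' @param crop_years optional integer vector of harvest years to build;
#'   defaults to every year for which the full 52-week window is covered.
#' @param season,subregion optional metadata recorded as attributes.
#' @return A tibble with columns `year`, `vci_w01`..`vci_w52`,
#'   `tci_w01`..`tci_w52` (class `season_table`).
#' @export
to_crop_years <- function(vci, tci, harvest_end_week, crop_years = NULL,
                          season = NA_character_, subregion = NA) {
  w <- as.integer(harvest_end_week)
  if (is.na(w) || w < 1L || w > 52L) stop("`harvest_end_week` must be in 1..52")

  grab <- function(series, yr) {
    # weeks w+1 .. 52 of yr-1, then 1 .. w of yr (w = 52: calendar year yr)
    if (w == 52L) {
      want_year <- rep(yr, 52L)
      want_week <- 1:52
    } else {
      want_year <- c(rep(yr - 1L, 52L - w), rep(yr, w))
      want_week <- c((w + 1L):52L, 1:w)
    }
    m <- match(paste(want_year, want_week), paste(series$year, series$week))
    if (anyNA(m)) return(NULL)
    series$value[m]
  }

  vci <- tibble::as_tibble(vci)
  tci <- tibble::as_tibble(tci)
  yrs <- crop_years %||% sort(unique(c(vci$year, tci$year)))
  rows <- purrr::map(yrs, function(yr) {
    v <- grab(vci, yr)
    t <- grab(tci, yr)
    if (is.null(v) || is.null(t)) return(NULL)
    c(v, t)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!is.null(crop_years) && !all(keep)) {
    stop("weekly data incomplete for crop year(s): ",
         paste(yrs[!keep], collapse = ", "),
         " (the window needs the preceding year's weeks)")
  }
  if (!any(keep)) stop("no crop year has complete 52-week coverage")
  mat <- do.call(rbind, rows[keep])
  colnames(mat) <- c(sprintf("vci_w%02d", 1:52), sprintf("tci_w%02d", 1:52))
  out <- dplyr::bind_cols(tibble::tibble(year = yrs[keep]),
                          tibble::as_tibble(mat))
  structure(out, class = c("season_table", class(out)),
            season = season, subregion = subregion,
            harvest_end_week = w)
}

#' Read a crop-calendar configuration
#'
#' YAML layout: top-level keys are regions, each mapping season names to
#' harvest-end weeks, e.g. `north: {winter_spring: 22, fall_winter: 48}`.
#'
#' @param path YAML file.
#' @return A tibble (`region`, `season`, `harvest_end_week`); errors on
#'   invalid weeks or duplicate harvest-end weeks within a region.
#' @export
read_crop_calendar <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(names(raw), function(rg) {
    tibble::tibble(region = rg,
                   season = names(raw[[rg]]),
                   harvest_end_week = as.integer(unlist(raw[[rg]])))
  })
  if (any(out$harvest_end_week < 1 | out$harvest_end_week > 52)) {
    stop("harvest-end weeks must lie in 1..52")
  }
  dup <- dplyr::summarise(dplyr::group_by(out, .data$region),
                          dup = anyDuplicated(.data$harvest_end_week) > 0,
                          .groups = "drop")
  if (any(dup$dup)) stop("seasons within a region must have distinct harvest-end weeks")
  out
}

#' Decompose annual yields into trend and anomaly
#'
#' The annual yield is split as `Y_i = T_i + dY_i`: a long-term trend
#' (environment and technology) plus a short-term weather-driven deviation.
#' The trend is an OLS straight line by default (`"ols_linear"`); `"loess"`
#' is available for slowly bending trends. Additivity is exact:
#' `trend + anomaly` reproduces the input bit for bit.
#'
#' @param data data frame with columns `year` and `yield` (tons/hectare),
#'   at least 5 years, all finite.
#' @param method `"ols_linear"` or `"loess"`.
#' @param span loess span (only used for `method = "loess"`).
#' @return A tibble of class `yield_series` (`year`, `yield`, `trend`,
#'   `anomaly`) with attribute `trend_fit` = list(method, coefficients or
#'   loess object).
#' @export
detrend_yield <- function(data, method = c("ols_linear", "loess"),
                          span = 0.75) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("year", "yield") %in% names(data)))
  data <- dplyr::arrange(data, .data$year)
  if (nrow(data) < 5L) stop("detrending needs at least 5 years")
  if (!all(is.finite(data$yield))) stop("yields must be finite")

  if (method == "ols_linear") {
    fit <- stats::lm(yield ~ year, data = data)
    trend <- as.numeric(stats::fitted(fit))
    handle <- list(method = method, coef = stats::coef(fit))
  } else {
    fit <- stats::loess(yield ~ year, data = data, span = span,
                        control = stats::loess.control(surface = "direct"))
    trend <- as.numeric(stats::fitted(fit))
    handle <- list(method = method, fit = fit)
  }
  out <- tibble::tibble(year = data$year, yield = data$yield,
                        trend = trend, anomaly = data$yield - trend)
  structure(out, class = c("yield_series", class(out)), trend_fit = handle)
}

# Evaluate a detrend_yield trend handle at new years.
eval_trend <- function(handle, years) {
  if (is.null(handle)) return(rep(0, length(years)))
  if (handle$method == "ols_linear") {
    as.numeric(handle$coef[1] + handle$coef[2] * years)
  } else {
    as.numeric(stats::predict(handle$fit, newdata = data.frame(year = years)))
  }
}

#' Stratified train/test split on yield anomalies
#'
#' Sorts the anomalies, cuts them into `n_strata` quantile bins, and draws
#' test years proportionally from every bin so both tails of the anomaly
#' distribution appear in training and test sets. The global test count is
#' `floor(test_fraction * n)` (a 25-year series at 20% gives 20 train / 5
#' test; a 23-year series gives 19/4); per-stratum counts follow
#' largest-remainder apportionment so the global count is hit exactly.
#'
#' @param responses a [detrend_yield()] result (or any data frame with
#'   `year` and `anomaly`).
#' @param test_fraction fraction of years held out, in (0,1).
#' @param n_strata number of quantile strata (1 = simple random split).
#' @param seed integer seed for the within-stratum draws.
#' @return A tibble of class `split_spec` (`year`, `anomaly`, `stratum`,
#'   `set` in {"train","test"}); attributes record the settings.
#' @export
stratified_split <- function(responses, test_fraction = 0.2, n_strata = 5L,
                             seed = 1L) {
  df <- tibble::as_tibble(responses)[, c("year", "anomaly")]
  n <- nrow(df)
  n_strata <- as.integer(n_strata)
  if (test_fraction <= 0 || test_fraction >= 1) stop("`test_fraction` must be in (0,1)")
  if (n_strata < 1L || n_strata > n) stop("need n years >= n_strata >= 1")

  df <- dplyr::arrange(df, .data$anomaly)
  df$stratum <- dplyr::ntile(seq_len(n), n_strata) # quantile bins on anomaly

  n_test <- floor(test_fraction * n)
  if (n_test < 1L || n_test >= n) {
    stop("test set would be empty or equal to the full set")
  }
  sizes <- as.integer(table(df$stratum))
  quota <- test_fraction * sizes
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    extra <- order(quota - take, sizes, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  } else if (rem < 0) {
    drop <- order(quota - take, -sizes)[seq_len(-rem)]
    take[drop] <- pmax(take[drop] - 1L, 0L)
  }

  df$set <- "train"
  withr::with_seed(as.integer(seed), {
    for (s in seq_len(n_strata)) {
      rows <- which(df$stratum == s)
      if (take[s] > 0L) {
        picked <- rows[sample.int(length(rows), take[s])]
        df$set[picked] <- "test"
      }
    }
  })
  df <- dplyr::arrange(df, .data$year)
  structure(df, class = c("split_spec", class(df)),
            test_fraction = test_fraction, n_strata = n_strata, seed = seed)
}

#' @rdname stratified_split
#' @param split a `split_spec`.
#' @export
train_years <- function(split) split$year[split$set == "train"]

#' @rdname stratified_split
#' @export
test_years <- function(split) split$year[split$set == "test"]
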
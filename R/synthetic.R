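#' Planted connected partition of a grid
#'
#' Seeded region growing: K centroid cells are drawn at random and regions
#' grow by claiming random unassigned 4-neighbours in random region order
#' until the grid is covered. Every region is connected; the result is
#' deterministic per seed.
#'
#' @param grid_rows,grid_cols grid dimensions.
#' @param K number of regions (`K <= grid_rows * grid_cols`).
#' @param seed integer seed.
#' @return A tibble (`cell`, `row`, `col`, `region`).
#' @export
make_partition <- function(grid_rows, grid_cols, K, seed = 1L) {
  n <- grid_rows * grid_cols
  K <- as.integer(K)
  if (K < 1L || K > n) stop("`K` must lie in 1..cells")
  nbrs <- function(i) {
    r <- (i - 1L) %/% grid_cols + 1L
    c <- (i - 1L) %% grid_cols + 1L
    c(if (r > 1L) i - grid_cols, if (r < grid_rows) i + grid_cols,
      if (c > 1L) i - 1L, if (c < grid_cols) i + 1L)
  }
  region <- integer(n)
  withr::with_seed(as.integer(seed), {
    region[sample.int(n, K)] <- seq_len(K)
    while (any(region == 0L)) {
      grew <- FALSE
      for (k in sample.int(K)) {
        cand <- unique(unlist(lapply(which(region == k), nbrs)))
        cand <- cand[region[cand] == 0L]
        if (length(cand)) {
          region[cand[sample.int(length(cand), 1L)]] <- k
          grew <- TRUE
        }
      }
      if (!grew) break
    }
  })
  tibble::tibble(cell = seq_len(n),
                 row = (seq_len(n) - 1L) %/% grid_cols + 1L,
                 col = (seq_len(n) - 1L) %% grid_cols + 1L,
                 region = region)
}

# K weekly temporal signals (n_years * 52 long): per region 2-3 random-phase
# seasonal harmonics (1-4 cycles per year) plus a year-level random offset.
# Regions are drawn greedily; each candidate is redrawn until its
# |correlation| with every accepted signal is <= max_cor, so the planted
# temporal courses are mutually near-uncorrelated.
gen_region_signals <- function(K, n_years, seed, max_cor = 0.2,
                               annual_sd = 0.6) {
  weeks <- rep(1:52, n_years)
  yr_idx <- rep(seq_len(n_years), each = 52L)
  draw_one <- function() {
    nh <- sample(2:3, 1L)
    freqs <- sample(1:4, nh) # cycles per year
    amps <- stats::runif(nh, 0.5, 1.5)
    phases <- stats::runif(nh, 0, 2 * pi)
    seasonal <- rowSums(vapply(seq_len(nh), function(h) {
      amps[h] * cos(2 * pi * freqs[h] * weeks / 52 + phases[h])
    }, numeric(length(weeks))))
    seasonal + stats::rnorm(n_years, 0, annual_sd)[yr_idx]
  }
  withr::with_seed(as.integer(seed), {
    sig <- matrix(NA_real_, length(weeks), K)
    sig[, 1] <- draw_one()
    for (k in seq_len(K)[-1]) {
      ok <- FALSE
      for (attempt in 1:500) {
        cand <- draw_one()
        if (max(abs(stats::cor(cand, sig[, seq_len(k - 1), drop = FALSE]))) <= max_cor) {
          sig[, k] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not draw K mutually near-uncorrelated temporal signals")
    }
    sig
  })
}

#' Ground truth for a synthetic gridded experiment
#'
#' Fixes everything the generators need: a planted connected partition,
#' per-region temporal signals for a VCI-like and a TCI-like variable,
#' the signal-to-noise ratio (region-signal variance over cell-noise
#' variance), the crop calendar and the yield-process parameters. A truth
#' object plus its seed replays every generated dataset bit-identically.
#'
#' @param grid_rows,grid_cols grid size (default 20 x 20).
#' @param K number of planted regions.
#' @param n_years years of weekly record (52 weeks per year).
#' @param snr signal-to-noise ratio of the stacks.
#' @param start_year first calendar year of the record.
#' @param harvest_end_week harvest-end week of the (single) synthetic
#'   season.
#' @param anomaly_sd standard deviation of the planted weather-driven yield
#'   anomaly (tons/hectare).
#' @param sigma_eps standard deviation of the yield measurement noise.
#' @param seed master seed.
#' @return An object of class `vh_truth`.
#' @export
synthetic_truth <- function(grid_rows = 20L, grid_cols = 20L, K = 3L,
                            n_years = 25L, snr = 5, start_year = 1994L,
                            harvest_end_week = 20L, anomaly_sd = 0.25,
                            sigma_eps = 0.05, seed = 1L) {
  seed <- as.integer(seed)
  partition <- make_partition(grid_rows, grid_cols, K, seed = seed)
  signals <- list(
    vci = gen_region_signals(K, n_years, seed = seed + 11L),
    tci = gen_region_signals(K, n_years, seed = seed + 23L)
  )
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         K = as.integer(K), n_years = as.integer(n_years), snr = snr,
         start_year = as.integer(start_year),
         harvest_end_week = as.integer(harvest_end_week),
         anomaly_sd = anomaly_sd, sigma_eps = sigma_eps,
         seed = seed, partition = partition, signals = signals,
         trend_intercept = 5, trend_slope = 0.03,
         anomaly_window = 12L),
    class = "vh_truth"
  )
}

#' @export
print.vh_truth <- function(x, ...) {
  cat(sprintf("<vh_truth> %dx%d grid, K = %d regions, %d years, SNR %.1f, seed %d\n",
              x$grid_rows, x$grid_cols, x$K, x$n_years, x$snr, x$seed))
  invisible(x)
}

#' Generate planted VCI/TCI-like stacks
#'
#' Each cell carries its region's temporal signal scaled by a per-cell
#' sensitivity gain (uniform on `gain_range`; real grids never respond
#' perfectly uniformly within a zone, and exactly uniform response would
#' make the spatially centred source maps linearly dependent and the region
#' count unidentifiable), plus i.i.d. Gaussian cell noise. The stack is
#' affinely rescaled into [0, 100] with one global map, so correlation
#' structure is untouched. With `noise_sigma = 0`, cells of the same region
#' have perfectly correlated (proportional) series. The noise standard
#' deviation defaults to the value implied by the truth's signal-to-noise
#' ratio: `sd = sqrt(mean over regions of var(signal) / snr)`.
#'
#' @param truth a [synthetic_truth()].
#' @param n_years years to generate (at most `truth$n_years`).
#' @param noise_sigma optional explicit noise standard deviation (on the
#'   pre-rescaling signal scale).
#' @param gain_range range of the per-cell sensitivity gain.
#' @return A list (`vci`, `tci`) of [vh_stack]s.
#' @export
make_vh_stacks <- function(truth, n_years = truth$n_years,
                           noise_sigma = NULL, gain_range = c(0.8, 1.2)) {
  n_years <- as.integer(n_years)
  if (n_years > truth$n_years) stop("`n_years` exceeds the truth's record")
  nt <- n_years * 52L
  cells <- truth$partition
  nc <- nrow(cells)
  gain <- withr::with_seed(truth$seed + 77L, {
    stats::runif(nc, gain_range[1], gain_range[2])
  })

  build <- function(which_sig, seed_off) {
    sig <- truth$signals[[which_sig]][seq_len(nt), , drop = FALSE]
    sd_noise <- noise_sigma %||%
      sqrt(mean(apply(sig, 2L, stats::var)) / truth$snr)
    base <- sig[, cells$region, drop = FALSE] *
      rep(gain, each = nt)
    noise <- withr::with_seed(truth$seed + seed_off, {
      matrix(stats::rnorm(nt * nc, 0, sd_noise), nt, nc)
    })
    x <- base + noise
    x <- (x - min(x)) / (max(x) - min(x)) * 100
    vh_stack(x, years = truth$start_year, cells = cells[c("cell", "row", "col")],
             variable = toupper(which_sig))
  }
  list(vci = build("vci", 101L), tci = build("tci", 202L))
}

#' Generate per-region yield series driven by the planted indices
#'
#' For region k and crop year i:
#' `Y_i = a + b * (i - first_year) + w . x_i + eps_i`, where `x_i` is the
#' 104-element crop-year predictor vector (the weekly VCI and TCI of the
#' region), `w` is a seeded random weight vector supported on the last
#' `anomaly_window` weeks of each index before harvest and scaled so the
#' planted weather anomaly has standard deviation `anomaly_sd`, and `eps`
#' is N(0, `sigma_eps`). The returned table carries the true decomposition
#' (`trend_true`, `anomaly_true`, `eps`) alongside the observable `yield`.
#'
#' @param truth a [synthetic_truth()].
#' @param vci_series,tci_series per-region weekly series as returned by
#'   [spatial_average()] over the planted partition (columns `subregion`,
#'   `year`, `week`, `value`).
#' @return A tibble (`region`, `season`, `year`, `yield`, `trend_true`,
#'   `anomaly_true`, `eps`) with attribute `weights` (per-region weight
#'   vectors).
#' @export
make_yields <- function(truth, vci_series, tci_series) {
  regions <- sort(unique(vci_series$subregion))
  wl <- truth$anomaly_window
  if (wl > 52L) stop("anomaly window exceeds the 52-week crop year")
  wcols <- c(sprintf("vci_w%02d", (52L - wl + 1L):52L),
             sprintf("tci_w%02d", (52L - wl + 1L):52L))
  weights <- list()
  out <- purrr::map_dfr(regions, function(k) {
    tbl <- to_crop_years(vci_series[vci_series$subregion == k, ],
                         tci_series[tci_series$subregion == k, ],
                         harvest_end_week = truth$harvest_end_week,
                         season = "synthetic", subregion = k)
    x <- as.matrix(tbl[, wcols, drop = FALSE])
    yrs <- tbl$year
    withr::with_seed(truth$seed + 500L + k, {
      w <- stats::rnorm(ncol(x))
      raw <- as.numeric(x %*% w)
      s <- stats::sd(raw)
      w <- if (s > 0) w * truth$anomaly_sd / s else w * 0
      anom <- as.numeric(x %*% w)
      anom <- anom - mean(anom)
      eps <- stats::rnorm(length(yrs), 0, truth$sigma_eps)
      weights[[as.character(k)]] <<- w
      trend <- truth$trend_intercept + truth$trend_slope * (yrs - yrs[1])
      tibble::tibble(region = k, season = "synthetic", year = yrs,
                     yield = trend + anom + eps,
                     trend_true = trend, anomaly_true = anom, eps = eps)
    })
  })
  structure(out, weights = weights)
}

#' Run the full synthetic pipeline once
#'
#' Generates stacks, spatially averages them over the planted partition,
#' builds per-region crop-year season tables joined with the generated
#' yields, and returns everything a test of any stage needs.
#'
#' @param truth a [synthetic_truth()].
#' @return A list: `truth`, `stacks` (vci/tci), `series` (vci/tci weekly
#'   per-region tibbles), `yields`, and `tables` (tibble with `region` and
#'   list-column `table`, each a modelling table `year`, `vci_w*`,
#'   `tci_w*`, `yield`, `anomaly_true`).
#' @export
simulate_vh_experiment <- function(truth) {
  stacks <- make_vh_stacks(truth)
  regions <- dplyr::rename(truth$partition, subregion = "region")
  series <- list(vci = spatial_average(stacks$vci, regions),
                 tci = spatial_average(stacks$tci, regions))
  yields <- make_yields(truth, series$vci, series$tci)
  tables <- purrr::map_dfr(sort(unique(regions$subregion)), function(k) {
    tbl <- to_crop_years(series$vci[series$vci$subregion == k, ],
                         series$tci[series$tci$subregion == k, ],
                         harvest_end_week = truth$harvest_end_week,
                         season = "synthetic", subregion = k)
    yk <- yields[yields$region == k, ]
    tbl <- dplyr::inner_join(tbl, yk[, c("year", "yield", "anomaly_true")],
                             by = "year")
    tibble::tibble(region = k, table = list(tbl))
  })
  list(truth = truth, stacks = stacks, series = series, yields = yields,
       tables = tables)
}
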
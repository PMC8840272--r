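# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

# A tiny gridded stack with known values: `value[t, c]` defaults to a
# deterministic ramp unless `values` is supplied.
tiny_stack <- function(n_years = 3, n_cells = 4, values = NULL,
                       start_year = 2000, variable = "NDVI") {
  nt <- n_years * 52
  if (is.null(values)) {
    values <- outer(seq_len(nt) / nt, seq_len(n_cells) / n_cells) + 0.1
  }
  cells <- tibble::tibble(cell = seq_len(n_cells),
                          row = rep(1, n_cells),
                          col = seq_len(n_cells))
  vh_stack(values, years = start_year, cells = cells, variable = variable)
}

# Weekly series tibble for prep tests.
weekly_series <- function(years, fill = function(y, w) 50 + w / 10) {
  df <- tidyr::expand_grid(year = years, week = 1:52)
  df$value <- mapply(fill, df$year, df$week)
  df
}

# Modelling table with a known linear anomaly in 3 predictors.
linear_anomaly_table <- function(n = 25, seed = 5, noise = 0) {
  withr::with_seed(seed, {
    tbl <- tibble::tibble(year = seq(1995, length.out = n),
                          x1 = stats::rnorm(n),
                          x2 = stats::rnorm(n),
                          x3 = stats::rnorm(n))
    tbl$anomaly <- 2 * tbl$x1 - tbl$x2 + 0.5 * tbl$x3 +
      stats::rnorm(n, 0, noise)
    tbl
  })
}

# Decomposition with planted one-hot sources plus Gaussian loading noise at
# a given signal-to-noise ratio; exercises labelling without running ICA.
planted_decomposition <- function(partition, snr = Inf, seed = 1,
                                  variable = "VCI") {
  K <- max(partition$region)
  nc <- nrow(partition)
  s <- t(sapply(seq_len(K), function(k) as.numeric(partition$region == k)))
  if (is.finite(snr)) {
    noise_sd <- sqrt(mean(apply(s, 1, stats::var)) / snr)
    s <- s + withr::with_seed(seed, matrix(stats::rnorm(K * nc, 0, noise_sd), K, nc))
  }
  s <- s / apply(s, 1, stats::sd)
  structure(
    list(A = matrix(stats::rnorm(10 * K), 10, K), S = s, j = K,
         center = rep(0, nc),
         cells = partition[c("cell", "row", "col")],
         times = tibble::tibble(year = 2000, week = 1:10),
         variable = variable, seed = seed, converged = TRUE, iter = 1),
    class = "sica_decomp"
  )
}

# Adjusted Rand index between two labelings (mclust is the oracle).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
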
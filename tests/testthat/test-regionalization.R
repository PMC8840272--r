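test_that("block splitting partitions time with near-equal sizes", {
  s <- tiny_stack(n_years = 10)
  b <- split_blocks(s, "odd_even_years")
  expect_equal(n_times(b$block1) + n_times(b$block2), n_times(s))
  expect_equal(n_times(b$block1), n_times(b$block2)) # 520 -> 260 + 260
  expect_equal(sort(unique(b$block1$times$year)), c(2000, 2002, 2004, 2006, 2008))

  odd <- vh_stack(matrix(1:11, 11, 1), years = rep(2000, 11), weeks = 1:11)
  for (strat in c("interleaved_weeks", "halves")) {
    bo <- split_blocks(odd, strat)
    expect_equal(sort(c(n_times(bo$block1), n_times(bo$block2))), c(5L, 6L))
  }
  b2 <- split_blocks(s, "odd_even_years", seed = 7)
  expect_identical(b$block1$values, b2$block1$values) # deterministic
  expect_error(split_blocks(vh_stack(matrix(1, 3, 1), years = rep(2000, 3),
                                     weeks = 1:3)), "4 time points")
})

test_that("sICA recovers a single planted source exactly up to sign/scale", {
  set.seed(3)
  smap <- rnorm(50)
  tcourse <- sin(2 * pi * (1:104) / 52) + rnorm(104, 0, 0.3)
  stk <- vh_stack(outer(tcourse, smap) + 5, years = 2000)
  d <- fit_sica(stk, j = 1, seed = 9)
  expect_gte(abs(cor(d$S[1, ], smap)), 1 - 1e-8)
  expect_lte(sica_recon_error(d, stk), 1e-6)
})

test_that("sICA separates planted disjoint-support sources", {
  tr <- synthetic_truth(K = 3, n_years = 12, seed = 31)
  st <- make_vh_stacks(tr)
  d <- fit_sica(st$vci, j = 3, seed = 31)
  ind <- sapply(1:3, function(k) as.numeric(tr$partition$region == k))
  best <- apply(abs(cor(t(d$S), ind)), 2, max)
  expect_true(all(best >= 0.95))
  # invariants: unit-variance rows, deterministic given seed
  expect_equal(apply(d$S, 1, sd), rep(1, 3))
  d2 <- fit_sica(st$vci, j = 3, seed = 31)
  expect_identical(d$S, d2$S)
  expect_error(fit_sica(st$vci, j = n_times(st$vci) + 1), "min\\(times")
})

test_that("noiseless low-rank stacks reconstruct to numerical precision", {
  set.seed(11)
  a <- matrix(rnorm(104 * 3), 104)
  s <- matrix(rnorm(3 * 40), 3)
  stk <- vh_stack(a %*% s + 2, years = 2000)
  d <- suppressWarnings(fit_sica(stk, j = 3, seed = 1))
  expect_lte(sica_recon_error(d, stk), 1e-6)
})

test_that("sICA refuses masked stacks", {
  s <- tiny_stack(n_years = 2)
  s$mask[3, 1] <- FALSE
  expect_error(fit_sica(s, j = 1), "gap-fill")
})

test_that("component matching: self-match, symmetry, sign and order invariance", {
  tr <- synthetic_truth(K = 3, n_years = 12, seed = 13)
  st <- make_vh_stacks(tr)
  d1 <- fit_sica(st$vci, j = 3, seed = 1)
  m <- match_components(d1, d1)
  expect_equal(m$abs_corr, rep(1, 3))
  expect_equal(nrow(m), 3) # j deduplicated matches out of the order-2j matrix

  d2 <- fit_sica(st$tci, j = 3, seed = 2)
  m12 <- match_components(d1, d2)
  m21 <- match_components(d2, d1)
  expect_equal(sort(m12$abs_corr), sort(m21$abs_corr)) # block-order symmetry

  d2f <- d2
  d2f$S <- d2$S[c(2, 3, 1), ] * c(-1, 1, -1) # permute rows, flip signs
  mf <- match_components(d1, d2f)
  expect_equal(sort(mf$abs_corr), sort(m12$abs_corr), tolerance = 1e-12)

  d3 <- fit_sica(st$vci, j = 2, seed = 1)
  expect_error(match_components(d1, d3), "different component counts")
})

test_that("independent noise decompositions match near zero", {
  set.seed(19)
  n1 <- vh_stack(matrix(rnorm(104 * 400), 104), years = 2000)
  n2 <- vh_stack(matrix(rnorm(104 * 400), 104), years = 2000)
  d1 <- suppressWarnings(fit_sica(n1, j = 3, seed = 2))
  d2 <- suppressWarnings(fit_sica(n2, j = 3, seed = 3))
  m <- match_components(d1, d2, alpha = 0.05)
  # insignificant correlations are zeroed; survivors stay tiny
  expect_true(all(m$abs_corr < 0.25))
})

test_that("the block profile brackets the planted component count", {
  tr <- synthetic_truth(K = 3, n_years = 15, seed = 5)
  st <- make_vh_stacks(tr)
  prof <- suppressWarnings(ica_by_blocks(st$vci, jmax = 6, seed = 5))
  expect_s3_class(prof, "ica_block_profile")
  expect_equal(sort(unique(prof$j)), 1:6)
  expect_true(all(prof$abs_corr >= 0 & prof$abs_corr <= 1))
  mins <- tapply(prof$abs_corr, prof$j, min)
  expect_true(all(mins[1:3] >= 0.8)) # reproduce up to the planted K
  expect_lt(min(mins[4:6]), 0.8)     # collapse beyond it
  expect_equal(select_optimal_j(prof), 3L)

  prof2 <- suppressWarnings(ica_by_blocks(st$vci, jmax = 6, seed = 5))
  expect_identical(as.data.frame(prof), as.data.frame(prof2)) # same seed
  expect_error(ica_by_blocks(st$vci, jmax = 1, seed = 5), "at least 2")
})

test_that("selection rules apply the threshold as specified", {
  prof <- tibble::tibble(
    j = rep(1:5, times = 1:5),
    match_rank = unlist(lapply(1:5, seq_len)),
    comp_block1 = 1L, comp_block2 = 1L,
    abs_corr = unlist(lapply(list(0.99, c(0.99, 0.98), c(0.99, 0.98, 0.97),
                                  c(0.9, 0.8, 0.5, 0.41),
                                  c(0.9, 0.8, 0.5, 0.4, 0.35)), identity)),
    p_value = 0)
  expect_equal(select_optimal_j(prof, threshold = 0.8), 3L)
  expect_equal(select_optimal_j(prof, threshold = 0.8, rule = "cumulative"), 3L)
  expect_error(select_optimal_j(prof, threshold = 0.999), "no component count")
  expect_error(select_optimal_j(prof, threshold = 1.5), "in \\(0,1\\)")
})

test_that("labelling assigns dominant components, sign-invariantly", {
  part <- make_partition(6, 6, 3, seed = 2)
  d <- planted_decomposition(part, snr = Inf)
  lab <- label_cells(d)
  expect_equal(ari(lab$label, part$region), 1)

  dflip <- d
  dflip$S[2, ] <- -dflip$S[2, ]
  expect_equal(label_cells(dflip)$label, lab$label)
})

test_that("labels survive Gaussian loading noise at moderate SNR", {
  over <- sapply(1:5, function(s) {
    part <- make_partition(10, 10, 4, seed = s)
    d <- planted_decomposition(part, snr = 5, seed = s)
    ari(label_cells(d)$label, part$region)
  })
  expect_true(all(over >= 0.9))
})

test_that("merging label maps: identical maps, quadrants, overrides", {
  part <- make_partition(6, 6, 3, seed = 4)
  d <- planted_decomposition(part)
  lab <- label_cells(d)
  merged <- merge_label_maps(lab, lab)
  expect_equal(ari(merged$subregion, part$region), 1)

  # left/right halves crossed with top/bottom halves -> 4 quadrants
  grid <- tidyr::expand_grid(row = 1:6, col = 1:6)
  grid$cell <- seq_len(36)
  lr <- structure(tibble::tibble(cell = grid$cell, row = grid$row,
                                 col = grid$col,
                                 component = ifelse(grid$col <= 3, 1L, 2L),
                                 label = ifelse(grid$col <= 3, 1L, 2L)),
                  class = c("vh_label_map", "tbl_df", "tbl", "data.frame"))
  tb <- lr
  tb$component <- tb$label <- ifelse(grid$row <= 3, 1L, 2L)
  quad <- merge_label_maps(lr, tb)
  expect_equal(dplyr::n_distinct(quad$subregion), 4)
  legend <- attr(quad, "legend")
  expect_equal(nrow(legend), 4)
  expect_equal(sum(legend$n_cells), 36)

  # user-supplied override splits one subregion in two
  ov <- merge_label_maps(lr, tb, overrides = list(split = 1:3))
  expect_equal(dplyr::n_distinct(ov$subregion), 5)
  expect_error(merge_label_maps(lr, tb[c(2:36, 1), ]), "same grid")
})

test_that("small fragments are absorbed by their longest-boundary neighbour", {
  grid <- tidyr::expand_grid(row = 1:5, col = 1:5)
  grid$cell <- seq_len(25)
  base <- ifelse(grid$col <= 2, 1L, 2L)
  base[grid$row == 3 & grid$col == 5] <- 3L # a 1-cell island inside region 2
  mk <- function(lbl) structure(
    tibble::tibble(cell = grid$cell, row = grid$row, col = grid$col,
                   component = lbl, label = lbl),
    class = c("vh_label_map", "tbl_df", "tbl", "data.frame"))
  merged <- merge_label_maps(mk(base), mk(base), min_cells = 2)
  expect_equal(dplyr::n_distinct(merged$subregion), 2)
  island <- merged$subregion[grid$row == 3 & grid$col == 5]
  neighbour <- merged$subregion[grid$row == 3 & grid$col == 4]
  expect_equal(island, neighbour)
})

test_that("distinct index-pair combinations produce the documented subregions", {
  # eight zones whose (VCI IC, TCI IC) pairs collapse to 7 distinct pairs;
  # one pair is shared by two zones and needs the manual override to split
  pairs <- list(c(2, 2), c(4, 4), c(4, 4), c(5, 3), c(5, 5), c(3, 5),
                c(3, 1), c(1, 1))
  expect_equal(dplyr::n_distinct(vapply(pairs, paste, collapse = "/",
                                        character(1))), 7L)
  # lay the 8 zones side by side on a 2 x 4 grid of 2x2 blocks
  grid <- tidyr::expand_grid(row = 1:4, col = 1:8)
  grid$cell <- seq_len(32)
  zone <- (ceiling(grid$col / 2) - 1) + 4 * (grid$row > 2) + 1
  vlab <- vapply(pairs, `[`, numeric(1), 1)[zone]
  tlab <- vapply(pairs, `[`, numeric(1), 2)[zone]
  mk <- function(lbl) structure(
    tibble::tibble(cell = grid$cell, row = grid$row, col = grid$col,
                   component = as.integer(lbl), label = as.integer(lbl)),
    class = c("vh_label_map", "tbl_df", "tbl", "data.frame"))
  merged <- merge_label_maps(mk(vlab), mk(tlab))
  # zones 2 and 3 share (4,4) and touch, so they merge: 7 subregions
  expect_equal(dplyr::n_distinct(merged$subregion), 7L)
  # the override reinstates the split -> 8 subregions
  ov_cells <- grid$cell[zone == 2]
  merged8 <- merge_label_maps(mk(vlab), mk(tlab),
                              overrides = list(northeast = ov_cells))
  expect_equal(dplyr::n_distinct(merged8$subregion), 8L)
})

test_that("label maps and legends serialize to CSV", {
  part <- make_partition(4, 4, 2, seed = 9)
  d <- planted_decomposition(part)
  lab <- label_cells(d)
  merged <- merge_label_maps(lab, lab)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_labels_csv(merged, p1, p2)
  expect_equal(nrow(utils::read.csv(p1)), 16)
  expect_true("vci_ic" %in% names(utils::read.csv(p2)))
})
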
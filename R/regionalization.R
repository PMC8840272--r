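#' Split a stack into two blocks of time points
#'
#' First stage of the split-half component-reproducibility (ICA-by-blocks)
#' procedure: the record is divided into two subsets of approximately equal
#' size that both represent the whole data matrix.
#'
#' Strategies: `"odd_even_years"` (default; alternate whole years, so both
#' blocks keep the full seasonal cycle), `"interleaved_weeks"` (alternate
#' individual time points; block sizes differ by at most one) and
#' `"halves"` (first vs second half of the record, for sensitivity checks).
#'
#' @param stack a [vh_stack] with at least 4 time points.
#' @param strategy block assignment rule.
#' @param seed reserved for seeded strategies; all current strategies are
#'   deterministic, the seed is recorded for provenance.
#' @return A list of two `vh_stack`s over the same cells whose time points
#'   partition the input.
#' @export
split_blocks <- function(stack,
                         strategy = c("odd_even_years", "interleaved_weeks",
                                      "halves"),
                         seed = 1L) {
  strategy <- match.arg(strategy)
  nt <- n_times(stack)
  if (nt < 4L) stop("need at least 4 time points to split into blocks")
  idx <- switch(strategy,
    interleaved_weeks = seq_len(nt) %% 2L == 1L,
    halves = seq_len(nt) <= ceiling(nt / 2),
    odd_even_years = {
      yrs <- sort(unique(stack$times$year))
      stack$times$year %in% yrs[seq_along(yrs) %% 2L == 1L]
    })
  b1 <- stack_time_subset(stack, which(idx))
  b2 <- stack_time_subset(stack, which(!idx))
  structure(list(block1 = b1, block2 = b2),
            strategy = strategy, seed = seed)
}

# Seeded random orthogonal j x j matrix (QR of a Gaussian matrix).
random_rotation <- function(j, seed) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    qr.Q(qr(matrix(stats::rnorm(j * j), j, j)))
  })
}

#' Spatial independent component analysis of a stack
#'
#' Decomposes the per-cell temporally centred matrix `X` (time x cell) as
#' `X = A S`: `S` (j x cell) holds spatial source maps that are as
#' statistically independent as possible over cells, and `A` (time x j)
#' their temporal mixing courses. The rotation is estimated by FastICA
#' (logcosh contrast, symmetric decorrelation) after whitening to `j`
#' components in the spatial second-moment metric. Spatial means are
#' deliberately *not* removed: zone-like source maps with disjoint support
#' are exactly orthogonal in second moments but become negatively
#' correlated once centred over cells, and centring would therefore push
#' the whitened space away from the true sources.
#'
#' FastICA's even contrast has competing fixed points for such sources
#' (mixtures of zone maps). The fit therefore runs `n_starts` seeded
#' restarts and keeps the solution with the largest total non-Gaussianity
#' measured by a Jarque-Bera-type score (squared skewness plus a quarter
#' squared excess kurtosis, summed over components), which sees the odd
#' moments that the logcosh objective ignores. The whitening, seeded
#' rotations and deterministic score make the fit reproducible given
#' `seed`. Rows of `S` are scaled to unit variance.
#'
#' Component sign and order are not identifiable; downstream operations use
#' absolute correlations and label maps only.
#'
#' @param stack a gap-free [vh_stack] (no masked entries; gap-fill first).
#' @param j number of independent components, `1 <= j <= min(times, cells)`.
#' @param seed integer seed for the initial rotations.
#' @param maxit,tol FastICA iteration cap and convergence tolerance (the
#'   tolerance is deliberately strict: loose stopping leaves the rotation
#'   partially mixed and degrades split-half reproducibility).
#' @param n_starts seeded restarts scored for non-Gaussianity.
#' @return An object of class `sica_decomp`: list with `A` (time x j), `S`
#'   (j x cell), `j`, `center` (per-cell temporal means), `cells`, `times`,
#'   `variable`, `seed`, `converged`, `score`.
#' @export
fit_sica <- function(stack, j, seed = 1L, maxit = 1000L, tol = 1e-9,
                     n_starts = 4L) {
  j <- as.integer(j)
  if (j < 1L || j > min(n_times(stack), n_cells(stack))) {
    stop("`j` must lie in 1..min(times, cells)")
  }
  if (!all(stack$mask)) {
    stop("stack contains missing values; gap-fill before fitting sICA")
  }
  center <- colMeans(stack$values)
  xc <- sweep(stack$values, 2L, center) # time x cell, centred over time
  xs <- t(xc) # rows = cells (samples), columns = time points: spatial ICA

  jb_score <- function(s) {
    # total non-Gaussianity over component maps, odd moments included
    sum(apply(s, 2L, function(v) {
      z <- (v - mean(v)) / stats::sd(v)
      mean(z^3)^2 + (mean(z^4) - 3)^2 / 4
    }))
  }

  best <- NULL
  best_score <- -Inf
  any_converged <- FALSE
  for (r in seq_len(max(1L, n_starts)) - 1L) {
    r0 <- random_rotation(j, seed + 1000L * r)
    fit <- ica::icafast(xs, nc = j, center = FALSE,
                        maxit = maxit, tol = tol, Rmat = r0,
                        alg = "par", fun = "logcosh")
    conv <- is.na(fit$iter) || fit$iter < maxit # iter is NA when j = 1
    any_converged <- any_converged || conv
    sc <- jb_score(fit$S)
    if (sc > best_score) {
      best <- fit
      best_score <- sc
    }
    if (j == 1L) break # no rotation to estimate
  }
  if (!any_converged) {
    warning(sprintf("FastICA did not converge in %d iterations (j = %d)",
                    maxit, j))
  }

  s <- t(best$S)      # j x cell
  a <- as.matrix(best$M) # time x j (icafast returns 1 x time when j = 1)
  if (ncol(a) != j) a <- t(a)
  sdv <- apply(s, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  s <- s / sdv
  a <- a * rep(sdv, each = nrow(a))

  structure(
    list(A = a, S = s, j = j, center = center,
         cells = stack$cells, times = stack$times,
         variable = stack$variable, seed = seed,
         converged = any_converged, iter = best$iter, score = best_score),
    class = "sica_decomp"
  )
}

#' @export
print.sica_decomp <- function(x, ...) {
  cat(sprintf("<sica_decomp> %s: j = %d over %d cells x %d weeks (%s)\n",
              x$variable, x$j, ncol(x$S), nrow(x$A),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_sica
#' @param x a `sica_decomp`.
#' @param ... unused.
#' @method tidy sica_decomp
#' @export
tidy.sica_decomp <- function(x, ...) {
  tibble::tibble(
    component = rep(seq_len(x$j), each = ncol(x$S)),
    cell = rep(x$cells$cell, x$j),
    row = rep(x$cells$row, x$j),
    col = rep(x$cells$col, x$j),
    loading = as.vector(t(x$S))
  )
}

#' @rdname fit_sica
#' @method glance sica_decomp
#' @export
glance.sica_decomp <- function(x, ...) {
  tibble::tibble(
    j = x$j, n_times = nrow(x$A), n_cells = ncol(x$S),
    converged = x$converged,
    recon_error = sica_recon_error(x)
  )
}

#' Relative reconstruction error of a decomposition
#'
#' `||X_centred - A S||_F / ||X_centred||_F`, where `X_centred` applies the
#' decomposition's recorded preprocessing (per-cell temporal centering) to
#' the supplied stack. Zero (to numerical tolerance) when `j` equals the
#' rank of a noiseless low-rank stack.
#'
#' @param d a `sica_decomp`.
#' @param stack the stack the decomposition was fitted to.
#' @return A non-negative number (`NA` without a stack).
#' @export
sica_recon_error <- function(d, stack = NULL) {
  if (is.null(stack)) return(NA_real_)
  xc <- sweep(stack$values, 2L, d$center)
  sqrt(sum((xc - d$A %*% d$S)^2)) / sqrt(sum(xc^2))
}

# Two-sided p-value for a correlation coefficient with n samples.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Match components across two block decompositions
#'
#' Builds the order-2j square matrix of absolute spatial correlations
#' between the stacked components of the two blocks, then extracts the j
#' cross-block matches. The default `"greedy"` pairing repeatedly takes the
#' largest remaining cross-block |correlation| and removes its row and
#' column, which reproduces the sorted-vector selection (drop the 2j
#' self-correlations, keep the next 2j, deduplicate the symmetric pairs)
#' while guaranteeing a one-to-one assignment. `"rank"` returns the literal
#' sorted-vector selection without the one-to-one constraint.
#'
#' Correlations whose two-sided p-value (correlation test with n = number
#' of cells) is `>= alpha` are set to 0 before matching.
#'
#' @param d1,d2 `sica_decomp`s with equal `j` over the same cells.
#' @param alpha significance level for the correlation test.
#' @param pairing `"greedy"` (one-to-one) or `"rank"`.
#' @return A tibble with columns `match_rank`, `comp_block1`, `comp_block2`,
#'   `abs_corr`, `p_value`, sorted by decreasing `abs_corr`.
#' @export
match_components <- function(d1, d2, alpha = 0.05,
                             pairing = c("greedy", "rank")) {
  pairing <- match.arg(pairing)
  if (d1$j != d2$j) stop("decompositions have different component counts")
  if (!identical(d1$cells$cell, d2$cells$cell)) {
    stop("decompositions are not over the same cells")
  }
  j <- d1$j
  n <- ncol(d1$S)
  cross <- abs(stats::cor(t(d1$S), t(d2$S))) # j x j
  pv <- cor_pvalue(cross, n)
  cross[pv >= alpha] <- 0

  if (pairing == "greedy") {
    m <- cross
    out <- vector("list", j)
    for (k in seq_len(j)) {
      top <- arrayInd(which.max(m), dim(m))
      i1 <- top[1]; i2 <- top[2]
      out[[k]] <- tibble::tibble(
        match_rank = k, comp_block1 = i1, comp_block2 = i2,
        abs_corr = cross[i1, i2], p_value = pv[i1, i2])
      m[i1, ] <- -Inf
      m[, i2] <- -Inf
    }
    res <- dplyr::bind_rows(out)
  } else {
    # literal selection on the order-2j stacked matrix: sort all entries,
    # drop the 2j self-correlations (the unit diagonal), take the next 2j,
    # deduplicate symmetric twins -> the j largest cross-block entries
    vals <- sort(cross, decreasing = TRUE)
    top <- utils::head(vals, j)            # = dedup of the next-2j selection
    idx <- order(cross, decreasing = TRUE)[seq_len(j)]
    pos <- arrayInd(idx, dim(cross))
    res <- tibble::tibble(
      match_rank = seq_len(j),
      comp_block1 = pos[, 1], comp_block2 = pos[, 2],
      abs_corr = top, p_value = pv[cbind(pos[, 1], pos[, 2])])
  }
  res
}

#' Split-half component reproducibility profile (ICA-by-blocks)
#'
#' Splits the record once, fits sICA with `j = 1..jmax` components on each
#' block, and matches the components across blocks at every `j`. The
#' resulting profile of matched absolute correlations is the basis for
#' selecting the number of components: while `j` does not exceed the true
#' number of spatial sources, every component reproduces across blocks
#' (correlations near 1); redundant components absorb noise and fail to
#' reproduce.
#'
#' @param stack a gap-free [vh_stack].
#' @param jmax largest component count to profile (>= 2 and at most
#'   `min(times, cells)` of either block).
#' @param seed master seed; both blocks at component count `j` start from
#'   the identical seeded rotation (`seed + j`).
#' @param strategy,alpha,pairing forwarded to [split_blocks()] and
#'   [match_components()].
#' @param n_starts restarts per component count: FastICA restart
#'   variability is a nuisance for the reproducibility question, so when a
#'   profile at some `j` is ambiguous (its minimum matched correlation is
#'   neither clearly reproduced, >= 0.95, nor clearly collapsed, < 0.2) the
#'   fits are repeated from fresh seeded rotations and the
#'   best-reproducing profile is kept. Decisive profiles stop early.
#' @param ... further arguments to [fit_sica()].
#' @return A tibble of class `ica_block_profile` with columns `j`,
#'   `match_rank`, `comp_block1`, `comp_block2`, `abs_corr`, `p_value`.
#' @export
ica_by_blocks <- function(stack, jmax, seed = 1L,
                          strategy = "odd_even_years", alpha = 0.05,
                          pairing = "greedy", n_starts = 3L, ...) {
  jmax <- as.integer(jmax)
  if (jmax < 2L) stop("`jmax` must be at least 2 to bracket an optimum")
  blocks <- split_blocks(stack, strategy = strategy, seed = seed)
  lim <- min(n_times(blocks$block1), n_times(blocks$block2),
             n_cells(stack))
  if (jmax > lim) stop("`jmax` exceeds min(times, cells) of a block")

  prof <- purrr::map_dfr(seq_len(jmax), function(j) {
    best <- NULL
    best_min <- -Inf
    for (r in seq_len(max(1L, n_starts)) - 1L) {
      # both blocks start from the same seeded rotation: the profile should
      # measure whether the DATA reproduce the components, not whether two
      # FastICA restarts happen to land in the same basin
      d1 <- fit_sica(blocks$block1, j = j, seed = seed + j + 10000L * r, ...)
      d2 <- fit_sica(blocks$block2, j = j, seed = seed + j + 10000L * r, ...)
      m <- match_components(d1, d2, alpha = alpha, pairing = pairing)
      mn <- min(m$abs_corr)
      if (mn > best_min) {
        best <- m
        best_min <- mn
      }
      if (best_min >= 0.95 || mn < 0.2) break
    }
    best$j <- j
    best
  })
  prof <- dplyr::select(prof, "j", "match_rank", "comp_block1",
                        "comp_block2", "abs_corr", "p_value")
  structure(prof,
            class = c("ica_block_profile", class(prof)),
            jmax = jmax, seed = seed, alpha = alpha,
            strategy = strategy)
}

#' Select the number of components from a block profile
#'
#' The optimum is the component count at which all cross-block matched
#' correlations are still high: redundant components absorb noise and stop
#' reproducing across blocks, so the profile collapses beyond the true
#' number of spatial sources.
#'
#' Rules: `"largest"` (default) returns the largest `j` whose matched
#' correlations at that `j` are all at least `threshold`. `"cumulative"`
#' additionally requires every smaller `j'` to qualify; it is stricter but
#' fragile at intermediate `j`, where ICA with fewer components than true
#' sources is ill-posed and the two blocks may settle on different mixtures.
#' `"elbow"` returns the qualifying `j` with the largest drop of the per-j
#' minimum correlation to `j + 1`.
#'
#' @param profile an [ica_by_blocks()] profile.
#' @param threshold minimum acceptable matched |correlation| (in (0,1)).
#' @param rule `"largest"`, `"cumulative"` or `"elbow"`.
#' @return The selected integer `j`; error when no `j` qualifies.
#' @export
select_optimal_j <- function(profile, threshold = 0.8,
                             rule = c("largest", "cumulative", "elbow")) {
  rule <- match.arg(rule)
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0,1)")
  mins <- dplyr::summarise(dplyr::group_by(profile, .data$j),
                           min_corr = min(.data$abs_corr), .groups = "drop")
  mins <- dplyr::arrange(mins, .data$j)
  ok <- mins$min_corr >= threshold
  if (!any(ok)) stop("no component count qualifies: all profiles fall below the threshold")
  if (rule == "largest") return(as.integer(mins$j[max(which(ok))]))
  if (!ok[1]) stop("no component count qualifies under the cumulative rule")
  jq <- if (all(ok)) nrow(mins) else which(!ok)[1] - 1L
  if (rule == "cumulative") return(as.integer(mins$j[jq]))
  drops <- mins$min_corr - c(mins$min_corr[-1], -Inf)
  as.integer(mins$j[which.max(drops[seq_len(jq)])])
}

#' Auto-expanding component selection
#'
#' Increases `jmax` until the selected component count is stable across two
#' successive increments, mirroring the recommendation to raise the
#' investigated range until the optimum stabilises.
#'
#' @inheritParams ica_by_blocks
#' @inheritParams select_optimal_j
#' @param jmax_start,jmax_cap initial and maximal `jmax`.
#' @return A list with `j` (selected count), `profile` (at the final jmax).
#' @export
select_j_auto <- function(stack, jmax_start = 6L, jmax_cap = 20L,
                          seed = 1L, threshold = 0.8, ...) {
  jmax <- jmax_start
  hist <- integer(0)
  prof <- NULL
  repeat {
    prof <- ica_by_blocks(stack, jmax = jmax, seed = seed, ...)
    hist <- c(hist, select_optimal_j(prof, threshold = threshold))
    nh <- length(hist)
    if (nh >= 3 && hist[nh] == hist[nh - 1] && hist[nh] == hist[nh - 2]) break
    if (jmax >= jmax_cap) break
    jmax <- min(jmax_cap, jmax + 2L)
  }
  list(j = hist[length(hist)], profile = prof, history = hist)
}

#' Label cells by dominant component
#'
#' Assigns each cell the component with the largest absolute standardized
#' spatial loading (ties broken by the lowest component index). Each
#' component map is standardized by subtracting its *median* and dividing
#' by its standard deviation: for a zone-shaped map the median sits on the
#' out-of-zone baseline (ICA leaves an arbitrary constant offset in each
#' map), so after standardization in-zone cells carry large deviations and
#' the baseline sits near zero. The mean would instead be dragged towards
#' the zone and make the baseline compete with genuine loadings. The rule
#' assumes each zone covers less than half the cells; at exactly half the
#' median is ambiguous. Because the assignment uses |loading|, it is
#' invariant to the sign indeterminacy of ICA.
#'
#' @param d a `sica_decomp`.
#' @return A tibble of class `vh_label_map` with columns `cell`, `row`,
#'   `col`, `component` (winning IC) and `label` (components relabelled to
#'   contiguous integers 1..m in order of component index).
#' @export
label_cells <- function(d) {
  s <- (d$S - apply(d$S, 1L, stats::median)) / apply(d$S, 1L, stats::sd)
  winner <- apply(abs(s), 2L, which.max) # ties: which.max takes the first
  lab <- match(winner, sort(unique(winner)))
  out <- tibble::tibble(cell = d$cells$cell, row = d$cells$row,
                        col = d$cells$col,
                        component = as.integer(winner),
                        label = as.integer(lab))
  structure(out, class = c("vh_label_map", class(out)),
            variable = d$variable, j = d$j)
}

# Connected components of equal-valued cells on the 4-neighbour grid.
grid_components <- function(row, col, value) {
  n <- length(row)
  key <- paste(row, col)
  pos <- stats::setNames(seq_len(n), key)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      nb <- c(paste(row[i] - 1L, col[i]), paste(row[i] + 1L, col[i]),
              paste(row[i], col[i] - 1L), paste(row[i], col[i] + 1L))
      for (k in pos[nb]) {
        if (!is.na(k) && comp[k] == 0L && value[k] == value[i]) {
          comp[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  comp
}

# Count adjacent cell pairs between each pair of subregions.
boundary_lengths <- function(row, col, comp) {
  key <- paste(row, col)
  pos <- stats::setNames(seq_along(row), key)
  res <- list()
  for (i in seq_along(row)) {
    for (nb in list(c(1L, 0L), c(0L, 1L))) {
      k <- pos[paste(row[i] + nb[1], col[i] + nb[2])]
      if (!is.na(k) && comp[k] != comp[i]) {
        a <- min(comp[i], comp[k]); b <- max(comp[i], comp[k])
        id <- paste(a, b)
        res[[id]] <- (res[[id]] %||% 0L) + 1L
      }
    }
  }
  res
}

#' Merge VCI and TCI label maps into subregions
#'
#' A subregion is a connected set of cells sharing the same (VCI label,
#' TCI label) pair. Fragments smaller than `min_cells` are absorbed into
#' the neighbouring subregion with which they share the longest boundary
#' (smallest fragments first). `overrides` are applied last and support
#' agronomically motivated splits that the statistical patterns alone do
#' not make (named list: each element a vector of cell ids carved out into
#' its own subregion).
#'
#' @param vci_labels,tci_labels [label_cells()] maps on the same grid with
#'   `row`/`col` coordinates.
#' @param min_cells smallest allowed subregion size before merging.
#' @param overrides optional named list of cell-id vectors to split out.
#' @return A tibble of class `vh_subregions` with columns `cell`, `row`,
#'   `col`, `vci_label`, `tci_label`, `subregion`, and a `legend` attribute
#'   (tibble: `subregion`, `vci_ic`, `tci_ic`, `n_cells`, `override`).
#' @export
merge_label_maps <- function(vci_labels, tci_labels, min_cells = 1L,
                             overrides = NULL) {
  if (!identical(vci_labels$cell, tci_labels$cell) ||
      !identical(vci_labels$row, tci_labels$row) ||
      !identical(vci_labels$col, tci_labels$col)) {
    stop("label maps are not on the same grid")
  }
  if (anyNA(vci_labels$row) || anyNA(vci_labels$col)) {
    stop("merging needs cell `row`/`col` coordinates")
  }
  row <- vci_labels$row; col <- vci_labels$col
  pair <- paste(vci_labels$label, tci_labels$label, sep = "/")
  comp <- grid_components(row, col, pair)

  # absorb undersized fragments, smallest first
  repeat {
    sizes <- table(comp)
    small <- names(sizes)[sizes < min_cells]
    if (length(small) == 0L || length(sizes) == 1L) break
    victim <- small[which.min(sizes[small])]
    bl <- boundary_lengths(row, col, comp)
    touching <- bl[grepl(paste0("^", victim, " | ", victim, "$"),
                         names(bl))]
    if (length(touching) == 0L) break
    best <- names(touching)[which.max(unlist(touching))]
    pairids <- strsplit(best, " ")[[1]]
    target <- setdiff(pairids, victim)
    comp[comp == as.integer(victim)] <- as.integer(target)
  }

  # overrides: carve out user-specified cell sets as their own subregions
  override_flag <- rep(NA_character_, length(comp))
  if (!is.null(overrides)) {
    nxt <- max(comp)
    for (nm in names(overrides)) {
      nxt <- nxt + 1L
      hit <- vci_labels$cell %in% overrides[[nm]]
      comp[hit] <- nxt
      override_flag[hit] <- nm
    }
  }

  sub <- match(comp, sort(unique(comp)))
  out <- tibble::tibble(cell = vci_labels$cell, row = row, col = col,
                        vci_label = vci_labels$label,
                        tci_label = tci_labels$label,
                        subregion = as.integer(sub))
  legend <- dplyr::summarise(
    dplyr::group_by(out, .data$subregion),
    vci_ic = .data$vci_label[which.max(tabulate(.data$vci_label))],
    tci_ic = .data$tci_label[which.max(tabulate(.data$tci_label))],
    n_cells = dplyr::n(), .groups = "drop")
  legend$override <- vapply(legend$subregion, function(s) {
    f <- unique(stats::na.omit(override_flag[sub == s]))
    if (length(f)) f[1] else NA_character_
  }, character(1))
  structure(out, class = c("vh_subregions", class(out)), legend = legend)
}

#' Write a label map or subregion set as CSV grid plus legend
#'
#' Emits `<path>` with one row per cell (`cell,row,col,label`) and, for
#' subregion sets, `<legend_path>` with the (VCI IC, TCI IC, size) legend.
#'
#' @param x a `vh_label_map` or `vh_subregions`.
#' @param path output CSV path for the per-cell table.
#' @param legend_path optional CSV path for the legend (subregion sets).
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(x, path, legend_path = NULL) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  if (!is.null(legend_path) && !is.null(attr(x, "legend"))) {
    utils::write.csv(as.data.frame(attr(x, "legend")), legend_path,
                     row.names = FALSE)
  }
  invisible(path)
}
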
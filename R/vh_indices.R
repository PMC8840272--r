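#' Temporal smoothing of a stack
#'
#' Optional high-frequency noise removal applied per cell along the time
#' axis before index computation. The operational NDVI/BT products are
#' already smoothed upstream by the provider, so the default here is
#' `"none"`; a centred moving mean or moving median is available for raw
#' inputs. Window ends are handled by shrinking the window.
#'
#' @param stack a [vh_stack].
#' @param method `"none"`, `"moving_mean"` or `"moving_median"`.
#' @param window odd positive window length (in weeks).
#' @return A `vh_stack` of the same shape and mask.
#' @export
smooth_stack <- function(stack,
                         method = c("none", "moving_mean", "moving_median"),
                         window = 5L) {
  method <- match.arg(method)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be a positive odd integer")
  }
  if (method == "none" || window == 1L) return(stack)

  fun <- if (method == "moving_mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  }
  sm <- apply(stack$values, 2L, function(col) {
    out <- zoo::rollapply(col, width = window, FUN = fun,
                          align = "center", partial = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  })
  sm[!stack$mask] <- NA_real_
  vh_stack(sm, years = stack$times$year, weeks = stack$times$week,
           cells = stack$cells, mask = stack$mask, variable = stack$variable)
}

#' Per-cell record extrema (index climatology)
#'
#' Computes the minimum and maximum of a stack per cell, either over the
#' full record (`per_week = FALSE`) or per calendar week across years
#' (`per_week = TRUE`, the default, which treats each week-of-year as its
#' own climatological slot). Only mask-valid values contribute; a cell
#' (or cell-week) with no valid data is flagged invalid (`NA` extrema).
#'
#' @param stack a [vh_stack].
#' @param per_week compute extrema per calendar week across years?
#' @return A tibble of class `vh_climatology` with columns `cell`, `week`
#'   (`NA` when `per_week = FALSE`), `min`, `max`, `n` (number of valid
#'   values behind each pair). The record span is stored in attributes
#'   `variable`, `per_week` and `span` (year range).
#' @export
compute_climatology <- function(stack, per_week = TRUE) {
  if (per_week) {
    if (length(unique(stack$times$year)) < 2L) {
      stop("per-week climatology needs at least 2 years of record")
    }
    groups <- split(seq_len(n_times(stack)), stack$times$week)
    out <- purrr::map_dfr(names(groups), function(w) {
      idx <- groups[[w]]
      vals <- stack$values[idx, , drop = FALSE]
      tibble::tibble(
        cell = stack$cells$cell,
        week = as.integer(w),
        min = suppressWarnings(apply(vals, 2L, min, na.rm = TRUE)),
        max = suppressWarnings(apply(vals, 2L, max, na.rm = TRUE)),
        n = colSums(!is.na(vals))
      )
    })
    out <- dplyr::arrange(out, .data$cell, .data$week)
  } else {
    if (n_times(stack) < 2L) {
      stop("climatology needs at least 2 time points")
    }
    out <- tibble::tibble(
      cell = stack$cells$cell,
      week = NA_integer_,
      min = suppressWarnings(apply(stack$values, 2L, min, na.rm = TRUE)),
      max = suppressWarnings(apply(stack$values, 2L, max, na.rm = TRUE)),
      n = colSums(!is.na(stack$values))
    )
  }
  out$min[out$n == 0L] <- NA_real_
  out$max[out$n == 0L] <- NA_real_
  structure(out,
            class = c("vh_climatology", class(out)),
            variable = stack$variable,
            per_week = per_week,
            span = range(stack$times$year))
}

# Align climatology extrema with the (time, cell) layout of a stack.
clim_matrices <- function(stack, clim) {
  per_week <- attr(clim, "per_week")
  nt <- n_times(stack)
  key_cell <- match(rep(stack$cells$cell, each = nt), clim$cell)
  if (per_week) {
    key <- match(
      paste(rep(stack$cells$cell, each = nt), rep(stack$times$week, n_cells(stack))),
      paste(clim$cell, clim$week)
    )
  } else {
    key <- key_cell
  }
  if (anyNA(key)) {
    stop("climatology does not cover every (cell, week) of the stack")
  }
  list(min = matrix(clim$min[key], nt, n_cells(stack)),
       max = matrix(clim$max[key], nt, n_cells(stack)))
}

rescale_index <- function(stack, clim, orientation, variable) {
  m <- clim_matrices(stack, clim)
  rng <- m$max - m$min
  used <- stack$mask
  bad <- used & (!is.finite(rng) | rng <= 0)
  if (any(bad)) {
    stop("zero or undefined climatology range at ", sum(colSums(bad) > 0),
         " cell(s) with valid data; widen the climatology record")
  }
  x <- if (orientation > 0) {
    (stack$values - m$min) / rng * 100
  } else {
    (m$max - stack$values) / rng * 100
  }
  # inputs outside the climatology window clip to the stated index range
  x <- pmin(pmax(x, 0), 100)
  x[!used] <- NA_real_
  vh_stack(x, years = stack$times$year, weeks = stack$times$week,
           cells = stack$cells, mask = used, variable = variable)
}

#' Vegetation condition index
#'
#' VCI = (NDVI - NDVImin) / (NDVImax - NDVImin) x 100, where the extrema
#' are the per-cell (optionally per-week) climatological minimum and
#' maximum. The index ranges from 0 (severe vegetation stress) to 100
#' (favourable conditions); inputs outside the climatology range are
#' clipped to that interval.
#'
#' @param ndvi a [vh_stack] of NDVI.
#' @param clim a [compute_climatology()] result derived from an NDVI record
#'   covering the same grid.
#' @return A `vh_stack` named `"VCI"`.
#' @export
compute_vci <- function(ndvi, clim) {
  rescale_index(ndvi, clim, orientation = +1, variable = "VCI")
}

#' Thermal condition index
#'
#' TCI = (BTmax - BT) / (BTmax - BTmin) x 100: the orientation is inverted
#' relative to [compute_vci()] because low brightness temperature (cool
#' conditions) is favourable. Same range, clipping and climatology
#' conventions as the VCI.
#'
#' @param bt a [vh_stack] of brightness temperature.
#' @param clim a [compute_climatology()] result for the BT record.
#' @return A `vh_stack` named `"TCI"`.
#' @export
compute_tci <- function(bt, clim) {
  rescale_index(bt, clim, orientation = -1, variable = "TCI")
}

#' One-call VCI/TCI computation
#'
#' Convenience wrapper: optional smoothing, climatology and both indices.
#'
#' @param ndvi,bt input [vh_stack]s on the same grid.
#' @param per_week per-week climatology? (see [compute_climatology()]).
#' @param smooth,window smoothing settings forwarded to [smooth_stack()].
#' @return A [vh_series] holding the VCI and TCI stacks.
#' @export
compute_vh_series <- function(ndvi, bt, per_week = TRUE,
                              smooth = "none", window = 5L) {
  ndvi <- smooth_stack(ndvi, method = smooth, window = window)
  bt <- smooth_stack(bt, method = smooth, window = window)
  vh_series(
    vci = compute_vci(ndvi, compute_climatology(ndvi, per_week = per_week)),
    tci = compute_tci(bt, compute_climatology(bt, per_week = per_week))
  )
}
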
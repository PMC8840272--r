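#' Gridded weekly index stack
#'
#' A `vh_stack` holds one gridded weekly variable (NDVI, BT, VCI, TCI, ...)
#' as a time-by-cell matrix together with weekly timestamps, cell
#' coordinates and a validity mask. It is the container every gridded
#' operation in the package consumes and returns; [as_tibble()] and
#' [as_vh_stack()] convert to and from the long tabular form
#' (`year`, `week`, `cell`, `value`).
#'
#' Weeks are numbered 1--52; a 53rd ISO week in incoming tabular data is
#' merged into week 52 (values averaged) so that every year contributes the
#' same 52 weekly slots.
#'
#' @param values numeric matrix, time (rows) by cell (columns).
#' @param years,weeks integer vectors, one per row of `values`. If `weeks`
#'   is omitted, rows are assumed to be consecutive weeks 1..52 starting at
#'   week 1 of `years[1]` (and `years` may then be a single starting year).
#' @param cells optional tibble with columns `cell` and, for gridded data,
#'   `row` and `col`. Defaults to cells `1..ncol(values)` without
#'   coordinates.
#' @param mask logical matrix of the same shape as `values`; `TRUE` marks a
#'   valid observation. Non-finite values are always masked.
#' @param variable name of the stored variable.
#'
#' @return An object of class `vh_stack`.
#' @export
vh_stack <- function(values, years, weeks = NULL, cells = NULL, mask = NULL,
                     variable = "index") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  nt <- nrow(values)
  nc <- ncol(values)

  if (is.null(weeks)) {
    if (length(years) == 1L) {
      weeks <- ((seq_len(nt) - 1L) %% 52L) + 1L
      years <- years + (seq_len(nt) - 1L) %/% 52L
    } else {
      stopifnot(length(years) == nt)
      weeks <- ((seq_len(nt) - 1L) %% 52L) + 1L
    }
  }
  years <- as.integer(years)
  weeks <- as.integer(weeks)
  if (length(years) != nt || length(weeks) != nt) {
    stop("`years` and `weeks` must have one entry per row of `values`")
  }
  if (any(weeks < 1L | weeks > 52L)) {
    stop("weeks must lie in 1..52 (merge a 53rd ISO week into week 52)")
  }
  tcode <- years * 100L + weeks
  if (is.unsorted(tcode, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }

  if (is.null(cells)) {
    cells <- tibble::tibble(cell = seq_len(nc), row = NA_integer_,
                            col = NA_integer_)
  } else {
    cells <- tibble::as_tibble(cells)
    if (!"cell" %in% names(cells)) stop("`cells` needs a `cell` column")
    if (!"row" %in% names(cells)) cells$row <- NA_integer_
    if (!"col" %in% names(cells)) cells$col <- NA_integer_
    if (nrow(cells) != nc) stop("`cells` must have one row per column of `values`")
  }

  if (is.null(mask)) mask <- matrix(TRUE, nt, nc)
  mask <- mask & is.finite(values)
  values[!mask] <- NA_real_

  structure(
    list(variable = variable,
         times = tibble::tibble(year = years, week = weeks),
         cells = cells,
         values = values,
         mask = mask),
    class = "vh_stack"
  )
}

#' @export
print.vh_stack <- function(x, ...) {
  cat(sprintf("<vh_stack> %s: %d weeks (%d-W%02d .. %d-W%02d) x %d cells, %.1f%% valid\n",
              x$variable, n_times(x),
              x$times$year[1], x$times$week[1],
              x$times$year[n_times(x)], x$times$week[n_times(x)],
              n_cells(x), 100 * mean(x$mask)))
  invisible(x)
}

#' @rdname vh_stack
#' @param x a `vh_stack`.
#' @export
n_times <- function(x) nrow(x$values)

#' @rdname vh_stack
#' @export
n_cells <- function(x) ncol(x$values)

#' @export
dim.vh_stack <- function(x) dim(x$values)

#' Convert a stack to a long tibble
#'
#' @param x a `vh_stack`.
#' @param ... unused.
#' @return A tibble with columns `year`, `week`, `cell`, `row`, `col`,
#'   `value` (`NA` where masked).
#' @importFrom tibble as_tibble
#' @method as_tibble vh_stack
#' @export
as_tibble.vh_stack <- function(x, ...) {
  nt <- n_times(x)
  nc <- n_cells(x)
  tibble::tibble(
    year = rep(x$times$year, nc),
    week = rep(x$times$week, nc),
    cell = rep(x$cells$cell, each = nt),
    row = rep(x$cells$row, each = nt),
    col = rep(x$cells$col, each = nt),
    value = as.vector(x$values)
  )
}

#' Build a stack from a long table
#'
#' Accepts the long dialect (`year`, `week`, `cell`, `value`, optionally
#' `row`/`col`). Missing (year, week, cell) combinations and non-finite
#' values become masked entries. ISO week 53 rows are folded into week 52.
#'
#' @param data a data frame in long form.
#' @param variable variable name recorded on the stack.
#' @return A [vh_stack].
#' @export
as_vh_stack <- function(data, variable = "index") {
  data <- tibble::as_tibble(data)
  need <- c("year", "week", "cell", "value")
  if (!all(need %in% names(data))) {
    stop("long stack data needs columns: ", paste(need, collapse = ", "))
  }
  data$week <- pmin(as.integer(data$week), 52L)
  data <- dplyr::summarise(
    dplyr::group_by(data, .data$year, .data$week, .data$cell),
    value = mean(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  data$value[!is.finite(data$value)] <- NA_real_

  coords <- NULL
  if (all(c("row", "col") %in% names(data))) {
    coords <- dplyr::distinct(data, .data$cell, .data$row, .data$col)
  }
  cells <- sort(unique(data$cell))
  times <- dplyr::arrange(dplyr::distinct(data, .data$year, .data$week),
                          .data$year, .data$week)
  wide <- matrix(NA_real_, nrow(times), length(cells))
  ti <- match(paste(data$year, data$week), paste(times$year, times$week))
  ci <- match(data$cell, cells)
  wide[cbind(ti, ci)] <- data$value

  cell_tbl <- tibble::tibble(cell = cells)
  if (!is.null(coords)) {
    cell_tbl <- dplyr::left_join(cell_tbl, coords, by = "cell")
  }
  vh_stack(wide, years = times$year, weeks = times$week, cells = cell_tbl,
           variable = variable)
}

#' Read / write stacks as long CSV
#'
#' The on-disk format is the long dialect: columns `year`, `week`, `cell`,
#' optionally `row`, `col`, and `value`. Masked entries are written as empty
#' fields.
#'
#' @param path file path.
#' @param variable variable name recorded on the stack.
#' @return `read_vh_csv()` returns a [vh_stack]; `write_vh_csv()` returns
#'   `path` invisibly.
#' @export
read_vh_csv <- function(path, variable = "index") {
  df <- utils::read.csv(path)
  as_vh_stack(df, variable = variable)
}

#' @rdname read_vh_csv
#' @param stack a `vh_stack`.
#' @export
write_vh_csv <- function(stack, path) {
  utils::write.csv(as_tibble(stack), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Subset a stack in time
#'
#' @param stack a `vh_stack`.
#' @param idx integer vector of time indices to keep (in order).
#' @return A `vh_stack` over the same cells.
#' @export
stack_time_subset <- function(stack, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= n_times(stack)))
  vh_stack(stack$values[idx, , drop = FALSE],
           years = stack$times$year[idx],
           weeks = stack$times$week[idx],
           cells = stack$cells,
           mask = stack$mask[idx, , drop = FALSE],
           variable = stack$variable)
}

#' Paired VCI/TCI stacks
#'
#' Container for a computed index pair; validates the stated 0--100 range.
#'
#' @param vci,tci `vh_stack`s of the two indices over the same grid.
#' @return An object of class `vh_series` (a named list).
#' @export
vh_series <- function(vci, tci) {
  stopifnot(inherits(vci, "vh_stack"), inherits(tci, "vh_stack"))
  for (s in list(vci, tci)) {
    v <- s$values[s$mask]
    if (length(v) && (min(v) < -1e-9 || max(v) > 100 + 1e-9)) {
      stop("index values must lie in [0, 100]")
    }
  }
  structure(list(vci = vci, tci = tci), class = "vh_series")
}

#' Write a VCI/TCI pair to NetCDF
#'
#' Writes variables `"VCI"` and `"TCI"` as float32 with a fill value at
#' masked entries, on dimensions (week-index, cell). Requires the `ncdf4`
#' package; the long-CSV writer ([write_vh_csv()]) is the portable default.
#'
#' @param series a [vh_series].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vh_netcdf <- function(series, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("write_vh_netcdf() requires the `ncdf4` package")
  }
  vci <- series$vci
  fill <- -9999
  dt <- ncdf4::ncdim_def("time", "week index", seq_len(n_times(vci)))
  dc <- ncdf4::ncdim_def("cell", "cell index", seq_len(n_cells(vci)))
  vv <- ncdf4::ncvar_def("VCI", "percent", list(dt, dc), fill, prec = "float")
  vt <- ncdf4::ncvar_def("TCI", "percent", list(dt, dc), fill, prec = "float")
  vy <- ncdf4::ncvar_def("year", "year", dt, prec = "integer")
  vw <- ncdf4::ncvar_def("week", "week of year", dt, prec = "integer")
  nc <- ncdf4::nc_create(path, list(vv, vt, vy, vw))
  on.exit(ncdf4::nc_close(nc))
  put <- function(var, stack) {
    x <- stack$values
    x[!stack$mask] <- fill
    ncdf4::ncvar_put(nc, var, x)
  }
  put(vv, vci)
  put(vt, series$tci)
  ncdf4::ncvar_put(nc, vy, vci$times$year)
  ncdf4::ncvar_put(nc, vw, vci$times$week)
  invisible(path)
}

#' Read one variable of a NetCDF file written by [write_vh_netcdf()]
#'
#' @param path NetCDF file.
#' @param variable variable name to read (e.g. `"VCI"`).
#' @return A [vh_stack].
#' @export
read_vh_netcdf <- function(path, variable) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("read_vh_netcdf() requires the `ncdf4` package")
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  x <- ncdf4::ncvar_get(nc, variable)
  years <- as.integer(ncdf4::ncvar_get(nc, "year"))
  weeks <- as.integer(ncdf4::ncvar_get(nc, "week"))
  vh_stack(x, years = years, weeks = weeks, variable = variable)
}
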
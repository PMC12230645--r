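#' Define a raster grid
#'
#' A `wl_grid` describes a regular grid of square cells. Cell `(1, 1)` sits at
#' the top-left corner; the vertical axis points downward, so the center of
#' cell `(row, col)` is at `origin + (index - 0.5) * cell_size` on both axes.
#' Two grids are *nested* when their cell sizes differ by an integer factor
#' and their origins coincide; all resampling in this package assumes nested
#' grids (general reprojection is deliberately unsupported).
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Side length of a (square) cell in map units.
#' @param origin_x,origin_y Map coordinates of the top-left grid corner.
#' @param crs_id Opaque coordinate-system identifier carried through outputs.
#' @return An object of class `wl_grid`.
#' @export
wl_grid <- function(n_rows, n_cols, cell_size = 1, origin_x = 0, origin_y = 0,
                    crs_id = "local") {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_id = as.character(crs_id)),
    class = "wl_grid")
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %d x %d cells of %g map units, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$n_rows, b$n_rows)) && isTRUE(all.equal(a$n_cols, b$n_cols)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [wl_grid()].
#' @return A list with numeric vectors `x` (per column) and `y` (per row).
#' @export
grid_centers <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

#' Refine or coarsen a grid by an integer factor
#'
#' Keeps the origin fixed so the result is nested in the input.
#'
#' @param grid A [wl_grid()].
#' @param factor Positive integer.
#' @param direction `"finer"` divides the cell size by `factor`; `"coarser"`
#'   multiplies it (dimensions are rounded up, matching padded aggregation).
#' @return A [wl_grid()].
#' @export
grid_rescale <- function(grid, factor, direction = c("finer", "coarser")) {
  direction <- match.arg(direction)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (direction == "finer")
    wl_grid(grid$n_rows * factor, grid$n_cols * factor, grid$cell_size / factor,
            grid$origin_x, grid$origin_y, grid$crs_id)
  else
    wl_grid(ceiling(grid$n_rows / factor), ceiling(grid$n_cols / factor),
            grid$cell_size * factor, grid$origin_x, grid$origin_y, grid$crs_id)
}

check_values_dim <- function(grid, values) {
  if (!is.matrix(values) || nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("values must be a %d x %d matrix congruent with the grid",
                 grid$n_rows, grid$n_cols))
}

#' Fractional woodland cover map
#'
#' The pipeline's common currency: per-cell woodland cover as a fraction in
#' \[0, 1\] on a [wl_grid()]. `NA` encodes nodata.
#'
#' @param grid A [wl_grid()].
#' @param values Numeric matrix (`n_rows x n_cols`) of fractions; `NA` = nodata.
#' @param epoch_year Integer year the map represents (optional).
#' @return An object of class `wl_cover`.
#' @export
cover_map <- function(grid, values, epoch_year = NA_integer_) {
  check_values_dim(grid, values)
  storage.mode(values) <- "double"
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("cover fractions must lie in [0, 1]")
  structure(list(grid = grid, values = values,
                 epoch_year = as.integer(epoch_year)),
            class = "wl_cover")
}

#' Binary woodland map
#'
#' @param grid A [wl_grid()].
#' @param values Logical matrix: `TRUE` = woodland, `FALSE` = other, `NA` = nodata.
#' @param epoch_year Integer year (optional).
#' @return An object of class `wl_binary`.
#' @export
binary_map <- function(grid, values, epoch_year = NA_integer_) {
  check_values_dim(grid, values)
  if (!is.logical(values)) stop("binary map values must be logical")
  structure(list(grid = grid, values = values,
                 epoch_year = as.integer(epoch_year)),
            class = "wl_binary")
}

#' Categorical land-cover map
#'
#' @param grid A [wl_grid()].
#' @param values Integer matrix of class codes; `NA` = nodata.
#' @param legend Named character vector mapping code (name) to class label,
#'   e.g. `c("1" = "woodland", "2" = "cropland")`. Every non-nodata code must
#'   appear in the legend.
#' @param epoch_year Integer year (optional).
#' @return An object of class `wl_categorical`.
#' @export
categorical_map <- function(grid, values, legend, epoch_year = NA_integer_) {
  check_values_dim(grid, values)
  storage.mode(values) <- "integer"
  codes <- unique(values[!is.na(values)])
  known <- as.integer(names(legend))
  if (length(setdiff(codes, known)))
    stop("map contains codes absent from the legend: ",
         paste(setdiff(codes, known), collapse = ", "))
  structure(list(grid = grid, values = values, legend = legend,
                 epoch_year = as.integer(epoch_year)),
            class = "wl_categorical")
}

#' Multi-epoch cover time series
#'
#' An ordered set of co-registered [cover_map()]s, one per epoch, optionally
#' carrying a persistent non-woodland mask (cells whose cover never exceeds a
#' cutoff in any epoch; see [apply_persistent_nonwoodland_mask()]).
#'
#' @param maps List of `wl_cover` maps sharing one grid.
#' @param epochs Strictly increasing integer years, one per map. Defaults to
#'   the maps' own `epoch_year`s.
#' @return An object of class `wl_series`.
#' @export
cover_series <- function(maps, epochs = vapply(maps, function(m) m$epoch_year, integer(1))) {
  if (!length(maps)) stop("at least one epoch map is required")
  if (length(epochs) != length(maps)) stop("one epoch year per map required")
  if (anyNA(epochs)) stop("every map needs an epoch year")
  if (is.unsorted(epochs, strictly = TRUE)) stop("epochs must be strictly increasing")
  g <- maps[[1L]]$grid
  for (m in maps) {
    if (!inherits(m, "wl_cover")) stop("all series members must be wl_cover maps")
    if (!grids_identical(m$grid, g)) stop("all series maps must share one grid")
  }
  maps <- Map(function(m, e) { m$epoch_year <- as.integer(e); m }, maps, epochs)
  names(maps) <- as.character(epochs)
  structure(list(grid = g, epochs = as.integer(epochs), maps = maps,
                 persistent_nonwoodland_mask = NULL, mask_cutoff = NA_real_),
            class = "wl_series")
}

#' @export
print.wl_series <- function(x, ...) {
  cat(sprintf("<wl_series> %d epochs (%s) on a %d x %d grid; mask %s\n",
              length(x$epochs), paste(x$epochs, collapse = ", "),
              x$grid$n_rows, x$grid$n_cols,
              if (is.null(x$persistent_nonwoodland_mask)) "unset"
              else sprintf("set (cutoff %g)", x$mask_cutoff)))
  invisible(x)
}

# values of a binary/cover map as a double matrix (woodland = 1)
as_fraction_matrix <- function(map) {
  if (inherits(map, "wl_cover")) map$values
  else if (inherits(map, "wl_binary")) {
    v <- map$values * 1.0
    v
  } else stop("expected a wl_cover or wl_binary map")
}

#' Reclassify a categorical map to binary woodland/other
#'
#' Multi-class sources are reduced to woodland vs. other by declaring which
#' class codes count as woodland.
#'
#' @param map A [categorical_map()].
#' @param woodland_codes Integer class codes treated as woodland; must all be
#'   present in the map legend (an unknown code is a configuration error).
#' @return A [binary_map()]; nodata preserved.
#' @export
reclassify_categorical <- function(map, woodland_codes) {
  if (!inherits(map, "wl_categorical")) stop("map must be a wl_categorical")
  woodland_codes <- as.integer(woodland_codes)
  known <- as.integer(names(map$legend))
  bad <- setdiff(woodland_codes, known)
  if (length(bad))
    stop("woodland_codes not in legend: ", paste(bad, collapse = ", "))
  v <- matrix(map$values %in% woodland_codes, nrow(map$values), ncol(map$values))
  v[is.na(map$values)] <- NA
  binary_map(map$grid, v, map$epoch_year)
}

#' Threshold a fractional map into binary woodland/other
#'
#' A cell is woodland iff its fraction is greater than or equal to the
#' threshold (boundary inclusive, so a cell exactly at the threshold counts
#' as woodland).
#'
#' @param map A [cover_map()].
#' @param threshold_pct Threshold in percent, in `(0, 100]`.
#' @return A [binary_map()].
#' @export
binarize_fractional <- function(map, threshold_pct) {
  if (!inherits(map, "wl_cover")) stop("map must be a wl_cover")
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1L ||
      threshold_pct <= 0 || threshold_pct > 100)
    stop("threshold_pct must be a single percent value in (0, 100]")
  binary_map(map$grid, map$values >= threshold_pct / 100, map$epoch_year)
}

#' Aggregate a map to a coarser grid by block means
#'
#' Each coarse cell is the mean of the valid fine cells in its
#' `factor x factor` block (binary maps counted as 1/0). Dimensions that are
#' not divisible by `factor` are padded with nodata at the bottom/right edge.
#' Blocks with at least one valid fine cell average over the valid cells only;
#' all-nodata blocks stay nodata.
#'
#' @param map A [cover_map()] or [binary_map()].
#' @param factor Positive integer aggregation factor.
#' @return A [cover_map()] on the coarsened grid.
#' @export
block_aggregate <- function(map, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer")
  v <- as_fraction_matrix(map)
  g <- map$grid
  nr <- nrow(v); nc <- ncol(v)
  nrp <- as.integer(ceiling(nr / factor) * factor)
  ncp <- as.integer(ceiling(nc / factor) * factor)
  if (nrp != nr || ncp != nc) {
    vp <- matrix(NA_real_, nrp, ncp)
    vp[seq_len(nr), seq_len(nc)] <- v
    v <- vp
  }
  nrc <- nrp %/% factor; ncc <- ncp %/% factor
  # column-major block id so rowsum output reshapes directly into the coarse matrix
  gid <- rep(ceiling(seq_len(nrp) / factor), times = ncp) +
    (rep(ceiling(seq_len(ncp) / factor), each = nrp) - 1L) * nrc
  vv <- as.vector(v)
  ok <- !is.na(vv)
  sums <- rowsum(ifelse(ok, vv, 0), gid)
  cnts <- rowsum(as.numeric(ok), gid)
  out <- as.vector(sums / cnts)
  out[as.vector(cnts) == 0] <- NA_real_
  cover_map(grid_rescale(g, factor, "coarser"), matrix(out, nrc, ncc),
            map$epoch_year)
}

#' Nearest-neighbor resampling onto a target grid
#'
#' Each target cell takes the value of the source cell containing the target
#' cell's center; nodata propagates. Target cells whose centers fall outside
#' the source extent become nodata; fully disjoint extents yield an all-nodata
#' map with a warning.
#'
#' @param map A [cover_map()].
#' @param target A [wl_grid()].
#' @return A [cover_map()] on `target`.
#' @export
nearest_resample <- function(map, target) {
  if (!inherits(map, "wl_cover")) stop("map must be a wl_cover")
  g <- map$grid
  ctr <- grid_centers(target)
  src_col <- floor((ctr$x - g$origin_x) / g$cell_size) + 1
  src_row <- floor((ctr$y - g$origin_y) / g$cell_size) + 1
  rr <- ifelse(src_row >= 1 & src_row <= g$n_rows, src_row, g$n_rows + 1L)
  cc <- ifelse(src_col >= 1 & src_col <= g$n_cols, src_col, g$n_cols + 1L)
  vext <- rbind(cbind(map$values, NA_real_), NA_real_)
  out <- vext[rr, cc, drop = FALSE]
  if (all(is.na(out)))
    warning("target grid is disjoint from the map extent; returning all-nodata")
  cover_map(target, out, map$epoch_year)
}

#' Mask persistent non-woodland cells in a time series
#'
#' Cells whose cover is less than or equal to `cutoff` in *every* epoch are
#' flagged persistent non-woodland and excluded from all downstream statistics
#' (the conventional reading that woodland begins strictly above the cutoff).
#' The operation is idempotent.
#'
#' @param series A [cover_series()].
#' @param cutoff Cover fraction, default `0.05` (the 5 percent rule).
#' @return The series with `persistent_nonwoodland_mask` set (`TRUE` = masked).
#' @export
apply_persistent_nonwoodland_mask <- function(series, cutoff = 0.05) {
  if (!inherits(series, "wl_series")) stop("series must be a wl_series")
  mask <- matrix(TRUE, series$grid$n_rows, series$grid$n_cols)
  for (m in series$maps) {
    v <- m$values
    le <- v <= cutoff
    le[is.na(le)] <- TRUE   # nodata never vetoes the mask
    mask <- mask & le
  }
  all_na <- Reduce(`&`, lapply(series$maps, function(m) is.na(m$values)))
  mask[all_na] <- NA       # cells with no data in any epoch are nodata, not masked
  series$persistent_nonwoodland_mask <- mask
  series$mask_cutoff <- cutoff
  series
}

# logical matrix of cells usable for statistics: not masked, not all-NA
series_active_cells <- function(series) {
  if (is.null(series$persistent_nonwoodland_mask))
    return(!Reduce(`&`, lapply(series$maps, function(m) is.na(m$values))))
  m <- series$persistent_nonwoodland_mask
  act <- !m
  act[is.na(m)] <- FALSE
  act
}
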
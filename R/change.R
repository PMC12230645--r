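#' Pixel-wise cover change between two epochs
#'
#' Change is reported in absolute percentage points,
#' `(cover(y2) - cover(y1)) * 100`, matching change-map legends of absolute
#' percent change (a drop from 80% to 55% cover is -25 points). Relative
#' change, `(cover(y2) - cover(y1)) / cover(y1) * 100`, is available as a
#' clearly labelled alternative. Persistent non-woodland cells are nodata.
#'
#' @param series A [cover_series()] (mask applied if present).
#' @param y1,y2 Epoch years, both present in `series$epochs`.
#' @param relative If `TRUE`, report relative change instead of points.
#' @return A list of class `wl_change_map`: `grid`, `values` (matrix),
#'   `epoch_pair`, `units`.
#' @export
change_map <- function(series, y1, y2, relative = FALSE) {
  for (y in c(y1, y2))
    if (!y %in% series$epochs)
      stop("epoch ", y, " not in series; available: ",
           paste(series$epochs, collapse = ", "))
  v1 <- series$maps[[as.character(y1)]]$values
  v2 <- series$maps[[as.character(y2)]]$values
  vals <- if (relative) (v2 - v1) / v1 * 100 else (v2 - v1) * 100
  act <- series_active_cells(series)
  vals[!act] <- NA_real_
  structure(list(grid = series$grid, values = vals,
                 epoch_pair = c(y1, y2),
                 units = if (relative) "percent (relative)" else "percentage points"),
            class = "wl_change_map")
}

#' Woodland area of a cover map
#'
#' Two accounting modes: `"fractional_sum"` integrates the cover fraction over
#' unmasked cells (`sum(fraction) * cell_area`); `"binary_threshold"` counts
#' cells at/above a percent threshold (`count * cell_area`). Both agree
#' exactly on {0,1}-valued maps.
#'
#' @param map A [cover_map()].
#' @param mode Accounting mode.
#' @param threshold_pct Threshold for `"binary_threshold"` (default 20, the
#'   usual best screening threshold).
#' @param active Optional logical matrix restricting the accounting (e.g. from
#'   a persistent non-woodland mask).
#' @return Area in squared map units.
#' @export
woodland_area <- function(map, mode = c("fractional_sum", "binary_threshold"),
                          threshold_pct = 20, active = NULL) {
  mode <- match.arg(mode)
  v <- map$values
  if (!is.null(active)) v[!active] <- NA
  cell_area <- map$grid$cell_size^2
  if (mode == "fractional_sum") sum(v, na.rm = TRUE) * cell_area
  else sum(v >= threshold_pct / 100, na.rm = TRUE) * cell_area
}

#' Per-period woodland area accounting
#'
#' Tabulates woodland area per epoch and the net change over every
#' consecutive period plus the full series, with percent-of-period-start
#' values. Consecutive period changes telescope exactly to the full-series
#' net change.
#'
#' @param series A [cover_series()].
#' @param mode,threshold_pct Passed to [woodland_area()].
#' @param area_scale Multiplier applied to areas (e.g. to express unit cells
#'   as Mha analogs); purely presentational.
#' @return A list of class `wl_area_account`: `epoch_areas` (data.frame
#'   `epoch`, `area`), `periods` (data.frame `start_year`, `end_year`,
#'   `area_start`, `area_end`, `net_change`, `pct_change`; last row is the
#'   full series), `mode`.
#' @export
period_change_table <- function(series, mode = c("fractional_sum", "binary_threshold"),
                                threshold_pct = 20, area_scale = 1) {
  mode <- match.arg(mode)
  if (length(series$epochs) < 2) stop("at least two epochs are required")
  act <- series_active_cells(series)
  areas <- vapply(series$maps, woodland_area, numeric(1),
                  mode = mode, threshold_pct = threshold_pct, active = act)
  areas <- areas * area_scale
  ne <- length(areas)
  per <- data.frame(start_year = series$epochs[-ne], end_year = series$epochs[-1],
                    area_start = areas[-ne], area_end = areas[-1])
  full <- data.frame(start_year = series$epochs[1], end_year = series$epochs[ne],
                     area_start = areas[1], area_end = areas[ne])
  per <- rbind(per, full)
  per$net_change <- per$area_end - per$area_start
  per$pct_change <- ifelse(per$area_start > 0,
                           per$net_change / per$area_start * 100, NA_real_)
  rownames(per) <- NULL
  structure(list(epoch_areas = data.frame(epoch = series$epochs, area = areas,
                                          row.names = NULL),
                 periods = per, mode = mode),
            class = "wl_area_account")
}

#' Net area change between two arbitrary epochs
#'
#' @inheritParams period_change_table
#' @param y1,y2 Epoch years.
#' @return One-row data.frame like the `periods` table of
#'   [period_change_table()].
#' @export
period_change <- function(series, y1, y2,
                          mode = c("fractional_sum", "binary_threshold"),
                          threshold_pct = 20, area_scale = 1) {
  mode <- match.arg(mode)
  act <- series_active_cells(series)
  a <- vapply(c(y1, y2), function(y) {
    if (!y %in% series$epochs)
      stop("epoch ", y, " not in series; available: ",
           paste(series$epochs, collapse = ", "))
    woodland_area(series$maps[[as.character(y)]], mode, threshold_pct, act) * area_scale
  }, numeric(1))
  data.frame(start_year = y1, end_year = y2, area_start = a[1], area_end = a[2],
             net_change = a[2] - a[1],
             pct_change = if (a[1] > 0) (a[2] - a[1]) / a[1] * 100 else NA_real_)
}

#' Ecoregion cover trajectories
#'
#' Per ecoregion and epoch: mean and population SD of the cover of unmasked
#' cells, plus woodland area (fractional accounting). Cells, not areas, are
#' the statistical unit.
#'
#' @param series A [cover_series()].
#' @param ecoregion_labels Integer matrix co-registered with the series grid.
#' @return A `data.frame` (`ecoregion`, `epoch`, `mean_cover`, `sd_cover`,
#'   `n_cells`, `area`) of class `wl_ecoregion_trajectory`.
#' @export
ecoregion_trajectory <- function(series, ecoregion_labels) {
  g <- series$grid
  if (!is.matrix(ecoregion_labels) || nrow(ecoregion_labels) != g$n_rows ||
      ncol(ecoregion_labels) != g$n_cols)
    stop("ecoregion label raster does not match the series grid")
  act <- series_active_cells(series)
  cell_area <- g$cell_size^2
  regions <- sort(unique(ecoregion_labels[!is.na(ecoregion_labels)]))
  out <- do.call(rbind, lapply(series$epochs, function(y) {
    v <- series$maps[[as.character(y)]]$values
    do.call(rbind, lapply(regions, function(rg) {
      sel <- ecoregion_labels == rg & act & !is.na(v)
      x <- v[sel]
      n <- length(x)
      data.frame(ecoregion = rg, epoch = y,
                 mean_cover = if (n) mean(x) else NA_real_,
                 sd_cover = if (n) sqrt(mean((x - mean(x))^2)) else NA_real_,
                 n_cells = n, area = sum(x) * cell_area)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("wl_ecoregion_trajectory", "data.frame")
  out
}
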
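#' Construct a species range object
#'
#' @param species_id Species identifier.
#' @param presence Logical matrix on the coarse grid (`TRUE` = present).
#' @param threatened Logical threat-group flag (threatened = critically
#'   endangered, endangered or vulnerable; non-threatened = near threatened or
#'   least concern).
#' @param grid The coarse [wl_grid()].
#' @return An object of class `wl_species_range`.
#' @export
species_range <- function(species_id, presence, threatened, grid) {
  check_values_dim(grid, presence)
  if (!any(presence, na.rm = TRUE))
    stop("species '", species_id, "' has no presence cells")
  structure(list(species_id = species_id, presence = presence,
                 threatened = isTRUE(threatened), grid = grid),
            class = "wl_species_range")
}

# even-odd ray-casting point-in-polygon; poly = matrix with columns x, y
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a species range onto the coarse grid
#'
#' Input is either a simple polygon (two-column vertex matrix, implicitly
#' closed) or a fine-resolution presence mask on a nested finer grid. Under
#' the default `"center"` rule a coarse cell is present iff its center falls
#' inside the polygon (or in a present fine cell); `"any_overlap"` marks a
#' coarse cell present if any fine cell in its block is present (mask input
#' only).
#'
#' @param geometry Two-column numeric matrix of polygon vertices, or a
#'   [binary_map()] presence mask on a finer nested grid.
#' @param coarse_grid Target [wl_grid()].
#' @param species_id,threatened Metadata for the resulting range.
#' @param rule `"center"` or `"any_overlap"`.
#' @return A [species_range()].
#' @export
rasterize_range <- function(geometry, coarse_grid, species_id,
                            threatened = FALSE,
                            rule = c("center", "any_overlap")) {
  rule <- match.arg(rule)
  ctr <- grid_centers(coarse_grid)
  if (is.matrix(geometry) && !inherits(geometry, "wl_binary")) {
    if (rule == "any_overlap")
      stop("any_overlap rule requires a fine presence mask, not a polygon")
    px <- rep(ctr$x, each = coarse_grid$n_rows)
    py <- rep(ctr$y, times = coarse_grid$n_cols)
    pres <- matrix(point_in_polygon(px, py, geometry),
                   coarse_grid$n_rows, coarse_grid$n_cols)
  } else if (inherits(geometry, "wl_binary")) {
    fine <- cover_map(geometry$grid,
                      ifelse(is.na(geometry$values), NA_real_, geometry$values * 1))
    if (rule == "center") {
      res <- nearest_resample(fine, coarse_grid)
      pres <- !is.na(res$values) & res$values > 0
    } else {
      factor <- round(coarse_grid$cell_size / geometry$grid$cell_size)
      agg <- block_aggregate(geometry, factor)
      pres <- !is.na(agg$values) & agg$values > 0
    }
  } else stop("geometry must be a vertex matrix or a wl_binary mask")
  if (!any(pres))
    stop("range of species '", species_id, "' does not intersect the grid")
  species_range(species_id, pres, threatened, coarse_grid)
}

#' Species richness map
#'
#' Per-cell count of group members present (the sum of the individual
#' presence/absence maps).
#'
#' @param ranges List of [species_range()]s sharing one grid.
#' @param group `"all"`, `"threatened"` or `"non_threatened"`.
#' @return A list of class `wl_richness`: `grid`, `values` (integer matrix),
#'   `group`, `n_species`.
#' @export
richness <- function(ranges, group = c("all", "threatened", "non_threatened")) {
  group <- match.arg(group)
  if (!length(ranges)) stop("at least one range is required")
  g <- ranges[[1]]$grid
  sel <- switch(group,
    all = ranges,
    threatened = Filter(function(r) r$threatened, ranges),
    non_threatened = Filter(function(r) !r$threatened, ranges))
  vals <- matrix(0L, g$n_rows, g$n_cols)
  for (r in sel) {
    if (!grids_identical(r$grid, g)) stop("ranges must share one grid")
    vals <- vals + r$presence
  }
  structure(list(grid = g, values = vals, group = group,
                 n_species = length(sel)),
            class = "wl_richness")
}

#' Pearson correlation between richness and cover
#'
#' Standard Pearson r with a two-sided p-value from the t transform. By
#' default the correlation runs over all unmasked coarse cells of the study
#' area (richness 0 is informative); `domain = "presence"` restricts to cells
#' where at least one species of the group is present.
#'
#' @param rich A [richness()] map.
#' @param cover A [cover_map()] on the same coarse grid.
#' @param domain `"all"` or `"presence"`.
#' @param active Optional logical matrix of study-area cells to include.
#' @return A list of class `wl_correlation`: `r`, `p`, `n`, `group`, `domain`.
#' @export
richness_cover_correlation <- function(rich, cover,
                                       domain = c("all", "presence"),
                                       active = NULL) {
  domain <- match.arg(domain)
  if (!grids_identical(rich$grid, cover$grid))
    stop("richness and cover grids differ")
  keep <- !is.na(cover$values)
  if (!is.null(active)) keep <- keep & active
  if (domain == "presence") keep <- keep & rich$values > 0
  x <- cover$values[keep]
  y <- rich$values[keep]
  if (length(x) < 3) stop("need at least 3 valid paired cells")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in ",
         if (stats::sd(x) == 0) "cover" else "richness")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 group = rich$group, domain = domain),
            class = "wl_correlation")
}

#' Mean cover trajectory inside a species range
#'
#' @param range A [species_range()].
#' @param series A coarse-grid [cover_series()].
#' @return `data.frame` with `species_id`, `epoch`, `mean_cover`, `n_cells`.
#' @export
range_cover_trajectory <- function(range, series) {
  if (!grids_identical(range$grid, series$grid))
    stop("range and series grids differ")
  out <- do.call(rbind, lapply(series$epochs, function(y) {
    v <- series$maps[[as.character(y)]]$values
    sel <- range$presence & !is.na(v)
    data.frame(species_id = range$species_id, epoch = y,
               mean_cover = mean(v[sel]), n_cells = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Archetype composition of a species range
#'
#' Share of the range's presence cells falling into each archetype; shares
#' sum to 1 over cells with an archetype label.
#'
#' @param range A [species_range()].
#' @param labels Archetype label map ([categorical_map()] or integer matrix)
#'   on the same grid.
#' @return `data.frame` with `species_id`, `archetype`, `n_cells`, `share`.
#' @export
archetype_composition <- function(range, labels) {
  lv <- if (inherits(labels, "wl_categorical")) labels$values else labels
  if (!is.matrix(lv) || !all(dim(lv) == c(range$grid$n_rows, range$grid$n_cols)))
    stop("label raster does not match the range grid")
  sel <- range$presence & !is.na(lv)
  counts <- table(factor(lv[sel], levels = sort(unique(lv[!is.na(lv)]))))
  total <- sum(counts)
  data.frame(species_id = range$species_id,
             archetype = as.integer(names(counts)),
             n_cells = as.integer(counts),
             share = if (total > 0) as.numeric(counts) / total else NA_real_,
             row.names = NULL)
}

#' Median species richness per archetype
#'
#' Even-count medians use the midpoint convention. Archetypes with zero
#' labelled cells are reported with `NA` (empty), not 0.
#'
#' @param rich A [richness()] map.
#' @param labels Archetype label map on the same grid.
#' @return `data.frame` with `archetype`, `n_cells`, `median_richness`.
#' @export
median_richness_per_archetype <- function(rich, labels) {
  lv <- if (inherits(labels, "wl_categorical")) labels$values else labels
  if (!is.matrix(lv) || !all(dim(lv) == dim(rich$values)))
    stop("label raster does not match the richness grid")
  archetypes <- sort(unique(lv[!is.na(lv)]))
  out <- do.call(rbind, lapply(archetypes, function(a) {
    sel <- !is.na(lv) & lv == a
    data.frame(archetype = a, n_cells = sum(sel),
               median_richness = if (any(sel))
                 stats::median(rich$values[sel]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
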
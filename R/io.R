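#' Read and write rasters as ESRI ASCII grids
#'
#' All map types round-trip through the plain-text ESRI ASCII grid format
#' (`.asc`): a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by one whitespace-separated row of
#' values per grid row, top row first. Because this package's vertical axis
#' points downward from the origin, `yllcorner` is written as
#' `origin_y + n_rows * cell_size` read back verbatim; round-trips are exact.
#' Metadata that a GeoTIFF would carry in tags (epoch year, class legend,
#' crs id, map kind) is stored in a JSON sidecar `<path>.json`.
#'
#' @param map A `wl_cover`, `wl_binary` or `wl_categorical` map.
#' @param path Output path (conventionally ending in `.asc`).
#' @param digits Significant digits for fractional values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(map, path, digits = 10) {
  g <- map$grid
  kind <- class(map)[1]
  v <- map$values
  if (kind == "wl_binary") v <- ifelse(is.na(v), NA_real_, v * 1)
  nodata <- -9999
  vv <- ifelse(is.na(v), nodata, v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y + g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %d", nodata)), con)
  write.table(format(vv, digits = digits, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(kind = kind, crs_id = g$crs_id,
               origin_y_convention = "top-left, axis down")
  if (!is.na(map$epoch_year)) meta$epoch_year <- map$epoch_year
  if (kind == "wl_categorical") meta$legend <- as.list(map$legend)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_asc
#' @param crs_id Coordinate-system identifier to attach when the sidecar is
#'   missing.
#' @export
read_asc <- function(path, crs_id = "local") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  kind <- meta$kind %||% "wl_cover"
  g <- wl_grid(h[["nrows"]], h[["ncols"]], h[["cellsize"]],
               h[["xllcorner"]],
               h[["yllcorner"]] - h[["nrows"]] * h[["cellsize"]],
               crs_id = meta$crs_id %||% crs_id)
  epoch <- as.integer(meta$epoch_year %||% NA_integer_)
  switch(kind,
    wl_cover = cover_map(g, m, epoch),
    wl_binary = binary_map(g, matrix(as.logical(m), nrow(m), ncol(m)), epoch),
    wl_categorical = {
      leg <- unlist(meta$legend)
      categorical_map(g, m, leg, epoch)
    },
    cover_map(g, m, epoch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
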
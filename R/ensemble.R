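#' Accuracy-weighted ensemble cover map
#'
#' Combines screened source maps into one consensus fractional cover map,
#' weighting each source's cover by the user's accuracy of its woodland class:
#'
#' \deqn{WL_E = \frac{\sum_{i=1}^{n} UA_i \, WL_i}{n}}
#'
#' Two normalizations are provided. `"as_printed"` divides by the source count
#' `n` (the formula exactly as published, which shrinks toward zero when
#' accuracies are below 1). `"weight_normalized"` divides by \eqn{\sum UA_i},
#' giving a proper convex weighted average; the surrounding description — an
#' average weighted by user's accuracy — arguably intends this. Which one the
#' original computation used cannot be determined, so neither is asserted as
#' such; the mode is recorded in the result.
#'
#' At cells where some sources are nodata, the sum and the denominator are
#' restricted to the valid sources; cells with no valid source are nodata.
#'
#' @param sources Non-empty list of `wl_source` objects with `ua_weight` set
#'   and co-registered `cover` maps.
#' @param mode `"as_printed"` or `"weight_normalized"`.
#' @return A list of class `wl_ensemble`: `cover` ([cover_map()]), `n_sources`,
#'   `mode`, `weights`.
#' @export
ensemble_cover <- function(sources, mode = c("as_printed", "weight_normalized")) {
  mode <- match.arg(mode)
  if (!length(sources)) stop("at least one source is required")
  g <- sources[[1]]$cover$grid
  ua <- vapply(sources, `[[`, numeric(1), "ua_weight")
  if (anyNA(ua) || any(ua <= 0) || any(ua > 1))
    stop("every source needs a ua_weight in (0, 1] (run screening first)")
  num <- matrix(0, g$n_rows, g$n_cols)
  den <- matrix(0, g$n_rows, g$n_cols)
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    if (!grids_identical(src$cover$grid, g))
      stop("source '", src$name, "' is not co-registered with the others")
    v <- src$cover$values
    valid <- !is.na(v)
    v[!valid] <- 0
    num <- num + ua[i] * v
    den <- den + if (mode == "as_printed") valid * 1 else valid * ua[i]
  }
  vals <- num / den
  vals[den == 0] <- NA_real_
  if (mode == "as_printed") vals <- pmin(vals, 1)  # guard fp round-up; bounded by sum(UA)/n <= 1 anyway
  structure(list(cover = cover_map(g, vals, sources[[1]]$cover$epoch_year),
                 n_sources = length(sources), mode = mode,
                 weights = stats::setNames(ua, vapply(sources, `[[`, character(1), "name"))),
            class = "wl_ensemble")
}
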
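#' Fuse two observers' cover-interval estimates
#'
#' Each observer reports the 10 percent interval containing their cover
#' estimate (identified by its lower bound: 0, 10, ..., 90). An interval is
#' represented by its midpoint; the fused value is the mean of the two
#' midpoints rounded to the nearest 5 percent, ties rounding half up.
#'
#' @param a_interval,b_interval Interval lower bounds in `{0, 10, ..., 90}`
#'   (vectorized).
#' @return Fused cover in percent, a multiple of 5 in `{0, 5, ..., 100}`.
#' @export
fuse_observers <- function(a_interval, b_interval) {
  ok <- function(v) all(v %in% seq(0, 90, by = 10))
  if (!ok(a_interval) || !ok(b_interval))
    stop("observer intervals must be lower bounds of 10% bins: 0, 10, ..., 90")
  mids <- ((a_interval + 5) + (b_interval + 5)) / 2
  floor(mids / 5 + 0.5) * 5
}

#' Binary error matrix with accuracy measures
#'
#' Cross-tabulates reference against predicted woodland labels and derives
#' overall accuracy (OA), user's accuracy of the woodland class
#' (UA = tp / (tp + fp)) and producer's accuracy (PA = tp / (tp + fn)).
#' UA (or PA) is `NA` — flagged undefined, not scored 0 — when nothing is
#' predicted (or referenced) as woodland.
#'
#' @param reference,predicted Logical vectors of equal length (`TRUE` =
#'   woodland).
#' @return An object of class `wl_error_matrix` with fields `tp`, `fp`, `fn`,
#'   `tn`, `n`, `oa`, `ua`, `pa`.
#' @export
error_matrix <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length")
  if (!length(reference)) stop("at least one sample is required")
  keep <- !(is.na(reference) | is.na(predicted))
  reference <- reference[keep]; predicted <- predicted[keep]
  tp <- sum(reference & predicted)
  fp <- sum(!reference & predicted)
  fn <- sum(reference & !predicted)
  tn <- sum(!reference & !predicted)
  n <- tp + fp + fn + tn
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    oa = (tp + tn) / n,
    ua = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    pa = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
    class = "wl_error_matrix")
}

#' @export
print.wl_error_matrix <- function(x, ...) {
  cat(sprintf("<error matrix> n=%d tp=%d fp=%d fn=%d tn=%d | OA=%.3f UA=%s PA=%s\n",
              x$n, x$tp, x$fp, x$fn, x$tn, x$oa,
              ifelse(is.na(x$ua), "undef", sprintf("%.3f", x$ua)),
              ifelse(is.na(x$pa), "undef", sprintf("%.3f", x$pa))))
  invisible(x)
}

# map a sample's coordinates to its containing cell; errors if outside extent
locate_samples <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1
  if (any(row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols))
    stop("validation samples fall outside the map extent")
  cbind(row, col)
}

#' Sweep binarization thresholds against a validation set
#'
#' For every threshold, both the fused reference fractions and the map's
#' fractions are binarized at that threshold and cross-tabulated with
#' [error_matrix()]. The best threshold maximizes the woodland user's
#' accuracy; ties break to the smallest threshold, and thresholds whose UA is
#' undefined (no predicted woodland) are disqualified from selection.
#'
#' @param map A [cover_map()] under evaluation.
#' @param samples A `wl_validation` data frame (needs `x`, `y`, `fused_pct`).
#' @param thresholds Percent thresholds to test (default 15:22).
#' @return A `data.frame` of class `wl_accuracy_table` with one row per
#'   threshold (`threshold`, `tp`, `fp`, `fn`, `tn`, `oa`, `ua`, `pa`,
#'   `is_best`) and attribute `best_threshold`.
#' @export
threshold_sweep <- function(map, samples, thresholds = 15:22) {
  if (!length(thresholds)) stop("threshold sweep must be non-empty")
  if (inherits(map, "wl_source")) map <- map$cover
  if (!inherits(map, "wl_cover")) stop("map must be a wl_cover or wl_source")
  rc <- locate_samples(map$grid, samples$x, samples$y)
  map_frac <- map$values[rc]
  rows <- lapply(thresholds, function(t) {
    ref <- samples$fused_pct >= t
    pred <- map_frac >= t / 100
    em <- error_matrix(ref, pred)
    data.frame(threshold = t, tp = em$tp, fp = em$fp, fn = em$fn, tn = em$tn,
               oa = em$oa, ua = em$ua, pa = em$pa)
  })
  tab <- do.call(rbind, rows)
  defined <- which(!is.na(tab$ua))
  best <- if (length(defined)) tab$threshold[defined[which.max(tab$ua[defined])]]
          else NA_real_
  # which.max returns the first maximum; thresholds ascend, so ties break small
  tab$is_best <- !is.na(best) & tab$threshold == best
  attr(tab, "best_threshold") <- best
  class(tab) <- c("wl_accuracy_table", "data.frame")
  tab
}

#' Screen candidate maps by accuracy floors
#'
#' A source is retained iff, at its best threshold, overall accuracy is at
#' least `oa_min` and woodland user's accuracy at least `ua_min`. Retained
#' sources carry their UA forward as the ensemble weight.
#'
#' @param sources List of `wl_source` objects.
#' @param tables List of [threshold_sweep()] tables, parallel to `sources`.
#' @param oa_min,ua_min Accuracy floors (defaults 0.70 and 0.90).
#' @return The retained subset of `sources`, each with `ua_weight` and
#'   `best_threshold` filled in; attribute `screening` holds the full decision
#'   table.
#' @export
screen_maps <- function(sources, tables, oa_min = 0.70, ua_min = 0.90) {
  if (length(sources) != length(tables))
    stop("one accuracy table per source is required")
  dec <- do.call(rbind, Map(function(src, tab) {
    bt <- attr(tab, "best_threshold")
    if (is.na(bt)) return(data.frame(source = src$name, best_threshold = NA_real_,
                                     oa = NA_real_, ua = NA_real_, retained = FALSE))
    row <- tab[tab$threshold == bt, ]
    data.frame(source = src$name, best_threshold = bt, oa = row$oa, ua = row$ua,
               retained = row$oa >= oa_min && !is.na(row$ua) && row$ua >= ua_min)
  }, sources, tables))
  kept <- Map(function(src, i) {
    src$ua_weight <- dec$ua[i]
    src$best_threshold <- dec$best_threshold[i]
    src
  }, sources, seq_along(sources))[dec$retained]
  attr(kept, "screening") <- dec
  kept
}
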
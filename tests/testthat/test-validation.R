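test_that("fuse_observers averages bin midpoints and rounds to nearest 5", {
  expect_equal(fuse_observers(20, 20), 25)   # identical observers -> midpoint
  expect_equal(fuse_observers(20, 30), 30)   # 25 & 35 -> 30 exactly
  expect_error(fuse_observers(25, 20), "intervals")
  # exhaustive oracle over all 100 bin pairs
  bins <- seq(0, 90, by = 10)
  for (a in bins) for (b in bins) {
    mid <- ((a + 5) + (b + 5)) / 2
    lo <- floor(mid / 5) * 5; hi <- ceiling(mid / 5) * 5
    exp5 <- if (mid - lo < hi - mid) lo else if (hi - mid < mid - lo) hi else hi # ties up
    expect_equal(fuse_observers(a, b), exp5)
  }
})

test_that("error_matrix counts and accuracies match hand counts", {
  w <- TRUE; o <- FALSE
  em <- error_matrix(c(w, w, o, o), c(w, w, o, o))
  expect_equal(c(em$oa, em$ua, em$pa), c(1, 1, 1))
  em2 <- error_matrix(c(w, w, o, o), c(w, o, w, o))
  expect_equal(c(em2$tp, em2$fn, em2$fp, em2$tn), c(1, 1, 1, 1))
  expect_equal(em2$oa, 0.5); expect_equal(em2$ua, 0.5)
  expect_error(error_matrix(c(w, o), c(w)), "equal length")
  # UA undefined (not zero) when nothing is predicted woodland
  em3 <- error_matrix(c(w, o), c(o, o))
  expect_true(is.na(em3$ua))
  expect_equal(em3$oa, 0.5)
})

test_that("error_matrix agrees with four independent counting loops", {
  set.seed(33)
  ref <- runif(500) > 0.6
  pred <- runif(500) > 0.5
  em <- error_matrix(ref, pred)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:500) {
    if (ref[i] && pred[i]) tp <- tp + 1
    if (!ref[i] && pred[i]) fp <- fp + 1
    if (ref[i] && !pred[i]) fn <- fn + 1
    if (!ref[i] && !pred[i]) tn <- tn + 1
  }
  expect_equal(c(em$tp, em$fp, em$fn, em$tn), c(tp, fp, fn, tn))
  expect_equal(em$n, 500)
  expect_equal(em$oa, (tp + tn) / 500)
  expect_equal(em$ua, tp / (tp + fp))
  expect_equal(em$pa, tp / (tp + fn))
})

test_that("UA never rises when false positives are injected", {
  set.seed(9)
  ref <- runif(200) > 0.5
  pred <- ref
  base <- error_matrix(ref, pred)$ua
  ua_prev <- base
  for (extra in c(5, 20, 50)) {
    ref2 <- c(ref, rep(FALSE, extra))
    pred2 <- c(pred, rep(TRUE, extra))
    ua <- error_matrix(ref2, pred2)$ua
    expect_lte(ua, ua_prev)
    ua_prev <- ua
  }
})

# a toy validation frame over a map's cells
toy_samples <- function(map, fused_pct) {
  ctr <- grid_centers(map$grid)
  n <- map$grid$n_rows * map$grid$n_cols
  out <- data.frame(x = rep(ctr$x, each = map$grid$n_rows),
                    y = rep(ctr$y, times = map$grid$n_cols),
                    fused_pct = fused_pct)
  out[seq_len(nrow(out)), , drop = FALSE]
}

test_that("threshold_sweep: perfect map gives UA 1 everywhere, tie to 15", {
  # map values sit well away from the 15-22% band, so reference and map agree
  # at every threshold in the sweep
  m <- mk_cover(matrix(rep(c(0.05, 0.30, 0.50, 0.90), length.out = 25), 5, 5))
  s <- toy_samples(m, as.vector(m$values) * 100)
  tab <- threshold_sweep(m, s, 15:22)
  expect_true(all(tab$ua == 1))
  expect_true(all(tab$oa == 1))
  expect_equal(attr(tab, "best_threshold"), 15)
})

test_that("threshold_sweep boundary walk matches the spec example", {
  m <- mk_cover(matrix(0.18, 1, 1))
  s <- toy_samples(m, 25)
  tab <- threshold_sweep(m, s, 15:22)
  for (t in 15:18) {
    row <- tab[tab$threshold == t, ]
    expect_equal(row$tp, 1)   # 0.18 >= t/100 up to t = 18 (inclusive boundary)
  }
  for (t in 19:22) {
    row <- tab[tab$threshold == t, ]
    expect_equal(row$fn, 1)
    expect_true(is.na(row$ua))  # nothing predicted woodland -> UA undefined
  }
  expect_equal(attr(tab, "best_threshold"), 15)
})

test_that("threshold_sweep equals a direct per-threshold recomputation", {
  g <- mk_grid(30, 30)
  tr <- generate_truth_series(two_templates(0.05), g, epochs = 2014:2020, seed = 3)
  truth2020 <- tr$series$maps[["2020"]]
  sp <- source_spec("s", 1, "binary", 0.1, 0.08)
  src <- generate_source_maps(tr$series, list(sp), 2020, seed = 5)[[1]]
  s <- generate_observer_samples(truth2020, 80, min_dist = 1.5, seed = 7)
  tab <- threshold_sweep(src$cover, s, 15:22)
  for (t in 15:22) {
    ref <- s$fused_pct >= t
    pred <- src$cover$values[cbind(s$row, s$col)] >= t / 100
    em <- error_matrix(ref, pred)
    row <- tab[tab$threshold == t, ]
    expect_equal(c(row$tp, row$fp, row$fn, row$tn), c(em$tp, em$fp, em$fn, em$tn))
    expect_equal(row$oa, em$oa)
  }
  # invariant to sample order
  perm <- sample(nrow(s))
  tab2 <- threshold_sweep(src$cover, s[perm, ], 15:22)
  expect_equal(tab$ua, tab2$ua)
  expect_equal(attr(tab, "best_threshold"), attr(tab2, "best_threshold"))
  expect_error(threshold_sweep(src$cover, s, numeric(0)), "non-empty")
})

test_that("screen_maps applies the OA/UA conjunction at the best threshold", {
  mk_tab <- function(oa, ua, best = 20) {
    tab <- data.frame(threshold = best, tp = 1, fp = 0, fn = 0, tn = 1,
                      oa = oa, ua = ua, pa = 1, is_best = TRUE)
    attr(tab, "best_threshold") <- best
    class(tab) <- c("wl_accuracy_table", "data.frame")
    tab
  }
  mk_src <- function(nm) structure(list(name = nm, cover = NULL,
                                        ua_weight = NA, best_threshold = NA),
                                   class = "wl_source")
  # the published passing map: OA 90%, UA 97%
  srcs <- list(mk_src("good"), mk_src("low_oa"), mk_src("low_ua"))
  tabs <- list(mk_tab(0.90, 0.97), mk_tab(0.69, 0.99), mk_tab(0.95, 0.89))
  kept <- screen_maps(srcs, tabs)
  expect_equal(vapply(kept, `[[`, character(1), "name"), "good")
  expect_equal(kept[[1]]$ua_weight, 0.97)
  # random tables vs a direct conjunction oracle
  set.seed(17)
  for (rep in 1:20) {
    oa <- runif(1); ua <- runif(1)
    kept <- screen_maps(list(mk_src("x")), list(mk_tab(oa, ua)))
    expect_equal(length(kept) == 1, oa >= 0.70 && ua >= 0.90)
  }
})
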
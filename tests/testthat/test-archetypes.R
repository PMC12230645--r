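# pure-R sequential competitive learning: the independent oracle for the
# radius-0 SOM (winner-only updates, same linear lr decay)
competitive_oracle <- function(X, init, order0, lr_start, lr_end) {
  W <- init
  nsteps <- length(order0)
  for (s in seq_len(nsteps)) {
    frac <- if (nsteps > 1) (s - 1) / (nsteps - 1) else 0
    lr <- lr_start + (lr_end - lr_start) * frac
    x <- X[order0[s] + 1, ]
    d <- rowSums(sweep(W, 2, x)^2)
    bmu <- which.min(d)  # first minimum = lowest index, same tie-break
    W[bmu, ] <- W[bmu, ] + lr * (x - W[bmu, ])
  }
  W
}

test_that("build_trajectory_matrix rows equal aggregate-then-lookup", {
  set.seed(2)
  mats <- replicate(3, matrix(runif(400, 0.1, 0.9), 20, 20), simplify = FALSE)
  s <- apply_persistent_nonwoodland_mask(mk_series(mats, 2000:2002))
  tm <- build_trajectory_matrix(s, factor = 5)
  expect_equal(ncol(tm$X), 3)
  coarse <- lapply(s$maps, block_aggregate, factor = 5)
  for (i in sample(nrow(tm$X), 10)) {
    r <- tm$cell_index$row[i]; c <- tm$cell_index$col[i]
    expect_equal(tm$X[i, ],
                 vapply(coarse, function(m) m$values[r, c], numeric(1)),
                 ignore_attr = TRUE)
  }
  # uniform series -> constant rows; one epoch -> single column
  us <- apply_persistent_nonwoodland_mask(
    mk_series(list(matrix(0.6, 10, 10)), 2020))
  utm <- build_trajectory_matrix(us, 5)
  expect_equal(ncol(utm$X), 1)
  expect_equal(unname(utm$X[, 1]), rep(0.6, nrow(utm$X)))
  # coarse cells that are persistently <= cutoff are dropped
  low <- mk_series(list(matrix(0.01, 10, 10)), 2020)
  low <- apply_persistent_nonwoodland_mask(low)
  expect_equal(nrow(build_trajectory_matrix(low, 5)$X), 0)
})

test_that("train_som is deterministic and respects the data envelope", {
  set.seed(4)
  X <- matrix(runif(200), 50, 4)
  m1 <- train_som(X, 4, seed = 99)
  m2 <- train_som(X, 4, seed = 99)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$assignments, m2$assignments)
  # prototypes stay inside [min, max] per coordinate (convex updates)
  for (j in 1:4) {
    expect_gte(min(m1$codebook[, j]), min(X[, j]))
    expect_lte(max(m1$codebook[, j]), max(X[, j]))
  }
  expect_error(train_som(X, 60), "exceeds")
  expect_error(train_som(X * NA, 3), "NA")
})

test_that("separable duplicated rows are a fixed point with ~zero error", {
  proto <- matrix(c(0, 0, 0, 1, 1, 1, 0.5, 0.5, 0.5, 0, 1, 0), 4, 3, byrow = TRUE)
  X <- proto[rep(1:4, each = 25), ]
  m <- train_som(X, 4, som_params(radius_start = 0), seed = 1)
  # init samples the distinct rows, winner-only updates cannot leave them
  expect_lt(m$quantization_error, 1e-6)
  reordered <- m$codebook[order(m$codebook[, 1], m$codebook[, 2]), ]
  expect_equal(reordered, proto[order(proto[, 1], proto[, 2]), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("radius-0 training equals the competitive-learning oracle", {
  set.seed(14)
  X <- matrix(runif(140), 20, 7)
  init <- X[1:5, ]
  order0 <- as.integer(sample(0:19, 200, replace = TRUE))
  cpp <- drywoodlands:::som_train_cpp(X, init, cbind(0:4, 0), order0,
                                      0.05, 0.01, 0, 0, 0.5,
                                      steps_per_pass = 20)
  oracle <- competitive_oracle(X, init, order0, 0.05, 0.01)
  expect_equal(cpp$codebook, oracle, tolerance = 1e-12)
})

test_that("quantization error never exceeds its value at initialization", {
  g <- mk_grid(30, 30)
  tr <- generate_truth_series(default_templates(), g, epochs = default_epochs(),
                              patch_factor = 5, seed = 2)
  s <- apply_persistent_nonwoodland_mask(tr$series)
  tm <- build_trajectory_matrix(s, factor = 1)
  for (sd in 1:5) {
    m <- train_som(tm, 6, seed = sd)
    expect_lte(m$quantization_error, m$initial_quantization_error)
  }
})

test_that("silhouette and ARI agree with small brute-force oracles", {
  # two clean 1-D clusters: silhouette computable by hand
  X <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  lab <- c(1, 1, 1, 2, 2, 2)
  sil <- silhouette_score(X, lab)
  brute <- mean(vapply(1:6, function(i) {
    a <- mean(abs(X[i, ] - X[lab == lab[i] & seq_len(6) != i, ]))
    b <- mean(abs(X[i, ] - X[lab != lab[i], ]))
    (b - a) / max(a, b)
  }, numeric(1)))
  expect_equal(sil, brute, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(lab, lab), 1)
  expect_equal(adjusted_rand_index(lab, c(2, 2, 2, 1, 1, 1)), 1)  # relabeling
  set.seed(8)
  a <- sample(1:3, 25, replace = TRUE); b <- sample(1:3, 25, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), ari_pairs_oracle(a, b),
               tolerance = 1e-12)
})

test_that("select_cluster_count reports diagnostics with the expected shape", {
  g <- mk_grid(20, 20)
  tr <- generate_truth_series(default_templates(), g, epochs = default_epochs(),
                              patch_factor = 4, seed = 6)
  tm <- build_trajectory_matrix(apply_persistent_nonwoodland_mask(tr$series), 1)
  tab <- select_cluster_count(tm, k_range = c(4, 6, 8), seeds = 1:2)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("quantization_error", "silhouette", "n_empty") %in% names(tab)))
  one <- select_cluster_count(tm, k_range = 5, seeds = 3)
  expect_equal(nrow(one), 1)
  # QE decreases with k on average across seeds
  avg <- tapply(tab$quantization_error, tab$k, mean)
  expect_true(avg[["4"]] >= avg[["8"]])
})

test_that("summarize_archetypes matches a group-by oracle and is label-stable", {
  set.seed(10)
  X <- matrix(runif(60), 20, 3)
  tmx <- structure(list(X = X, epochs = 2000:2002,
                        coarse_grid = wl_grid(4, 5, cell_size = 2),
                        cell_index = data.frame(row = rep(1:4, 5),
                                                col = rep(1:5, each = 4))),
                   class = "wl_trajectory_matrix")
  model <- list(k = 3, assignments = sample(1:3, 20, replace = TRUE))
  sm <- summarize_archetypes(model, tmx)
  expect_equal(sum(sm$table$share_pct), 100)
  expect_equal(sum(sm$table$n_cells), 20)
  for (kk in 1:3) {
    sel <- model$assignments == kk
    expect_equal(sm$table$n_cells[kk], sum(sel))
    expect_equal(sm$mean_trajectory[kk, ], colMeans(X[sel, , drop = FALSE]),
                 ignore_attr = TRUE)
    expect_equal(sm$table$net_area_change[kk],
                 sum(X[sel, 3] - X[sel, 1]) * 4)
  }
  # permuting node indices permutes, but does not change, the summaries
  perm <- c(2, 3, 1)
  model2 <- list(k = 3, assignments = perm[model$assignments])
  sm2 <- summarize_archetypes(model2, tmx)
  expect_equal(sm2$table$n_cells[perm], sm$table$n_cells)
  # degenerate cases: one cluster -> 100%; two equal halves -> 50/50
  m1 <- list(k = 1, assignments = rep(1L, 20))
  expect_equal(summarize_archetypes(m1, tmx)$table$share_pct, 100)
  m2 <- list(k = 2, assignments = rep(1:2, each = 10))
  expect_equal(summarize_archetypes(m2, tmx)$table$share_pct, c(50, 50))
})

test_that("archetype_label_map places assignments at their coarse cells", {
  set.seed(12)
  mats <- replicate(2, matrix(runif(100, 0.2, 0.9), 10, 10), simplify = FALSE)
  s <- apply_persistent_nonwoodland_mask(mk_series(mats, c(2000, 2020)))
  tm <- build_trajectory_matrix(s, 5)
  m <- train_som(tm, 2, seed = 3)
  lm <- archetype_label_map(m, tm)
  expect_equal(lm$values[cbind(tm$cell_index$row, tm$cell_index$col)],
               m$assignments)
})
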
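#' Build the trajectory matrix for archetype clustering
#'
#' Aggregates every epoch map of the series to the coarse grid by block means
#' and stacks the coarse cells as rows (one column per epoch). Coarse cells
#' that are persistent non-woodland at coarse scale (cover at or below the
#' series' mask cutoff in every epoch) are dropped, as are cells with any
#' missing epoch.
#'
#' @param series A [cover_series()].
#' @param factor Aggregation factor from analysis to coarse grid (default 10,
#'   the 300 m to 3 km step).
#' @param apply_mask Drop coarse persistent non-woodland cells (default TRUE).
#' @return A list of class `wl_trajectory_matrix`: `X` (numeric matrix, rows =
#'   retained coarse cells, columns = epochs), `epochs`, `coarse_grid`,
#'   `cell_index` (data.frame `row`, `col` into the coarse grid).
#' @export
build_trajectory_matrix <- function(series, factor = 10, apply_mask = TRUE) {
  coarse <- lapply(series$maps, block_aggregate, factor = factor)
  cg <- coarse[[1]]$grid
  X <- vapply(coarse, function(m) as.vector(m$values),
              numeric(cg$n_rows * cg$n_cols))
  X <- matrix(X, ncol = length(series$epochs),
              dimnames = list(NULL, as.character(series$epochs)))
  keep <- rowSums(is.na(X)) == 0
  if (apply_mask) {
    cutoff <- if (is.na(series$mask_cutoff)) 0.05 else series$mask_cutoff
    keep <- keep & rowSums(X > cutoff, na.rm = TRUE) > 0
  }
  idx <- which(keep)
  structure(list(
    X = X[keep, , drop = FALSE],
    epochs = series$epochs, coarse_grid = cg,
    cell_index = data.frame(row = (idx - 1L) %% cg$n_rows + 1L,
                            col = (idx - 1L) %/% cg$n_rows + 1L)),
    class = "wl_trajectory_matrix")
}

#' SOM training parameters
#'
#' Defaults: every sample presented `n_passes` times, learning rate decaying
#' linearly from 0.05 to 0.01, Gaussian neighborhood with initial radius 0.25
#' decaying linearly to 0, Euclidean distance. The weak default neighborhood
#' is deliberate: on trajectory data whose clusters are much tighter than
#' their separation, a strong chain neighborhood (the textbook `k/2`)
#' reliably strands "dead" units between clusters and merges nearby cluster
#' pairs — recovery experiments against generated labels show this directly —
#' while a weak neighborhood keeps the topological ordering role of the chain
#' without the merging pathology. `radius_start` is fully configurable (set
#' `k/2` to recover textbook behavior). All values are recorded in the fitted
#' model.
#'
#' @param n_passes Passes over the data (presentations per sample).
#' @param lr_start,lr_end Learning-rate schedule endpoints.
#' @param radius_start Initial neighborhood radius (node-coordinate units).
#' @param radius_end Final neighborhood radius.
#' @param radius_frac Fraction of training over which the radius decays from
#'   `radius_start` to `radius_end` (the ordering phase); the remainder runs
#'   at `radius_end`, i.e. winner-only fine-tuning when `radius_end = 0`.
#' @param topology `"chain"` (k nodes on a line; the default, since k
#'   *clusters* are wanted) or `"grid"` (near-square 2-D layout).
#' @export
som_params <- function(n_passes = 100, lr_start = 0.05, lr_end = 0.01,
                       radius_start = 0.25, radius_end = 0, radius_frac = 0.5,
                       topology = c("chain", "grid")) {
  topology <- match.arg(topology)
  if (lr_start <= 0 || lr_start > 1 || lr_end <= 0 || lr_end > lr_start)
    stop("need 0 < lr_end <= lr_start <= 1")
  if (radius_frac < 0 || radius_frac > 1) stop("radius_frac must be in [0, 1]")
  list(n_passes = n_passes, lr_start = lr_start, lr_end = lr_end,
       radius_start = radius_start, radius_end = radius_end,
       radius_frac = radius_frac, topology = topology)
}

# distance-weighted seeding over data rows (k-means++ style): the first
# prototype is a uniform draw, each further one a draw with probability
# proportional to squared distance from the chosen set
seed_prototypes <- function(X, k) {
  n <- nrow(X)
  chosen <- sample.int(n, 1)
  d2 <- colSums((t(X) - X[chosen, ])^2)
  while (length(chosen) < k) {
    if (all(d2 <= 0))
      stop("fewer than k distinct data rows; cannot initialize ", k, " prototypes")
    nxt <- sample.int(n, 1, prob = pmax(d2, 0))
    chosen <- c(chosen, nxt)
    d2 <- pmin(d2, colSums((t(X) - X[nxt, ])^2))
  }
  chosen
}

node_positions <- function(k, topology) {
  if (topology == "chain") cbind(seq_len(k) - 1, 0)
  else {
    nc <- ceiling(sqrt(k)); nr <- ceiling(k / nc)
    pos <- expand.grid(x = seq_len(nc) - 1, y = seq_len(nr) - 1)[seq_len(k), ]
    as.matrix(pos)
  }
}

#' Train a self-organizing map on cover trajectories
#'
#' Online SOM on a 1-D chain of `k` nodes (2-D grids via
#' `som_params(topology = "grid")`). Prototypes are initialized from `k`
#' distinct data rows chosen by distance-weighted (k-means++ style) seeded
#' sampling. At each step the best-matching node — squared Euclidean
#' distance, ties to the lowest index — and its neighbors (Gaussian
#' neighborhood in node space, radius decaying linearly) move toward the
#' sample by the decaying learning rate. Final hard assignments use plain
#' nearest-prototype distance, decoupled from the training neighborhood.
#'
#' Because online SOMs converge to local optima, training restarts
#' `n_restarts` times from different seeded initializations and presentation
#' orders and keeps the fit with the lowest quantization error — the
#' standard guard against split/merged-cluster solutions. Deterministic under
#' a fixed seed.
#'
#' @param X A [build_trajectory_matrix()] result or a plain numeric matrix.
#' @param k Number of clusters (3–10 is the intended range; at least 2 and at
#'   most the number of rows is enforced).
#' @param params A [som_params()] list.
#' @param seed Integer RNG seed.
#' @param n_restarts Independent seeded restarts; the lowest-quantization-
#'   error fit is returned.
#' @return An object of class `wl_som`: `k`, `codebook` (k x epochs),
#'   `assignments` (1-based), `quantization_error`, `initial_codebook`,
#'   `initial_quantization_error`, `qe_trace` (per pass), `params`, `seed`,
#'   `n_restarts`, `node_pos`, `epochs`.
#' @export
train_som <- function(X, k, params = som_params(), seed = 1, n_restarts = 5) {
  tm <- NULL
  if (inherits(X, "wl_trajectory_matrix")) { tm <- X; X <- X$X }
  if (!is.matrix(X)) stop("X must be a matrix or wl_trajectory_matrix")
  if (anyNA(X)) stop("X contains NA; drop or impute missing trajectories first")
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of trajectories (", n, ")")
  pos <- node_positions(k, params$topology)
  one_fit <- function(sub_seed) with_seed(sub_seed, {
    init <- X[seed_prototypes(X, k), , drop = FALSE]
    order0 <- as.integer(unlist(lapply(seq_len(params$n_passes),
                                       function(p) sample.int(n))) - 1L)
    fit <- som_train_cpp(X, init, pos, order0,
                         params$lr_start, params$lr_end,
                         params$radius_start, params$radius_end,
                         params$radius_frac %||% 0.5, steps_per_pass = n)
    asg <- som_assign_cpp(X, fit$codebook)
    list(init = init, codebook = fit$codebook, qe_trace = fit$qe_trace,
         assignments = asg$assignments, qe = asg$quantization_error)
  })
  fits <- lapply(seq_len(max(1L, n_restarts)), function(r)
    one_fit((abs(seed) * 1009 + r) %% 2147483647))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "qe"))]]
  structure(list(k = k, codebook = best$codebook,
                 assignments = best$assignments,
                 quantization_error = best$qe,
                 initial_codebook = best$init,
                 initial_quantization_error =
                   som_assign_cpp(X, best$init)$quantization_error,
                 qe_trace = best$qe_trace,
                 params = params, seed = seed,
                 n_restarts = max(1L, n_restarts), node_pos = pos,
                 epochs = if (!is.null(tm)) tm$epochs else colnames(X)),
            class = "wl_som")
}

#' @export
print.wl_som <- function(x, ...) {
  cat(sprintf("<wl_som> k=%d, %d trajectories, quantization error %.5f (init %.5f)\n",
              x$k, length(x$assignments), x$quantization_error,
              x$initial_quantization_error))
  invisible(x)
}

#' Mean silhouette of a clustering
#'
#' Standard silhouette with Euclidean distances; singleton clusters score 0.
#'
#' @param X Numeric data matrix (rows = samples).
#' @param labels Integer cluster labels.
#' @param D Optional precomputed distance matrix (class `dist` or full matrix).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(X, labels, D = NULL) {
  n <- length(labels)
  if (is.null(D)) D <- stats::dist(X)
  if (inherits(D, "dist")) D <- as.matrix(D)
  labs <- sort(unique(labels))
  if (length(labs) < 2) return(NA_real_)
  sizes <- vapply(labs, function(l) sum(labels == l), numeric(1))
  # mean distance of every point to every cluster, via one matrix product
  ind <- vapply(labs, function(l) as.numeric(labels == l), numeric(n))
  M <- sweep(D %*% ind, 2, sizes, "/")
  own <- match(labels, labs)
  a <- (M[cbind(seq_len(n), own)] * sizes[own]) / pmax(sizes[own] - 1, 1)
  Mb <- M
  Mb[cbind(seq_len(n), own)] <- Inf
  b <- apply(Mb, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1] <- 0
  mean(s)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to relabeling),
#' about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Cluster-count diagnostics
#'
#' Trains a SOM for every k in `k_range` and every seed, reporting
#' quantization error, mean silhouette and the number of empty clusters.
#' The choice of k is reported, never silently applied: pick k from the table
#' (the conventional default is 6) and pass it to [train_som()].
#'
#' @param X A [build_trajectory_matrix()] result or matrix.
#' @param k_range Candidate cluster counts (default 3:10).
#' @param params A [som_params()] list.
#' @param seeds Integer seeds (one SOM per k per seed).
#' @return `data.frame` with columns `k`, `seed`, `quantization_error`,
#'   `silhouette`, `n_empty`.
#' @export
select_cluster_count <- function(X, k_range = 3:10, params = som_params(),
                                 seeds = 1:5) {
  if (!length(k_range)) stop("k_range must be non-empty")
  Xm <- if (inherits(X, "wl_trajectory_matrix")) X$X else X
  D <- as.matrix(stats::dist(Xm))
  out <- do.call(rbind, lapply(seeds, function(s) {
    do.call(rbind, lapply(k_range, function(k) {
      m <- train_som(Xm, k, params, seed = s)
      data.frame(k = k, seed = s,
                 quantization_error = m$quantization_error,
                 silhouette = silhouette_score(Xm, m$assignments, D),
                 n_empty = k - length(unique(m$assignments)))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Summarize archetype clusters
#'
#' Per cluster: extent (cell count and area), share of the total (%), mean and
#' population-SD trajectory, and net woodland-area change over the series
#' (fractional accounting at coarse cells).
#'
#' @param model A [train_som()] fit.
#' @param tm The [build_trajectory_matrix()] the model was trained on.
#' @return A list of class `wl_archetype_summary`: `table` (data.frame
#'   `cluster`, `n_cells`, `area`, `share_pct`, `net_area_change`),
#'   `mean_trajectory` and `sd_trajectory` (k x epochs matrices).
#' @export
summarize_archetypes <- function(model, tm) {
  X <- tm$X
  if (length(model$assignments) != nrow(X))
    stop("model assignments do not align with the trajectory matrix")
  cell_area <- tm$coarse_grid$cell_size^2
  ks <- seq_len(model$k)
  ne <- ncol(X)
  mean_tr <- matrix(NA_real_, model$k, ne,
                    dimnames = list(ks, colnames(X)))
  sd_tr <- mean_tr
  tab <- do.call(rbind, lapply(ks, function(kk) {
    sel <- model$assignments == kk
    n <- sum(sel)
    if (n) {
      sub <- X[sel, , drop = FALSE]
      mean_tr[kk, ] <<- colMeans(sub)
      sd_tr[kk, ] <<- sqrt(colMeans(sweep(sub, 2, colMeans(sub))^2))
    }
    data.frame(cluster = kk, n_cells = n, area = n * cell_area,
               share_pct = n / nrow(X) * 100,
               net_area_change = if (n)
                 sum(X[sel, ne] - X[sel, 1]) * cell_area else NA_real_)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, mean_trajectory = mean_tr, sd_trajectory = sd_tr),
            class = "wl_archetype_summary")
}

#' Archetype labels as a coarse-grid raster
#'
#' @param model A [train_som()] fit.
#' @param tm The matching [build_trajectory_matrix()].
#' @return A [categorical_map()] on the coarse grid (`NA` where cells were
#'   dropped).
#' @export
archetype_label_map <- function(model, tm) {
  g <- tm$coarse_grid
  v <- matrix(NA_integer_, g$n_rows, g$n_cols)
  v[cbind(tm$cell_index$row, tm$cell_index$col)] <- model$assignments
  categorical_map(g, v, stats::setNames(paste0("archetype_", seq_len(model$k)),
                                        seq_len(model$k)))
}
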
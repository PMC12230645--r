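#' Archetype trajectory templates
#'
#' A template is a named per-epoch mean cover trajectory plus a per-epoch
#' spread; the truth generator assigns templates to contiguous patches and adds
#' spatially smoothed noise. [default_templates()] ships six shapes modelled on
#' the change archetypes commonly reported for Indian dry woodlands: three
#' levels of continuous decline ("strongholds" staying near-saturated,
#' sustained loss from high cover, moderate loss from mid cover) and three
#' forest-transition shapes (historical decline, stabilization, post-1995
#' recovery, at high/mid/low starting cover). Values are generator defaults,
#' not claims about any real dataset.
#'
#' @param name Template label.
#' @param trajectory Per-epoch mean cover fractions in \[0, 1\].
#' @param sd Per-epoch noise standard deviation (recycled if length 1).
#' @return An object of class `wl_template`.
#' @export
archetype_template <- function(name, trajectory, sd = 0.02) {
  if (any(trajectory < 0 | trajectory > 1)) stop("trajectory values must be in [0, 1]")
  sd <- rep_len(sd, length(trajectory))
  if (any(sd < 0)) stop("sd must be non-negative")
  structure(list(name = name, trajectory = as.numeric(trajectory), sd = sd),
            class = "wl_template")
}

#' @rdname archetype_template
#' @param sd_all Noise sd applied to every epoch of every default template.
#' @export
default_templates <- function(sd_all = 0.02) {
  tr <- list(
    woodland_strongholds     = c(0.980, 0.950, 0.920, 0.910, 0.900, 0.860, 0.836),
    sustained_loss           = c(0.861, 0.700, 0.550, 0.530, 0.520, 0.500, 0.417),
    moderate_loss            = c(0.505, 0.360, 0.310, 0.300, 0.300, 0.290, 0.231),
    rampant_defor_recovery   = c(0.875, 0.700, 0.250, 0.200, 0.180, 0.280, 0.159),
    widespread_defor_recovery= c(0.499, 0.350, 0.120, 0.100, 0.090, 0.140, 0.088),
    low_level_recovery       = c(0.106, 0.100, 0.085, 0.082, 0.080, 0.100, 0.075))
  Map(function(nm, t) archetype_template(nm, t, sd_all), names(tr), tr)
}

#' Default epoch years of the synthetic world
#' @export
default_epochs <- function() c(1880L, 1930L, 1975L, 1985L, 1995L, 2010L, 2020L)

#' Minimum pairwise L2 separation between templates
#'
#' Used to guarantee that generated worlds are recoverable by trajectory
#' clustering: worlds whose templates are closer than a floor can be rejected
#' up front.
#'
#' @param templates List of [archetype_template()]s.
#' @return Smallest pairwise Euclidean distance between template trajectories.
#' @export
template_separation <- function(templates) {
  tm <- do.call(rbind, lapply(templates, `[[`, "trajectory"))
  if (nrow(tm) < 2) return(Inf)
  min(stats::dist(tm))
}

# clip to [0, 1] preserving dim (pmin/pmax take attributes from arg 1)
clip01 <- function(m) pmax(pmin(m, 1), 0)

# moving-average smoothing with edge renormalization; window = 2*half + 1
box_smooth <- function(m, half) {
  if (half <= 0) return(m)
  k <- rep(1, 2 * half + 1)
  sm_dir <- function(x) {
    num <- apply(x, 2, function(col) stats::filter(col, k, sides = 2))
    den <- apply(matrix(1, nrow(x), ncol(x)), 2,
                 function(col) stats::filter(col, k, sides = 2))
    # filter() leaves NA at the edges; recompute there with truncated windows
    n <- nrow(x)
    for (i in c(seq_len(min(half, n)), seq.int(max(1, n - half + 1), n))) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      num[i, ] <- colSums(x[lo:hi, , drop = FALSE])
      den[i, ] <- hi - lo + 1
    }
    num / den
  }
  t(sm_dir(t(sm_dir(m))))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a true cover time series with archetype-structured trajectories
#'
#' Contiguous patches of the grid are assigned archetype templates (via a
#' seeded Voronoi partition at a configurable patch scale, so patches respect
#' coarse-cell boundaries when `patch_factor` divides the aggregation factor).
#' Each cell's trajectory is its template trajectory plus spatially smoothed
#' Gaussian noise (moving-average kernel of half-width `spatial_corr_len`,
#' rescaled to the template's per-epoch sd), clipped to \[0, 1\]. Ecoregions
#' are labelled rectangular blocks.
#'
#' @param templates Non-empty list of [archetype_template()]s.
#' @param grid Analysis [wl_grid()].
#' @param epochs Epoch years, one per template trajectory entry.
#' @param spatial_corr_len Noise correlation half-width in cells (>= 0).
#' @param patch_factor Patch lattice scale in cells; template labels are
#'   constant on `patch_factor x patch_factor` blocks.
#' @param seeds_per_template Voronoi seeds per template (patch count control).
#' @param n_ecoregions Number of rectangular ecoregion blocks.
#' @param seed Integer RNG seed; same seed gives bit-identical output.
#' @return List with `series` ([cover_series()] over `epochs`),
#'   `archetype_labels` (integer matrix, index into `templates`),
#'   `ecoregion_labels` (integer matrix), and `templates`.
#' @export
generate_truth_series <- function(templates, grid, epochs = default_epochs(),
                                  spatial_corr_len = 2, patch_factor = 10,
                                  seeds_per_template = 3, n_ecoregions = 8,
                                  seed = 1) {
  if (!length(templates)) stop("at least one archetype template is required")
  ne <- length(epochs)
  for (tp in templates)
    if (length(tp$trajectory) != ne)
      stop("template '", tp$name, "' trajectory length != number of epochs")
  with_seed(seed, {
    pr <- max(1L, ceiling(grid$n_rows / patch_factor))
    pc <- max(1L, ceiling(grid$n_cols / patch_factor))
    k <- length(templates)
    nseed <- min(pr * pc, k * seeds_per_template)
    seed_cells <- sample.int(pr * pc, nseed)
    sr <- (seed_cells - 1L) %% pr + 1L
    sc <- (seed_cells - 1L) %/% pr + 1L
    seed_tmpl <- rep_len(sample.int(k), nseed)  # every template represented
    # nearest-seed (Voronoi) labels on the patch lattice -> contiguous patches
    gr <- matrix(seq_len(pr), pr, pc)
    gc <- matrix(rep(seq_len(pc), each = pr), pr, pc)
    best_d <- matrix(Inf, pr, pc); lab_p <- matrix(1L, pr, pc)
    for (i in seq_len(nseed)) {
      d <- (gr - sr[i])^2 + (gc - sc[i])^2
      upd <- d < best_d
      lab_p[upd] <- seed_tmpl[i]
      best_d[upd] <- d[upd]
    }
    labels <- lab_p[ceiling(seq_len(grid$n_rows) / patch_factor),
                    ceiling(seq_len(grid$n_cols) / patch_factor), drop = FALSE]
    maps <- vector("list", ne)
    tmat <- do.call(rbind, lapply(templates, `[[`, "trajectory"))
    smat <- do.call(rbind, lapply(templates, `[[`, "sd"))
    for (e in seq_len(ne)) {
      mu <- matrix(tmat[labels, e], grid$n_rows, grid$n_cols)
      sde <- matrix(smat[labels, e], grid$n_rows, grid$n_cols)
      z <- matrix(stats::rnorm(grid$n_rows * grid$n_cols), grid$n_rows, grid$n_cols)
      if (spatial_corr_len > 0) {
        z <- box_smooth(z, spatial_corr_len)
        z <- z / stats::sd(as.vector(z))   # restore unit variance after smoothing
      }
      vals <- clip01(mu + sde * z)
      maps[[e]] <- cover_map(grid, vals, epochs[e])
    }
    # ecoregions: near-square lattice of rectangular blocks
    er <- max(1L, floor(sqrt(n_ecoregions)))
    ec <- ceiling(n_ecoregions / er)
    row_band <- pmin(er, ceiling(seq_len(grid$n_rows) / (grid$n_rows / er)))
    col_band <- pmin(ec, ceiling(seq_len(grid$n_cols) / (grid$n_cols / ec)))
    eco <- outer(row_band, col_band, function(r, c) (r - 1L) * ec + c)
    eco[eco > n_ecoregions] <- n_ecoregions
    list(series = cover_series(maps, epochs),
         archetype_labels = labels, ecoregion_labels = eco,
         templates = templates)
  })
}

#' Specification of a synthetic source map
#'
#' Stands in for a real candidate dataset: a native resolution (an integer
#' refinement factor of the analysis grid), a representation, and an error
#' model. Binary and categorical sources flip woodland cells to other with
#' probability `omission_rate` and other cells to woodland with probability
#' `commission_rate` at native resolution; fractional sources add `bias` plus
#' Gaussian noise.
#'
#' @param name Source label.
#' @param native_factor Integer >= 1; native cell = analysis cell / factor.
#' @param representation `"binary"`, `"categorical"` or `"fractional"`.
#' @param omission_rate,commission_rate Flip probabilities in \[0, 1).
#' @param bias Additive fraction, |bias| < 1 (fractional sources only).
#' @param noise_sd Gaussian noise sd for fractional sources.
#' @param threshold_pct Percent threshold defining "woodland" at native scale.
#' @return An object of class `wl_source_spec`.
#' @export
source_spec <- function(name, native_factor = 1,
                        representation = c("binary", "categorical", "fractional"),
                        omission_rate = 0, commission_rate = 0,
                        bias = 0, noise_sd = 0.02, threshold_pct = 20) {
  representation <- match.arg(representation)
  if (omission_rate < 0 || omission_rate >= 1 || commission_rate < 0 || commission_rate >= 1)
    stop("omission/commission rates must lie in [0, 1)")
  if (abs(bias) >= 1) stop("|bias| must be < 1")
  if (native_factor < 1 || native_factor != round(native_factor))
    stop("native_factor must be a positive integer")
  structure(list(name = name, native_factor = as.integer(native_factor),
                 representation = representation,
                 omission_rate = omission_rate, commission_rate = commission_rate,
                 bias = bias, noise_sd = noise_sd, threshold_pct = threshold_pct),
            class = "wl_source_spec")
}

#' Default source specifications
#'
#' Five sources emulating the structure of typical candidate datasets: one
#' continuous (fractional) product, two accurate fine-scale binary products,
#' one clean categorical product, and one sloppy product intended to fail
#' accuracy screening. Binary products saturate mid-cover cells (a block of
#' smooth 0.16 cover thresholds to all-zero at native scale), so depending on
#' the world they can fall below the overall-accuracy floor at their best
#' threshold — the continuous product keeps the default ensemble non-empty,
#' as continuous tree-cover layers did in practice.
#' @export
default_source_specs <- function() list(
  source_spec("fractional_a", native_factor = 1, representation = "fractional",
              bias = 0.01, noise_sd = 0.03),
  source_spec("fine_binary_b", native_factor = 2, representation = "binary",
              omission_rate = 0.03, commission_rate = 0.02),
  source_spec("fine_binary_c", native_factor = 2, representation = "binary",
              omission_rate = 0.05, commission_rate = 0.03),
  source_spec("categorical_d", native_factor = 1, representation = "categorical",
              omission_rate = 0.05, commission_rate = 0.04),
  source_spec("sloppy_e", native_factor = 1, representation = "binary",
              omission_rate = 0.30, commission_rate = 0.35))

#' Generate noisy source maps from a truth series
#'
#' Each source is the truth at one epoch, resampled to its native grid,
#' degraded according to its [source_spec()], then harmonized back to the
#' analysis grid as a fractional map (block mean of the native binary map, or
#' the noisy fractional map itself). The realized confusion against the
#' binarized native truth is returned alongside, so analytic user's accuracy
#' is known for every generated source.
#'
#' @param truth A [cover_series()] of true cover.
#' @param specs List of [source_spec()]s.
#' @param epoch Epoch year to depict (must be in `truth$epochs`).
#' @param seed Integer RNG seed.
#' @return List of `wl_source` objects with fields `name`, `cover` (analysis
#'   grid [cover_map()]), `spec`, `realized` (native tp/fp/fn/tn and rates),
#'   `ua_weight` and `best_threshold` (NA until validation fills them).
#' @export
generate_source_maps <- function(truth, specs, epoch, seed = 1) {
  if (!epoch %in% truth$epochs)
    stop("epoch ", epoch, " not in truth series (", paste(truth$epochs, collapse = ", "), ")")
  tm <- truth$maps[[as.character(epoch)]]
  with_seed(seed, lapply(specs, function(sp) {
    native <- if (sp$native_factor == 1) tm$grid
              else grid_rescale(tm$grid, sp$native_factor, "finer")
    tnat <- if (sp$native_factor == 1) tm else nearest_resample(tm, native)
    if (sp$representation == "fractional") {
      vals <- clip01(tnat$values + sp$bias +
                       matrix(stats::rnorm(length(tnat$values), 0, sp$noise_sd),
                              nrow(tnat$values), ncol(tnat$values)))
      nat_map <- cover_map(native, vals, epoch)
      cov <- if (sp$native_factor == 1) nat_map else block_aggregate(nat_map, sp$native_factor)
      realized <- NULL
    } else {
      truth_bin <- tnat$values >= sp$threshold_pct / 100
      u <- matrix(stats::runif(length(truth_bin)), nrow(truth_bin), ncol(truth_bin))
      pred <- truth_bin
      pred[truth_bin & u < sp$omission_rate] <- FALSE
      pred[!truth_bin & u < sp$commission_rate] <- TRUE
      realized <- list(
        tp = sum(pred & truth_bin, na.rm = TRUE),
        fp = sum(pred & !truth_bin, na.rm = TRUE),
        fn = sum(!pred & truth_bin, na.rm = TRUE),
        tn = sum(!pred & !truth_bin, na.rm = TRUE))
      realized$ua <- with(realized, if (tp + fp > 0) tp / (tp + fp) else NA_real_)
      nat_bin <- binary_map(native, pred, epoch)
      cov <- block_aggregate(nat_bin, sp$native_factor)
      if (sp$representation == "categorical") {
        codes <- matrix(ifelse(pred, 1L, 2L), nrow(pred), ncol(pred))
        nat_map <- categorical_map(native, codes,
                                   c("1" = "woodland", "2" = "other"), epoch)
      } else nat_map <- nat_bin
    }
    structure(list(name = sp$name, cover = cov, native = nat_map, spec = sp,
                   realized = realized, ua_weight = NA_real_,
                   best_threshold = NA_real_),
              class = "wl_source")
  }))
}

#' Analytic user's accuracy implied by generator rates
#'
#' For a binary source with omission rate `om`, commission rate `com` and true
#' woodland prevalence `p` (fraction of cells at/above the woodland threshold),
#' UA = p(1-om) / (p(1-om) + (1-p)com).
#'
#' @param omission_rate,commission_rate Flip probabilities.
#' @param prevalence True woodland prevalence in \[0, 1\].
#' @export
analytic_users_accuracy <- function(omission_rate, commission_rate, prevalence) {
  num <- prevalence * (1 - omission_rate)
  den <- num + (1 - prevalence) * commission_rate
  if (den == 0) return(NA_real_)
  num / den
}

# snap a fraction to the lower bound of its 10% bin: {0, 10, ..., 90}
snap_to_bin <- function(frac) pmin(floor(pmin(pmax(frac, 0), 1) * 10), 9) * 10

#' Generate a two-observer validation sample set
#'
#' Samples `n` cells with all pairwise center distances at least `min_dist`
#' (rejection sampling, capped at `1000 * n` attempts). Each sample carries two
#' independent observer estimates: the true fraction plus Gaussian noise,
#' snapped to the containing 10 percent interval (reported by its lower bound),
#' plus their fusion via [fuse_observers()].
#'
#' @param truth A [cover_map()] of true cover at the analysis grid.
#' @param n Number of samples.
#' @param min_dist Minimum pairwise distance in map units.
#' @param obs_noise_sd Observer noise sd (cover fraction units).
#' @param seed Integer RNG seed.
#' @return A `data.frame` of class `wl_validation` with columns `x`, `y`,
#'   `row`, `col`, `true_fraction`, `observer_a_bin`, `observer_b_bin`,
#'   `fused_pct`.
#' @export
generate_observer_samples <- function(truth, n, min_dist, obs_noise_sd = 0.03,
                                      seed = 1) {
  g <- truth$grid
  with_seed(seed, {
    max_att <- 1000 * n
    xs <- ys <- numeric(0); rows <- cols <- integer(0)
    att <- 0
    while (length(xs) < n && att < max_att) {
      att <- att + 1
      r <- sample.int(g$n_rows, 1); c <- sample.int(g$n_cols, 1)
      if (is.na(truth$values[r, c])) next
      x <- g$origin_x + (c - 0.5) * g$cell_size
      y <- g$origin_y + (r - 0.5) * g$cell_size
      if (length(xs) && min(sqrt((xs - x)^2 + (ys - y)^2)) < min_dist) next
      xs <- c(xs, x); ys <- c(ys, y); rows <- c(rows, r); cols <- c(cols, c)
    }
    if (length(xs) < n)
      stop(sprintf(paste0("could not place %d samples at min_dist %g after %d ",
                          "attempts; %d were achievable"),
                   n, min_dist, max_att, length(xs)))
    tf <- truth$values[cbind(rows, cols)]
    a <- snap_to_bin(tf + stats::rnorm(n, 0, obs_noise_sd))
    b <- snap_to_bin(tf + stats::rnorm(n, 0, obs_noise_sd))
    out <- data.frame(x = xs, y = ys, row = rows, col = cols,
                      true_fraction = tf, observer_a_bin = a, observer_b_bin = b,
                      fused_pct = fuse_observers(a, b))
    class(out) <- c("wl_validation", "data.frame")
    out
  })
}

#' Generate synthetic species ranges on a coarse grid
#'
#' Threatened ranges are grown (random contiguous region growth) from seed
#' cells placed with probability proportional to `exp(cover_affinity * cover)`;
#' non-threatened ranges start from uniformly random seeds. With
#' `cover_affinity = 0` both placement distributions are identical.
#'
#' @param cover A [cover_map()] at the coarse grid (placement weight field).
#' @param n_threatened,n_nonthreatened Species counts (>= 0).
#' @param cover_affinity Non-negative weight; larger values concentrate
#'   threatened seeds in high-cover cells.
#' @param size_range Two-element integer vector: range extent (cells) drawn
#'   uniformly per species.
#' @param seed Integer RNG seed.
#' @return List of `wl_species_range` objects (`species_id`, `presence`
#'   logical matrix, `threatened` flag).
#' @export
generate_species_ranges <- function(cover, n_threatened, n_nonthreatened,
                                    cover_affinity = 8,
                                    size_range = NULL, seed = 1) {
  g <- cover$grid
  ncell <- g$n_rows * g$n_cols
  if (is.null(size_range))
    size_range <- pmax(1L, c(floor(0.05 * ncell), floor(0.15 * ncell)))
  vals <- cover$values
  vals[is.na(vals)] <- 0
  with_seed(seed, {
    grow_range <- function(id, threatened) {
      w <- if (threatened) exp(cover_affinity * as.vector(vals)) else rep(1, ncell)
      start <- sample.int(ncell, 1, prob = w)
      target <- sample(seq.int(size_range[1], size_range[2]), 1)
      inpatch <- logical(ncell)
      inpatch[start] <- TRUE
      frontier <- neighbors4(start, g$n_rows, g$n_cols)
      while (sum(inpatch) < target && length(frontier)) {
        nxt <- frontier[sample.int(length(frontier), 1)]
        frontier <- frontier[frontier != nxt]
        if (!inpatch[nxt]) {
          inpatch[nxt] <- TRUE
          nb <- neighbors4(nxt, g$n_rows, g$n_cols)
          frontier <- union(frontier, nb[!inpatch[nb]])
        }
      }
      structure(list(species_id = id,
                     presence = matrix(inpatch, g$n_rows, g$n_cols),
                     threatened = threatened, grid = g),
                class = "wl_species_range")
    }
    c(
      if (n_threatened > 0)
        lapply(seq_len(n_threatened),
               function(i) grow_range(sprintf("threatened_%02d", i), TRUE))
      else list(),
      if (n_nonthreatened > 0)
        lapply(seq_len(n_nonthreatened),
               function(i) grow_range(sprintf("nonthreatened_%02d", i), FALSE))
      else list())
  })
}

neighbors4 <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  nb <- c(if (r > 1) idx - 1L, if (r < nr) idx + 1L,
          if (c > 1) idx - nr, if (c < nc) idx + nr)
  nb
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper producing everything downstream stages need: the true
#' cover series (with the persistent non-woodland mask applied), archetype and
#' ecoregion labels, noisy source maps for the final epoch, a two-observer
#' validation set, and species ranges placed on the coarse-aggregated final
#' cover.
#'
#' @param grid Analysis [wl_grid()].
#' @param templates,epochs,spatial_corr_len,patch_factor,n_ecoregions Passed to
#'   [generate_truth_series()].
#' @param source_specs Passed to [generate_source_maps()] (final epoch).
#' @param n_samples,min_dist,obs_noise_sd Passed to [generate_observer_samples()].
#' @param coarse_factor Aggregation factor from analysis to coarse grid.
#' @param n_threatened,n_nonthreatened,cover_affinity Passed to
#'   [generate_species_ranges()].
#' @param mask_cutoff Persistent non-woodland cutoff fraction.
#' @param seed Master seed; stage seeds are derived deterministically from it.
#' @return An object of class `wl_world`.
#' @export
generate_world <- function(grid, templates = default_templates(),
                           epochs = default_epochs(),
                           spatial_corr_len = 2, patch_factor = 10,
                           n_ecoregions = 8,
                           source_specs = default_source_specs(),
                           n_samples = 600, min_dist = NULL, obs_noise_sd = 0.03,
                           coarse_factor = 10,
                           n_threatened = 7, n_nonthreatened = 7,
                           cover_affinity = 8, mask_cutoff = 0.05, seed = 1) {
  if (is.null(min_dist)) min_dist <- 2 * grid$cell_size
  sub <- function(k) (seed * 7L + k) %% 2147483647L
  tr <- generate_truth_series(templates, grid, epochs, spatial_corr_len,
                              patch_factor, n_ecoregions = n_ecoregions,
                              seed = sub(1L))
  series <- apply_persistent_nonwoodland_mask(tr$series, mask_cutoff)
  final_epoch <- epochs[length(epochs)]
  sources <- generate_source_maps(series, source_specs, final_epoch, seed = sub(2L))
  samples <- generate_observer_samples(series$maps[[as.character(final_epoch)]],
                                       n_samples, min_dist, obs_noise_sd,
                                       seed = sub(3L))
  coarse_final <- block_aggregate(series$maps[[as.character(final_epoch)]],
                                  coarse_factor)
  species <- generate_species_ranges(coarse_final, n_threatened, n_nonthreatened,
                                     cover_affinity, seed = sub(4L))
  structure(list(truth_series = series, archetype_labels = tr$archetype_labels,
                 ecoregion_labels = tr$ecoregion_labels, templates = templates,
                 sources = sources, samples = samples, species = species,
                 coarse_factor = coarse_factor, seed = seed),
            class = "wl_world")
}
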
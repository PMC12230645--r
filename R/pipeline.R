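#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end pipeline uses. Defaults
#' reproduce the published settings: threshold sweep 15–22%, screening floors
#' OA 0.70 / UA 0.90, 300 m-to-3 km aggregation factor 10, six SOM clusters,
#' 5% persistent non-woodland cutoff, epochs 1880–2020.
#'
#' @param grid Analysis [wl_grid()] for the synthetic world.
#' @param epochs Epoch years (strictly increasing).
#' @param coarse_factor Analysis-to-coarse aggregation factor.
#' @param sweep Percent thresholds for accuracy evaluation.
#' @param oa_min,ua_min Screening floors in \[0, 1\].
#' @param ensemble_mode `"as_printed"` or `"weight_normalized"`.
#' @param area_mode `"fractional_sum"` or `"binary_threshold"`.
#' @param mask_cutoff Persistent non-woodland cutoff fraction.
#' @param som_k Cluster count for the archetype SOM.
#' @param som Som hyperparameters ([som_params()]).
#' @param run_diagnostics Also run [select_cluster_count()] (slower).
#' @param n_samples,min_dist,obs_noise_sd Validation sampling settings
#'   (`min_dist = NULL` means twice the analysis cell size).
#' @param source_specs Source error models ([source_spec()] list).
#' @param n_threatened,n_nonthreatened,cover_affinity Species-range settings.
#' @param n_ecoregions,spatial_corr_len,patch_factor Truth-surface settings.
#' @param seed Master seed for all generators.
#' @return A validated list of class `wl_config`.
#' @export
pipeline_config <- function(grid = wl_grid(200, 200),
                            epochs = default_epochs(),
                            coarse_factor = 10,
                            sweep = 15:22,
                            oa_min = 0.70, ua_min = 0.90,
                            ensemble_mode = "as_printed",
                            area_mode = "fractional_sum",
                            mask_cutoff = 0.05,
                            som_k = 6, som = som_params(),
                            run_diagnostics = FALSE,
                            n_samples = 600, min_dist = NULL,
                            obs_noise_sd = 0.03,
                            source_specs = default_source_specs(),
                            n_threatened = 7, n_nonthreatened = 7,
                            cover_affinity = 8,
                            n_ecoregions = 8, spatial_corr_len = 2,
                            patch_factor = 10,
                            seed = 1) {
  fail <- function(field, why) stop("invalid config: ", field, " ", why, call. = FALSE)
  if (!inherits(grid, "wl_grid")) fail("grid", "must be a wl_grid")
  if (length(epochs) < 2 || is.unsorted(epochs, strictly = TRUE))
    fail("epochs", "must be >= 2 strictly increasing years")
  if (coarse_factor < 1 || coarse_factor != round(coarse_factor))
    fail("coarse_factor", "must be a positive integer")
  if (!length(sweep) || any(sweep <= 0 | sweep > 100))
    fail("sweep", "thresholds must be percents in (0, 100]")
  for (nm in c("oa_min", "ua_min")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      fail(nm, "must be a proportion in [0, 1]")
  }
  if (!ensemble_mode %in% c("as_printed", "weight_normalized"))
    fail("ensemble_mode", "must be 'as_printed' or 'weight_normalized'")
  if (!area_mode %in% c("fractional_sum", "binary_threshold"))
    fail("area_mode", "must be 'fractional_sum' or 'binary_threshold'")
  if (mask_cutoff < 0 || mask_cutoff >= 1)
    fail("mask_cutoff", "must be a fraction in [0, 1)")
  if (som_k < 2) fail("som_k", "must be at least 2")
  if (n_samples < 1) fail("n_samples", "must be positive")
  if (seed != round(seed)) fail("seed", "must be an integer")
  structure(as.list(environment())[setdiff(names(environment()), "fail")],
            class = "wl_config")
}

write_tidy_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes the four stages in order — (1) simulate the world and validate /
#' screen the candidate sources, (2) build the ensemble and the cover time
#' series with change maps and area accounting, (3) cluster coarse-cell
#' trajectories into archetypes, (4) overlay species ranges — writing every
#' intermediate artifact (text rasters, tidy CSVs) plus a JSON manifest of
#' parameters, seeds and file digests into `out_dir`. Re-running with the same
#' config is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "wl_config")) stop("config must be a pipeline_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # stage 1: synthetic world, validation, screening
  world <- stage("simulate", generate_world(
    grid = config$grid, epochs = config$epochs,
    spatial_corr_len = config$spatial_corr_len,
    patch_factor = config$patch_factor, n_ecoregions = config$n_ecoregions,
    source_specs = config$source_specs, n_samples = config$n_samples,
    min_dist = config$min_dist, obs_noise_sd = config$obs_noise_sd,
    coarse_factor = config$coarse_factor,
    n_threatened = config$n_threatened,
    n_nonthreatened = config$n_nonthreatened,
    cover_affinity = config$cover_affinity,
    mask_cutoff = config$mask_cutoff, seed = config$seed))
  final_epoch <- config$epochs[length(config$epochs)]
  for (y in config$epochs)
    write_asc(world$truth_series$maps[[as.character(y)]],
              file.path(out_dir, sprintf("truth_%d.asc", y)))
  write_tidy_csv(as.data.frame(world$samples), file.path(out_dir, "validation_samples.csv"))
  tables <- stage("validate", lapply(world$sources, threshold_sweep,
                                     samples = world$samples,
                                     thresholds = config$sweep))
  acc <- do.call(rbind, Map(function(src, tab) cbind(source = src$name,
                                                     as.data.frame(tab)),
                            world$sources, tables))
  write_tidy_csv(acc, file.path(out_dir, "accuracy_table.csv"))
  retained <- stage("screen", screen_maps(world$sources, tables,
                                          config$oa_min, config$ua_min))
  write_tidy_csv(attr(retained, "screening"), file.path(out_dir, "screening.csv"))
  if (!length(retained))
    stop("pipeline stage 'screen' failed: no source map passed the accuracy floors")

  # stage 2: ensemble, series, change, areas, ecoregions
  ens <- stage("ensemble", ensemble_cover(retained, config$ensemble_mode))
  write_asc(ens$cover, file.path(out_dir, "ensemble_cover.asc"))
  maps <- world$truth_series$maps
  maps[[as.character(final_epoch)]] <- ens$cover  # contemporary epoch from the ensemble
  series <- stage("series", apply_persistent_nonwoodland_mask(
    cover_series(maps, config$epochs), config$mask_cutoff))
  ch_full <- stage("change", change_map(series, config$epochs[1], final_epoch))
  ch_recent <- change_map(series, config$epochs[length(config$epochs) - 2], final_epoch)
  write_asc(cover_map_from_change(ch_full), file.path(out_dir, "change_full.asc"))
  write_asc(cover_map_from_change(ch_recent), file.path(out_dir, "change_recent.asc"))
  account <- period_change_table(series, config$area_mode)
  write_tidy_csv(cbind(account$periods, units = "map_units2"),
                 file.path(out_dir, "area_account.csv"))
  eco <- ecoregion_trajectory(series, world$ecoregion_labels)
  write_tidy_csv(as.data.frame(eco), file.path(out_dir, "ecoregion_trajectories.csv"))

  # stage 3: archetypes
  tm <- stage("archetypes", build_trajectory_matrix(series, config$coarse_factor))
  som <- train_som(tm, config$som_k, config$som, seed = config$seed)
  diag_tab <- if (config$run_diagnostics)
    select_cluster_count(tm, params = config$som, seeds = config$seed) else NULL
  if (!is.null(diag_tab))
    write_tidy_csv(diag_tab, file.path(out_dir, "cluster_diagnostics.csv"))
  summ <- summarize_archetypes(som, tm)
  write_tidy_csv(summ$table, file.path(out_dir, "archetype_summary.csv"))
  write_tidy_csv(data.frame(cluster = seq_len(som$k), som$codebook),
                 file.path(out_dir, "archetype_codebook.csv"))
  labels <- archetype_label_map(som, tm)
  write_asc(labels, file.path(out_dir, "archetype_labels.asc"))

  # stage 4: megafauna
  mega <- stage("megafauna", {
    coarse_maps <- lapply(series$maps, block_aggregate, factor = config$coarse_factor)
    coarse_series <- apply_persistent_nonwoodland_mask(
      cover_series(coarse_maps, config$epochs), config$mask_cutoff)
    cover2020 <- coarse_maps[[as.character(final_epoch)]]
    r_all <- richness(world$species, "all")
    r_thr <- richness(world$species, "threatened")
    r_non <- richness(world$species, "non_threatened")
    act <- series_active_cells(coarse_series)
    cors <- lapply(list(all = r_all, threatened = r_thr, non_threatened = r_non),
                   richness_cover_correlation, cover = cover2020, active = act)
    traj <- do.call(rbind, lapply(world$species, range_cover_trajectory,
                                  series = coarse_series))
    comp <- do.call(rbind, lapply(world$species, archetype_composition,
                                  labels = labels))
    med <- median_richness_per_archetype(r_all, labels)
    list(richness = list(all = r_all, threatened = r_thr, non_threatened = r_non),
         correlations = cors, trajectories = traj, composition = comp,
         median_richness = med)
  })
  write_tidy_csv(data.frame(
    group = names(mega$correlations),
    r = vapply(mega$correlations, `[[`, numeric(1), "r"),
    p = vapply(mega$correlations, `[[`, numeric(1), "p"),
    n = vapply(mega$correlations, `[[`, numeric(1), "n")),
    file.path(out_dir, "richness_correlations.csv"))
  write_tidy_csv(mega$trajectories, file.path(out_dir, "range_trajectories.csv"))
  write_tidy_csv(mega$composition, file.path(out_dir, "archetype_composition.csv"))
  write_tidy_csv(mega$median_richness, file.path(out_dir, "median_richness.csv"))

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("drywoodlands")),
    seed = config$seed, epochs = config$epochs,
    sweep = config$sweep, oa_min = config$oa_min, ua_min = config$ua_min,
    ensemble_mode = config$ensemble_mode, area_mode = config$area_mode,
    mask_cutoff = config$mask_cutoff, som_k = config$som_k,
    coarse_factor = config$coarse_factor,
    retained_sources = names(ens$weights), ua_weights = as.list(ens$weights),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(world = world, tables = tables, retained = retained,
                 ensemble = ens, series = series, account = account,
                 ecoregions = eco, trajectory_matrix = tm, som = som,
                 summary = summ, labels = labels, megafauna = mega,
                 diagnostics = diag_tab, manifest = manifest))
}

# change maps are in percentage points; rescale into a storable cover map
cover_map_from_change <- function(ch) {
  v <- (ch$values + 100) / 200   # [-100, 100] points -> [0, 1] for storage
  cover_map(ch$grid, v)
}
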
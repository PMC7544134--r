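#' Default end-to-end run configuration
#'
#' Nested parameter blocks for every stage of the pipeline, with desk-scale
#' defaults: a 60 x 80 cell world at 0.1 degrees, 20 Gaussian-niche species
#' with 300 effort-biased occurrence points each, and two future scenarios
#' warming the temperature band by +1 (a low-emission analogue, labelled
#' `rcp26`) and +3 units (a high-emission analogue, `rcp85`).
#'
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    world = list(
      n_rows = 60, n_cols = 80, lon_min = 100, lat_min = 20,
      cell_size = 0.1, n_climate_vars = 4, smoothing_scale = 4,
      noise_sd = 1.5, n_regions = 4, reserve_fraction = 0.15
    ),
    species = list(
      n_species = 20, n_points = 300, effort_bias = TRUE,
      effort_strength = 1, breadth_range = c(0.8, 1.6)
    ),
    # per-scenario additive offset on the temperature band
    scenarios = list(rcp26 = 1, rcp85 = 3),
    prep = list(min_localities = 5, min_sep_arcmin = 1),
    model = list(
      k_folds = 5, regularization = 1, n_background = 10000,
      cor_threshold = 0.9, prune_tolerance = 1e-8, block_size = 3
    ),
    prioritization = list(
      warp_factor = 1000, fractions = c(0.3, 0.5), masked = TRUE,
      w_min = 0.1, w_max = 2
    )
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()];
#' everything else keeps its default. The merged configuration is validated
#' before use.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = user$seed %||% 1L)
  for (block in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[block]]) && is.list(user[[block]])) {
      for (k in names(user[[block]])) cfg[[block]][[k]] <- user[[block]][[k]]
    } else {
      cfg[[block]] <- user[[block]]
    }
  }
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config A `run_config`.
#' @return Invisibly `TRUE`; aborts with a configuration error otherwise.
#' @export
validate_config <- function(config) {
  chk <- function(cond, msg) {
    if (!cond) rlang::abort(msg, class = "avishift_error_config")
  }
  chk(is.numeric(config$seed), "`seed` must be numeric.")
  w <- config$world
  chk(w$n_rows >= 8 && w$n_cols >= 8, "World grid must be at least 8 x 8.")
  chk(w$cell_size > 0, "`cell_size` must be positive.")
  s <- config$species
  chk(s$n_species >= 1 && s$n_points >= 1,
      "Need at least one species and one point per species.")
  chk(all(vapply(config$scenarios, is.numeric, logical(1))),
      "Each scenario must give a numeric temperature-band offset.")
  chk(config$prep$min_localities >= 1 && config$prep$min_sep_arcmin > 0,
      "Cleaning thresholds must be positive.")
  m <- config$model
  chk(m$k_folds >= 2 && m$regularization >= 0 && m$n_background >= 1,
      "Model parameters out of range.")
  p <- config$prioritization
  chk(p$warp_factor >= 1 && all(p$fractions > 0 & p$fractions <= 1),
      "Prioritization parameters out of range.")
  invisible(TRUE)
}

# smoothed multiplicative observation-effort surface (log-normal field)
make_effort_surface <- function(world, strength, seed) {
  nr <- rg_nrow(world$climate_current); nc <- rg_ncol(world$climate_current)
  with_seed(seed, {
    f <- box_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                    world$config$smoothing_scale)
  })
  rg_like(world$climate_current, exp(strength * f / stats::sd(f)),
          bands = "effort")
}

#' Run the full pipeline on a synthetic world
#'
#' Executes every stage in order — simulate, prep, two-round model fitting
#' and projection, range-dynamics analysis, and prioritization (unmasked and
#' reserve-masked per future scenario) — writing all declared outputs plus a
#' JSON manifest with seeds, per-stage counts, exclusion logs and output
#' checksums into `out_dir`. With no future scenarios the analysis and
#' prioritization stages are skipped with an explicit notice in the
#' manifest. Per-species failures are logged and do not abort the batch.
#'
#' @param config A `run_config` (default [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of every stage
#'   (`world`, `occurrences`, `batch`, `analysis`, `priority`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  notices <- character()

  # --- simulate ------------------------------------------------------------
  wc <- world_config(
    n_rows = config$world$n_rows, n_cols = config$world$n_cols,
    lon_min = config$world$lon_min, lat_min = config$world$lat_min,
    cell_size = config$world$cell_size,
    n_climate_vars = config$world$n_climate_vars,
    climate_shift = 0,
    smoothing_scale = config$world$smoothing_scale,
    noise_sd = config$world$noise_sd,
    n_regions = config$world$n_regions,
    reserve_fraction = config$world$reserve_fraction,
    seed = derive_seed(seed, "world")
  )
  world <- make_world(wc)

  scenario_climates <- list(current = world$climate_current)
  for (scn in names(config$scenarios)) {
    shifted <- world$climate_current$values
    shifted[, , 1] <- shifted[, , 1] + config$scenarios[[scn]]
    scenario_climates[[scn]] <- rg_like(
      world$climate_current, shifted, bands = rg_bands(world$climate_current)
    )
  }

  pool <- make_species_pool(
    world, n_species = config$species$n_species,
    breadth_range = config$species$breadth_range,
    seed = derive_seed(seed, "pool")
  )
  effort <- if (isTRUE(config$species$effort_bias)) {
    make_effort_surface(world, config$species$effort_strength,
                        derive_seed(seed, "effort"))
  }
  occ_raw <- purrr::map_dfr(pool$truths, function(tr) {
    sample_occurrences(tr, world$climate_current, config$species$n_points,
                       effort_bias = effort,
                       seed = derive_seed(seed, paste0("occ_", tr$species_id)))
  })

  write_raster(world$climate_current, file.path(out_dir, "climate_current.asc"))
  for (scn in names(config$scenarios)) {
    write_raster(scenario_climates[[scn]],
                 file.path(out_dir, sprintf("climate_%s.asc", scn)))
  }
  write_raster(world$elevation, file.path(out_dir, "elevation.asc"))
  write_raster(world$regions, file.path(out_dir, "regions.asc"))
  write_raster(world$reserve_mask, file.path(out_dir, "reserve_mask.asc"))
  utils::write.csv(occ_raw, file.path(out_dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(pool$meta, file.path(out_dir, "species_meta.csv"),
                   row.names = FALSE)

  # --- prep ----------------------------------------------------------------
  bbox <- c(
    lon_min = world$config$lon_min,
    lat_min = world$config$lat_min,
    lon_max = world$config$lon_min +
      world$config$n_cols * world$config$cell_size,
    lat_max = world$config$lat_min +
      world$config$n_rows * world$config$cell_size
  )
  cleaned <- validate_and_filter(occ_raw, bbox,
                                 min_localities = config$prep$min_localities)
  prep_exclusions <- exclusion_log(cleaned)
  thinned <- thin_presences(cleaned,
                            min_sep_arcmin = config$prep$min_sep_arcmin,
                            seed = derive_seed(seed, "thin"))
  # the five-locality rule applies to independent (thinned) localities too
  counts <- dplyr::count(thinned, .data$species_id)
  ok_sp <- counts$species_id[counts$n >= config$prep$min_localities]
  thinned <- dplyr::filter(thinned, .data$species_id %in% ok_sp)
  utils::write.csv(thinned, file.path(out_dir, "occurrences_cleaned.csv"),
                   row.names = FALSE)
  uniformity <- uniformity_stats(thinned)
  jsonlite::write_json(as.list(uniformity),
                       file.path(out_dir, "uniformity.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- fit / project (two rounds) -----------------------------------------
  batch <- run_two_rounds(
    thinned, world, scenarios = scenario_climates,
    k_folds = config$model$k_folds,
    regularization = config$model$regularization,
    n_background = config$model$n_background,
    cor_threshold = config$model$cor_threshold,
    prune_tolerance = config$model$prune_tolerance,
    block_size = config$model$block_size,
    seed = derive_seed(seed, "model")
  )
  utils::write.csv(batch$status, file.path(out_dir, "model_status.csv"),
                   row.names = FALSE)
  model_json <- lapply(batch$models, function(m) {
    list(species_id = m$species_id, variables = m$variables,
         coefficients = as.list(m$coef_full),
         standardization = m$standardization,
         replicate_scores = m$replicate_scores,
         regularization = m$regularization,
         threshold = unname(batch$thresholds[m$species_id]))
  })
  jsonlite::write_json(model_json, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  analysis <- list(); priority <- list()
  if (length(config$scenarios) == 0) {
    notices <- c(notices,
                 "no future scenarios configured: analysis and prioritization skipped")
  } else if (length(batch$models) == 0) {
    notices <- c(notices,
                 "no species survived modelling: analysis and prioritization skipped")
  } else {
    drms <- lapply(names(scenario_climates), function(scn) {
      lapply(stats::setNames(names(batch$models), names(batch$models)),
             function(sp) {
               binarize(batch$suitability[[scn]][[sp]],
                        batch$thresholds[[sp]],
                        species_id = sp, scenario = scn)
             })
    })
    names(drms) <- names(scenario_climates)

    # --- analyze -----------------------------------------------------------
    richness <- lapply(drms, stack_richness)
    for (scn in names(richness)) {
      write_raster(richness[[scn]],
                   file.path(out_dir, sprintf("richness_%s.asc", scn)))
    }
    records <- list(); summaries <- list(); profiles <- list()
    for (scn in names(config$scenarios)) {
      rec <- compute_range_changes(drms$current, drms[[scn]],
                                   scenario = scn)
      records[[scn]] <- rec
      summaries[[scn]] <- summarize_groups(rec, pool$meta)
      profiles[[scn]] <- elevation_profile(drms$current, drms[[scn]],
                                           world$elevation)
      write_raster(richness_change(richness$current, richness[[scn]]),
                   file.path(out_dir,
                             sprintf("richness_change_%s.asc", scn)))
    }
    all_records <- dplyr::bind_rows(records)
    utils::write.csv(all_records, file.path(out_dir, "range_changes.csv"),
                     row.names = FALSE)
    utils::write.csv(
      dplyr::bind_rows(lapply(summaries, function(s) s$area_change)),
      file.path(out_dir, "group_area_change.csv"), row.names = FALSE)
    utils::write.csv(
      dplyr::bind_rows(lapply(summaries, function(s) s$shifts)),
      file.path(out_dir, "group_shifts.csv"), row.names = FALSE)
    utils::write.csv(
      purrr::map_dfr(names(profiles),
                     function(scn) dplyr::mutate(profiles[[scn]]$profile,
                                                 scenario = scn)),
      file.path(out_dir, "elevation_profile.csv"), row.names = FALSE)
    analysis <- list(drms = drms, richness = richness, records = records,
                     summaries = summaries, profiles = profiles)

    # --- prioritize ---------------------------------------------------------
    coverage <- list()
    for (scn in names(config$scenarios)) {
      wts <- compute_weights(records[[scn]], pool$meta,
                             w_min = config$prioritization$w_min,
                             w_max = config$prioritization$w_max)
      layers <- batch$suitability[[scn]][wts$species_id]
      rank_open <- caz_rank(layers, wts,
                            warp_factor = config$prioritization$warp_factor)
      write_raster(rank_open$rank_grid,
                   file.path(out_dir, sprintf("rank_%s.asc", scn)))
      scen_priority <- list(unmasked = rank_open)
      if (isTRUE(config$prioritization$masked)) {
        rank_masked <- caz_rank(
          layers, wts, warp_factor = config$prioritization$warp_factor,
          mask = world$reserve_mask)
        write_raster(rank_masked$rank_grid,
                     file.path(out_dir, sprintf("rank_%s_masked.asc", scn)))
        scen_priority$masked <- rank_masked
      }
      for (f in config$prioritization$fractions) {
        top <- top_fraction(rank_open, f)
        write_raster(top, file.path(
          out_dir, sprintf("top%g_%s.asc", 100 * f, scn)))
        coverage[[sprintf("%s_top%g", scn, 100 * f)]] <-
          coverage_stats(top, world$reserve_mask)
      }
      priority[[scn]] <- scen_priority
    }
    jsonlite::write_json(coverage, file.path(out_dir, "coverage.json"),
                         auto_unbox = TRUE, digits = NA)
    priority$coverage <- coverage
  }

  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("avishift")),
    seed = seed,
    config = unclass(config),
    counts = list(
      species_simulated = config$species$n_species,
      occurrences_raw = nrow(occ_raw),
      occurrences_cleaned = nrow(thinned),
      species_cleaned = length(unique(thinned$species_id)),
      species_modelled = length(batch$models),
      species_excluded = sum(batch$status$action != "modelled")
    ),
    exclusions = list(
      prep = prep_exclusions,
      model = batch$status[batch$status$action != "modelled", ]
    ),
    notices = notices,
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)

  invisible(list(world = world, pool = pool, occurrences = occ_raw,
                 cleaned = thinned, uniformity = uniformity, batch = batch,
                 analysis = analysis, priority = priority,
                 manifest = manifest, out_dir = out_dir))
}
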
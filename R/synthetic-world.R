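#' Configure a synthetic study region
#'
#' Describes a rectangular lon/lat world on which seeded climate, elevation,
#' region and reserve layers are generated. Each climate band is a
#' deterministic latitudinal gradient plus spatially smoothed seeded noise;
#' the future scenario is the current scenario plus a per-band additive
#' offset, so the imposed climate displacement is known exactly.
#'
#' @param n_rows,n_cols Grid dimensions (both at least 8). Default 60 x 80.
#' @param lon_min,lat_min South-west corner of the grid, decimal degrees.
#' @param cell_size Cell size in decimal degrees (default 0.1, i.e. desk-scale
#'   rather than the 30 arc-second resolution of global climatologies).
#' @param n_climate_vars Number of climate bands. Band 1 (`"temp"`) carries
#'   the dominant north-south temperature gradient; remaining bands
#'   (`"clim2"`, ...) have weaker gradients of alternating sign.
#' @param climate_shift Per-band additive offset applied to build the future
#'   scenario, recycled to `n_climate_vars`. Units of the band itself.
#' @param smoothing_scale Half-width (cells) of the box kernel used to
#'   spatially autocorrelate the noise field.
#' @param noise_sd Standard deviation of the pre-smoothing white noise,
#'   recycled per band.
#' @param n_regions Number of contiguous axis-aligned region blocks
#'   (province analogues), at least 4.
#' @param reserve_fraction Fraction of cells inside the reserve mask.
#' @param seed Integer seed; the whole world is a pure function of the
#'   configuration including this seed.
#'
#' @return A `world_config` list.
#' @export
world_config <- function(n_rows = 60, n_cols = 80, lon_min = 100,
                         lat_min = 20, cell_size = 0.1, n_climate_vars = 4,
                         climate_shift = 0, smoothing_scale = 4,
                         noise_sd = 1.5, n_regions = 4,
                         reserve_fraction = 0.15, seed = 1L) {
  if (n_rows < 8 || n_cols < 8) {
    rlang::abort("Grid must be at least 8 x 8 cells.",
                 class = "avishift_error_config")
  }
  if (cell_size <= 0) {
    rlang::abort("`cell_size` must be positive.",
                 class = "avishift_error_config")
  }
  if (n_climate_vars < 1 || n_regions < 4) {
    rlang::abort("Need at least 1 climate band and 4 regions.",
                 class = "avishift_error_config")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      lon_min = lon_min, lat_min = lat_min, cell_size = cell_size,
      n_climate_vars = as.integer(n_climate_vars),
      climate_shift = rep_len(climate_shift, n_climate_vars),
      smoothing_scale = as.integer(smoothing_scale),
      noise_sd = rep_len(noise_sd, n_climate_vars),
      n_regions = as.integer(n_regions),
      reserve_fraction = reserve_fraction,
      seed = as.integer(seed)
    ),
    class = "world_config"
  )
}

climate_band_names <- function(n) {
  if (n == 1L) "temp" else c("temp", paste0("clim", 2:n))
}

#' Generate a seeded synthetic world
#'
#' Builds the full set of co-registered layers downstream stages need:
#' current and future multi-band climate, elevation, an integer region
#' partition, and a binary reserve mask. All grids share shape and
#' georeference; the future climate differs from the current climate by
#' exactly the configured per-band offset.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world` with elements `climate_current`,
#'   `climate_future`, `elevation`, `regions`, `reserve_mask` (all
#'   `raster_grid`) and `config`.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  nr <- config$n_rows; nc <- config$n_cols
  bands <- climate_band_names(config$n_climate_vars)

  # latitudes per row, row 1 northernmost
  lat <- config$lat_min + (nr - seq_len(nr) + 0.5) * config$cell_size
  lat_span <- nr * config$cell_size

  with_seed(derive_seed(config$seed, "make_world"), {
    lon <- config$lon_min + (seq_len(nc) - 0.5) * config$cell_size
    lon_span <- nc * config$cell_size
    clim <- array(NA_real_, dim = c(nr, nc, config$n_climate_vars))
    for (b in seq_len(config$n_climate_vars)) {
      # band 1: temperature analogue falling poleward, spanning ~10 units
      # over the grid; later bands are precipitation-like with east-west
      # (coastal/continental) gradients of alternating sign, so bands are
      # correlated only moderately, as real bioclim layers are
      grad <- if (b == 1L) {
        matrix(rep(-10 / lat_span * (lat - config$lat_min), nc), nrow = nr)
      } else {
        slope <- ((-1)^b) * (5 + b) / lon_span
        matrix(rep(slope * (lon - config$lon_min), each = nr), nrow = nr)
      }
      base <- if (b == 1L) 25 else 10 * b
      noise <- box_smooth(
        matrix(stats::rnorm(nr * nc, sd = config$noise_sd[b]), nr, nc),
        config$smoothing_scale
      )
      clim[, , b] <- base + grad + noise
    }
    climate_current <- raster_grid(clim, config$lon_min, config$lat_min,
                                   config$cell_size, bands = bands)

    shifted <- clim
    for (b in seq_len(config$n_climate_vars)) {
      shifted[, , b] <- clim[, , b] + config$climate_shift[b]
    }
    climate_future <- raster_grid(shifted, config$lon_min, config$lat_min,
                                  config$cell_size, bands = bands)

    # terrain: high in the west, lowlands in the east, plus smoothed relief
    colfrac <- (nc - matrix(rep(seq_len(nc), each = nr), nr, nc)) / nc
    relief <- box_smooth(matrix(stats::rnorm(nr * nc, sd = 400), nr, nc),
                         config$smoothing_scale)
    elev <- pmax(5200 * colfrac^2 + relief, 0)
    elevation <- raster_grid(elev, config$lon_min, config$lat_min,
                             config$cell_size, bands = "elevation")

    # axis-aligned contiguous blocks
    rb <- max(1L, floor(sqrt(config$n_regions)))
    cb <- ceiling(config$n_regions / rb)
    row_blk <- pmin(ceiling(seq_len(nr) / (nr / rb)), rb)
    col_blk <- pmin(ceiling(seq_len(nc) / (nc / cb)), cb)
    reg <- outer(row_blk, col_blk, function(r, c) (r - 1L) * cb + c)
    reg[reg > config$n_regions] <- config$n_regions
    regions <- raster_grid(reg, config$lon_min, config$lat_min,
                           config$cell_size, bands = "region")

    # reserves: upper tail of a smoothed noise surface -> clumped patches
    field <- box_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                        config$smoothing_scale)
    thr <- stats::quantile(field, 1 - config$reserve_fraction)
    reserve_mask <- raster_grid((field >= thr) * 1, config$lon_min,
                                config$lat_min, config$cell_size,
                                bands = "reserve")
  })

  structure(
    list(climate_current = climate_current, climate_future = climate_future,
         elevation = elevation, regions = regions,
         reserve_mask = reserve_mask, config = config),
    class = "synthetic_world"
  )
}

#' Define a virtual species with a Gaussian climatic niche
#'
#' Ground truth for recovery tests: occupancy probability falls off as a
#' Gaussian in each named climate variable around `niche_optimum` with scale
#' `niche_breadth`.
#'
#' @param species_id Identifier string.
#' @param niche_optimum Named numeric vector of niche optima (names must match
#'   climate band names).
#' @param niche_breadth Named positive numeric vector, same names.
#' @param max_prevalence Peak occupancy probability, in (0, 1].
#' @param migratory,endemic,threatened Logical trait flags.
#' @return A `species_truth` list.
#' @export
species_truth <- function(species_id, niche_optimum, niche_breadth,
                          max_prevalence = 1, migratory = FALSE,
                          endemic = FALSE, threatened = FALSE) {
  if (any(niche_breadth <= 0)) {
    rlang::abort("`niche_breadth` must be positive for every variable.",
                 class = "avishift_error_config")
  }
  if (!setequal(names(niche_optimum), names(niche_breadth))) {
    rlang::abort("`niche_optimum` and `niche_breadth` must share names.",
                 class = "avishift_error_config")
  }
  if (max_prevalence <= 0 || max_prevalence > 1) {
    rlang::abort("`max_prevalence` must lie in (0, 1].",
                 class = "avishift_error_config")
  }
  structure(
    list(species_id = species_id, niche_optimum = niche_optimum,
         niche_breadth = niche_breadth[names(niche_optimum)],
         max_prevalence = max_prevalence,
         migratory = isTRUE(migratory), endemic = isTRUE(endemic),
         threatened = isTRUE(threatened)),
    class = "species_truth"
  )
}

#' True suitability surface of a virtual species
#'
#' Evaluates the generating Gaussian niche over a climate raster:
#' `max_prevalence * exp(-0.5 * sum(((x - optimum) / breadth)^2))`.
#'
#' @param truth A [species_truth()].
#' @param climate Multi-band climate `raster_grid`.
#' @return A single-band `raster_grid` of occupancy probabilities.
#' @export
true_suitability <- function(truth, climate) {
  vars <- names(truth$niche_optimum)
  missing <- setdiff(vars, rg_bands(climate))
  if (length(missing)) {
    rlang::abort(paste("Climate lacks band(s):",
                       paste(missing, collapse = ", ")),
                 class = "avishift_error_projection")
  }
  q <- matrix(0, rg_nrow(climate), rg_ncol(climate))
  for (v in vars) {
    z <- (rg_band(climate, v) - truth$niche_optimum[[v]]) /
      truth$niche_breadth[[v]]
    q <- q + z^2
  }
  rg_like(climate, truth$max_prevalence * exp(-0.5 * q),
          bands = "suitability")
}

#' Sample effort-biased presence-only occurrences
#'
#' Draws occurrence points from grid cells with probability proportional to
#' the species' true Gaussian suitability, optionally multiplied by an
#' observation-effort surface (emulating the geographic reporting bias of
#' citizen-science records). Points are jittered uniformly within their cell.
#'
#' @param truth A [species_truth()].
#' @param climate Multi-band climate `raster_grid` covering the study area.
#' @param n_points Number of points to draw (with replacement across cells).
#' @param effort_bias Optional single-band `raster_grid` of non-negative
#'   effort multipliers; `NULL` for unbiased sampling.
#' @param seed Integer seed.
#' @return A tibble with columns `species_id`, `lon`, `lat`.
#' @export
sample_occurrences <- function(truth, climate, n_points,
                               effort_bias = NULL, seed = 1L) {
  stopifnot(n_points >= 1)
  suit <- rg_band(true_suitability(truth, climate), 1L)
  w <- as.vector(suit)
  if (!is.null(effort_bias)) {
    rg_check_aligned(climate, effort_bias)
    w <- w * as.vector(rg_band(effort_bias, 1L))
  }
  w[is.na(w)] <- 0
  if (all(w == 0)) {
    rlang::abort(
      paste0("Species '", truth$species_id,
             "' has zero sampling weight everywhere (degenerate niche)."),
      class = "avishift_error_degenerate_species"
    )
  }
  nr <- rg_nrow(climate)
  with_seed(seed, {
    idx <- sample.int(length(w), n_points, replace = TRUE, prob = w)
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
    cs <- climate$cellsize
    lon <- climate$xmin + (col - 1L) * cs + stats::runif(n_points) * cs
    lat <- climate$ymin + (nr - row) * cs + stats::runif(n_points) * cs
    tibble::tibble(species_id = truth$species_id, lon = lon, lat = lat)
  })
}

#' Generate a pool of virtual species and their metadata
#'
#' Draws `n_species` Gaussian-niche species whose temperature optima span the
#' interior of the current climate, so most species occupy a latitudinal
#' band and track the gradient when the climate shifts. Roughly half the
#' species also respond to a second climate band when one exists.
#'
#' @param world A `synthetic_world` from [make_world()].
#' @param n_species Number of species.
#' @param breadth_range Range of temperature niche breadths (units of the
#'   temperature band) drawn uniformly.
#' @param seed Integer seed.
#' @return A list with `truths` (list of [species_truth()]) and `meta`
#'   (tibble: `species_id`, `migratory`, `endemic`, `threatened`).
#' @export
make_species_pool <- function(world, n_species = 20,
                              breadth_range = c(0.8, 1.6), seed = 1L) {
  temp <- rg_band(world$climate_current, "temp")
  qs <- stats::quantile(temp, c(0.15, 0.85), na.rm = TRUE)
  bands <- rg_bands(world$climate_current)
  with_seed(derive_seed(seed, "species_pool"), {
    opts <- stats::runif(n_species, qs[1], qs[2])
    brs <- stats::runif(n_species, breadth_range[1], breadth_range[2])
    use2 <- length(bands) > 1 & (seq_len(n_species) %% 2 == 0)
    migratory <- stats::runif(n_species) < 0.5
    endemic <- stats::runif(n_species) < 0.3
    threatened <- stats::runif(n_species) < 0.2
    truths <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      opt <- c(temp = opts[i])
      br <- c(temp = brs[i])
      if (use2[i]) {
        b2 <- rg_band(world$climate_current, bands[2])
        opt[bands[2]] <- stats::runif(1, stats::quantile(b2, 0.2),
                                      stats::quantile(b2, 0.8))
        br[bands[2]] <- stats::runif(1, 1.5, 3)
      }
      truths[[i]] <- species_truth(
        species_id = sprintf("sp%03d", i),
        niche_optimum = opt, niche_breadth = br,
        migratory = migratory[i], endemic = endemic[i],
        threatened = threatened[i]
      )
    }
    list(
      truths = truths,
      meta = tibble::tibble(
        species_id = sprintf("sp%03d", seq_len(n_species)),
        migratory = migratory, endemic = endemic, threatened = threatened
      )
    )
  })
}
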
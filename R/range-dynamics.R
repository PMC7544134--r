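#' Maximum test sensitivity plus specificity threshold
#'
#' Chooses the suitability cutoff that maximizes sensitivity (share of test
#' presences scoring at or above the cutoff) plus specificity (share of
#' background scoring below it). Candidate cutoffs are the midpoints between
#' adjacent distinct pooled scores plus the pooled extremes; among ties the
#' smallest maximizing cutoff is returned.
#'
#' @param test_presence_scores Held-out presence suitability scores.
#' @param background_scores Background suitability scores.
#' @return The threshold (numeric scalar).
#' @export
mtss_threshold <- function(test_presence_scores, background_scores) {
  p <- test_presence_scores; b <- background_scores
  if (length(p) == 0 || length(b) == 0) {
    rlang::abort("Both score lists must be non-empty.",
                 class = "avishift_error_insufficient_data")
  }
  s <- sort(unique(c(p, b)))
  cands <- sort(unique(c(s[1], (s[-1] + s[-length(s)]) / 2,
                         s[length(s)])))
  tss <- vapply(cands, function(t) mean(p >= t) + mean(b < t), numeric(1))
  cands[which.max(tss)] # which.max takes the first (smallest) maximizer
}

#' Binarize a suitability surface into a range map
#'
#' Cells with suitability at or above the threshold become presence (1),
#' below become absence (0); missing cells stay missing. The result is the
#' species' predicted distribution range map for a scenario.
#'
#' @param suitability Single-band suitability `raster_grid` in (0, 1).
#' @param threshold Cutoff in (0, 1), typically from [mtss_threshold()].
#' @param species_id,scenario Labels carried on the result.
#' @return A `binary_range` object (`grid`, `threshold`, `species_id`,
#'   `scenario`).
#' @export
binarize <- function(suitability, threshold, species_id = NA_character_,
                     scenario = NA_character_) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    rlang::abort("`threshold` must lie strictly inside (0, 1).",
                 class = "avishift_error_config")
  }
  m <- rg_band(suitability, 1L)
  out <- (m >= threshold) * 1
  if (all(out == 0, na.rm = TRUE)) {
    rlang::warn(paste0("Threshold exceeds all suitabilities",
                       if (!is.na(species_id)) paste0(" for ", species_id),
                       ": empty range map."))
  }
  structure(
    list(grid = rg_like(suitability, out, bands = "presence"),
         threshold = threshold, species_id = species_id,
         scenario = scenario),
    class = "binary_range"
  )
}

#' @export
print.binary_range <- function(x, ...) {
  m <- rg_band(x$grid, 1L)
  cat(sprintf("<binary_range> %s [%s]: %d presence cells (threshold %.4f)\n",
              x$species_id, x$scenario, sum(m == 1, na.rm = TRUE),
              x$threshold))
  invisible(x)
}

drm_grid <- function(x) {
  if (inherits(x, "binary_range")) x$grid else x
}

# presence cell centers of a binary range as a tibble (lon, lat)
drm_cells <- function(x) {
  grid <- drm_grid(x)
  m <- rg_band(grid, 1L)
  idx <- which(!is.na(m) & m == 1)
  nr <- rg_nrow(grid)
  tibble::tibble(
    lon = rg_lon(grid)[((idx - 1L) %/% nr) + 1L],
    lat = rg_lat(grid)[((idx - 1L) %% nr) + 1L]
  )
}

#' Area change between two range maps
#'
#' Areas are reported both as presence-cell counts and in square kilometers
#' (latitude-dependent spherical cell area); the percentage change uses cell
#' counts: `100 * (future - current) / current`.
#'
#' @param current,future `binary_range` maps on the same grid.
#' @return A one-row tibble: `species_id`, `area_current_cells`,
#'   `area_future_cells`, `area_current_km2`, `area_future_km2`,
#'   `pct_change`.
#' @export
range_change <- function(current, future) {
  gc <- drm_grid(current); gf <- drm_grid(future)
  rg_check_aligned(gc, gf)
  mc <- rg_band(gc, 1L); mf <- rg_band(gf, 1L)
  area <- rg_cell_area_km2(gc)
  a_c <- sum(mc == 1, na.rm = TRUE)
  a_f <- sum(mf == 1, na.rm = TRUE)
  if (a_c == 0) {
    rlang::abort("Current range is empty: percentage change undefined.",
                 class = "avishift_error_undefined_change")
  }
  tibble::tibble(
    species_id = if (inherits(current, "binary_range"))
      current$species_id else NA_character_,
    area_current_cells = a_c, area_future_cells = a_f,
    area_current_km2 = sum(area[!is.na(mc) & mc == 1]),
    area_future_km2 = sum(area[!is.na(mf) & mf == 1]),
    pct_change = 100 * (a_f - a_c) / a_c
  )
}

#' Geometric median of a point set
#'
#' The location minimizing the summed Euclidean distance to all points,
#' computed by Weiszfeld iterative reweighting in a local equirectangular
#' frame about the centroid (so east-west degrees are scaled by cos of the
#' central latitude), to a tolerance of 1e-8 degrees. A single point is its
#' own median.
#'
#' @param lon,lat Point coordinates, decimal degrees.
#' @param tol Convergence tolerance, degrees.
#' @return Named numeric vector `c(lon, lat)`.
#' @export
geometric_median <- function(lon, lat, tol = 1e-8) {
  n <- length(lon)
  if (n == 0) {
    rlang::abort("Cannot locate the median center of an empty set.",
                 class = "avishift_error_no_center")
  }
  if (n == 1) return(c(lon = lon, lat = lat))
  lat0 <- mean(lat); lon0 <- mean(lon)
  k <- cos(lat0 * pi / 180)
  x <- (lon - lon0) * k; y <- lat - lat0
  cx <- mean(x); cy <- mean(y)
  for (it in 1:1000) {
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    d <- pmax(d, 1e-12) # guard: estimate coinciding with a data point
    w <- 1 / d
    nx <- sum(w * x) / sum(w)
    ny <- sum(w * y) / sum(w)
    if (max(abs(nx - cx), abs(ny - cy)) < tol) {
      cx <- nx; cy <- ny
      break
    }
    cx <- nx; cy <- ny
  }
  c(lon = lon0 + cx / k, lat = lat0 + cy)
}

#' Median center of a range map
#'
#' @param x A `binary_range` (or 0/1 `raster_grid`).
#' @return Named numeric `c(lon, lat)` of the geometric median of presence
#'   cell centers.
#' @export
range_median_center <- function(x) {
  cells <- drm_cells(x)
  if (nrow(cells) == 0) {
    rlang::abort("Range map has no presence cells.",
                 class = "avishift_error_no_center")
  }
  geometric_median(cells$lon, cells$lat)
}

#' Displacement vector between two range centers
#'
#' Great-circle distance (haversine, R = 6371 km) and initial bearing from
#' north between the median centers of a species' current and future ranges,
#' with the compass quadrant given by the signs of the lon/lat displacement
#' (north requires a strictly positive latitude shift; boundary cases with a
#' zero component are flagged).
#'
#' @param center_current,center_future Named numerics `c(lon, lat)`.
#' @return One-row tibble: `shift_km`, `bearing_deg`, `quadrant`, `poleward`,
#'   `boundary`.
#' @export
shift_vector <- function(center_current, center_future) {
  dlon <- center_future[["lon"]] - center_current[["lon"]]
  dlat <- center_future[["lat"]] - center_current[["lat"]]
  km <- haversine_km(center_current[["lon"]], center_current[["lat"]],
                     center_future[["lon"]], center_future[["lat"]])
  if (dlon == 0 && dlat == 0) {
    return(tibble::tibble(shift_km = 0, bearing_deg = NA_real_,
                          quadrant = NA_character_,
                          poleward = NA_character_, boundary = TRUE))
  }
  bearing <- geosphere::bearing(
    c(center_current[["lon"]], center_current[["lat"]]),
    c(center_future[["lon"]], center_future[["lat"]])
  ) %% 360
  ew <- if (dlon > 0) "E" else "W"
  ns <- if (dlat > 0) "N" else "S"
  tibble::tibble(
    shift_km = km,
    bearing_deg = bearing,
    quadrant = paste0(ns, ew),
    poleward = if (dlat > 0) "north" else "south",
    boundary = dlon == 0 || dlat == 0
  )
}

#' Per-species range-change records across a scenario pair
#'
#' Combines [range_change()], [range_median_center()] and [shift_vector()]
#' over matched current/future range maps. Species with an empty current
#' range are excluded and logged in the `"exclusions"` attribute.
#'
#' @param drms_current,drms_future Named lists of `binary_range` maps keyed
#'   by species.
#' @param scenario Label stored in the output.
#' @return A tibble with one row per species: areas, `pct_change`, median
#'   centers, `shift_km`, `bearing_deg`, `quadrant`, `poleward`.
#' @export
compute_range_changes <- function(drms_current, drms_future,
                                  scenario = "future") {
  species <- intersect(names(drms_current), names(drms_future))
  rows <- list(); excluded <- list()
  for (sp in species) {
    rec <- tryCatch({
      rc <- range_change(drms_current[[sp]], drms_future[[sp]])
      cc <- range_median_center(drms_current[[sp]])
      cf <- tryCatch(range_median_center(drms_future[[sp]]),
                     error = function(e) NULL)
      sv <- if (is.null(cf)) {
        tibble::tibble(shift_km = NA_real_, bearing_deg = NA_real_,
                       quadrant = NA_character_, poleward = NA_character_,
                       boundary = NA)
      } else {
        shift_vector(cc, cf)
      }
      dplyr::bind_cols(
        tibble::tibble(species_id = sp, scenario = scenario),
        rc[-1],
        tibble::tibble(
          center_current_lon = cc[["lon"]], center_current_lat = cc[["lat"]],
          center_future_lon = if (is.null(cf)) NA_real_ else cf[["lon"]],
          center_future_lat = if (is.null(cf)) NA_real_ else cf[["lat"]]
        ),
        sv
      )
    }, error = function(e) NULL)
    if (is.null(rec)) {
      excluded[[sp]] <- tibble::tibble(
        species_id = sp, reason = "empty current range: change undefined")
    } else {
      rows[[sp]] <- rec
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- dplyr::bind_rows(excluded)
  out
}

#' Stack binary range maps into a species-richness surface
#'
#' Per-cell count of species present. Missing cells in individual range maps
#' count as absence; an optional land mask re-imposes missingness off land.
#'
#' @param drms List of `binary_range` maps on a common grid.
#' @param land_mask Optional `raster_grid`; cells where it is `NA` or 0
#'   become missing in the result.
#' @param template Optional `raster_grid` fixing the output grid; required
#'   when `drms` is empty (the result is then all zero).
#' @return A single-band `raster_grid` of counts.
#' @export
stack_richness <- function(drms, land_mask = NULL, template = NULL) {
  if (length(drms) == 0 && is.null(template)) {
    rlang::abort("Cannot stack an empty set of range maps without a template.",
                 class = "avishift_error_empty_input")
  }
  template <- template %||% drm_grid(drms[[1]])
  acc <- matrix(0, rg_nrow(template), rg_ncol(template))
  for (d in drms) {
    g <- drm_grid(d)
    rg_check_aligned(template, g)
    m <- rg_band(g, 1L)
    m[is.na(m)] <- 0
    acc <- acc + m
  }
  if (!is.null(land_mask)) {
    rg_check_aligned(template, land_mask)
    lm <- rg_band(land_mask, 1L)
    acc[is.na(lm) | lm == 0] <- NA_real_
  }
  rg_like(template, acc, bands = "richness")
}

#' Signed richness-change surface
#'
#' @param richness_current,richness_future Aligned richness rasters.
#' @return A `raster_grid`: per-cell `future - current`.
#' @export
richness_change <- function(richness_current, richness_future) {
  rg_check_aligned(richness_current, richness_future)
  rg_like(richness_current,
          rg_band(richness_future, 1L) - rg_band(richness_current, 1L),
          bands = "richness_change")
}

#' Elevation bands used for diversity profiles
#'
#' Half-open bands in meters: 0-500, 500-1000, ..., 3500-4000, 4000-5000,
#' and 5000 m upward, labelled A through J.
#' @export
elevation_band_edges <- c(0, 500, 1000, 1500, 2000, 2500, 3000, 3500,
                          4000, 5000, Inf)

#' Species diversity by elevation band and its turning point
#'
#' For each elevation band (half-open `[lo, hi)`), diversity is the number
#' of species with at least one presence cell whose elevation falls in the
#' band, per scenario. The turning point is the lowest band edge such that
#' the future-minus-current diversity change is non-positive in every band
#' entirely below it and non-negative in every band at or above it, with at
#' least one strict loss below and one strict gain at or above (so an
#' unchanged profile has no turning point).
#'
#' @param drms_current,drms_future Named lists of `binary_range` maps.
#' @param elevation Elevation `raster_grid` (meters), aligned with the maps.
#' @param band_edges Strictly increasing band boundaries (meters); default
#'   [elevation_band_edges].
#' @return An `elevation_profile`: `profile` tibble (`band`, `lo`, `hi`,
#'   `diversity_current`, `diversity_future`, `change`) and `turning_point`
#'   (meters, or `NA`).
#' @export
elevation_profile <- function(drms_current, drms_future, elevation,
                              band_edges = elevation_band_edges) {
  if (any(diff(band_edges) <= 0)) {
    rlang::abort("`band_edges` must be strictly increasing.",
                 class = "avishift_error_config")
  }
  n_band <- length(band_edges) - 1
  labels <- make.unique(LETTERS[((seq_len(n_band) - 1) %% 26) + 1])
  elev <- rg_band(elevation, 1L)

  count_bands <- function(drms) {
    counts <- integer(n_band)
    for (d in drms) {
      g <- drm_grid(d)
      rg_check_aligned(elevation, g)
      m <- rg_band(g, 1L)
      e <- elev[!is.na(m) & m == 1]
      e <- e[!is.na(e)]
      if (length(e) == 0) next
      in_band <- findInterval(e, band_edges, rightmost.closed = FALSE)
      counts <- counts + (seq_len(n_band) %in% in_band)
    }
    counts
  }
  cur <- count_bands(drms_current)
  fut <- count_bands(drms_future)
  change <- fut - cur

  turning <- NA_real_
  for (i in 2:n_band) { # candidate edges between bands
    e <- band_edges[i]
    below <- seq_len(i - 1)
    above <- i:n_band
    if (all(change[below] <= 0) && all(change[above] >= 0) &&
        any(change[below] < 0) && any(change[above] > 0)) {
      turning <- e
      break
    }
  }

  structure(
    list(
      profile = tibble::tibble(
        band = labels,
        lo = band_edges[-length(band_edges)], hi = band_edges[-1],
        diversity_current = cur, diversity_future = fut, change = change
      ),
      turning_point = turning
    ),
    class = "elevation_profile"
  )
}

#' @export
print.elevation_profile <- function(x, ...) {
  cat("<elevation_profile>\n")
  print(x$profile)
  cat("turning point:",
      if (is.na(x$turning_point)) "none" else
        paste(x$turning_point, "m"), "\n")
  invisible(x)
}

#' @method tidy elevation_profile
#' @export
tidy.elevation_profile <- function(x, ...) x$profile

#' Group summaries of range changes and shifts
#'
#' Reproduces the standard reporting cuts: per group (all species, migratory,
#' resident), counts and mean percentage change for range-reducing versus
#' range-expanding species; counts and mean shift distance for north- versus
#' south-moving species; and per-quadrant counts with mean shift distances.
#' Species with exactly zero change fall in neither the reduce nor the
#' expand class and are logged in the `"zero_change"` attribute.
#'
#' @param records Range-change tibble from [compute_range_changes()].
#' @param meta Species metadata tibble (`species_id`, `migratory`, `endemic`,
#'   `threatened`).
#' @return A `group_summary` list of tibbles: `area_change`, `shifts`,
#'   `quadrants`.
#' @export
summarize_groups <- function(records, meta) {
  missing <- setdiff(records$species_id, meta$species_id)
  if (length(missing)) {
    rlang::abort(paste("Species missing from metadata:",
                       paste(missing, collapse = ", ")),
                 class = "avishift_error_keying")
  }
  df <- dplyr::left_join(records, meta, by = "species_id")
  df$group_all <- "all"
  df$group_mig <- ifelse(df$migratory, "migratory", "resident")

  long <- dplyr::bind_rows(
    dplyr::rename(dplyr::select(df, -"group_mig"), group = "group_all"),
    dplyr::rename(dplyr::select(df, -"group_all"), group = "group_mig")
  )

  area <- long |>
    dplyr::filter(.data$pct_change != 0) |>
    dplyr::mutate(direction = ifelse(.data$pct_change < 0, "reduce",
                                     "expand")) |>
    dplyr::group_by(.data$scenario, .data$group, .data$direction) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_pct_change = mean(.data$pct_change),
                     .groups = "drop")

  shifts <- long |>
    dplyr::filter(!is.na(.data$poleward)) |>
    dplyr::group_by(.data$scenario, .data$group, .data$poleward) |>
    dplyr::summarise(n = dplyr::n(), mean_shift_km = mean(.data$shift_km),
                     .groups = "drop")

  quadrants <- long |>
    dplyr::filter(!is.na(.data$quadrant)) |>
    dplyr::group_by(.data$scenario, .data$group, .data$quadrant) |>
    dplyr::summarise(n = dplyr::n(), mean_shift_km = mean(.data$shift_km),
                     .groups = "drop")

  out <- structure(
    list(area_change = area, shifts = shifts, quadrants = quadrants),
    class = "group_summary"
  )
  attr(out, "zero_change") <- df$species_id[df$pct_change == 0]
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary>\n-- area change --\n")
  print(x$area_change)
  cat("-- shifts --\n")
  print(x$shifts)
  invisible(x)
}
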
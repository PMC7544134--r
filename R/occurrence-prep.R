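#' Validate, deduplicate and filter occurrence records
#'
#' Cleans a presence-only occurrence table: rows with missing or physically
#' impossible coordinates are dropped, rows outside the study bounding box
#' are dropped, exact duplicate localities (identical lon/lat within a
#' species) are collapsed, and species left with fewer than `min_localities`
#' independent localities are removed entirely. An exclusion log recording
#' every dropped species and the reason is attached as the `"exclusions"`
#' attribute (see [exclusion_log()]).
#'
#' @param points Tibble/data frame with columns `species_id`, `lon`, `lat`.
#' @param study_bbox Named numeric vector `c(lon_min, lat_min, lon_max,
#'   lat_max)` or a list with those names.
#' @param min_localities Minimum number of distinct localities a species must
#'   retain (default 5: species with four or fewer are excluded).
#' @return A tibble of retained rows, with the exclusion log attached.
#' @export
validate_and_filter <- function(points, study_bbox, min_localities = 5) {
  stopifnot(min_localities >= 1)
  if (nrow(points) == 0) {
    rlang::abort("Occurrence table is empty.",
                 class = "avishift_error_empty_input")
  }
  bb <- as.list(study_bbox)
  pts <- tibble::as_tibble(points)

  valid <- !is.na(pts$lon) & !is.na(pts$lat) &
    pts$lat >= -90 & pts$lat <= 90 & pts$lon >= -180 & pts$lon <= 180 &
    pts$lon >= bb$lon_min & pts$lon <= bb$lon_max &
    pts$lat >= bb$lat_min & pts$lat <= bb$lat_max
  kept <- dplyr::distinct(pts[valid, , drop = FALSE],
                          .data$species_id, .data$lon, .data$lat)

  counts <- dplyr::count(kept, .data$species_id)
  too_few <- counts$species_id[counts$n < min_localities]
  out <- dplyr::filter(kept, !.data$species_id %in% too_few)

  log <- dplyr::bind_rows(
    tibble::tibble(
      species_id = unique(pts$species_id[!valid & !is.na(pts$species_id)]),
      reason = "invalid or out-of-bounds rows dropped"
    ),
    tibble::tibble(
      species_id = too_few,
      reason = sprintf("fewer than %d independent localities", min_localities)
    )
  )
  attr(out, "exclusions") <- log
  out
}

#' Exclusion log of a cleaning step
#'
#' @param x A tibble returned by [validate_and_filter()].
#' @return A tibble with `species_id` and `reason`.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusions") %||%
    tibble::tibble(species_id = character(), reason = character())
}

#' Thin concentrated presence records
#'
#' Removes excess localities so that no two retained points of the same
#' species lie closer than `min_sep_arcmin` arc-minutes (Euclidean distance
#' in degree space). Points are visited in seeded random order and a point is
#' kept iff no already-kept conspecific point is within the separation, so
#' which member of a close pair survives is random but reproducible.
#'
#' @param points Occurrence tibble (`species_id`, `lon`, `lat`).
#' @param min_sep_arcmin Minimum pairwise separation, arc-minutes (default 1).
#' @param seed Integer seed controlling removal order.
#' @return A thinned subset of `points` (row order follows the input).
#' @export
thin_presences <- function(points, min_sep_arcmin = 1, seed = 1L) {
  stopifnot(min_sep_arcmin > 0)
  pts <- tibble::as_tibble(points)
  if (nrow(pts) <= 1) return(pts)
  sep <- min_sep_arcmin / 60 # degrees

  keep <- logical(nrow(pts))
  with_seed(seed, {
    for (sp in unique(pts$species_id)) {
      idx <- which(pts$species_id == sp)
      ord <- idx[sample.int(length(idx))]
      # coarse grid buckets of side `sep`: any conflicting pair shares a
      # bucket or sits in one of the 8 neighbours
      gx <- floor(pts$lon[ord] / sep)
      gy <- floor(pts$lat[ord] / sep)
      kept_at <- new.env(parent = emptyenv(), hash = TRUE)
      for (j in seq_along(ord)) {
        i <- ord[j]
        conflict <- FALSE
        for (dx in -1:1) {
          for (dy in -1:1) {
            key <- paste(gx[j] + dx, gy[j] + dy)
            prev <- kept_at[[key]]
            if (!is.null(prev)) {
              d2 <- (pts$lon[prev] - pts$lon[i])^2 +
                (pts$lat[prev] - pts$lat[i])^2
              if (any(d2 < sep^2)) conflict <- TRUE
            }
          }
          if (conflict) break
        }
        if (!conflict) {
          keep[i] <- TRUE
          key <- paste(gx[j], gy[j])
          kept_at[[key]] <- c(kept_at[[key]], i)
        }
      }
    }
  })
  pts[keep, , drop = FALSE]
}

#' Spatial-uniformity diagnostics of an occurrence set
#'
#' Summarizes how concentrated a point cloud is: the arithmetic mean center,
#' the geometric median center (the location minimizing summed distance to
#' all points), the great-circle offset between the two, the standard
#' distance (root-mean-square great-circle distance from the mean center),
#' and the share of points inside the standard-distance circle. A strongly
#' biased sampling effort shows up as a large mean/median offset and a
#' concentrated circle holding well over ~63% of points.
#'
#' @param points Occurrence tibble with `lon`, `lat` (at least 2 rows).
#' @return A one-row tibble: `n`, `mean_lon`, `mean_lat`, `median_lon`,
#'   `median_lat`, `center_offset_km`, `standard_distance_km`,
#'   `fraction_within_one_sd`.
#' @export
uniformity_stats <- function(points) {
  pts <- tibble::as_tibble(points)
  if (nrow(pts) < 2) {
    rlang::abort("Need at least 2 points for uniformity diagnostics.",
                 class = "avishift_error_insufficient_data")
  }
  mean_lon <- mean(pts$lon)
  mean_lat <- mean(pts$lat)
  med <- geometric_median(pts$lon, pts$lat)
  d <- haversine_km(pts$lon, pts$lat, mean_lon, mean_lat)
  sd_km <- sqrt(mean(d^2))
  tibble::tibble(
    n = nrow(pts),
    mean_lon = mean_lon, mean_lat = mean_lat,
    median_lon = med[["lon"]], median_lat = med[["lat"]],
    center_offset_km = haversine_km(mean_lon, mean_lat,
                                    med[["lon"]], med[["lat"]]),
    standard_distance_km = sd_km,
    fraction_within_one_sd = mean(d <= sd_km)
  )
}
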
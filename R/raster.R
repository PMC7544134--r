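#' Georeferenced gridded surface
#'
#' A lightweight in-memory raster: a row x col x band array of values on a
#' regular lon/lat (WGS84) grid, north-up (row 1 is the northernmost row),
#' cell-center registered. `NA` marks missing cells. This is the common
#' currency of the pipeline: climate layers, elevation, suitability
#' surfaces, binary range maps, richness and priority ranks are all
#' `raster_grid` objects.
#'
#' @param values A matrix (single band) or 3-D array (row, col, band).
#' @param xmin Longitude of the western edge of the grid, decimal degrees.
#' @param ymin Latitude of the southern edge of the grid, decimal degrees.
#' @param cellsize Cell size in decimal degrees (square cells).
#' @param bands Character vector of band names; defaults to `"band1"`, ...
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymin, cellsize, bands = NULL) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(nrow(values), ncol(values), 1L))
  }
  if (length(dim(values)) != 3L) {
    rlang::abort("`values` must be a matrix or a 3-D array.",
                 class = "avishift_error_config")
  }
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    rlang::abort("`cellsize` must be a single positive number.",
                 class = "avishift_error_config")
  }
  nb <- dim(values)[3L]
  if (is.null(bands)) bands <- paste0("band", seq_len(nb))
  if (length(bands) != nb) {
    rlang::abort("`bands` must name every layer of `values`.",
                 class = "avishift_error_config")
  }
  dimnames(values) <- list(NULL, NULL, bands)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<raster_grid> %d rows x %d cols x %d band(s) [%s]\n", d[1], d[2], d[3],
    paste(rg_bands(x), collapse = ", ")
  ))
  cat(sprintf(
    "  origin lon %.4f, lat %.4f; cell %.4f deg; extent lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
    x$xmin, x$ymin, x$cellsize,
    x$xmin, x$xmin + d[2] * x$cellsize, x$ymin, x$ymin + d[1] * x$cellsize
  ))
  invisible(x)
}

#' @rdname raster_grid
#' @param x A `raster_grid`.
#' @export
rg_nrow <- function(x) dim(x$values)[1L]

#' @rdname raster_grid
#' @export
rg_ncol <- function(x) dim(x$values)[2L]

#' @rdname raster_grid
#' @export
rg_bands <- function(x) dimnames(x$values)[[3L]]

#' Extract a single band as a matrix
#'
#' @param x A `raster_grid`.
#' @param band Band name or index.
#' @return A numeric matrix (rows north to south).
#' @export
rg_band <- function(x, band = 1L) {
  if (is.character(band) && !band %in% rg_bands(x)) {
    rlang::abort(paste0("Band '", band, "' not present in raster."),
                 class = "avishift_error_projection")
  }
  m <- x$values[, , band, drop = FALSE]
  dim(m) <- dim(x$values)[1:2] # drop only the band axis
  m
}

#' Cell-center coordinates
#'
#' Longitudes of columns and latitudes of rows (row 1 = northernmost).
#'
#' @param x A `raster_grid`.
#' @return For `rg_lon`/`rg_lat`, a numeric vector; for `rg_coords`, a tibble
#'   with one row per cell (`row`, `col`, `lon`, `lat`) in row-major order.
#' @export
rg_lon <- function(x) x$xmin + (seq_len(rg_ncol(x)) - 0.5) * x$cellsize

#' @rdname rg_lon
#' @export
rg_lat <- function(x) {
  nr <- rg_nrow(x)
  x$ymin + (nr - seq_len(nr) + 0.5) * x$cellsize
}

#' @rdname rg_lon
#' @export
rg_coords <- function(x) {
  nr <- rg_nrow(x); nc <- rg_ncol(x)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    lon = rep(rg_lon(x), each = nr),
    lat = rep(rg_lat(x), times = nc)
  )
}

#' Locate points on the grid
#'
#' Cell membership uses half-open intervals `[edge, edge + cellsize)` in both
#' axes, so a point on a shared edge belongs to the east/north-adjacent cell.
#'
#' @param x A `raster_grid`.
#' @param lon,lat Point coordinates, decimal degrees.
#' @return A tibble with `row`, `col` (NA for points off the grid).
#' @export
rg_cell_of <- function(x, lon, lat) {
  nr <- rg_nrow(x); nc <- rg_ncol(x)
  col <- floor((lon - x$xmin) / x$cellsize) + 1
  row <- nr - floor((lat - x$ymin) / x$cellsize)
  bad <- col < 1 | col > nc | row < 1 | row > nr |
    is.na(lon) | is.na(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Values of all bands at point locations
#'
#' @param x A `raster_grid`.
#' @param lon,lat Point coordinates.
#' @return A tibble with one column per band (NA off-grid or over missing cells).
#' @export
rg_extract <- function(x, lon, lat) {
  cells <- rg_cell_of(x, lon, lat)
  nr <- rg_nrow(x)
  out <- lapply(rg_bands(x), function(b) {
    m <- rg_band(x, b)
    v <- rep(NA_real_, nrow(cells))
    ok <- !is.na(cells$row)
    v[ok] <- m[cbind(cells$row[ok], cells$col[ok])]
    v
  })
  names(out) <- rg_bands(x)
  tibble::as_tibble(out)
}

#' Check that two rasters share shape and georeference
#'
#' @param a,b `raster_grid` objects.
#' @param tol Tolerance on origin/cellsize agreement, degrees.
#' @return Invisibly `TRUE`; aborts with an alignment error otherwise.
#' @export
rg_check_aligned <- function(a, b, tol = 1e-9) {
  ok <- rg_nrow(a) == rg_nrow(b) && rg_ncol(a) == rg_ncol(b) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
  if (!ok) {
    rlang::abort("Rasters are not aligned (shape or georeference differ).",
                 class = "avishift_error_alignment")
  }
  invisible(TRUE)
}

#' Per-cell area in square kilometers
#'
#' Spherical cell area with latitude-dependent width,
#' `A = R^2 * cellsize_rad^2 * cos(lat)`, R = 6371 km.
#'
#' @param x A `raster_grid`.
#' @return A matrix of cell areas (km^2) matching the grid shape.
#' @export
rg_cell_area_km2 <- function(x) {
  r_earth <- 6371
  d <- x$cellsize * pi / 180
  lat <- rg_lat(x) * pi / 180
  matrix(rep(r_earth^2 * d^2 * cos(lat), rg_ncol(x)),
         nrow = rg_nrow(x), ncol = rg_ncol(x))
}

#' Build a raster like another, with new values
#' @param x Template `raster_grid`.
#' @param values Matrix or 3-D array with the template's row/col shape.
#' @param bands Optional band names.
#' @return A `raster_grid` sharing `x`'s georeference.
#' @export
rg_like <- function(x, values, bands = NULL) {
  raster_grid(values, x$xmin, x$ymin, x$cellsize, bands = bands)
}

# ---- ESRI ASCII grid I/O --------------------------------------------------

NODATA_DEFAULT <- -9999

write_ascii_band <- function(m, xmin, ymin, cellsize, path,
                             nodata = NODATA_DEFAULT) {
  m[is.na(m)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10f", xmin),
    sprintf("yllcorner %.10f", ymin),
    sprintf("cellsize %.10f", cellsize),
    sprintf("NODATA_value %s", format(nodata))
  )
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(header, body), path)
}

read_ascii_band <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  list(values = m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange: a single-band raster round-trips through one
#' `.asc` file; a multiband raster is written as one `.asc` per band next to
#' a small JSON manifest (`<stem>.json`) listing band order. Values, the
#' missing-data mask and the georeference (origin, cell size) survive a
#' write/read cycle losslessly.
#'
#' @param path File path. For `write_raster` with multiple bands, the `.asc`
#'   extension is replaced per band by `_<band>.asc`.
#' @param grid A `raster_grid`.
#' @return `read_raster` returns a `raster_grid`; `write_raster` returns the
#'   path(s) written, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  bands <- rg_bands(grid)
  if (length(bands) == 1L) {
    write_ascii_band(rg_band(grid, 1L), grid$xmin, grid$ymin, grid$cellsize,
                     path)
    return(invisible(path))
  }
  stem <- sub("\\.asc$", "", path)
  files <- sprintf("%s_%s.asc", stem, bands)
  for (i in seq_along(bands)) {
    write_ascii_band(rg_band(grid, bands[i]), grid$xmin, grid$ymin,
                     grid$cellsize, files[i])
  }
  jsonlite::write_json(
    list(bands = bands, files = basename(files)),
    paste0(stem, ".json")
  )
  invisible(c(files, paste0(stem, ".json")))
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (grepl("\\.json$", path)) {
    man <- jsonlite::read_json(path, simplifyVector = TRUE)
    dir <- dirname(path)
    parts <- lapply(file.path(dir, man$files), read_ascii_band)
    first <- parts[[1]]
    for (p in parts[-1]) {
      if (nrow(p$values) != nrow(first$values) ||
          ncol(p$values) != ncol(first$values) ||
          abs(p$cellsize - first$cellsize) > 1e-9) {
        rlang::abort("Band files disagree on shape or georeference.",
                     class = "avishift_error_alignment")
      }
    }
    vals <- array(unlist(lapply(parts, `[[`, "values")),
                  dim = c(nrow(first$values), ncol(first$values),
                          length(parts)))
    return(raster_grid(vals, first$xmin, first$ymin, first$cellsize,
                       bands = man$bands))
  }
  b <- read_ascii_band(path)
  raster_grid(b$values, b$xmin, b$ymin, b$cellsize)
}

#' Tidy a raster into a long tibble
#'
#' One row per cell per band: `row`, `col`, `lon`, `lat`, `band`, `value`.
#' Useful for dplyr summaries and ggplot2 maps.
#'
#' @param x A `raster_grid`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy raster_grid
#' @export
tidy.raster_grid <- function(x, ...) {
  co <- rg_coords(x)
  purrr::map_dfr(rg_bands(x), function(b) {
    dplyr::mutate(co, band = b, value = as.vector(rg_band(x, b)))
  })
}

#' Plot a raster band with ggplot2
#'
#' @param object A `raster_grid`.
#' @param band Band to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(object, band = 1L, ...) {
  if (is.numeric(band)) band <- rg_bands(object)[band]
  df <- dplyr::filter(tidy(object), .data$band == !!band)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = band)
}
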
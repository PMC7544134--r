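# shared fixtures, built in code

# a small flat raster with given values
mk_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1, bands = NULL) {
  raster_grid(values, xmin, ymin, cellsize, bands = bands)
}

# a binary range from a 0/1 matrix
mk_drm <- function(m, species_id = "spX", scenario = "current",
                   xmin = 0, ymin = 0, cellsize = 1) {
  structure(
    list(grid = raster_grid(m, xmin, ymin, cellsize, bands = "presence"),
         threshold = 0.5, species_id = species_id, scenario = scenario),
    class = "binary_range"
  )
}

small_config <- function(seed = 11L) {
  cfg <- default_config(seed = seed)
  cfg$world$n_rows <- 40
  cfg$world$n_cols <- 48
  cfg$species$n_species <- 10
  cfg$species$n_points <- 200
  cfg$model$n_background <- 2000
  cfg$scenarios <- list(rcp26 = 1, rcp85 = 3)
  cfg
}

# one shared end-to-end run, computed once per test session
.run_cache <- new.env(parent = emptyenv())
get_small_run <- function() {
  if (is.null(.run_cache$run)) {
    dir <- file.path(tempdir(), "avishift-small-run")
    .run_cache$run <- suppressWarnings(
      run_pipeline(small_config(), out_dir = dir))
  }
  .run_cache$run
}

# brute-force sensitivity + specificity maximization used as the MTSS oracle:
# evaluates every pooled observed score and all midpoints/extremes, returning
# the maximum achievable sens + spec
oracle_max_tss <- function(p, b) {
  s <- sort(unique(c(p, b)))
  cands <- sort(unique(c(s, (s[-1] + s[-length(s)]) / 2)))
  max(vapply(cands, function(t) mean(p >= t) + mean(b < t), numeric(1)))
}

tss_at <- function(t, p, b) mean(p >= t) + mean(b < t)

# brute-force greedy CAZ oracle: full marginal-loss recomputation and argmin
# scan each step, warp 1; returns removal order as row-major cell ids
oracle_caz_order <- function(S, w, nr, nc, land_idx) {
  n <- nrow(S)
  row_of <- ((land_idx - 1L) %% nr) + 1L
  col_of <- ((land_idx - 1L) %/% nr) + 1L
  rowmajor <- (row_of - 1L) * nc + col_of
  remaining <- rep(TRUE, n)
  Q <- colSums(S)
  order_out <- integer(0)
  while (any(remaining)) {
    idx <- which(remaining)
    ml <- vapply(idx, function(i) max(w * S[i, ] / pmax(Q, 1e-300)),
                 numeric(1))
    best <- idx[order(ml, rowmajor[idx])][1]
    order_out <- c(order_out, best)
    remaining[best] <- FALSE
    Q <- Q - S[best, ]
  }
  order_out
}
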
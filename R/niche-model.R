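#' Iterative collinearity screening of climate variables
#'
#' Computes Pearson correlations between all variable pairs at presence
#' sites and repeatedly drops the variable involved in the most
#' high-correlation pairs (|r| above `threshold`) until no pair exceeds the
#' threshold. Ties are broken by the largest mean |r| against all remaining
#' variables, then lexicographically by name. Constant variables cannot be
#' correlated and are removed first with a warning.
#'
#' @param presence_values Data frame of variable values at presence sites
#'   (one column per variable, at least 3 rows and 2 columns).
#' @param threshold Absolute Pearson correlation above which a pair counts as
#'   highly correlated (default 0.9).
#' @return A `screening_result` list: `retained_variables`, `removal_order`
#'   (tibble of `variable`, `high_pairs` at removal), `correlation_matrix`
#'   (initial matrix over non-constant variables).
#' @export
correlation_screen <- function(presence_values, threshold = 0.9) {
  pv <- as.data.frame(presence_values)
  if (nrow(pv) < 3) {
    rlang::abort("Need at least 3 presence sites to screen correlations.",
                 class = "avishift_error_insufficient_data")
  }
  if (ncol(pv) < 2) {
    rlang::abort("Need at least 2 variables to screen.",
                 class = "avishift_error_config")
  }
  sds <- vapply(pv, stats::sd, numeric(1))
  removal <- tibble::tibble(variable = character(), high_pairs = integer())
  if (any(sds == 0 | is.na(sds))) {
    const <- names(pv)[sds == 0 | is.na(sds)]
    rlang::warn(paste("Removing constant variable(s) before screening:",
                      paste(const, collapse = ", ")))
    removal <- tibble::tibble(variable = const,
                              high_pairs = NA_integer_)
    pv <- pv[, !(names(pv) %in% const), drop = FALSE]
  }
  full_cor <- stats::cor(pv)
  vars <- names(pv)
  repeat {
    if (length(vars) < 2) break
    cm <- full_cor[vars, vars, drop = FALSE]
    high <- abs(cm) > threshold
    diag(high) <- FALSE
    counts <- rowSums(high)
    if (all(counts == 0)) break
    worst <- counts == max(counts)
    if (sum(worst) > 1) {
      mean_abs <- rowMeans(abs(cm) - diag(1, length(vars)))
      cand <- names(counts)[worst]
      cand <- cand[order(-mean_abs[cand], cand)]
      drop_var <- cand[1]
    } else {
      drop_var <- names(counts)[which.max(counts)]
    }
    removal <- dplyr::bind_rows(
      removal,
      tibble::tibble(variable = drop_var,
                     high_pairs = as.integer(counts[drop_var]))
    )
    vars <- setdiff(vars, drop_var)
  }
  structure(
    list(retained_variables = vars, removal_order = removal,
         correlation_matrix = full_cor, threshold = threshold),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d variable(s) retained, %d removed (|r| > %g)\n",
              length(x$retained_variables), nrow(x$removal_order),
              x$threshold))
  cat("  retained:", paste(x$retained_variables, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy screening_result
#' @export
tidy.screening_result <- function(x, ...) {
  tibble::tibble(
    variable = c(x$retained_variables, x$removal_order$variable),
    retained = c(rep(TRUE, length(x$retained_variables)),
                 rep(FALSE, nrow(x$removal_order)))
  )
}

#' Region-restricted background sample
#'
#' Draws background (pseudo-absence) cells uniformly at random, without
#' replacement when possible, only from land cells belonging to regions
#' (province analogues) where the species has at least one presence. This is
#' the sampling-bias correction of background selection: the model contrasts
#' presences against the environment of regions the observers actually
#' covered.
#'
#' @param species_points Occurrence tibble (`lon`, `lat`) for one species.
#' @param regions Integer region `raster_grid`; `NA` cells are not land.
#' @param n_background Target number of background cells (default 10000,
#'   capped at the number of eligible cells).
#' @param seed Integer seed.
#' @return A tibble of background cells: `row`, `col`, `lon`, `lat`.
#' @export
build_background <- function(species_points, regions, n_background = 10000,
                             seed = 1L) {
  occupied <- rg_extract(regions, species_points$lon, species_points$lat)[[1]]
  occupied <- unique(occupied[!is.na(occupied)])
  if (length(occupied) == 0) {
    rlang::abort("Species points fall outside all regions.",
                 class = "avishift_error_no_region")
  }
  reg <- rg_band(regions, 1L)
  eligible <- which(!is.na(reg) & reg %in% occupied)
  n_take <- min(n_background, length(eligible))
  with_seed(seed, {
    take <- if (n_take == length(eligible)) eligible else
      sample(eligible, n_take)
  })
  nr <- rg_nrow(regions)
  row <- ((take - 1L) %% nr) + 1L
  col <- ((take - 1L) %/% nr) + 1L
  tibble::tibble(
    row = row, col = col,
    lon = rg_lon(regions)[col],
    lat = rg_lat(regions)[row]
  )
}

# ---- penalized presence-background fit ------------------------------------

# Ridge-penalized logistic-style log-linear fit by Newton/IRLS.
# X includes an intercept column, which is not penalized.
ridge_loglinear <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(clamp(mean(y), 1e-6, 1 - 1e-6))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    hess <- crossprod(X * w, X) + pen
    step <- drop(solve(hess, grad))
    beta_new <- beta + step
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# feature matrix: intercept + standardized linear and quadratic terms
feature_matrix <- function(env, standardization) {
  n <- nrow(env)
  vars <- standardization$variable
  X <- matrix(1, n, 1 + 2 * length(vars))
  cn <- "(Intercept)"
  for (i in seq_along(vars)) {
    z <- (env[[vars[i]]] - standardization$mean[i]) / standardization$scale[i]
    X[, 2 * i] <- z
    X[, 2 * i + 1] <- z^2
    cn <- c(cn, paste0(vars[i], "_lin"), paste0(vars[i], "_quad"))
  }
  colnames(X) <- cn
  X
}

cloglog <- function(eta) 1 - exp(-exp(eta))

#' Fit a presence-background niche model with replicated cross-validation
#'
#' Fits a ridge-penalized log-linear model contrasting presence sites against
#' background cells, on standardized linear plus quadratic terms of each
#' environmental variable (which represents a Gaussian niche exactly).
#' Presences are split into `k_folds` seeded folds; each replicate trains on
#' the remaining folds plus the shared background and is scored by AUC on
#' the held-out presences. Suitability is reported through the cloglog link
#' `p = 1 - exp(-exp(eta))`. The stored coefficients comprise both the
#' all-data fit and the per-replicate fits; held-out presence scores are
#' pooled across replicates for later threshold selection.
#'
#' Variables that are constant over the training data carry no information;
#' they are dropped with a warning, and a model with every variable constant
#' degenerates to an intercept-only fit with spatially uniform suitability.
#'
#' @param presences Occurrence tibble (`lon`, `lat`) for one species.
#' @param background Background cell tibble from [build_background()].
#' @param env Multi-band environmental `raster_grid` (climate, elevation).
#' @param variables Bands to use (default: all bands of `env`).
#' @param k_folds Number of cross-validation replicates (default 5, i.e.
#'   80/20 train/test splits).
#' @param regularization Ridge penalty on standardized features (default 1).
#' @param species_id Identifier stored with the model.
#' @param seed Integer seed for fold assignment.
#' @return A `niche_model` object.
#' @export
fit_niche_model <- function(presences, background, env, variables = NULL,
                            k_folds = 5, regularization = 1,
                            species_id = NA_character_, seed = 1L) {
  variables <- variables %||% rg_bands(env)
  if (nrow(presences) < max(5, k_folds)) {
    rlang::abort("Too few presences to fit a replicated model.",
                 class = "avishift_error_insufficient_data")
  }
  if (nrow(background) == 0) {
    rlang::abort("Background sample is empty.",
                 class = "avishift_error_insufficient_data")
  }
  pres_env <- rg_extract(env, presences$lon, presences$lat)[variables]
  ok <- stats::complete.cases(pres_env)
  pres_env <- pres_env[ok, , drop = FALSE]
  bg_env <- rg_extract(env, background$lon, background$lat)[variables]
  bg_ok <- stats::complete.cases(bg_env)
  bg_env <- bg_env[bg_ok, , drop = FALSE]
  n_p <- nrow(pres_env); n_b <- nrow(bg_env)
  if (n_p < max(5, k_folds)) {
    rlang::abort("Too few presences with complete environmental data.",
                 class = "avishift_error_insufficient_data")
  }

  all_env <- dplyr::bind_rows(pres_env, bg_env)
  mu <- vapply(all_env, mean, numeric(1))
  sc <- vapply(all_env, stats::sd, numeric(1))
  const <- sc == 0 | is.na(sc)
  if (any(const)) {
    rlang::warn(paste("Dropping constant variable(s):",
                      paste(variables[const], collapse = ", ")))
    variables <- variables[!const]
    mu <- mu[!const]; sc <- sc[!const]
  }
  standardization <- tibble::tibble(variable = variables, mean = unname(mu),
                                    scale = unname(sc))

  X <- feature_matrix(all_env, standardization)
  y <- c(rep(1, n_p), rep(0, n_b))
  bg_rows <- n_p + seq_len(n_b)

  coef_full <- ridge_loglinear(X, y, regularization)

  fold <- with_seed(seed, {
    sample(rep_len(seq_len(k_folds), n_p))
  })
  coef_reps <- vector("list", k_folds)
  scores <- tibble::tibble(replicate = seq_len(k_folds),
                           train_auc = NA_real_, test_auc = NA_real_)
  pooled_test <- numeric(n_p)
  bg_rep_scores <- matrix(NA_real_, n_b, k_folds)
  for (r in seq_len(k_folds)) {
    test_rows <- which(fold == r)
    train_rows <- c(setdiff(seq_len(n_p), test_rows), bg_rows)
    beta <- ridge_loglinear(X[train_rows, , drop = FALSE], y[train_rows],
                            regularization)
    coef_reps[[r]] <- beta
    s_all <- cloglog(drop(X %*% beta))
    s_bg <- s_all[bg_rows]
    bg_rep_scores[, r] <- s_bg
    pooled_test[test_rows] <- s_all[test_rows]
    scores$train_auc[r] <- evaluate_auc(
      s_all[setdiff(seq_len(n_p), test_rows)], s_bg)
    scores$test_auc[r] <- evaluate_auc(s_all[test_rows], s_bg)
  }

  structure(
    list(
      species_id = species_id,
      variables = variables,
      standardization = standardization,
      coef_full = stats::setNames(coef_full, colnames(X)),
      coef_replicates = lapply(coef_reps, stats::setNames, colnames(X)),
      replicate_scores = scores,
      regularization = regularization,
      n_presence = n_p, n_background = n_b,
      mtss_presence_scores = pooled_test,
      mtss_background_scores = rowMeans(bg_rep_scores)
    ),
    class = "niche_model"
  )
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf(
    "<niche_model> %s: %d presences vs %d background, %d variable(s)\n",
    x$species_id, x$n_presence, x$n_background, length(x$variables)))
  cat(sprintf("  mean test AUC %.3f (train %.3f), ridge penalty %g\n",
              mean(x$replicate_scores$test_auc),
              mean(x$replicate_scores$train_auc), x$regularization))
  invisible(x)
}

#' Tidy the coefficients of a fitted niche model
#'
#' @param x A `niche_model`.
#' @param ... Unused.
#' @return A tibble: `variable`, `term` (`"linear"`/`"quadratic"`/
#'   `"intercept"`), `estimate` (on the standardized feature scale).
#' @method tidy niche_model
#' @export
tidy.niche_model <- function(x, ...) {
  co <- x$coef_full
  out <- tibble::tibble(variable = "(Intercept)", term = "intercept",
                        estimate = unname(co[1]))
  for (v in x$variables) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      variable = v,
      term = c("linear", "quadratic"),
      estimate = unname(co[paste0(v, c("_lin", "_quad"))])
    ))
  }
  out
}

#' One-row model summary
#'
#' @param x A `niche_model`.
#' @param ... Unused.
#' @return A one-row tibble with sizes, penalty and mean replicate AUCs.
#' @method glance niche_model
#' @export
glance.niche_model <- function(x, ...) {
  tibble::tibble(
    species_id = x$species_id,
    n_presence = x$n_presence,
    n_background = x$n_background,
    n_variables = length(x$variables),
    regularization = x$regularization,
    mean_train_auc = mean(x$replicate_scores$train_auc),
    mean_test_auc = mean(x$replicate_scores$test_auc)
  )
}

#' Estimated niche optimum of a fitted model
#'
#' For each variable with a concave quadratic response, the stationary point
#' of the fitted parabola on the original variable scale (`NA` when the
#' quadratic coefficient is non-negative, i.e. no interior optimum).
#'
#' @param model A `niche_model`.
#' @return A tibble: `variable`, `optimum`.
#' @export
niche_optimum <- function(model) {
  co <- model$coef_full
  purrr::map_dfr(seq_along(model$variables), function(i) {
    v <- model$variables[i]
    b1 <- co[paste0(v, "_lin")]
    b2 <- co[paste0(v, "_quad")]
    z_star <- if (b2 < 0) -b1 / (2 * b2) else NA_real_
    tibble::tibble(
      variable = v,
      optimum = model$standardization$mean[i] +
        z_star * model$standardization$scale[i]
    )
  })
}

#' Project a niche model onto a climate raster
#'
#' Evaluates the model's linear predictor per cell from standardized
#' features and maps it through the cloglog link. The default reports the
#' mean of the per-replicate cloglog surfaces (the averaged replicate output
#' used for range mapping); `use = "full"` reports the all-data fit. Cells
#' with missing climate stay missing.
#'
#' @param model A `niche_model`.
#' @param env Environmental `raster_grid` providing every model variable.
#' @param use `"mean_replicate"` (default) or `"full"`.
#' @return A single-band suitability `raster_grid` with values in (0, 1).
#' @export
predict_suitability <- function(model, env,
                                use = c("mean_replicate", "full")) {
  use <- match.arg(use)
  missing <- setdiff(model$variables, rg_bands(env))
  if (length(missing)) {
    rlang::abort(paste("Projection raster lacks band(s):",
                       paste(missing, collapse = ", ")),
                 class = "avishift_error_projection")
  }
  nr <- rg_nrow(env); nc <- rg_ncol(env)
  envdf <- tibble::as_tibble(lapply(
    stats::setNames(model$variables, model$variables),
    function(v) as.vector(rg_band(env, v))
  ))
  # an intercept-only model (every variable constant at fit time) predicts
  # a uniform surface over all cells
  ok <- if (ncol(envdf) == 0) rep(TRUE, nr * nc) else
    stats::complete.cases(envdf)
  X <- if (ncol(envdf) == 0) {
    matrix(1, sum(ok), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    feature_matrix(envdf[ok, , drop = FALSE], model$standardization)
  }
  p <- rep(NA_real_, nr * nc)
  if (use == "full") {
    p[ok] <- cloglog(drop(X %*% model$coef_full))
  } else {
    preds <- vapply(model$coef_replicates,
                    function(b) cloglog(drop(X %*% b)),
                    numeric(sum(ok)))
    p[ok] <- rowMeans(preds)
  }
  rg_like(env, matrix(p, nr, nc), bands = "suitability")
}

#' Rank-based AUC of presence vs background scores
#'
#' The probability that a random presence scores above a random background
#' point, ties counting one half: `(concordant + 0.5 * ties) / (n_p * n_b)`.
#'
#' @param scores_presence,scores_background Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(scores_presence, scores_background) {
  n_p <- length(scores_presence); n_b <- length(scores_background)
  if (n_p == 0 || n_b == 0) {
    rlang::abort("Both score lists must be non-empty.",
                 class = "avishift_error_insufficient_data")
  }
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(n_p)]) - n_p * (n_p + 1) / 2) / (n_p * n_b)
}

#' Variables with non-negligible fitted contribution
#'
#' Keeps variables whose total absolute standardized coefficient mass
#' (|linear| + |quadratic| in the all-data fit) exceeds `tolerance`; the
#' rest are treated as contributing nothing and are dropped before a
#' second-round refit.
#'
#' @param model A `niche_model`.
#' @param tolerance Coefficient-mass cutoff (default 1e-8).
#' @return Character vector of retained variable names.
#' @export
prune_zero_contribution <- function(model, tolerance = 1e-8) {
  co <- model$coef_full
  mass <- vapply(model$variables, function(v) {
    abs(co[paste0(v, "_lin")]) + abs(co[paste0(v, "_quad")])
  }, numeric(1))
  keep <- model$variables[mass > tolerance]
  if (length(keep) == 0) {
    rlang::abort("All variables pruned: model is degenerate.",
                 class = "avishift_error_degenerate_model")
  }
  keep
}

#' Locality-density filter on a predicted range map
#'
#' Tiles the globe into `block_size` x `block_size` degree blocks, counts the
#' blocks intersecting at least one presence cell of the binary range map,
#' and computes localities per block. Species with a density strictly below
#' one locality per block are flagged for exclusion (sparse records spread
#' over a wide predicted range are unreliable).
#'
#' @param species_drm A binary range map ([binarize()] output or a 0/1
#'   `raster_grid`).
#' @param n_localities Number of independent localities for the species.
#' @param block_size Block side, degrees (default 3).
#' @return A one-row tibble: `keep`, `density`, `n_blocks`, `reason`.
#' @export
density_filter <- function(species_drm, n_localities, block_size = 3) {
  grid <- if (inherits(species_drm, "binary_range")) species_drm$grid else
    species_drm
  m <- rg_band(grid, 1L)
  pres <- which(!is.na(m) & m == 1)
  if (length(pres) == 0) {
    return(tibble::tibble(keep = FALSE, density = NA_real_,
                          n_blocks = 0L, reason = "no predicted range"))
  }
  nr <- rg_nrow(grid)
  row <- ((pres - 1L) %% nr) + 1L
  col <- ((pres - 1L) %/% nr) + 1L
  lon <- rg_lon(grid)[col]
  lat <- rg_lat(grid)[row]
  blocks <- unique(paste(floor(lon / block_size), floor(lat / block_size)))
  density <- n_localities / length(blocks)
  tibble::tibble(
    keep = density >= 1, density = density, n_blocks = length(blocks),
    reason = if (density >= 1) NA_character_ else
      sprintf("locality density %.3g < 1 per %g-degree block", density,
              block_size)
  )
}

stack_env <- function(climate, elevation) {
  rg_check_aligned(climate, elevation)
  vals <- array(
    c(climate$values, elevation$values),
    dim = c(rg_nrow(climate), rg_ncol(climate),
            length(rg_bands(climate)) + length(rg_bands(elevation)))
  )
  raster_grid(vals, climate$xmin, climate$ymin, climate$cellsize,
              bands = c(rg_bands(climate), rg_bands(elevation)))
}

#' Two-round species distribution modelling over a species batch
#'
#' Round one fits every species with all screened climate variables plus
#' elevation against an unrestricted background, then applies two filters:
#' species whose predicted range fails the locality-density rule are
#' excluded, and variables with no fitted contribution are dropped per
#' species. Round two refits the surviving species with their own variable
#' sets and a region-restricted background, and projects suitability for the
#' current scenario and every future scenario. Failures are logged per
#' species without aborting the batch.
#'
#' @param occurrences Cleaned occurrence tibble (`species_id`, `lon`, `lat`).
#' @param world A `synthetic_world` (or compatible list with
#'   `climate_current`, `elevation`, `regions`).
#' @param scenarios Named list of climate rasters to project; must contain
#'   `"current"`. Defaults to current plus the world's `climate_future` as
#'   `"future"`.
#' @param k_folds,regularization,n_background,cor_threshold,prune_tolerance,
#'   block_size Modelling parameters (see the individual stage functions).
#' @param seed Master seed; per-species and per-stage seeds are derived.
#' @return An `sdm_batch` list: `models` (round-2 fits), `suitability`
#'   (scenario -> species -> `raster_grid`), `thresholds` (per-species MTSS),
#'   `screening` (the [correlation_screen()] result), `status` (per-species
#'   log tibble), `meta_vars` (variable sets per round).
#' @export
run_two_rounds <- function(occurrences, world, scenarios = NULL,
                           k_folds = 5, regularization = 1,
                           n_background = 10000, cor_threshold = 0.9,
                           prune_tolerance = 1e-8, block_size = 3,
                           seed = 1L) {
  scenarios <- scenarios %||% list(current = world$climate_current,
                                   future = world$climate_future)
  if (!"current" %in% names(scenarios)) {
    rlang::abort("`scenarios` must include a 'current' climate raster.",
                 class = "avishift_error_config")
  }
  env_current <- stack_env(scenarios$current, world$elevation)

  # pooled presence-site screening of the climate bands
  clim_vals <- rg_extract(scenarios$current, occurrences$lon,
                          occurrences$lat)
  clim_vals <- clim_vals[stats::complete.cases(clim_vals), , drop = FALSE]
  screening <- if (ncol(clim_vals) >= 2) {
    correlation_screen(clim_vals, threshold = cor_threshold)
  } else {
    structure(list(retained_variables = names(clim_vals),
                   removal_order = tibble::tibble(variable = character(),
                                                  high_pairs = integer()),
                   correlation_matrix = NULL, threshold = cor_threshold),
              class = "screening_result")
  }
  round1_vars <- c(screening$retained_variables, rg_bands(world$elevation))

  reg_band <- rg_band(world$regions, 1L)
  land <- which(!is.na(reg_band))
  nr <- rg_nrow(world$regions)
  land_cells <- tibble::tibble(
    row = ((land - 1L) %% nr) + 1L,
    col = ((land - 1L) %/% nr) + 1L
  )
  land_cells$lon <- rg_lon(world$regions)[land_cells$col]
  land_cells$lat <- rg_lat(world$regions)[land_cells$row]

  species <- unique(occurrences$species_id)
  status <- list(); models <- list(); thresholds <- c()
  meta_vars <- list()
  suitability <- stats::setNames(
    replicate(length(scenarios), list(), simplify = FALSE), names(scenarios))

  for (sp in species) {
    pts <- dplyr::filter(occurrences, .data$species_id == sp)
    sp_seed <- derive_seed(seed, paste0("fit_", sp))
    res <- tryCatch({
      # round 1: all variables, unrestricted background
      with_seed(derive_seed(sp_seed, "bg1"), {
        bg1 <- land_cells[sample(nrow(land_cells),
                                 min(n_background, nrow(land_cells))), ]
      })
      m1 <- fit_niche_model(pts, bg1, env_current, variables = round1_vars,
                            k_folds = k_folds,
                            regularization = regularization,
                            species_id = sp, seed = sp_seed)
      thr1 <- mtss_threshold(m1$mtss_presence_scores,
                             m1$mtss_background_scores)
      drm1 <- binarize(predict_suitability(m1, env_current), thr1,
                       species_id = sp, scenario = "round1")
      dens <- density_filter(drm1, nrow(pts), block_size = block_size)
      if (!dens$keep) {
        list(status = tibble::tibble(
          species_id = sp, stage = "round1", action = "excluded",
          reason = dens$reason %||% "no predicted range"))
      } else {
        vars2 <- prune_zero_contribution(m1, tolerance = prune_tolerance)
        # round 2: per-species variables, region-restricted background
        bg2 <- build_background(pts, world$regions,
                                n_background = n_background,
                                seed = derive_seed(sp_seed, "bg2"))
        m2 <- fit_niche_model(pts, bg2, env_current, variables = vars2,
                              k_folds = k_folds,
                              regularization = regularization,
                              species_id = sp,
                              seed = derive_seed(sp_seed, "round2"))
        thr2 <- mtss_threshold(m2$mtss_presence_scores,
                               m2$mtss_background_scores)
        suits <- lapply(scenarios, function(clim) {
          predict_suitability(m2, stack_env(clim, world$elevation))
        })
        list(model = m2, threshold = thr2, suits = suits,
             vars = list(round1 = round1_vars, round2 = vars2),
             status = tibble::tibble(
               species_id = sp, stage = "round2", action = "modelled",
               reason = NA_character_))
      }
    }, error = function(e) {
      list(status = tibble::tibble(
        species_id = sp, stage = "fit", action = "failed",
        reason = conditionMessage(e)))
    })
    status[[sp]] <- res$status
    if (!is.null(res$model)) {
      models[[sp]] <- res$model
      thresholds[sp] <- res$threshold
      meta_vars[[sp]] <- res$vars
      for (scn in names(scenarios)) {
        suitability[[scn]][[sp]] <- res$suits[[scn]]
      }
    }
  }

  structure(
    list(models = models, suitability = suitability,
         thresholds = thresholds, screening = screening,
         status = dplyr::bind_rows(status), meta_vars = meta_vars,
         scenarios = names(scenarios)),
    class = "sdm_batch"
  )
}

#' @export
print.sdm_batch <- function(x, ...) {
  cat(sprintf("<sdm_batch> %d species modelled, %d excluded/failed; scenarios: %s\n",
              length(x$models), sum(x$status$action != "modelled"),
              paste(x$scenarios, collapse = ", ")))
  invisible(x)
}

#' @method glance sdm_batch
#' @export
glance.sdm_batch <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}
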
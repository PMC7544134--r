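test_that("correlation screening removes the right variables", {
  set.seed(1)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  # X3 duplicates X1: exactly one of the pair is removed
  res <- correlation_screen(data.frame(X1 = x1, X2 = x2, X3 = x1))
  expect_equal(length(res$retained_variables), 2)
  expect_equal(sum(c("X1", "X3") %in% res$retained_variables), 1)
  cm <- res$correlation_matrix[res$retained_variables,
                               res$retained_variables]
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.9))
})

test_that("the variable with the most high-correlation pairs goes first", {
  set.seed(2)
  n <- 2000
  x1 <- rnorm(n)
  # independent noise at sd 0.4 puts r(1,2) and r(1,3) near 0.93 while
  # r(2,3) stays near 0.86 -- only X1 exceeds the threshold twice
  x2 <- x1 + rnorm(n, sd = 0.4)
  x3 <- x1 + rnorm(n, sd = 0.4)
  stopifnot(abs(cor(x2, x3)) < 0.9, abs(cor(x1, x3)) > 0.9,
            abs(cor(x1, x2)) > 0.9)
  res <- correlation_screen(data.frame(X1 = x1, X2 = x2, X3 = x3))
  expect_equal(res$removal_order$variable[1], "X1")
  expect_equal(res$removal_order$high_pairs[1], 2L)
  expect_setequal(res$retained_variables, c("X2", "X3"))
})

test_that("screening is a no-op below threshold and validates its input", {
  set.seed(3)
  df <- as.data.frame(matrix(rnorm(300), 100, 3))
  res <- correlation_screen(df)
  expect_setequal(res$retained_variables, names(df))
  expect_equal(nrow(res$removal_order), 0)
  expect_error(correlation_screen(df[1:2, ]),
               class = "avishift_error_insufficient_data")
  expect_warning(correlation_screen(cbind(df, K = 1)), "constant")
})

test_that("retained pairs never exceed the threshold (property)", {
  for (s in 1:10) {
    set.seed(s)
    n <- 80; k <- 6
    base <- matrix(rnorm(n * 3), n, 3)
    mix <- matrix(runif(3 * k), 3, k)
    df <- as.data.frame(base %*% mix + matrix(rnorm(n * k, sd = 0.2), n, k))
    res <- correlation_screen(df, threshold = 0.9)
    if (length(res$retained_variables) >= 2) {
      cm <- cor(df[res$retained_variables])
      expect_true(all(abs(cm[upper.tri(cm)]) <= 0.9))
    }
  }
})

test_that("background sampling respects region membership", {
  reg <- raster_grid(matrix(rep(1:4, each = 25), 10, 10), 0, 0, 1,
                     bands = "region")
  # regions are column blocks 1..4; presences only in region 2
  pts <- tibble::tibble(lon = c(3.2, 4.8), lat = c(2, 7))
  bg <- build_background(pts, reg, n_background = 30, seed = 1L)
  expect_true(all(rg_extract(reg, bg$lon, bg$lat)$region == 2))
  # asking for more cells than the region holds returns every eligible cell
  bg_all <- build_background(pts, reg, n_background = 1000, seed = 1L)
  expect_equal(nrow(bg_all), 25)
  # presences spanning all regions -> support is the whole grid
  pts_all <- tibble::tibble(lon = c(1, 3.5, 6, 8.5), lat = rep(5, 4))
  bg_full <- build_background(pts_all, reg, n_background = 1e5, seed = 1L)
  expect_equal(nrow(bg_full), 100)
  # points outside every region
  expect_error(
    build_background(tibble::tibble(lon = -5, lat = -5), reg, 10, seed = 1L),
    class = "avishift_error_no_region")
})

test_that("AUC matches brute-force pair counting and its closed forms", {
  expect_equal(evaluate_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(evaluate_auc(c(0.9, 0.3), c(0.1, 0.5)), 0.75)
  expect_equal(evaluate_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_error(evaluate_auc(numeric(0), 1),
               class = "avishift_error_insufficient_data")
  brute <- function(p, b) {
    s <- 0
    for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s / (length(p) * length(b))
  }
  for (s in 1:20) {
    set.seed(s)
    p <- round(runif(sample(1:50, 1)), 2)
    b <- round(runif(sample(1:50, 1)), 2)
    expect_identical(evaluate_auc(p, b), brute(p, b))
  }
})

test_that("the ridge fit agrees with an independent penalized solver", {
  skip_if_not_installed("glmnet")
  set.seed(10)
  n <- 400
  X <- cbind(1, scale(matrix(rnorm(n * 4), n, 4)))
  eta <- -0.5 + X[, 2] - 0.8 * X[, 3]^2
  y <- rbinom(n, 1, plogis(eta))
  lambda <- 2
  beta <- avishift:::ridge_loglinear(X, y, lambda)
  fit <- glmnet::glmnet(X[, -1], y, family = "binomial", alpha = 0,
                        lambda = lambda / n, standardize = FALSE,
                        thresh = 1e-12)
  ref <- as.numeric(coef(fit))
  expect_equal(unname(beta), ref, tolerance = 1e-3)
})

test_that("a species' Gaussian niche optimum is recovered from samples", {
  w <- make_world(world_config(seed = 21L))
  temp <- rg_band(w$climate_current, "temp")
  opt <- as.numeric(quantile(temp, 0.5))
  tr <- species_truth("rec", c(temp = opt), c(temp = 1))
  occ <- sample_occurrences(tr, w$climate_current, 500, seed = 8L)
  bg <- build_background(occ, w$regions, n_background = 2000, seed = 9L)
  m <- fit_niche_model(occ, bg, w$climate_current, variables = "temp",
                       species_id = "rec", seed = 10L)
  est <- niche_optimum(m)$optimum[1]
  expect_lt(abs(est - opt), 0.5) # within half a niche breadth
  expect_gt(mean(m$replicate_scores$test_auc), 0.8)
  # suitability bounded in (0,1) everywhere climate is finite
  suit <- rg_band(predict_suitability(m, w$climate_current), 1L)
  expect_true(all(suit > 0 & suit < 1))
})

test_that("constant climate yields a spatially uniform prediction", {
  flat <- raster_grid(array(c(matrix(5, 6, 6)), c(6, 6, 1)), 0, 0, 1,
                      bands = "temp")
  occ <- tibble::tibble(lon = runif(20, 0, 6), lat = runif(20, 0, 6))
  bg <- tibble::tibble(row = rep(1:6, 6), col = rep(1:6, each = 6),
                       lon = rep(rg_lon(flat), each = 6),
                       lat = rep(rg_lat(flat), 6))
  expect_warning(
    m <- fit_niche_model(occ, bg, flat, variables = "temp", seed = 1L),
    "constant")
  suit <- rg_band(predict_suitability(m, flat), 1L)
  expect_equal(max(suit) - min(suit), 0)
})

test_that("cloglog link hits its closed form and limits", {
  w <- make_world(world_config(n_rows = 8, n_cols = 8, seed = 31L))
  occ <- sample_occurrences(
    species_truth("s", c(temp = 24), c(temp = 2)), w$climate_current, 50,
    seed = 1L)
  bg <- build_background(occ, w$regions, 100, seed = 2L)
  m <- fit_niche_model(occ, bg, w$climate_current, variables = "temp",
                       seed = 3L)
  # zero all coefficients: eta = 0 everywhere -> p = 1 - exp(-1)
  m$coef_full[] <- 0
  for (r in seq_along(m$coef_replicates)) m$coef_replicates[[r]][] <- 0
  suit <- rg_band(predict_suitability(m, w$climate_current), 1L)
  expect_equal(unique(round(as.vector(suit), 10)), round(1 - exp(-1), 10))
  # large negative / positive predictors saturate at 0 and 1
  m$coef_full["(Intercept)"] <- -50
  expect_equal(max(rg_band(predict_suitability(m, w$climate_current,
                                               use = "full"), 1L)), 0,
               tolerance = 1e-15)
  m$coef_full["(Intercept)"] <- 50
  expect_equal(min(rg_band(predict_suitability(m, w$climate_current,
                                               use = "full"), 1L)), 1)
  # projecting onto a raster lacking a model variable fails
  bad <- raster_grid(matrix(1, 8, 8), 100, 20, 0.1, bands = "other")
  expect_error(predict_suitability(m, bad),
               class = "avishift_error_projection")
})

test_that("zero-contribution pruning keeps informative variables", {
  w <- make_world(world_config(seed = 41L))
  tr <- species_truth("p", c(temp = 24), c(temp = 1))
  occ <- sample_occurrences(tr, w$climate_current, 300, seed = 5L)
  bg <- build_background(occ, w$regions, 1500, seed = 6L)
  m <- fit_niche_model(occ, bg, w$climate_current,
                       variables = c("temp", "clim2"), seed = 7L)
  # the generating variable survives pruning
  expect_true("temp" %in% prune_zero_contribution(m))
  # exactly-zero coefficients are pruned
  m2 <- m
  m2$coef_full[c("clim2_lin", "clim2_quad")] <- 0
  expect_equal(prune_zero_contribution(m2), "temp")
  # an infinite tolerance prunes everything -> degenerate model
  expect_error(prune_zero_contribution(m, tolerance = Inf),
               class = "avishift_error_degenerate_model")
})

test_that("the locality-density rule applies strict less-than-one", {
  # DRM spanning 2 blocks (3-degree tiles), 1 locality -> density 0.5, excluded
  m2 <- matrix(0, 8, 8); m2[4, c(2, 7)] <- 1 # lon 1.5 and 6.5: blocks 0 and 2
  drm2 <- mk_drm(m2)
  res <- density_filter(drm2, n_localities = 1)
  expect_false(res$keep)
  expect_equal(res$density, 0.5)
  # DRM within one block, 5 localities -> density 5, kept
  m1 <- matrix(0, 8, 8); m1[3:4, 1:2] <- 1
  expect_true(density_filter(mk_drm(m1), 5)$keep)
  # 4 blocks, 4 localities -> density exactly 1: kept under strict "< 1"
  m4 <- matrix(0, 8, 8); m4[c(1, 7), c(2, 7)] <- 1 # lat/lon in 4 distinct blocks
  res4 <- density_filter(mk_drm(m4), 4)
  expect_equal(res4$n_blocks, 4L)
  expect_equal(res4$density, 1)
  expect_true(res4$keep)
  # empty DRM excluded with its own reason
  res0 <- density_filter(mk_drm(matrix(0, 8, 8)), 10)
  expect_false(res0$keep)
  expect_equal(res0$reason, "no predicted range")
})

test_that("two-round batch filters, prunes and stays deterministic", {
  run <- get_small_run()
  batch <- run$batch
  expect_gt(length(batch$models), 0)
  # every round-2 model uses no more variables than round 1 offered
  for (sp in names(batch$models)) {
    expect_lte(length(batch$meta_vars[[sp]]$round2),
               length(batch$meta_vars[[sp]]$round1))
  }
  # excluded species are absent from outputs but present in the status log
  excluded <- batch$status$species_id[batch$status$action != "modelled"]
  expect_true(all(!excluded %in% names(batch$models)))
  # determinism: re-fitting one species with the same derived seeds matches
  g1 <- generics::glance(batch)
  expect_true(all(g1$mean_test_auc > 0.5))
})
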
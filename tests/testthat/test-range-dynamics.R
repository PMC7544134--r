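test_that("MTSS threshold reproduces enumerated fixtures", {
  # clean separation: any cutoff in (0.3, 0.7] attains sens+spec = 2;
  # the smallest maximizing midpoint is 0.5
  t1 <- mtss_threshold(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(t1, 0.5)
  expect_equal(tss_at(t1, c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3)), 2)
  # overlapping scores: exhaustive enumeration gives 1.75 at t = 0.35
  p <- c(0.9, 0.6, 0.5, 0.4); b <- c(0.55, 0.3, 0.2, 0.1)
  t2 <- mtss_threshold(p, b)
  expect_equal(t2, 0.35)
  expect_equal(tss_at(t2, p, b), 1.75)
  expect_error(mtss_threshold(numeric(0), 1),
               class = "avishift_error_insufficient_data")
})

test_that("MTSS equals brute-force maximization on random score lists", {
  for (s in 1:50) {
    set.seed(s)
    p <- round(runif(sample(1:200, 1)), 3)
    b <- round(runif(sample(1:200, 1)), 3)
    t_star <- mtss_threshold(p, b)
    expect_equal(tss_at(t_star, p, b), oracle_max_tss(p, b))
  }
})

test_that("binarization uses the at-or-above convention and is idempotent", {
  g <- mk_grid(matrix(c(0.4, 0.5, 0.6, NA), 2, 2))
  br <- binarize(g, 0.5)
  expect_equal(as.vector(rg_band(br$grid, 1L)), c(0, 1, 1, NA))
  # re-binarizing the binary map at 0.5 changes nothing
  br2 <- binarize(br$grid, 0.5)
  expect_equal(br2$grid$values, br$grid$values)
  # threshold above every value -> empty map with a warning
  expect_warning(b0 <- binarize(g, 0.99), "empty range")
  expect_equal(sum(rg_band(b0$grid, 1L), na.rm = TRUE), 0)
  expect_error(binarize(g, 1.5), class = "avishift_error_config")
})

test_that("range change percentages follow the cell-count ratio", {
  cur <- mk_drm(matrix(rep(c(1, 0), c(100, 100)), 20, 10))
  fut <- mk_drm(matrix(rep(c(1, 0), c(150, 50)), 20, 10))
  rc <- range_change(cur, fut)
  expect_equal(rc$pct_change, 50)
  # total loss and identity
  expect_equal(range_change(cur, mk_drm(matrix(0, 20, 10)))$pct_change, -100)
  expect_equal(range_change(cur, cur)$pct_change, 0)
  expect_error(range_change(mk_drm(matrix(0, 20, 10)), cur),
               class = "avishift_error_undefined_change")
  # km2 areas use the latitude-dependent cell area
  a <- rg_cell_area_km2(cur$grid)
  expect_equal(rc$area_current_km2, sum(a[rg_band(cur$grid, 1L) == 1]))
})

test_that("geometric median matches symmetry and 1-D fixtures", {
  expect_equal(geometric_median(3, 7), c(lon = 3, lat = 7))
  sq <- geometric_median(c(9, 11, 9, 11), c(9, 9, 11, 11))
  expect_equal(unname(sq), c(10, 10), tolerance = 1e-6)
  # three collinear points: the middle one minimizes total distance
  col3 <- geometric_median(c(1, 2, 6), c(0, 0, 0))
  expect_equal(unname(col3), c(2, 0), tolerance = 1e-6)
  expect_error(geometric_median(numeric(0), numeric(0)),
               class = "avishift_error_no_center")
})

test_that("geometric median agrees with dense grid search", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(5:50, 1)
    lon <- runif(n, 100, 102); lat <- runif(n, 30, 32)
    med <- geometric_median(lon, lat)
    # grid search on a 0.01-degree lattice in the same local frame
    k <- cos(mean(lat) * pi / 180)
    gx <- seq(min(lon), max(lon), by = 0.01)
    gy <- seq(min(lat), max(lat), by = 0.01)
    obj <- outer(gx, gy, function(x, y) {
      vapply(seq_along(x), function(i) {
        sum(sqrt(((lon - x[i]) * k)^2 + (lat - y[i])^2))
      }, numeric(1))
    })
    best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    expect_lt(abs(med[["lon"]] - gx[best[1]]), 0.02)
    expect_lt(abs(med[["lat"]] - gy[best[2]]), 0.02)
  }
})

test_that("displacement vectors carry haversine distance and sign quadrants", {
  due_north <- shift_vector(c(lon = 100, lat = 30), c(lon = 100, lat = 31))
  expect_equal(due_north$bearing_deg, 0)
  expect_equal(due_north$poleward, "north")
  expect_equal(due_north$shift_km, 111.2, tolerance = 0.001)
  # pure eastward shift sits on the quadrant boundary: strict rule -> south
  east <- shift_vector(c(lon = 100, lat = 30), c(lon = 101, lat = 30))
  expect_equal(east$quadrant, "SE")
  expect_equal(east$poleward, "south")
  expect_true(east$boundary)
  # both components negative -> SW
  sw <- shift_vector(c(lon = 100, lat = 30), c(lon = 99.5, lat = 29.5))
  expect_equal(sw$quadrant, "SW")
  # identical centers: zero vector, quadrant undefined but flagged
  zero <- shift_vector(c(lon = 100, lat = 30), c(lon = 100, lat = 30))
  expect_equal(zero$shift_km, 0)
  expect_true(is.na(zero$quadrant) && zero$boundary)
})

test_that("richness stacking sums presences and respects the identity", {
  m1 <- matrix(0, 5, 5); m1[1:2, 1] <- 1
  m2 <- matrix(0, 5, 5); m2[2:3, 1] <- 1
  drms <- list(a = mk_drm(m1), b = mk_drm(m2))
  rich <- stack_richness(drms)
  expect_equal(rg_band(rich, 1L)[2, 1], 2)
  expect_equal(rg_band(rich, 1L)[1, 1], 1)
  # sum over cells of richness equals sum over species of area, exactly
  expect_equal(sum(rg_band(rich, 1L)), sum(m1) + sum(m2))
  # empty set with a template -> all-zero grid; without -> error
  z <- stack_richness(list(), template = drms$a$grid)
  expect_true(all(rg_band(z, 1L) == 0))
  expect_error(stack_richness(list()), class = "avishift_error_empty_input")
  # misaligned grids refuse to stack
  off <- mk_drm(m1, xmin = 1)
  expect_error(stack_richness(list(drms$a, off)),
               class = "avishift_error_alignment")
})

test_that("richness change is exactly additive", {
  set.seed(4)
  a <- mk_grid(matrix(rpois(25, 3), 5, 5))
  b <- mk_grid(matrix(rpois(25, 3), 5, 5))
  ch <- richness_change(a, b)
  expect_equal(rg_band(ch, 1L) + rg_band(a, 1L), rg_band(b, 1L))
  expect_true(all(rg_band(richness_change(a, a), 1L) == 0))
})

test_that("elevation-band diversity counts species once per band", {
  elev <- mk_grid(matrix(c(100, 600, 1200, 1700, 2200, rep(0, 20)), 5, 5))
  m <- matrix(0, 5, 5); m[1:2, 1] <- 1 # cells at 100 m and 600 m
  prof <- elevation_profile(list(mk_drm(m)), list(mk_drm(m)), elev)
  expect_equal(prof$profile$diversity_current[1:2], c(1, 1))
  expect_equal(sum(prof$profile$diversity_current), 2)
  # unchanged maps -> zero change everywhere and no turning point
  expect_true(all(prof$profile$change == 0))
  expect_true(is.na(prof$turning_point))
  expect_error(
    elevation_profile(list(mk_drm(m)), list(mk_drm(m)), elev,
                      band_edges = c(0, 500, 400)),
    class = "avishift_error_config")
})

test_that("a low-loss/high-gain cohort has its turning point at 1500 m", {
  # one elevation value per column: bands A..E at 250,750,1250,1750,2250 m
  elev <- mk_grid(matrix(rep(c(250, 750, 1250, 1750, 2250), each = 5), 5, 5))
  # species losing cells below 1500 m and gaining at/above it
  cur1 <- matrix(0, 5, 5); cur1[, 1:3] <- 1 # occupies bands A-C
  fut1 <- matrix(0, 5, 5); fut1[, 4:5] <- 1 # moves to bands D-E
  cur2 <- matrix(0, 5, 5); cur2[, 3] <- 1
  fut2 <- matrix(0, 5, 5); fut2[, 4] <- 1
  prof <- elevation_profile(
    list(a = mk_drm(cur1), b = mk_drm(cur2)),
    list(a = mk_drm(fut1), b = mk_drm(fut2)),
    elev
  )
  expect_equal(prof$turning_point, 1500)
})

test_that("group summaries split reduce/expand and north/south correctly", {
  records <- tibble::tibble(
    species_id = c("s1", "s2", "s3", "s4"),
    scenario = "fut",
    pct_change = c(-10, 20, 40, 0),
    shift_km = c(50, 60, 70, 10),
    bearing_deg = c(10, 350, 20, 170),
    quadrant = c("NE", "NW", "NE", "SE"),
    poleward = c("north", "north", "north", "south")
  )
  meta <- tibble::tibble(species_id = paste0("s", 1:4),
                         migratory = c(TRUE, TRUE, FALSE, FALSE),
                         endemic = FALSE, threatened = FALSE)
  gs <- summarize_groups(records, meta)
  all_area <- dplyr::filter(gs$area_change, group == "all")
  expect_equal(all_area$n[all_area$direction == "reduce"], 1L)
  expect_equal(all_area$mean_pct_change[all_area$direction == "reduce"], -10)
  expect_equal(all_area$n[all_area$direction == "expand"], 2L)
  expect_equal(all_area$mean_pct_change[all_area$direction == "expand"], 30)
  # zero-change species is in neither class but logged
  expect_equal(attr(gs, "zero_change"), "s4")
  # migratory species all moved north -> no south row for that group
  mig <- dplyr::filter(gs$shifts, group == "migratory")
  expect_setequal(mig$poleward, "north")
  # unknown species in records is a keying error
  expect_error(summarize_groups(dplyr::mutate(records,
                                              species_id = paste0("x", 1:4)),
                                meta),
               class = "avishift_error_keying")
})
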
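test_that("weights decrease with range change and carry the endemic bonus", {
  records <- tibble::tibble(species_id = c("a", "b", "c", "d"),
                            pct_change = c(-50, 200, 0, -50))
  meta <- tibble::tibble(species_id = c("a", "b", "c", "d"),
                         endemic = c(FALSE, TRUE, FALSE, TRUE))
  w <- compute_weights(records, meta)
  expect_equal(w$weight[w$species_id == "a"], 1.5)
  expect_equal(w$weight[w$species_id == "b"], 0.6) # clamped at 0.1, + 0.5
  expect_equal(w$weight[w$species_id == "c"], 1.0)
  # the endemic bonus is exactly 0.5 over the same record without the flag
  expect_equal(w$weight[w$species_id == "d"] - w$weight[w$species_id == "a"],
               0.5)
  expect_error(compute_weights(records,
                               meta[meta$species_id != "b", ]),
               class = "avishift_error_keying")
})

caz_fixture <- function() {
  # 3 cells in one row; A holds 0.5 in cells 1-2, B holds 1.0 in cell 3
  a <- mk_grid(matrix(c(0.5, 0.5, 0), 1, 3))
  b <- mk_grid(matrix(c(0, 0, 1), 1, 3))
  list(layers = list(A = a, B = b),
       weights = tibble::tibble(species_id = c("A", "B"),
                                weight = c(1, 1)))
}

test_that("the 3-cell worked trace removes cells 1, 2, 3 in order", {
  fx <- caz_fixture()
  # initial marginal losses (0.5, 0.5, 1.0): index tie-break removes cell 1,
  # then 2, then 3; cell 3 ends with rank 1
  rk <- caz_rank(fx$layers, fx$weights, warp_factor = 1)
  ord <- rk$removal_order
  expect_equal(ord$col, c(1L, 2L, 3L))
  expect_equal(ord$rank, c(1, 2, 3) / 3)
  expect_equal(rg_band(rk$rank_grid, 1L)[1, 3], 1)
  # doubling B's weight leaves the order unchanged (cell 3 already last)
  fx$weights$weight[2] <- 2
  rk2 <- caz_rank(fx$layers, fx$weights, warp_factor = 1)
  expect_equal(rk2$removal_order$col, c(1L, 2L, 3L))
})

test_that("a warp factor at or above the cell count removes one ordered batch", {
  fx <- caz_fixture()
  rk <- caz_rank(fx$layers, fx$weights, warp_factor = 10)
  # single batch, ranked by within-batch marginal-loss order
  expect_equal(rk$removal_order$col, c(1L, 2L, 3L))
  expect_equal(sort(rk$removal_order$rank), c(1, 2, 3) / 3)
})

test_that("warp-1 ranking equals the brute-force greedy oracle", {
  for (s in 1:10) {
    set.seed(s)
    nr <- sample(3:10, 1); nc <- sample(3:10, 1)
    n_sp <- sample(2:5, 1)
    layers <- lapply(seq_len(n_sp), function(j) {
      mk_grid(matrix(runif(nr * nc), nr, nc))
    })
    names(layers) <- paste0("sp", seq_len(n_sp))
    wts <- tibble::tibble(species_id = names(layers),
                          weight = runif(n_sp, 0.2, 2))
    rk <- caz_rank(layers, wts, warp_factor = 1)
    S <- vapply(layers, function(l) as.vector(rg_band(l, 1L)),
                numeric(nr * nc))
    oracle <- oracle_caz_order(S, wts$weight, nr, nc, seq_len(nr * nc))
    expect_identical(rk$removal_order$cell, oracle)
  }
})

test_that("ranks form a permutation of i/N over land cells", {
  run <- get_small_run()
  rk <- run$priority$rcp85$unmasked
  n <- nrow(rk$removal_order)
  expect_equal(sort(rk$removal_order$rank), seq_len(n) / n)
  m <- rg_band(rk$rank_grid, 1L)
  expect_equal(sort(m[!is.na(m)]), seq_len(n) / n)
})

test_that("masked ranking puts every reserve cell below every open cell", {
  set.seed(21)
  layers <- list(a = mk_grid(matrix(runif(64), 8, 8)),
                 b = mk_grid(matrix(runif(64), 8, 8)))
  wts <- tibble::tibble(species_id = c("a", "b"), weight = c(1, 1.3))
  mask <- mk_grid(matrix(rbinom(64, 1, 0.3), 8, 8))
  rk <- caz_rank(layers, wts, warp_factor = 1, mask = mask)
  mv <- as.vector(rg_band(mask, 1L))
  rv <- as.vector(rg_band(rk$rank_grid, 1L))
  expect_lt(max(rv[mv == 1]), min(rv[mv == 0]))
  # a species with no suitability anywhere is dropped with a warning
  layers$z <- mk_grid(matrix(0, 8, 8))
  wts <- dplyr::add_row(wts, species_id = "z", weight = 1)
  expect_warning(caz_rank(layers, wts, warp_factor = 64), "zero total")
})

test_that("top fractions are nested, sized correctly, and coverage is a ratio", {
  set.seed(31)
  layers <- list(a = mk_grid(matrix(runif(100), 10, 10)))
  wts <- tibble::tibble(species_id = "a", weight = 1)
  rk <- caz_rank(layers, wts, warp_factor = 1)
  top30 <- top_fraction(rk, 0.3)
  top50 <- top_fraction(rk, 0.5)
  expect_equal(sum(rg_band(top30, 1L)), 30)
  expect_equal(sum(rg_band(top50, 1L)), 50)
  # nestedness and the full-fraction limit
  expect_true(all(rg_band(top50, 1L)[rg_band(top30, 1L) == 1] == 1))
  expect_equal(sum(rg_band(top_fraction(rk, 1), 1L)), 100)
  # coverage: share of priority cells inside reserves
  reserves <- mk_grid(matrix(0, 10, 10))
  expect_equal(coverage_stats(top30, reserves), 0)
  reserves2 <- mk_grid(matrix(1, 10, 10))
  expect_equal(coverage_stats(top30, reserves2), 1)
  sel <- rg_band(top30, 1L)
  partial <- matrix(0, 10, 10); partial[which(sel == 1)[1:3]] <- 1
  expect_equal(coverage_stats(top30, mk_grid(partial)), 0.1)
  empty <- mk_grid(matrix(0, 10, 10))
  expect_error(coverage_stats(empty, reserves),
               class = "avishift_error_undefined_coverage")
})

test_that("dropping a species' layer preserves removal order among cells it never occupied", {
  # in the core-area rule a cell's marginal loss outside species b is
  # w_a * p_a / Q_a, and Q_a rescales every such cell identically, so the
  # relative removal order of b-free cells is a pure function of p_a
  set.seed(41)
  a <- matrix(runif(36), 6, 6)
  b <- matrix(0, 6, 6); b[1:2, 1:2] <- runif(4)
  layers <- list(a = mk_grid(a), b = mk_grid(b))
  wts <- tibble::tibble(species_id = c("a", "b"), weight = c(1, 1))
  rk_with <- caz_rank(layers, wts, warp_factor = 1)
  rk_without <- caz_rank(layers["a"], wts[1, ], warp_factor = 1)
  absent <- which(as.vector(rg_band(layers$b, 1L)) == 0)
  order_among <- function(r) {
    ord <- r$removal_order
    ord$cell[ord$cell %in% absent]
  }
  expect_identical(order_among(rk_with), order_among(rk_without))
})
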
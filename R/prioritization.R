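#' Range-change-based species weights for prioritization
#'
#' Species losing range under climate change should pull conservation
#' priority toward their strongholds, so weights decrease with the
#' percentage range change: `w = clamp(1 - pct_change/100, w_min, w_max)`,
#' plus a bonus of exactly 0.5 for endemic species. A species losing half
#' its range gets 1.5; a stable species gets 1; strong expanders are floored
#' at `w_min`.
#'
#' @param records Range-change tibble with `species_id` and `pct_change`.
#' @param meta Species metadata with `species_id` and `endemic`.
#' @param w_min,w_max Clamp bounds applied before the endemic bonus
#'   (defaults 0.1 and 2).
#' @return A tibble: `species_id`, `pct_change`, `endemic`, `weight`.
#' @export
compute_weights <- function(records, meta, w_min = 0.1, w_max = 2) {
  missing <- setdiff(records$species_id, meta$species_id)
  if (length(missing)) {
    rlang::abort(paste("Species missing from metadata:",
                       paste(missing, collapse = ", ")),
                 class = "avishift_error_keying")
  }
  df <- dplyr::left_join(
    dplyr::select(records, "species_id", "pct_change"),
    dplyr::select(meta, "species_id", "endemic"),
    by = "species_id"
  )
  if (anyNA(df$pct_change)) {
    rlang::abort("Missing `pct_change` for some species.",
                 class = "avishift_error_keying")
  }
  dplyr::mutate(
    df,
    weight = clamp(1 - .data$pct_change / 100, w_min, w_max) +
      0.5 * .data$endemic
  )
}

#' Core-area zonation cell-removal ranking
#'
#' Greedy reverse prioritization: cells are removed one batch at a time, each
#' batch holding the `warp_factor` cells with the smallest marginal loss,
#' where the marginal loss of cell i is the maximum over species j of
#' `w_j * p_ij / Q_j` — species j's weighted share of its remaining total
#' suitability `Q_j` that sits in the cell. Cells removed later rank higher;
#' ranks are removal position divided by the number of land cells, so the
#' best cell ranks 1. Ties are broken by smallest marginal loss, then
#' row-major cell index. With a mask, all masked-in cells (e.g. existing
#' reserves) are removed first in their own greedy phase, so the top of the
#' ranking lies entirely outside the mask.
#'
#' @param species_layers Named list of aligned suitability `raster_grid`s.
#' @param weights Weight tibble from [compute_weights()] (`species_id`,
#'   `weight`); species without a layer are ignored, layers without a weight
#'   are an error.
#' @param warp_factor Cells removed per iteration without recomputing
#'   marginal losses within the batch (default 1000).
#' @param mask Optional `raster_grid`; cells where it equals 1 are removed
#'   first.
#' @return A `priority_ranking`: `rank_grid` (`raster_grid` in (0, 1]),
#'   `removal_order` tibble (`cell`, `row`, `col`, `position`, `rank`,
#'   `masked_phase`), `warp_factor`, `masked`.
#' @export
caz_rank <- function(species_layers, weights, warp_factor = 1000,
                     mask = NULL) {
  stopifnot(warp_factor >= 1, length(species_layers) >= 1)
  template <- species_layers[[1]]
  for (l in species_layers) rg_check_aligned(template, l)
  if (!is.null(mask)) rg_check_aligned(template, mask)

  sp <- names(species_layers)
  no_weight <- setdiff(sp, weights$species_id)
  if (length(no_weight)) {
    rlang::abort(paste("No weight for species:",
                       paste(no_weight, collapse = ", ")),
                 class = "avishift_error_keying")
  }
  w <- weights$weight[match(sp, weights$species_id)]
  if (any(w <= 0)) {
    rlang::abort("All weights must be positive.",
                 class = "avishift_error_config")
  }

  nr <- rg_nrow(template); nc <- rg_ncol(template)
  mats <- lapply(species_layers, rg_band, 1L)
  land <- Reduce(`|`, lapply(mats, function(m) !is.na(m)))
  land_idx <- which(land)
  n_land <- length(land_idx)
  S <- vapply(mats, function(m) {
    v <- m[land_idx]
    v[is.na(v)] <- 0
    v
  }, numeric(n_land))
  S <- matrix(S, nrow = n_land)

  Q <- colSums(S * rep(1, n_land))
  dead <- Q <= 0
  if (any(dead)) {
    rlang::warn(paste("Dropping species with zero total suitability:",
                      paste(sp[dead], collapse = ", ")))
    S <- S[, !dead, drop = FALSE]
    w <- w[!dead]
    Q <- Q[!dead]
  }
  if (ncol(S) == 0) {
    rlang::abort("No species with positive suitability remain.",
                 class = "avishift_error_config")
  }

  # row-major id for deterministic tie-breaking
  row_of <- ((land_idx - 1L) %% nr) + 1L
  col_of <- ((land_idx - 1L) %/% nr) + 1L
  rowmajor <- (row_of - 1L) * nc + col_of

  in_mask <- if (is.null(mask)) rep(FALSE, n_land) else {
    mv <- rg_band(mask, 1L)[land_idx]
    !is.na(mv) & mv == 1
  }

  remaining <- rep(TRUE, n_land)
  position <- integer(n_land)
  phase_of <- logical(n_land)
  pos <- 0L

  remove_phase <- function(eligible_fun) {
    repeat {
      elig <- which(remaining & eligible_fun())
      if (length(elig) == 0) break
      q_safe <- pmax(Q, 1e-300)
      ml <- as.vector(
        apply(S[elig, , drop = FALSE] *
                rep(w / q_safe, each = length(elig)), 1L, max)
      )
      ord <- elig[order(ml, rowmajor[elig])]
      batch <- ord[seq_len(min(warp_factor, length(ord)))]
      position[batch] <<- pos + seq_along(batch)
      pos <<- pos + length(batch)
      remaining[batch] <<- FALSE
      Q <<- Q - colSums(S[batch, , drop = FALSE])
    }
  }

  if (any(in_mask)) {
    remove_phase(function() in_mask)
    phase_of[in_mask] <- TRUE
  }
  remove_phase(function() rep(TRUE, n_land))

  rank_val <- position / n_land
  rank_m <- matrix(NA_real_, nr, nc)
  rank_m[land_idx] <- rank_val

  structure(
    list(
      rank_grid = rg_like(template, rank_m, bands = "rank"),
      removal_order = tibble::tibble(
        cell = land_idx, row = row_of, col = col_of,
        position = position, rank = rank_val, masked_phase = phase_of
      ) |> dplyr::arrange(.data$position),
      warp_factor = warp_factor,
      masked = any(in_mask)
    ),
    class = "priority_ranking"
  )
}

#' @export
print.priority_ranking <- function(x, ...) {
  cat(sprintf("<priority_ranking> %d land cells, warp %d%s\n",
              nrow(x$removal_order), x$warp_factor,
              if (x$masked) ", reserve-masked" else ""))
  invisible(x)
}

#' @method tidy priority_ranking
#' @export
tidy.priority_ranking <- function(x, ...) x$removal_order

#' Top-priority fraction of a ranking
#'
#' Marks the best-ranked `fraction` of land cells (rank strictly above
#' `1 - fraction`).
#'
#' @param ranking A `priority_ranking`.
#' @param fraction Proportion of land cells to select, in (0, 1].
#' @return A binary `raster_grid` (1 = selected, 0 = other land, `NA` off
#'   land).
#' @export
top_fraction <- function(ranking, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  m <- rg_band(ranking$rank_grid, 1L)
  out <- (m > 1 - fraction) * 1
  rg_like(ranking$rank_grid, out,
          bands = sprintf("top%g", 100 * fraction))
}

#' Reserve coverage of a priority area
#'
#' The share of selected priority cells that fall inside the reserve mask —
#' the gap statistic showing how much of the priority area the current
#' reserve network already protects.
#'
#' @param priority Binary priority `raster_grid` (from [top_fraction()]).
#' @param reserves Binary reserve-mask `raster_grid`, aligned.
#' @return Proportion in \[0, 1\].
#' @export
coverage_stats <- function(priority, reserves) {
  rg_check_aligned(priority, reserves)
  p <- rg_band(priority, 1L)
  r <- rg_band(reserves, 1L)
  sel <- !is.na(p) & p == 1
  if (!any(sel)) {
    rlang::abort("Priority set is empty: coverage undefined.",
                 class = "avishift_error_undefined_coverage")
  }
  mean(!is.na(r[sel]) & r[sel] == 1)
}
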
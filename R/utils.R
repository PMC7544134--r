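#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Derive a stage-specific seed from a master seed
#'
#' Mixes a stage label into the master seed so each pipeline stage draws from
#' its own reproducible stream, and re-running one stage does not depend on
#' the RNG consumption of the stages before it.
#'
#' @param master Master seed (integer).
#' @param stage Stage label (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(as.double(utf8ToInt(stage)) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.double(master) %% 2147483647 * 31 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sliding box mean along both axes with truncated windows at the edges;
# k is the half-width in cells (window 2k+1)
box_smooth <- function(m, k) {
  if (k < 1) return(m)
  smooth1 <- function(v) {
    n <- length(v)
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - k, 1)
    hi <- pmin(seq_len(n) + k, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2L, smooth1)
  t(apply(m, 1L, smooth1))
}

haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}
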
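# Alternative-hypothesis relative-risk surfaces: a single local cluster, a
# global spiral decaying outward from a central cluster, and a west-east
# linear trend. Counts under an alternative are multinomial with
# p_i = r_i n_i / sum_j r_j n_j.

new_risk_surface <- function(geo, risk, pattern, parameters) {
  out <- tibble(id = geo$id, risk = risk)
  attr(out, "pattern") <- pattern
  attr(out, "parameters") <- parameters
  class(out) <- c("risk_surface", class(out))
  out
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf("<risk_surface> '%s' pattern, %d regions, risk in [%g, %g]\n",
              attr(x, "pattern"), nrow(x), min(x$risk), max(x$risk)))
  invisible(x)
}

#' Pattern tag of a risk surface
#' @param risks A `risk_surface`.
#' @export
risk_pattern <- function(risks) attr(risks, "pattern")

# Regions sorted by ascending distance from the center (center first, ties by
# geography order), with cumulative population.
center_ordering <- function(geo, distances, center_id) {
  ci <- match(center_id, geo$id)
  if (is.na(ci)) abort(sprintf("center id '%s' not in geography", center_id),
                       class = "moranmod_validation_error")
  ord <- c(ci, neighbor_order(distances, ci))
  tibble(index = ord, id = geo$id[ord],
         cum_pop = cumsum(geo$population[ord]))
}

#' Single local cluster risk surface
#'
#' Regions are sorted by distance from the center (center first) and added
#' until their cumulative population first reaches
#' `population_fraction * n_+`; the region crossing the threshold is included.
#' Included regions get relative risk `rr`, all others 1.
#'
#' @param geo A [geography].
#' @param distances Matrix from [pairwise_distances()]; computed when `NULL`.
#' @param center_id Region id at the cluster center.
#' @param population_fraction Fraction of total population inside the cluster
#'   (the reference study grid is 5, 10, 15, 20, 30%).
#' @param rr Relative risk inside the cluster (default 1.5).
#' @return A `risk_surface` tibble (`id`, `risk`) with attributes recording
#'   the pattern and its parameters (including realized cluster size).
#' @export
local_cluster_risks <- function(geo, distances = NULL, center_id,
                                population_fraction, rr = 1.5) {
  if (population_fraction <= 0 || population_fraction >= 1) {
    abort("population_fraction must be in (0, 1)",
          class = "moranmod_validation_error")
  }
  if (is.null(distances)) distances <- pairwise_distances(geo)
  ord <- center_ordering(geo, distances, center_id)
  target <- population_fraction * total_population(geo)
  size <- which(ord$cum_pop >= target)[1]
  if (is.na(size)) size <- nrow(ord)
  if (size == 1) warn("cluster fraction so small that only the center qualifies")
  risk <- rep(1, nrow(geo))
  risk[ord$index[seq_len(size)]] <- rr
  new_risk_surface(geo, risk, "local",
                   list(center_id = center_id,
                        population_fraction = population_fraction,
                        rr = rr, cluster_size = size))
}

#' Global spiral risk surface
#'
#' A central cluster containing `core_fraction` of the total population gets
#' relative risk `rr_max`; the remaining regions, ordered by distance from the
#' center, are split into `steps` near-equal-count groups whose risk decreases
#' in equal decrements from just under `rr_max` down to exactly 1 in the
#' outermost group.
#'
#' @inheritParams local_cluster_risks
#' @param core_fraction Population fraction of the central cluster
#'   (default 0.02).
#' @param rr_max Risk of the central cluster (default 1.5).
#' @param steps Number of equal risk decrements (default 100); reduced with a
#'   warning when fewer regions remain.
#' @return A `risk_surface`.
#' @export
spiral_risks <- function(geo, distances = NULL, center_id,
                         core_fraction = 0.02, rr_max = 1.5, steps = 100) {
  if (is.null(distances)) distances <- pairwise_distances(geo)
  ord <- center_ordering(geo, distances, center_id)
  target <- core_fraction * total_population(geo)
  core_size <- which(ord$cum_pop >= target)[1]
  if (is.na(core_size)) core_size <- nrow(ord)
  n_rest <- nrow(geo) - core_size
  if (n_rest < steps) {
    warn(sprintf("only %d regions outside the core; steps reduced from %d",
                 n_rest, steps))
    steps <- max(n_rest, 1L)
  }
  risk <- rep(1, nrow(geo))
  risk[ord$index[seq_len(core_size)]] <- rr_max
  if (n_rest > 0) {
    group <- ceiling(seq_len(n_rest) / (n_rest / steps))
    group <- pmin(group, steps)
    risk[ord$index[core_size + seq_len(n_rest)]] <-
      rr_max - group * (rr_max - 1) / steps
  }
  new_risk_surface(geo, risk, "spiral",
                   list(center_id = center_id, core_fraction = core_fraction,
                        rr_max = rr_max, steps = steps,
                        core_size = core_size))
}

#' West-east linear trend risk surface
#'
#' The longitude interval `[lon_west, lon_east]` is divided into `bins`
#' sub-intervals of equal length; a region in sub-interval `a` (an integer
#' from 0 to `bins - 1`) gets `r = 1 + (rr_max - 1) * a / (bins - 1)`, a
#' monotone step function from 1 at the west edge to `rr_max` at the east
#' edge. Defaults span the continental United States.
#'
#' @param geo A [geography]; the x coordinate is treated as longitude.
#' @param lon_west,lon_east Interval endpoints (defaults -124.161, -67.623).
#' @param rr_max Maximum relative risk on the east coast (default 1.5).
#' @param bins Number of sub-intervals (default 100).
#' @return A `risk_surface`.
#' @export
linear_risks <- function(geo, lon_west = -124.161, lon_east = -67.623,
                         rr_max = 1.5, bins = 100) {
  if (lon_east <= lon_west) abort("degenerate longitude range",
                                  class = "moranmod_validation_error")
  lon <- geo$x
  if (any(lon < lon_west | lon > lon_east)) {
    warn("longitudes outside [lon_west, lon_east] clamped")
    lon <- pmin(pmax(lon, lon_west), lon_east)
  }
  a <- pmin(floor(bins * (lon - lon_west) / (lon_east - lon_west)), bins - 1)
  risk <- 1 + (rr_max - 1) * a / (bins - 1)
  new_risk_surface(geo, risk, "linear",
                   list(lon_west = lon_west, lon_east = lon_east,
                        rr_max = rr_max, bins = bins))
}

#' Simulate regional counts under an alternative risk surface
#'
#' Each replicate is multinomial with `p_i = r_i n_i / sum_j r_j n_j` and the
#' same total `y_plus` as the matched null simulation. With `r == 1`
#' everywhere this reduces exactly to [simulate_null()].
#'
#' @param risks A `risk_surface` (or numeric risk vector in region order).
#' @param populations A [geography] or numeric population vector.
#' @param y_plus Total cases per replicate.
#' @param R Number of replicates.
#' @param seed Integer seed.
#' @return Integer matrix, `N x R`.
#' @export
simulate_alternative <- function(risks, populations, y_plus, R, seed = NULL) {
  if (inherits(populations, "geography") || is.data.frame(populations)) {
    populations <- populations$population
  }
  r <- if (is.data.frame(risks)) risks$risk else as.numeric(risks)
  if (length(r) != length(populations)) {
    abort("risk surface and populations have different lengths",
          class = "moranmod_validation_error")
  }
  if (y_plus < 1) abort("y_plus must be >= 1",
                        class = "moranmod_validation_error")
  p <- r * populations
  if (sum(p) <= 0) abort("all-zero risk-weighted populations",
                         class = "moranmod_validation_error")
  p <- p / sum(p)
  draw <- function() rmultinom(R, size = y_plus, prob = p)
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}
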
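# Power of the Monte Carlo clustering tests against simulated risk patterns:
# critical value from M null replicates, power = percent of R alternative
# replicates whose statistic exceeds it.

#' Power of a clustering test against a risk surface
#'
#' Builds the constant-risk null distribution (`M_null` replicates), takes the
#' `1 - alpha` empirical critical value, simulates `R_alt` data sets under the
#' alternative, and reports the percentage whose statistic exceeds the
#' critical value. Degenerate alternative draws (undefined statistic) are
#' redrawn like null ones.
#'
#' @param statistic `"I"`, `"I_w"`, or `"I_pop"`.
#' @param W A `weight_matrix`.
#' @param risks A `risk_surface` (or risk vector in region order).
#' @param populations A [geography] or numeric population vector.
#' @param y_plus Total cases per replicate (the study convention is one
#'   expected case per 1,000 at risk: `round(n_+ / 1000)`).
#' @param M_null Null replicates (reference 10,000).
#' @param R_alt Alternative replicates (reference 1,000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed covering both null and alternative simulation.
#' @param wii_policy Diagonal policy for I_pop.
#' @return A one-row tibble: `power` (percent), `critical_value`, replicate
#'   counts and provenance.
#' @export
estimate_power <- function(statistic, W, risks, populations, y_plus,
                           M_null = 10000, R_alt = 1000, alpha = 0.05,
                           seed = NULL, wii_policy = "auto") {
  if (inherits(populations, "geography") || is.data.frame(populations)) {
    populations <- populations$population
  }
  seeds <- derive_seeds(seed, 2)
  nd <- null_distribution(statistic, W, populations, y_plus, M = M_null,
                          seed = seeds[1], wii_policy = wii_policy)
  cv <- critical_value(nd, alpha)
  run_alt <- function() {
    Y <- simulate_alternative(risks, populations, y_plus, R_alt)
    vals <- compute_statistic(statistic, Y, W, populations, wii_policy)
    bad <- which(!is.finite(vals))
    while (length(bad) > 0) {
      Yb <- simulate_alternative(risks, populations, y_plus, length(bad))
      vals[bad] <- compute_statistic(statistic, Yb, W, populations, wii_policy)
      bad <- bad[!is.finite(vals[bad])]
    }
    vals
  }
  vals <- if (!is.null(seeds)) withr::with_seed(seeds[2], run_alt()) else run_alt()
  tibble(
    statistic = statistic,
    scheme = weight_scheme(W),
    pattern = if (is.data.frame(risks)) risk_pattern(risks) else "custom",
    power = 100 * mean(vals > cv),
    critical_value = cv,
    M_null = M_null, R_alt = R_alt, alpha = alpha,
    y_plus = y_plus, seed = seed %||% NA_integer_
  )
}

# Deterministic sub-seeds below 2^31 from one user seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1000003 + 7919 * seq_len(n)) %% 2147483629
}

#' Run a full power study over patterns, statistics and weight schemes
#'
#' Evaluates the cross-product of the configured risk patterns, statistics and
#' weight schemes on one geography, reusing each (statistic, scheme) null
#' distribution across patterns. The configuration is a nested list (readable
#' from YAML by the CLI) with elements:
#'
#' * `geography`: either `list(lattice = list(rows, cols, population_per_cell,
#'   spacing))` or `list(csv = path, gal = path)`
#' * `patterns`: list of pattern specs, e.g. `list(type = "local", fraction =
#'   0.05, rr = 1.5)`, `list(type = "spiral", core_fraction = 0.02)`,
#'   `list(type = "linear")`; optional `center_id` (defaults to the region
#'   closest to the map's geometric center)
#' * `statistics`: subset of `c("I_w", "I", "I_pop")`
#' * `schemes`: subset of `c("Adj", "PD")`
#' * `M`, `R`, `alpha`, `seed`, `lambda_fraction`, `total_cases`
#'   (default `round(n_+ / 1000)`)
#'
#' @param config Nested configuration list (see Details).
#' @param cache_dir Optional directory; completed cells are written there as
#'   JSON and reused on re-run, making long studies resumable.
#' @return A `power_table` tibble: one row per (pattern, fraction, statistic,
#'   scheme) with power in percent and per-cell seeds.
#' @export
power_study <- function(config, cache_dir = NULL) {
  geo_cfg <- config$geography
  if (!is.null(geo_cfg$lattice)) {
    l <- geo_cfg$lattice
    lat <- make_lattice(l$rows, l$cols,
                        population_per_cell = l$population_per_cell %||% 5000,
                        spacing = l$spacing %||% 1)
    geo <- lat$geography
    adj <- lat$adjacency
  } else {
    geo <- load_geography(geo_cfg$csv)
    adj <- if (!is.null(geo_cfg$gal)) load_adjacency(geo_cfg$gal, geo) else NULL
  }
  distances <- pairwise_distances(geo)
  statistics <- config$statistics %||% c("I_w", "I", "I_pop")
  schemes <- config$schemes %||% c("Adj", "PD")
  M <- config$M %||% 10000
  R <- config$R %||% 1000
  alpha <- config$alpha %||% 0.05
  base_seed <- config$seed %||% 1
  y_plus <- config$total_cases %||% round(total_population(geo) / 1000)
  lambda_fraction <- config$lambda_fraction %||% 0.5

  Ws <- list()
  if ("Adj" %in% schemes) {
    if (is.null(adj)) abort("Adj scheme requested but no adjacency available",
                            class = "moranmod_validation_error")
    Ws$Adj <- adjacency_weights(adj)
  }
  if ("PD" %in% schemes) {
    Ws$PD <- pd_weights(geo, distances,
                        pd_parameters(lambda_fraction = lambda_fraction))
  }

  default_center <- function() {
    cx <- mean(range(geo$x)); cy <- mean(range(geo$y))
    geo$id[which.min((geo$x - cx)^2 + (geo$y - cy)^2)]
  }
  build_risks <- function(pat) {
    center <- pat$center_id %||% default_center()
    switch(pat$type,
      local = local_cluster_risks(geo, distances, center,
                                  population_fraction = pat$fraction,
                                  rr = pat$rr %||% 1.5),
      spiral = spiral_risks(geo, distances, center,
                            core_fraction = pat$core_fraction %||% 0.02,
                            rr_max = pat$rr %||% 1.5,
                            steps = pat$steps %||% 100),
      linear = linear_risks(geo,
                            lon_west = pat$lon_west %||% min(geo$x),
                            lon_east = pat$lon_east %||% max(geo$x),
                            rr_max = pat$rr %||% 1.5,
                            bins = pat$bins %||% 100),
      abort(sprintf("unknown pattern type '%s'", pat$type),
            class = "moranmod_validation_error")
    )
  }

  cells <- list()
  cell_i <- 0
  for (pat in config$patterns) {
    risks <- build_risks(pat)
    label <- if (identical(pat$type, "local"))
      sprintf("local_%g", 100 * pat$fraction) else pat$type
    for (stat in statistics) {
      for (scheme in names(Ws)) {
        cell_i <- cell_i + 1
        cell_seed <- derive_seeds(base_seed, cell_i)[cell_i]
        cache_file <- if (!is.null(cache_dir))
          file.path(cache_dir, paste0(label, "_", stat, "_", scheme, ".json"))
        if (!is.null(cache_file) && file.exists(cache_file)) {
          row <- as_tibble(jsonlite::read_json(cache_file, simplifyVector = TRUE))
        } else {
          row <- estimate_power(stat, Ws[[scheme]], risks, geo, y_plus,
                                M_null = M, R_alt = R, alpha = alpha,
                                seed = cell_seed)
          if (!is.null(cache_file)) {
            dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
            jsonlite::write_json(as.list(row), cache_file, auto_unbox = TRUE,
                                 digits = NA)
          }
        }
        row$cell <- label
        row$fraction <- if (identical(pat$type, "local")) pat$fraction else NA_real_
        cells[[cell_i]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(cells)
  class(out) <- c("power_table", class(out))
  out
}

#' Write a power table as TSV in the wide reference layout
#'
#' Rows are pattern (and, for local clusters, the percent of population in
#' the cluster); columns are statistic x weight scheme; cells are power in
#' percent with one decimal.
#'
#' @param pt A `power_table` from [power_study()].
#' @param path Output path.
#' @return The wide tibble, invisibly.
#' @export
write_power_table <- function(pt, path) {
  wide <- pt |>
    dplyr::mutate(column = paste(.data$statistic, .data$scheme, sep = "_"),
                  power = round(.data$power, 1)) |>
    dplyr::select("cell", "fraction", "column", "power") |>
    tidyr::pivot_wider(names_from = "column", values_from = "power")
  readr::write_tsv(wide, path)
  invisible(wide)
}
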
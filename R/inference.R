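# Monte Carlo inference under the constant-risk multinomial null: simulated
# null count vectors, empirical null distributions, 95th-percentile critical
# values and add-one empirical p-values.

#' Simulate regional counts under the constant-risk null
#'
#' Each replicate is a multinomial draw of `y_plus` cases over regions with
#' probabilities `p_i = n_i / n_+` (equal relative risk everywhere), so every
#' replicate sums exactly to `y_plus` — the same total as the data (or
#' alternative-hypothesis simulation) being tested.
#'
#' @param y_plus Total number of cases per replicate.
#' @param populations A [geography] or numeric vector of populations `n_i`.
#' @param M Number of replicates.
#' @param seed Integer seed (RNG state is restored afterwards).
#' @return Integer matrix, `N x M`, one replicate per column.
#' @export
simulate_null <- function(y_plus, populations, M, seed = NULL) {
  if (inherits(populations, "geography") || is.data.frame(populations)) {
    populations <- populations$population
  }
  if (sum(populations) <= 0) abort("all-zero populations",
                                   class = "moranmod_validation_error")
  if (y_plus < 1) abort("y_plus must be >= 1",
                        class = "moranmod_validation_error")
  p <- populations / sum(populations)
  draw <- function() rmultinom(M, size = y_plus, prob = p)
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Empirical null distribution of a clustering statistic
#'
#' Computes the chosen statistic on `M` constant-risk multinomial replicates.
#' Replicates on which the statistic is undefined (e.g. a constant count
#' vector) are redrawn; more than 1% degenerate draws aborts with a
#' diagnostic, as that signals a pathological `y_plus` relative to `N`.
#'
#' @param statistic `"I"`, `"I_w"`, or `"I_pop"`.
#' @param W A `weight_matrix`.
#' @param populations A [geography] or numeric population vector.
#' @param y_plus Total cases per replicate.
#' @param M Number of replicates (the reference null size is 10,000; scaled
#'   runs commonly use 2,000).
#' @param seed Integer seed; fixed seed gives a bit-identical distribution.
#' @param wii_policy Diagonal policy for I_pop (see [oden_ipop()]).
#' @return A `null_dist` object: sorted statistic values plus provenance
#'   (`M`, `seed`, `y_plus`, statistic and scheme tags).
#' @export
null_distribution <- function(statistic, W, populations, y_plus, M,
                              seed = NULL, wii_policy = "auto") {
  if (inherits(populations, "geography") || is.data.frame(populations)) {
    populations <- populations$population
  }
  run <- function() {
    Y <- simulate_null(y_plus, populations, M)
    vals <- compute_statistic(statistic, Y, W, populations, wii_policy)
    degen <- 0L
    bad <- which(!is.finite(vals))
    while (length(bad) > 0) {
      degen <- degen + length(bad)
      if (degen > 0.01 * M) {
        abort(sprintf(
          "more than 1%% of null replicates degenerate (%d of %d): y_plus = %g is pathological for N = %d",
          degen, M, y_plus, nrow(W)), class = "moranmod_degenerate_error")
      }
      Yb <- simulate_null(y_plus, populations, length(bad))
      vals[bad] <- compute_statistic(statistic, Yb, W, populations, wii_policy)
      bad <- bad[!is.finite(vals[bad])]
    }
    list(vals = vals, degen = degen)
  }
  r <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  structure(list(statistic = statistic, values = sort(r$vals), M = M,
                 seed = seed, y_plus = y_plus, scheme = weight_scheme(W),
                 degenerate_redraws = r$degen),
            class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf("<null_dist> %s under constant risk: M = %d, y_+ = %g, %s weights\n",
              x$statistic, x$M, x$y_plus, x$scheme))
  cat(sprintf("  quartiles %s\n",
              paste(signif(quantile(x$values, c(.25, .5, .75)), 4),
                    collapse = " / ")))
  invisible(x)
}

#' Empirical critical value
#'
#' The order statistic of rank `ceiling((1 - alpha) * M)` of the null values
#' (no interpolation); at `alpha = 0.05` and `M = 10,000` this is the
#' 9,500-th order statistic, the 95th percentile of the empirical null.
#'
#' @param nd A `null_dist`.
#' @param alpha Significance level in (0, 1).
#' @return Scalar critical value.
#' @export
critical_value <- function(nd, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)",
                                      class = "moranmod_validation_error")
  nd$values[ceiling((1 - alpha) * nd$M)]
}

#' Monte Carlo p-value (one-sided, upper tail)
#'
#' Add-one convention: `p = (1 + #{null >= observed}) / (M + 1)`, guaranteeing
#' a valid test and `p >= 1/(M+1)`. Upper tail because positive spatial
#' autocorrelation is the alternative throughout.
#'
#' @param observed Observed statistic value.
#' @param nd A `null_dist`.
#' @return p-value in `(0, 1]`.
#' @export
mc_pvalue <- function(observed, nd) {
  (1 + sum(nd$values >= observed)) / (nd$M + 1)
}

#' Monte Carlo test for global clustering
#'
#' Computes the chosen statistic on observed counts, builds the constant-risk
#' null distribution with the observed total `y_+`, and returns the empirical
#' p-value and critical value with full provenance.
#'
#' @param counts Data frame with columns `id`, `cases` (or numeric vector in
#'   region order).
#' @param geo A [geography].
#' @param statistic `"I"`, `"I_w"`, or `"I_pop"`.
#' @param weights `"adj"` (requires `adjacency`) or `"pd"`, or a prebuilt
#'   `weight_matrix`.
#' @param adjacency An `adjacency` object (for `weights = "adj"`).
#' @param pd_params [pd_parameters()] (for `weights = "pd"`).
#' @param M Null replicates (default 10,000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param wii_policy Diagonal policy for I_pop.
#' @return A `moran_test` object; see [tidy.moran_test()] and
#'   [glance.moran_test()].
#' @examples
#' lat <- make_lattice(5, 5, population_per_cell = 1000)
#' y <- simulate_null(100, lat$geography, M = 1, seed = 7)[, 1]
#' counts <- data.frame(id = lat$geography$id, cases = y)
#' run_test(counts, lat$geography, statistic = "I_w", weights = "adj",
#'          adjacency = lat$adjacency, M = 200, seed = 1)
#' @export
run_test <- function(counts, geo, statistic = c("I_w", "I", "I_pop"),
                     weights = c("adj", "pd"), adjacency = NULL,
                     pd_params = pd_parameters(), M = 10000, alpha = 0.05,
                     seed = NULL, wii_policy = "auto") {
  statistic <- match.arg(statistic)
  if (inherits(weights, "weight_matrix")) {
    W <- weights
  } else {
    weights <- match.arg(weights)
    W <- switch(weights,
      adj = {
        if (is.null(adjacency)) abort("weights = 'adj' needs an `adjacency`",
                                      class = "moranmod_validation_error")
        adjacency_weights(adjacency)
      },
      pd = pd_weights(geo, pairwise_distances(geo), pd_params)
    )
  }
  y <- align_counts(counts, rownames(W))
  observed <- switch(statistic,
    I = moran_i(y, W),
    I_w = modified_moran_i(y, W),
    I_pop = oden_ipop(y, geo, W, wii_policy = wii_policy)
  )
  nd <- null_distribution(statistic, W, geo, y_plus = sum(y), M = M,
                          seed = seed, wii_policy = wii_policy)
  structure(list(
    statistic = statistic,
    observed = observed$value,
    p_value = mc_pvalue(observed$value, nd),
    critical_value = critical_value(nd, alpha),
    alpha = alpha, M = M, seed = seed,
    y_plus = sum(y),
    scheme = weight_scheme(W),
    lambda_fraction = attr(W, "lambda_fraction"),
    null = nd,
    components = observed$components
  ), class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Monte Carlo test of global clustering (constant-risk null)\n"))
  cat(sprintf("  statistic: %s (%s weights)   observed = %.6g\n",
              x$statistic, x$scheme, x$observed))
  cat(sprintf("  M = %d null replicates, y_+ = %g\n", x$M, x$y_plus))
  cat(sprintf("  critical value (alpha = %g): %.6g\n", x$alpha,
              x$critical_value))
  cat(sprintf("  p-value: %.4g%s\n", x$p_value,
              if (x$observed > x$critical_value) "  *" else ""))
  invisible(x)
}

#' Tidy a Monte Carlo clustering test
#'
#' @param x A `moran_test`.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic, p-value, critical
#'   value, and provenance (M, seed, weight scheme, lambda fraction).
#' @method tidy moran_test
#' @export
tidy.moran_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         p_value = x$p_value, critical_value = x$critical_value,
         alpha = x$alpha, M = x$M, y_plus = x$y_plus,
         scheme = x$scheme,
         lambda_fraction = x$lambda_fraction %||% NA_real_,
         seed = x$seed %||% NA_integer_)
}

#' @rdname tidy.moran_test
#' @method glance moran_test
#' @export
glance.moran_test <- function(x, ...) tidy(x)

#' Serialize a test result to JSON
#'
#' @param x A `moran_test`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(x, path) {
  jsonlite::write_json(as.list(tidy(x)), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
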
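# ggplot2 methods for the package's result types.

#' Plot a risk surface on its geography
#'
#' @param object A `risk_surface`.
#' @param geo The [geography] it was built on.
#' @param ... Unused.
#' @return A ggplot: centroids colored by relative risk.
#' @method autoplot risk_surface
#' @export
autoplot.risk_surface <- function(object, geo, ...) {
  df <- dplyr::left_join(as_tibble(geo), as_tibble(object), by = "id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$risk)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "relative risk") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("'%s' risk pattern", risk_pattern(object)),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an empirical null distribution
#'
#' @param object A `null_dist`.
#' @param observed Optional observed statistic to mark.
#' @param alpha Level at which to mark the critical value.
#' @param ... Unused.
#' @return A ggplot histogram with critical value (dashed) and observed
#'   statistic (solid) marked.
#' @method autoplot null_dist
#' @export
autoplot.null_dist <- function(object, observed = NULL, alpha = 0.05, ...) {
  df <- tibble(value = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = critical_value(object, alpha),
                        linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("Null distribution of %s (%s weights, M = %d)",
                      object$statistic, object$scheme, object$M),
      x = object$statistic, y = "replicates") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "firebrick")
  }
  p
}

#' Plot a Monte Carlo clustering test
#'
#' @param object A `moran_test`.
#' @param ... Unused.
#' @return A ggplot of the null distribution with the observed value marked.
#' @method autoplot moran_test
#' @export
autoplot.moran_test <- function(object, ...) {
  autoplot(object$null, observed = object$observed, alpha = object$alpha)
}

#' Plot a power table
#'
#' @param object A `power_table` from [power_study()].
#' @param ... Unused.
#' @return A ggplot: power versus cluster fraction for local patterns, with
#'   global patterns as labeled points.
#' @method autoplot power_table
#' @export
autoplot.power_table <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      combo = paste(.data$statistic, .data$scheme))
  local <- dplyr::filter(df, !is.na(.data$fraction))
  global <- dplyr::filter(df, is.na(.data$fraction))
  p <- ggplot2::ggplot(local,
                       ggplot2::aes(x = 100 * .data$fraction, y = .data$power,
                                    colour = .data$combo)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "% of population in cluster", y = "power (%)",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (nrow(global) > 0) {
    p <- p + ggplot2::geom_hline(data = global,
                                 ggplot2::aes(yintercept = .data$power,
                                              colour = .data$combo),
                                 linetype = "dotted")
  }
  p
}
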
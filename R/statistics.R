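# Global clustering statistics on regional counts: classic Moran's I, the
# modified Moran's I in which the spatial weight function also enters the
# variance term, and Oden's I_pop which adjusts for population heterogeneity.
#
# Classic I:    I   = (N / S0) * s_yy_w / s_y2
# Modified I:   I_w = (N / S0) * s_yy_w / s2_yw
#   with  s_yy_w = sum_{i != j} w_ij (y_i - ybar)(y_j - ybar)
#         s_y2   = sum_i (y_i - ybar)^2
#         s2_yw  = (N / S0) * sum_{i != j} w_ij [(y_i - ybar)^2 + (y_j - ybar)^2] / 2
# so neighbors that contribute more to the cross-product also contribute more
# to the variation, and s2_yw collapses to s_y2 under homogeneous weights
# (hence I_w = I on constant positive weights).
#
# Oden's I_pop is Moran's I applied to individual-level case indicators: with
# v_i = n_i/n_+, e_i = y_i/y_+, b = y_+/n_+ and A_i = y_i - b n_i
# (= y_+ (e_i - v_i)),
#   I_pop = [ sum_{i != j} w_ij A_i A_j
#             + sum_i w_ii (A_i^2 - y_i (1-b)^2 - (n_i - y_i) b^2) ]
#           / [ b (1 - b) * (sum_{i != j} w_ij n_i n_j + sum_i w_ii n_i (n_i - 1)) ]
# The w_ii term is the chi-square-like heterogeneity component; weights need
# not be symmetric and w_ii may be nonzero (kept by default for PD weights).

# Align a count input (tibble with id/cases, or bare numeric vector) to the
# region order of a weight matrix.
align_counts <- function(counts, ids) {
  if (is.data.frame(counts)) {
    if (!all(c("id", "cases") %in% names(counts))) {
      abort("count data needs columns `id` and `cases`",
            class = "moranmod_validation_error")
    }
    pos <- match(ids, as.character(counts$id))
    if (anyNA(pos)) {
      abort(paste0("counts missing region id(s): ",
                   paste(head(ids[is.na(pos)], 5), collapse = ", ")),
            class = "moranmod_validation_error")
    }
    y <- as.numeric(counts$cases[pos])
  } else {
    y <- as.numeric(counts)
    if (!is.null(names(y)) && !is.null(ids) && all(ids %in% names(y))) {
      y <- y[ids]
    }
  }
  if (length(y) != length(ids) && !is.null(ids)) {
    abort("count vector length does not match number of regions",
          class = "moranmod_validation_error")
  }
  if (any(y < 0) || anyNA(y)) {
    abort("counts must be nonnegative", class = "moranmod_validation_error")
  }
  unname(y)
}

off_diagonal <- function(W) {
  W0 <- unclass(W)
  diag(W0) <- 0
  W0
}

new_moran_stat <- function(statistic, value, components, W) {
  structure(list(statistic = statistic, value = value,
                 components = components,
                 n_regions = nrow(W), scheme = weight_scheme(W)),
            class = "moran_stat")
}

#' @export
print.moran_stat <- function(x, ...) {
  cat(sprintf("%s = %.6g  (%d regions, %s weights)\n",
              x$statistic, x$value, x$n_regions, x$scheme))
  invisible(x)
}

#' @rdname moran_i
#' @param x A `moran_stat` object.
#' @param ... Unused.
#' @method tidy moran_stat
#' @export
tidy.moran_stat <- function(x, ...) {
  tibble(statistic = x$statistic, value = x$value,
         n_regions = x$n_regions, scheme = x$scheme,
         !!!x$components)
}

#' @rdname moran_i
#' @method glance moran_stat
#' @export
glance.moran_stat <- function(x, ...) tidy(x)

# ---- batch kernels (shared by the scalar statistics and Monte Carlo) --------

moran_batch <- function(Y, W, modified = FALSE) {
  W0 <- off_diagonal(W)
  S0 <- sum(W0)
  if (S0 <= 0) abort("all weights are zero", class = "moranmod_degenerate_error")
  n <- nrow(Y)
  Z <- sweep(Y, 2, colMeans(Y))
  s_yy_w <- colSums(Z * (W0 %*% Z))
  if (modified) {
    wrow <- (rowSums(W0) + colSums(W0)) / 2
    s2 <- (n / S0) * colSums(Z^2 * wrow)
  } else {
    s2 <- colSums(Z^2)
  }
  list(value = (n / S0) * s_yy_w / s2, s_yy_w = s_yy_w, s2 = s2, S0 = S0)
}

ipop_batch <- function(Y, W, populations, wii_policy = c("keep", "zero")) {
  wii_policy <- match.arg(wii_policy)
  W0 <- off_diagonal(W)
  wd <- if (wii_policy == "keep") diag(unclass(W)) else rep(0, nrow(W))
  n <- as.numeric(populations)
  n_plus <- sum(n)
  y_plus <- colSums(Y)
  if (any(y_plus <= 0)) abort("total cases must be positive",
                              class = "moranmod_degenerate_error")
  b <- y_plus / n_plus
  A <- Y - outer(n, b)
  cross <- colSums(A * (W0 %*% A))
  het <- colSums(wd * A^2) -
    ((1 - b)^2 * colSums(wd * Y) + b^2 * (colSums(wd * (n - Y))))
  S0_star <- drop(n %*% W0 %*% n) + sum(wd * n * (n - 1))
  den <- b * (1 - b) * S0_star
  list(value = (cross + het) / den, cross = cross, het = het,
       S0_star = S0_star, b_hat = b)
}

# ---- user-facing statistics --------------------------------------------------

#' Moran's I for regional counts
#'
#' Spatially weighted cross-product of deviations of the regional counts from
#' their mean, normalized by the unweighted variance term:
#' `I = (N/S0) * sum_{i!=j} w_ij (y_i - ybar)(y_j - ybar) / sum_i (y_i - ybar)^2`.
#' The diagonal of the weight matrix is always masked. The value usually lies
#' in \[-1, 1\] but is not clamped; its range depends on the weight function.
#'
#' @param counts Data frame with columns `id`, `cases`, or a numeric vector in
#'   region order.
#' @param W A `weight_matrix` from [adjacency_weights()] or [pd_weights()].
#' @return A `moran_stat` object: the statistic value plus its components
#'   (`s_yy_w`, the variance term, `S0`). Use [tidy()] for a one-row tibble.
#' @examples
#' lat <- make_lattice(3, 3)
#' W <- adjacency_weights(lat$adjacency)
#' y <- data.frame(id = lat$geography$id, cases = c(5, 1, 4, 2, 6, 1, 3, 2, 4))
#' moran_i(y, W)
#' @export
moran_i <- function(counts, W) {
  y <- align_counts(counts, rownames(W))
  check_nonconstant(y)
  r <- moran_batch(cbind(y), W, modified = FALSE)
  new_moran_stat("I", unname(r$value),
                 list(ybar = mean(y), s_yy_w = unname(r$s_yy_w),
                      s_y2 = unname(r$s2), S0 = r$S0), W)
}

check_nonconstant <- function(y) {
  if (length(unique(y)) < 2) {
    abort("constant counts: Moran-type statistics are undefined (zero variance)",
          class = "moranmod_degenerate_error")
  }
}

#' Modified Moran's I (weights in the variance term)
#'
#' Same cross-product numerator as [moran_i()], but the variance term is also
#' weight-dependent:
#' `s2_yw = (N/S0) * sum_{i!=j} w_ij [(y_i - ybar)^2 + (y_j - ybar)^2] / 2`,
#' so pairs that contribute more to the cross-product also contribute more to
#' the variation. When all off-diagonal weights are equal and positive,
#' `s2_yw` equals the ordinary sum of squares and the statistic reduces to
#' classic Moran's I exactly. Its null distribution is not tractable; use
#' Monte Carlo inference ([run_test()]).
#'
#' @inheritParams moran_i
#' @return A `moran_stat` object; component `iw_le_i` flags whether the
#'   weighted variance term dominates the unweighted one (which implies
#'   `I_w <= I` for positive `I`).
#' @export
modified_moran_i <- function(counts, W) {
  y <- align_counts(counts, rownames(W))
  check_nonconstant(y)
  r <- moran_batch(cbind(y), W, modified = TRUE)
  if (r$s2 <= 0) {
    abort("all weighted deviations vanish: modified Moran's I is undefined",
          class = "moranmod_degenerate_error")
  }
  s_y2 <- sum((y - mean(y))^2)
  new_moran_stat("I_w", unname(r$value),
                 list(ybar = mean(y), s_yy_w = unname(r$s_yy_w),
                      s_y2 = s_y2, s_y2_w = unname(r$s2), S0 = r$S0,
                      iw_le_i = unname(r$s2 >= s_y2)), W)
}

#' Oden's I_pop
#'
#' Moran-type statistic on case and population proportions (`e_i = y_i/y_+`,
#' `v_i = n_i/n_+`) that adjusts for heterogeneous populations: it is Moran's I
#' applied to individual-level case indicators, aggregated by region. Weight
#' symmetry is not required and the diagonal `w_ii` may be nonzero; when kept
#' (the default for PD weights, whose diagonal is defined as 1) it contributes
#' a chi-square-like heterogeneity term analogous to the conventional
#' chi-squared test for heterogeneity of rates.
#'
#' @inheritParams moran_i
#' @param populations A [geography] or numeric vector of populations at risk
#'   `n_i` in region order.
#' @param wii_policy `"auto"` (keep the diagonal when the weight matrix
#'   defines one, i.e. PD; zero for Adj), `"keep"`, or `"zero"`.
#' @return A `moran_stat` object with components `b_hat`, the spatial
#'   cross-product term, and the heterogeneity term.
#' @export
oden_ipop <- function(counts, populations, W,
                      wii_policy = c("auto", "keep", "zero")) {
  wii_policy <- match.arg(wii_policy)
  if (inherits(populations, "geography") || is.data.frame(populations)) {
    populations <- populations$population
  }
  if (wii_policy == "auto") {
    wii_policy <- if (identical(attr(W, "diagonal_policy"), "defined"))
      "keep" else "zero"
  }
  y <- align_counts(counts, rownames(W))
  if (sum(y) <= 0) abort("total cases must be positive",
                         class = "moranmod_degenerate_error")
  r <- ipop_batch(cbind(y), W, populations, wii_policy = wii_policy)
  n_plus <- sum(populations)
  new_moran_stat("I_pop", unname(r$value),
                 list(b_hat = unname(r$b_hat),
                      spatial_term = unname(r$cross),
                      heterogeneity_term = unname(r$het),
                      S0_star = r$S0_star,
                      wii_policy = wii_policy), W)
}

# Dispatch used by the Monte Carlo machinery.
compute_statistic <- function(statistic, Y, W, populations = NULL,
                              wii_policy = "auto") {
  switch(statistic,
    I = moran_batch(Y, W, modified = FALSE)$value,
    I_w = moran_batch(Y, W, modified = TRUE)$value,
    I_pop = {
      if (is.null(populations)) {
        abort("I_pop needs populations", class = "moranmod_validation_error")
      }
      if (wii_policy == "auto") {
        wii_policy <- if (identical(attr(W, "diagonal_policy"), "defined"))
          "keep" else "zero"
      }
      ipop_batch(Y, W, populations, wii_policy = wii_policy)$value
    },
    abort(sprintf("unknown statistic '%s' (use I, I_w, or I_pop)", statistic),
          class = "moranmod_validation_error")
  )
}
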
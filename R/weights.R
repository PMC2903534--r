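# Spatial weight matrices: binary adjacency (Adj) weights and population
# density adjusted exponential (PD) weights w_ij = exp(-d_ij / k_i), where the
# bandwidth k_i is the distance from region i to its m_i-th nearest neighbor
# and m_i is the largest neighbor count whose cumulative population (self
# included) stays within lambda, a user-chosen fraction of total population.

new_weight_matrix <- function(values, scheme, diagonal_policy, symmetric) {
  structure(values,
            scheme = scheme,
            diagonal_policy = diagonal_policy,
            symmetric = symmetric,
            class = c("weight_matrix", "matrix", "array"))
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %s scheme, %d x %d, S0 = %g%s\n",
              attr(x, "scheme"), nrow(x), ncol(x), s0(x),
              if (attr(x, "symmetric")) ", symmetric" else ""))
  invisible(x)
}

#' Sum of weights S0
#'
#' Off-diagonal weight sum; the diagonal is included only when the matrix's
#' diagonal policy is `"defined"` and `include_diagonal = TRUE`.
#'
#' @param W A weight matrix.
#' @param include_diagonal Count `w_ii` (only meaningful for PD weights).
#' @return Scalar weight sum.
#' @export
s0 <- function(W, include_diagonal = FALSE) {
  tot <- sum(W)
  if (include_diagonal && identical(attr(W, "diagonal_policy"), "defined")) tot
  else tot - sum(diag(W))
}

#' Weight scheme tag
#' @param W A weight matrix.
#' @return `"Adj"` or `"PD"`.
#' @export
weight_scheme <- function(W) attr(W, "scheme") %||% "custom"

#' Binary adjacency (Adj) weights
#'
#' `w_ij = 1` if regions i and j are adjacent, 0 otherwise; zero diagonal.
#' Island regions (no neighbors) give an all-zero row and column.
#'
#' @param adj An `adjacency` object.
#' @return A symmetric 0/1 `weight_matrix` with `S0` equal to twice the number
#'   of undirected adjacent pairs.
#' @examples
#' lat <- make_lattice(2, 2)
#' s0(adjacency_weights(lat$adjacency))  # 4 edges -> 8
#' @export
adjacency_weights <- function(adj) {
  ids <- adj$id
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, match(adj$neighbors[[i]], ids)] <- 1
  }
  new_weight_matrix(m, scheme = "Adj", diagonal_policy = "zero",
                    symmetric = TRUE)
}

#' PD weight parameters
#'
#' @param lambda_fraction Fraction of total population defining the population
#'   threshold `lambda = lambda_fraction * n_plus`; default 0.5 (50% of the
#'   total population), which includes a large share of the map in each
#'   region's neighborhood.
#' @param includes_self Whether the cumulative population u_j(i) counts region
#'   i's own population (default TRUE: the neighborhood is the larger region
#'   comprised of unit i and its j nearest neighbors).
#' @param exponent_scale Constant multiplying `d_ij / k_i` in the exponent
#'   (default 1).
#' @return A `pd_parameters` list.
#' @export
pd_parameters <- function(lambda_fraction = 0.5, includes_self = TRUE,
                          exponent_scale = 1) {
  if (lambda_fraction <= 0 || lambda_fraction > 1) {
    abort("lambda_fraction must be in (0, 1]",
          class = "moranmod_validation_error")
  }
  structure(list(lambda_fraction = lambda_fraction,
                 includes_self = includes_self,
                 exponent_scale = exponent_scale),
            class = "pd_parameters")
}

#' Cumulative population over nearest neighbors
#'
#' `u_j(i)`: total population of the region comprised of unit i (when
#' `includes_self`) and its j nearest neighbors, for j = 0, ..., length(order).
#'
#' @param geo A [geography].
#' @param order Neighbor ordering for region `i`, from [neighbor_order()].
#' @param i Region index.
#' @param includes_self Count region i's own population (default TRUE).
#' @return Numeric vector of length `length(order) + 1`; element `j + 1` is
#'   `u_j(i)`. Nondecreasing.
#' @export
cumulative_population <- function(geo, order, i, includes_self = TRUE) {
  base <- if (includes_self) geo$population[i] else 0
  c(base, base + cumsum(geo$population[order]))
}

#' PD bandwidth: neighbor count m_i and distance k_i
#'
#' `m_i = max{ j : u_j(i) <= lambda }`, capped at `N - 1`; `k_i` is the
#' distance from i to its m_i-th nearest neighbor. `k_i` is larger where the
#' population is sparse, so greater distances are incorporated in the weight.
#' When even the single nearest neighbor exceeds lambda, `m_i` is floored at 1
#' with a warning (a zero bandwidth would degenerate the weight).
#'
#' @param geo A [geography].
#' @param distances Matrix from [pairwise_distances()].
#' @param i Region index.
#' @param params A [pd_parameters()] list.
#' @return List with integer `m_i` and positive `k_i`.
#' @export
pd_bandwidth <- function(geo, distances, i, params = pd_parameters()) {
  lambda <- params$lambda_fraction * total_population(geo)
  ord <- neighbor_order(distances, i)
  u <- cumulative_population(geo, ord, i, includes_self = params$includes_self)
  # u[j + 1] = u_j(i); admissible neighbor counts j >= 1
  ok <- which(u[-1] <= lambda)
  if (length(ok) == 0) {
    warn(sprintf("region %s: lambda below u_1(i); bandwidth floored at 1 neighbor",
                 geo$id[i]))
    m_i <- 1L
  } else {
    m_i <- max(ok)
  }
  m_i <- min(m_i, nrow(geo) - 1L)
  k_i <- distances[i, ord[m_i]]
  if (k_i <= 0) {
    # co-located nearest neighbors: fall back to the nearest strictly positive
    # distance so exp(-d/k) stays defined
    pos <- distances[i, ord][distances[i, ord] > 0]
    if (length(pos) == 0) abort("all centroids coincide; PD bandwidth undefined",
                                class = "moranmod_validation_error")
    k_i <- min(pos)
  }
  list(m_i = as.integer(m_i), k_i = unname(k_i))
}

#' Population-density-adjusted exponential (PD) weights
#'
#' `w_ij = exp(-scale * d_ij / k_i)` with the row-specific bandwidth `k_i` from
#' [pd_bandwidth()]. Generally asymmetric (`k_i != k_j`); the asymmetry is
#' meaningful and is not corrected unless `symmetrize = TRUE` (average of
#' `w_ij` and `w_ji`). The diagonal is stored as 1 (`exp(0)`) under diagonal
#' policy `"defined"`; Moran-type statistics mask it, Oden's I_pop may keep it.
#'
#' @param geo A [geography].
#' @param distances Matrix from [pairwise_distances()].
#' @param params A [pd_parameters()] list.
#' @param symmetrize Average with the transpose (default FALSE).
#' @return A `weight_matrix` with values in (0, 1], scheme `"PD"`, and
#'   attributes `m` and `k` holding the per-region bandwidths.
#' @export
pd_weights <- function(geo, distances, params = pd_parameters(),
                       symmetrize = FALSE) {
  n <- nrow(geo)
  bw <- lapply(seq_len(n), function(i) pd_bandwidth(geo, distances, i, params))
  k <- vapply(bw, `[[`, numeric(1), "k_i")
  m <- vapply(bw, `[[`, integer(1), "m_i")
  vals <- exp(-params$exponent_scale * unclass(distances) / k)
  if (symmetrize) vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(geo$id, geo$id)
  out <- new_weight_matrix(vals, scheme = "PD", diagonal_policy = "defined",
                           symmetric = symmetrize)
  attr(out, "m") <- m
  attr(out, "k") <- k
  attr(out, "lambda_fraction") <- params$lambda_fraction
  out
}

#' Write a weight matrix as dense CSV or sparse triples
#'
#' `format = "csv"` writes a dense matrix with region ids as header and first
#' column; `format = "gwt"` writes one `i j w_ij` triple per positive
#' off-diagonal weight.
#'
#' @param W A `weight_matrix`.
#' @param path Output path.
#' @param format `"csv"` or `"gwt"`.
#' @return `path`, invisibly.
#' @export
write_weights <- function(W, path, format = c("csv", "gwt")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- as.data.frame(unclass(W))
    df <- cbind(id = rownames(W), df)
    readr::write_csv(tibble::as_tibble(df), path)
  } else {
    idx <- which(unclass(W) != 0 & row(W) != col(W), arr.ind = TRUE)
    df <- tibble(i = rownames(W)[idx[, 1]], j = colnames(W)[idx[, 2]],
                 w = W[idx])
    readr::write_delim(df, path, delim = " ", col_names = FALSE)
  }
  invisible(path)
}

#' Read a dense weight-matrix CSV written by [write_weights()]
#'
#' @param path Path to the CSV.
#' @param scheme Scheme tag to attach.
#' @return A `weight_matrix`.
#' @export
read_weights <- function(path, scheme = "custom") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  new_weight_matrix(m, scheme = scheme,
                    diagonal_policy = if (all(diag(m) == 0)) "zero" else "defined",
                    symmetric = isTRUE(all.equal(m, t(m))))
}
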
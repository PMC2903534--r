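# Regional geographies: tibble-first containers for region ids, centroids and
# populations at risk, plus distances, neighbor orderings and GAL adjacency.

#' Build a geography from a data frame of regions
#'
#' A geography is a tibble with one row per geographic unit (census tract,
#' county, lattice cell) carrying a unique `id`, centroid coordinates and the
#' population at risk `population` (\eqn{n_i}). Row order is meaningful: it
#' defines the region ordering used for deterministic tie-breaking everywhere
#' downstream.
#'
#' @param data Data frame with columns `id`, `population`, and either
#'   `lon`/`lat` (degrees) or `x`/`y` (planar units).
#' @param coordinate_system `"lonlat"` or `"planar"`. Guessed from the column
#'   names when `NULL`.
#' @return A `geography` tibble with columns `id` (character), `x`, `y`,
#'   `population`, and a `coordinate_system` attribute.
#' @examples
#' geo <- geography(data.frame(id = c("A", "B"), x = c(0, 1), y = c(0, 0),
#'                             population = c(5000, 5000)))
#' total_population(geo)
#' @export
geography <- function(data, coordinate_system = NULL) {
  data <- as_tibble(data)
  has_lonlat <- all(c("lon", "lat") %in% names(data))
  has_planar <- all(c("x", "y") %in% names(data))
  if (is.null(coordinate_system)) {
    coordinate_system <- if (has_lonlat) "lonlat" else "planar"
  }
  coordinate_system <- match.arg(coordinate_system, c("lonlat", "planar"))
  if (!has_lonlat && !has_planar) {
    abort("geography needs columns `lon`/`lat` or `x`/`y`",
          class = "moranmod_validation_error")
  }
  if (!all(c("id", "population") %in% names(data))) {
    missing <- setdiff(c("id", "population"), names(data))
    abort(paste0("geography is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "moranmod_validation_error")
  }
  xy <- if (has_lonlat) c("lon", "lat") else c("x", "y")
  out <- tibble(
    id = as.character(data$id),
    x = as.numeric(data[[xy[1]]]),
    y = as.numeric(data[[xy[2]]]),
    population = as.numeric(data$population)
  )
  validate_geography(out, coordinate_system)
  attr(out, "coordinate_system") <- coordinate_system
  class(out) <- c("geography", class(out))
  out
}

validate_geography <- function(geo, coordinate_system) {
  if (nrow(geo) < 2) {
    abort("a geography needs at least 2 regions",
          class = "moranmod_validation_error")
  }
  dup <- geo$id[duplicated(geo$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate region id(s): ", paste(unique(dup), collapse = ", ")),
          class = "moranmod_validation_error")
  }
  bad <- which(is.na(geo$population) | geo$population < 0)
  if (length(bad) > 0) {
    abort(paste0("negative or missing population in row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "moranmod_validation_error")
  }
  if (sum(geo$population) <= 0) {
    abort("at least one region must have population > 0",
          class = "moranmod_validation_error")
  }
  if (coordinate_system == "lonlat") {
    out_of_range <- which(abs(geo$x) > 180 | abs(geo$y) > 90)
    if (length(out_of_range) > 0) {
      abort(paste0("lon/lat out of range in row(s): ",
                   paste(head(out_of_range, 5), collapse = ", ")),
            class = "moranmod_validation_error")
    }
  }
  if (anyNA(geo$x) || anyNA(geo$y)) {
    abort("missing coordinates", class = "moranmod_validation_error")
  }
  invisible(geo)
}

#' @export
print.geography <- function(x, ...) {
  cat(sprintf("<geography> %d regions (%s), total population %s\n",
              nrow(x), coordinate_system(x),
              format(total_population(x), big.mark = ",")))
  NextMethod()
}

#' @rdname geography
#' @param geo A geography.
#' @export
total_population <- function(geo) sum(geo$population)

#' @rdname geography
#' @export
coordinate_system <- function(geo) attr(geo, "coordinate_system") %||% "planar"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a geography from a CSV file
#'
#' Expects header `id,lon,lat,population` or `id,x,y,population`; row order in
#' the file defines the region ordering.
#'
#' @param path Path to the CSV file.
#' @param coordinate_system `"lonlat"`, `"planar"`, or `NULL` to infer from
#'   the header.
#' @return A [geography] tibble.
#' @export
load_geography <- function(path, coordinate_system = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  geography(data, coordinate_system = coordinate_system)
}

#' Write a geography to CSV
#'
#' @param geo A [geography].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geography <- function(geo, path) {
  out <- as_tibble(geo)
  if (coordinate_system(geo) == "lonlat") {
    names(out)[names(out) == "x"] <- "lon"
    names(out)[names(out) == "y"] <- "lat"
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Regular lattice geography with rook adjacency
#'
#' Builds a planar `rows x cols` grid of equally populated cells at unit
#' centroid `spacing`, the desk-scale stand-in for a homogeneously populated
#' county map, together with its rook (edge-sharing) adjacency.
#'
#' @param rows,cols Grid dimensions; `rows * cols >= 2`.
#' @param population_per_cell Population at risk in every cell.
#' @param spacing Distance between adjacent centroids.
#' @return A list with elements `geography` and `adjacency`.
#' @examples
#' lat <- make_lattice(2, 2, population_per_cell = 5000)
#' total_population(lat$geography)
#' @export
make_lattice <- function(rows, cols, population_per_cell = 5000, spacing = 1) {
  if (rows < 1 || cols < 1 || rows * cols < 2) {
    abort("lattice needs rows*cols >= 2 with positive dimensions",
          class = "moranmod_validation_error")
  }
  if (spacing <= 0) abort("spacing must be positive",
                          class = "moranmod_validation_error")
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  ids <- sprintf("r%dc%d", grid$row, grid$col)
  geo <- geography(tibble(
    id = ids,
    x = (grid$col - 1) * spacing,
    y = (grid$row - 1) * spacing,
    population = population_per_cell
  ), coordinate_system = "planar")

  idx <- function(r, c) (r - 1) * cols + c
  edges <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      nb <- character(0)
      if (r > 1) nb <- c(nb, ids[idx(r - 1, c)])
      if (r < rows) nb <- c(nb, ids[idx(r + 1, c)])
      if (c > 1) nb <- c(nb, ids[idx(r, c - 1)])
      if (c < cols) nb <- c(nb, ids[idx(r, c + 1)])
      edges[[idx(r, c)]] <- nb[order(match(nb, ids))]
    }
  }
  adj <- new_adjacency(ids, edges)
  list(geography = geo, adjacency = adj)
}

# ---- adjacency ---------------------------------------------------------------

new_adjacency <- function(ids, neighbors) {
  stopifnot(length(ids) == length(neighbors))
  out <- tibble(id = as.character(ids), neighbors = neighbors)
  class(out) <- c("adjacency", class(out))
  out
}

#' @export
print.adjacency <- function(x, ...) {
  nedge <- sum(lengths(x$neighbors)) / 2
  cat(sprintf("<adjacency> %d regions, %g undirected edges\n", nrow(x), nedge))
  invisible(x)
}

#' Neighbor lists for a set of regions
#'
#' @param x An `adjacency` object.
#' @return A tibble with one row per undirected edge (`id_i`, `id_j`).
#' @method tidy adjacency
#' @export
tidy.adjacency <- function(x, ...) {
  long <- tidyr::unnest(tibble(id_i = x$id, id_j = x$neighbors),
                        cols = "id_j")
  dplyr::filter(long, .data$id_i < .data$id_j)
}

#' Read adjacency from a GAL spatial-weights file
#'
#' GAL is the plain-text neighbor-list exchange format: a header line with the
#' number of regions (variants with leading `0` and dataset names are
#' tolerated), then per region one line `id  n_neighbors` followed by a line of
#' neighbor ids. Asymmetric input is symmetrized by union with a warning;
#' self-loops are stripped with a warning.
#'
#' @param path Path to the GAL file.
#' @param geo A [geography]; every id in the file must exist in it.
#' @return An `adjacency` object aligned to the geography's region order.
#' @export
load_adjacency <- function(path, geo) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], "\\s+")[[1]]
  # header forms: "N" or "0 N name name"
  n_declared <- if (length(header) == 1) as.integer(header[1]) else as.integer(header[2])
  nb <- list()
  i <- 2
  while (i <= length(lines)) {
    rec <- strsplit(lines[i], "\\s+")[[1]]
    id <- rec[1]
    k <- as.integer(rec[2])
    if (k > 0) {
      nbr <- strsplit(lines[i + 1], "\\s+")[[1]]
      if (length(nbr) != k) {
        abort(sprintf("GAL record for '%s' declares %d neighbors but lists %d",
                      id, k, length(nbr)), class = "moranmod_format_error")
      }
      i <- i + 2
    } else {
      nbr <- character(0)
      # tolerate an empty neighbor line
      if (i + 1 <= length(lines)) {
        peek <- strsplit(lines[i + 1], "\\s+")[[1]]
        if (length(peek) == 0) i <- i + 1
      }
      i <- i + 1
    }
    nb[[id]] <- nbr
  }
  if (!is.na(n_declared) && length(nb) != n_declared) {
    warn(sprintf("GAL header declares %d regions, file has %d records",
                 n_declared, length(nb)))
  }
  unknown <- setdiff(c(names(nb), unlist(nb)), geo$id)
  if (length(unknown) > 0) {
    abort(paste0("GAL file names unknown region id(s): ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "moranmod_validation_error")
  }
  full <- stats::setNames(rep(list(character(0)), nrow(geo)), geo$id)
  full[names(nb)] <- nb
  adjacency_from_lists(geo$id, full)
}

# Symmetrize by union, strip self-loops, warn on both.
adjacency_from_lists <- function(ids, nb) {
  nb <- unname(lapply(nb, unique))
  selfs <- vapply(seq_along(ids), function(i) ids[i] %in% nb[[i]], logical(1))
  if (any(selfs)) {
    warn(paste0("self-loop(s) stripped for: ",
                paste(head(ids[selfs], 5), collapse = ", ")))
    nb <- lapply(seq_along(ids), function(i) setdiff(nb[[i]], ids[i]))
  }
  asym <- FALSE
  for (i in seq_along(ids)) {
    for (j in nb[[i]]) {
      jj <- match(j, ids)
      if (!(ids[i] %in% nb[[jj]])) {
        asym <- TRUE
        nb[[jj]] <- c(nb[[jj]], ids[i])
      }
    }
  }
  if (asym) warn("asymmetric adjacency symmetrized by union")
  nb <- lapply(nb, function(v) v[order(match(v, ids))])
  new_adjacency(ids, nb)
}

#' Write adjacency to a GAL file
#'
#' @param adj An `adjacency` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(adj)), con)
  for (i in seq_len(nrow(adj))) {
    nbr <- adj$neighbors[[i]]
    writeLines(paste(adj$id[i], length(nbr)), con)
    if (length(nbr) > 0) writeLines(paste(nbr, collapse = " "), con)
  }
  invisible(path)
}

# ---- distances and neighbor order --------------------------------------------

#' Pairwise inter-centroid distances
#'
#' Great-circle (haversine, spherical Earth radius 6371 km, so kilometres) for
#' lon/lat geographies; Euclidean in coordinate units for planar ones.
#'
#' @param geo A [geography].
#' @return A symmetric `N x N` matrix with zero diagonal, dimnames = region
#'   ids, and a `metric` attribute (`"great-circle"` or `"euclidean"`).
#' @export
pairwise_distances <- function(geo) {
  if (coordinate_system(geo) == "lonlat") {
    m <- geosphere::distm(cbind(geo$x, geo$y),
                          fun = function(p1, p2) {
                            geosphere::distHaversine(p1, p2, r = 6371)
                          })
    metric <- "great-circle"
  } else {
    m <- as.matrix(dist(cbind(geo$x, geo$y)))
    metric <- "euclidean"
  }
  dimnames(m) <- list(geo$id, geo$id)
  attr(m, "metric") <- metric
  m
}

#' Nearest-neighbor ordering for one region
#'
#' Other regions sorted by ascending distance from region `i`; ties broken by
#' ascending position in the geography's row order, so the ordering is
#' deterministic and reproducible.
#'
#' @param distances Distance matrix from [pairwise_distances()].
#' @param i Region index (row number) or region id.
#' @return Integer vector of the other `N - 1` region indices.
#' @export
neighbor_order <- function(distances, i) {
  if (is.character(i)) i <- match(i, rownames(distances))
  n <- nrow(distances)
  others <- setdiff(seq_len(n), i)
  others[order(distances[i, others], others)]
}
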
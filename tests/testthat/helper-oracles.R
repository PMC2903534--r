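# Independent naive double-loop transcriptions of the three statistics,
# written against the formulas directly. These are the oracles; they share no
# code with the vectorized implementations in the package.

oracle_moran_i <- function(y, W) {
  n <- length(y)
  ybar <- mean(y)
  S0 <- 0
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        S0 <- S0 + W[i, j]
        num <- num + W[i, j] * (y[i] - ybar) * (y[j] - ybar)
      }
    }
  }
  den <- sum((y - ybar)^2)
  (n / S0) * num / den
}

oracle_modified_moran_i <- function(y, W) {
  n <- length(y)
  ybar <- mean(y)
  S0 <- 0
  num <- 0
  s2w <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        S0 <- S0 + W[i, j]
        num <- num + W[i, j] * (y[i] - ybar) * (y[j] - ybar)
        s2w <- s2w + W[i, j] * ((y[i] - ybar)^2 + (y[j] - ybar)^2) / 2
      }
    }
  }
  (n / S0) * num / ((n / S0) * s2w)
}

# Moran's I on individual-level case indicators, aggregated by region:
# cross-product of A_i = y_i - b n_i over distinct-region pairs, plus (when
# the diagonal is kept) the within-region term, over b(1-b) times the
# individual-level weight sum.
oracle_oden_ipop <- function(y, n, W, keep_diagonal = FALSE) {
  N <- length(y)
  b <- sum(y) / sum(n)
  A <- y - b * n
  num <- 0
  S0s <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j) {
        num <- num + W[i, j] * A[i] * A[j]
        S0s <- S0s + W[i, j] * n[i] * n[j]
      } else if (keep_diagonal) {
        num <- num + W[i, i] * (A[i]^2 - y[i] * (1 - b)^2 - (n[i] - y[i]) * b^2)
        S0s <- S0s + W[i, i] * n[i] * (n[i] - 1)
      }
    }
  }
  num / (b * (1 - b) * S0s)
}

# Random test instances ---------------------------------------------------

random_counts <- function(n, max_cases = 20) {
  y <- rpois(n, lambda = runif(1, 1, max_cases))
  if (length(unique(y)) < 2) y[1] <- y[1] + 1  # avoid degenerate draws
  y
}

random_weight_matrix <- function(n, defined_diagonal = FALSE) {
  m <- matrix(runif(n * n), n, n)
  diag(m) <- if (defined_diagonal) 1 else 0
  dimnames(m) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  m
}

# Ring adjacency written as a GAL file and read back through the package's
# loader, so tests exercise the format path.
ring_geography <- function(n, population = 5000) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  geography(data.frame(id = paste0("g", seq_len(n)),
                       x = cos(theta), y = sin(theta),
                       population = population))
}

ring_adjacency <- function(geo) {
  n <- nrow(geo)
  ids <- geo$id
  path <- withr::local_tempfile(fileext = ".gal",
                                .local_envir = parent.frame())
  lines <- as.character(n)
  for (i in seq_len(n)) {
    nb <- ids[c(((i - 2) %% n) + 1, (i %% n) + 1)]
    lines <- c(lines, paste(ids[i], 2), paste(nb, collapse = " "))
  }
  writeLines(lines, path)
  load_adjacency(path, geo)
}
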
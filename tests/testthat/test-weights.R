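test_that("adjacency weights are binary, symmetric, zero-diagonal with S0 = 2 * edges", {
  lat <- make_lattice(2, 2)
  W <- adjacency_weights(lat$adjacency)
  expect_equal(s0(W), 8)  # 4 undirected edges
  expect_true(all(W %in% c(0, 1)))
  expect_equal(unname(diag(W)), rep(0, 4))

  path <- make_lattice(1, 3)
  Wp <- adjacency_weights(path$adjacency)
  expect_equal(s0(Wp), 4)
  expect_equal(Wp[1, 3], 0, ignore_attr = TRUE)

  withr::with_seed(5, {
    for (rep in 1:10) {
      lat <- make_lattice(sample(2:6, 1), sample(2:6, 1))
      W <- adjacency_weights(lat$adjacency)
      expect_equal(unclass(W), t(unclass(W)), ignore_attr = TRUE)
      expect_true(all(W %in% c(0, 1)))
      expect_equal(sum(diag(W)), 0)
    }
  })
})

test_that("island regions contribute all-zero rows and columns under Adj weights", {
  geo <- geography(data.frame(id = c("A", "B", "C"), x = 0:2, y = 0,
                              population = 100))
  path <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("3", "A 1", "B", "B 1", "A", "C 0"), path)
  W <- adjacency_weights(load_adjacency(path, geo))
  expect_equal(unname(W["C", ]), rep(0, 3))
  expect_equal(unname(W[, "C"]), rep(0, 3))
  expect_equal(s0(W), 2)
})

test_that("cumulative population u_j(i) matches brute-force prefix sums", {
  lat <- make_lattice(1, 4, population_per_cell = 5000)
  d <- pairwise_distances(lat$geography)
  ord <- neighbor_order(d, 1)
  u <- cumulative_population(lat$geography, ord, 1)
  expect_equal(u, 5000 * (1:4))        # homogeneous: u_j = 5000 (j + 1)
  expect_equal(u[1], 5000)             # j = 0 -> own population
  expect_true(all(diff(u) >= 0))

  # mixed populations on a path: prefix sums over the distance ordering
  geo <- geography(data.frame(id = letters[1:4], x = 0:3, y = 0,
                              population = c(10, 40, 20, 30)))
  d2 <- pairwise_distances(geo)
  ord2 <- neighbor_order(d2, 2)
  expect_equal(cumulative_population(geo, ord2, 2),
               c(40, 40 + 10, 40 + 10 + 20, 40 + 10 + 20 + 30))
  expect_equal(cumulative_population(geo, ord2, 2, includes_self = FALSE),
               c(0, 10, 30, 60))
})

test_that("PD bandwidth takes the most neighbors within lambda", {
  # homogeneous 30x30 lattice, lambda = 50% of total population:
  # u_j = 5000 (j + 1) <= 2,250,000  <=>  j <= 449
  lat <- make_lattice(30, 30, population_per_cell = 5000)
  d <- pairwise_distances(lat$geography)
  for (i in c(1, 240, 450, 900)) {
    bw <- pd_bandwidth(lat$geography, d, i)
    # independent enumeration of max{j : u_j <= lambda}
    ord <- neighbor_order(d, i)
    u <- 5000 + cumsum(lat$geography$population[ord])
    expect_equal(bw$m_i, max(which(u <= 0.5 * 4500000)))
    expect_equal(bw$m_i, 449L)
    expect_equal(bw$k_i, d[i, ord[449]], ignore_attr = TRUE)
  }

  # lambda = total population -> m_i = N - 1 (whole map)
  lat2 <- make_lattice(3, 3)
  d2 <- pairwise_distances(lat2$geography)
  bw2 <- pd_bandwidth(lat2$geography, d2, 5, pd_parameters(lambda_fraction = 1))
  expect_equal(bw2$m_i, 8L)

  # lambda below u_1(i): floored at one neighbor with a warning
  expect_warning(
    bw3 <- pd_bandwidth(lat2$geography, d2, 5,
                        pd_parameters(lambda_fraction = 0.2)),
    "floored")
  expect_equal(bw3$m_i, 1L)
  expect_gt(bw3$k_i, 0)
})

test_that("sparse regions get larger bandwidths than dense ones", {
  # same populations, the 'sparse' half has stretched coordinates
  df <- data.frame(id = paste0("g", 1:10),
                   x = c(0:4 * 0.5, 10 + 0:4 * 5), y = 0,
                   population = 100)
  geo <- geography(df)
  d <- pairwise_distances(geo)
  p <- pd_parameters(lambda_fraction = 0.3)
  dense <- pd_bandwidth(geo, d, 3, p)
  sparse <- pd_bandwidth(geo, d, 8, p)
  expect_equal(dense$m_i, sparse$m_i)
  expect_gt(sparse$k_i, dense$k_i)
})

test_that("PD weights match element-by-element brute force of exp(-d_ij/k_i)", {
  geo <- geography(data.frame(id = letters[1:4], x = c(0, 1, 3, 7), y = 0,
                              population = c(10, 40, 20, 30)))
  d <- pairwise_distances(geo)
  params <- pd_parameters(lambda_fraction = 0.6)
  W <- pd_weights(geo, d, params)
  for (i in 1:4) {
    k_i <- pd_bandwidth(geo, d, i, params)$k_i
    for (j in 1:4) {
      expect_equal(W[i, j], exp(-d[i, j] / k_i), ignore_attr = TRUE)
    }
  }
  expect_equal(unname(diag(W)), rep(1, 4))      # exp(0)
  expect_true(all(W > 0 & W <= 1))
  expect_false(isTRUE(all.equal(unclass(W), t(unclass(W)))))  # asymmetric

  # d_ij = k_i -> exp(-1)
  i <- 1
  k1 <- pd_bandwidth(geo, d, 1, params)$k_i
  j <- which(abs(d[1, ] - k1) < 1e-12)[1]
  expect_equal(W[1, j], exp(-1), ignore_attr = TRUE)

  # exponent scale config
  W2 <- pd_weights(geo, d, pd_parameters(lambda_fraction = 0.6,
                                         exponent_scale = 4))
  expect_equal(unclass(W2), unclass(W)^4, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PD rows decay with distance and k_i grows with lambda", {
  withr::with_seed(21, {
    lat <- make_lattice(6, 6, population_per_cell = sample(1000:9000, 36,
                                                           replace = TRUE)[1])
    geo <- lat$geography
    d <- pairwise_distances(geo)
    W <- pd_weights(geo, d, pd_parameters(lambda_fraction = 0.4))
    for (i in sample(36, 6)) {
      ord <- neighbor_order(d, i)
      expect_true(all(diff(W[i, ord]) <= 1e-12))  # nonincreasing in d_ij
    }
    k_small <- attr(pd_weights(geo, d, pd_parameters(0.3)), "k")
    k_large <- attr(pd_weights(geo, d, pd_parameters(0.8)), "k")
    expect_true(all(k_large >= k_small - 1e-12))
  })
})

test_that("weight matrices round-trip through dense CSV and GWT triples", {
  lat <- make_lattice(3, 3)
  W <- adjacency_weights(lat$adjacency)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_weights(W, csv)
  back <- read_weights(csv, scheme = "Adj")
  expect_equal(unclass(back), unclass(W), ignore_attr = TRUE)

  gwt <- withr::local_tempfile(fileext = ".gwt")
  write_weights(W, gwt, format = "gwt")
  triples <- read.table(gwt, col.names = c("i", "j", "w"))
  expect_equal(nrow(triples), s0(W))
  expect_true(all(triples$w == 1))
})
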
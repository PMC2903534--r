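test_that("closed-form anchors: alternating ring gives I = I_w = -1", {
  geo <- ring_geography(4)
  W <- adjacency_weights(ring_adjacency(geo))
  y <- c(2, 0, 2, 0)
  # hand check: z = (1,-1,1,-1), s_yy_w = -8, S0 = 8, s_y2 = 4
  res <- moran_i(y, W)
  expect_equal(res$value, -1)
  expect_equal(res$components$s_yy_w, -8)
  expect_equal(res$components$S0, 8)
  expect_equal(res$components$s_y2, 4)
  resw <- modified_moran_i(y, W)
  expect_equal(resw$value, -1)
  expect_equal(resw$components$s_y2_w, 4)  # (4/8) * sum w (z_i^2+z_j^2)/2 = 4
})

test_that("closed-form anchor: complete graph gives I = -1/(N-1)", {
  withr::with_seed(31, {
    for (n in c(4, 5, 9)) {
      W <- matrix(1, n, n); diag(W) <- 0
      dimnames(W) <- list(paste0("g", 1:n), paste0("g", 1:n))
      y <- random_counts(n)
      expect_equal(moran_i(y, W)$value, -1 / (n - 1), tolerance = 1e-12)
    }
  })
})

test_that("homogeneous weights collapse the modified statistic onto classic I", {
  withr::with_seed(32, {
    for (rep in 1:100) {
      n <- sample(4:25, 1)
      const <- runif(1, 0.1, 5)
      W <- matrix(const, n, n); diag(W) <- 0
      y <- random_counts(n)
      i_cl <- moran_i(y, W)
      i_w <- modified_moran_i(y, W)
      expect_equal(i_w$value, i_cl$value, tolerance = 1e-10)
      # s2_yw reduces to the plain sum of squares
      expect_equal(i_w$components$s_y2_w, i_w$components$s_y2,
                   tolerance = 1e-10)
    }
  })
})

test_that("all three statistics match naive double-loop oracles on random instances", {
  withr::with_seed(33, {
    for (rep in 1:100) {
      n <- sample(3:30, 1)
      W <- random_weight_matrix(n, defined_diagonal = rep %% 2 == 0)
      y <- random_counts(n)
      pop <- sample(500:5000, n, replace = TRUE)
      expect_equal(moran_i(y, W)$value, oracle_moran_i(y, W),
                   tolerance = 1e-12)
      expect_equal(modified_moran_i(y, W)$value,
                   oracle_modified_moran_i(y, W), tolerance = 1e-12)
      expect_equal(oden_ipop(y, pop, W, wii_policy = "zero")$value,
                   oracle_oden_ipop(y, pop, W, keep_diagonal = FALSE),
                   tolerance = 1e-12)
      expect_equal(oden_ipop(y, pop, W, wii_policy = "keep")$value,
                   oracle_oden_ipop(y, pop, W, keep_diagonal = TRUE),
                   tolerance = 1e-12)
    }
  })
})

test_that("I_pop on a 3-region chain equals a hand term-by-term transcription", {
  geo <- geography(data.frame(id = c("A", "B", "C"), x = 0:2, y = 0,
                              population = 5000))
  path <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("3", "A 1", "B", "B 2", "A C", "C 1", "B"), path)
  W <- adjacency_weights(load_adjacency(path, geo))
  y <- c(3, 1, 2)
  # hand transcription: b = 6/15000, A = y - b n = (1, -1, 0)
  #   cross = 2 w_AB A_A A_B + 2 w_BC A_B A_C = -2
  #   S0* = 4 * 5000^2 = 1e8; denominator = b (1 - b) S0*
  b <- 6 / 15000
  expected <- -2 / (b * (1 - b) * 1e8)
  res <- oden_ipop(y, geo, W)
  expect_equal(res$value, expected, tolerance = 1e-12)
  expect_equal(res$components$b_hat, b)
  expect_equal(res$components$wii_policy, "zero")  # Adj diagonal masked
})

test_that("I_pop proportions are scale invariant and vanish for uniform rates", {
  geo <- ring_geography(6, population = 4000)
  W <- adjacency_weights(ring_adjacency(geo))
  y <- c(8, 2, 5, 7, 1, 4)
  a <- oden_ipop(y, geo, W)
  b <- oden_ipop(y * 10, geo$population * 10, W)
  expect_equal(a$value, b$value, tolerance = 1e-12)

  # identical rates across regions: e_i = v_i, so the spatial
  # cross-product term is exactly zero and the statistic sits at its
  # no-heterogeneity baseline (0 with a masked diagonal)
  yu <- rep(5, 6)
  res <- oden_ipop(yu, geo, W)
  expect_equal(res$components$spatial_term, 0)
  expect_equal(res$value, 0)
})

test_that("modified I carries the variance-dominance flag and |I_w| <= 1 on nonnegative weights", {
  withr::with_seed(34, {
    for (rep in 1:50) {
      n <- sample(4:20, 1)
      W <- random_weight_matrix(n)
      y <- random_counts(n)
      res <- modified_moran_i(y, W)
      expect_lte(abs(res$value), 1 + 1e-12)
      expect_identical(res$components$iw_le_i,
                       res$components$s_y2_w >= res$components$s_y2)
    }
  })
})

test_that("statistics are invariant to joint region reordering", {
  withr::with_seed(35, {
    for (rep in 1:20) {
      n <- sample(4:15, 1)
      W <- random_weight_matrix(n, defined_diagonal = TRUE)
      y <- random_counts(n)
      pop <- sample(500:5000, n, replace = TRUE)
      perm <- sample(n)
      Wp <- W[perm, perm]
      expect_equal(moran_i(y[perm], Wp)$value, moran_i(y, W)$value,
                   tolerance = 1e-12)
      expect_equal(modified_moran_i(y[perm], Wp)$value,
                   modified_moran_i(y, W)$value, tolerance = 1e-12)
      expect_equal(oden_ipop(y[perm], pop[perm], Wp)$value,
                   oden_ipop(y, pop, W)$value, tolerance = 1e-12)
    }
  })
})

test_that("permutation null of classic I centers on -1/(N-1)", {
  withr::with_seed(36, {
    lat <- make_lattice(5, 5)
    W <- adjacency_weights(lat$adjacency)
    y <- random_counts(25, max_cases = 50)
    vals <- replicate(3000, moran_i(sample(y), W)$value)
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - (-1 / 24)), 4 * se)
  })
})

test_that("degenerate inputs raise typed errors", {
  lat <- make_lattice(2, 2)
  W <- adjacency_weights(lat$adjacency)
  expect_error(moran_i(rep(3, 4), W), class = "moranmod_degenerate_error")
  expect_error(modified_moran_i(rep(0, 4), W),
               class = "moranmod_degenerate_error")
  expect_error(oden_ipop(rep(0, 4), rep(100, 4), W),
               class = "moranmod_degenerate_error")
  Wz <- matrix(0, 4, 4, dimnames = dimnames(W))
  expect_error(moran_i(c(1, 2, 3, 4), Wz), class = "moranmod_degenerate_error")
  expect_error(moran_i(c(1, 2, 3), W), class = "moranmod_validation_error")
})

test_that("tidy() and counts data frames work through the pipe", {
  lat <- make_lattice(3, 3)
  W <- adjacency_weights(lat$adjacency)
  counts <- data.frame(id = rev(lat$geography$id), cases = c(9:1))
  res <- counts |> moran_i(W) |> tidy()
  expect_s3_class(res, "tbl_df")
  expect_equal(res$statistic, "I")
  # id-matched: same as passing the vector in region order
  expect_equal(res$value, moran_i(1:9, W)$value)
})
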
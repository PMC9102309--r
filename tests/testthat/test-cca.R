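test_that("neighbor surrogate matches the printed definition", {
  expect_equal(neighbor_surrogate(matrix(1:4, nrow = 1)),
               matrix(c(4, 6), nrow = 1))
  expect_equal(neighbor_surrogate(matrix(rep(3, 10), nrow = 1)),
               matrix(rep(6, 8), nrow = 1))
  expect_equal(neighbor_surrogate(matrix(0, 2, 5)), matrix(0, 2, 3))
  expect_error(neighbor_surrogate(matrix(1:4, nrow = 2)), "at least 3")
})

test_that("cca_fit validates its preconditions", {
  expect_error(cca_fit(matrix(1:10, nrow = 1)), "two input channels")
  expect_error(cca_fit(matrix(stats::rnorm(8), nrow = 4)), "too few samples")
})

test_that("canonical correlations match the whitening+SVD oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    M <- sample(2:8, 1)
    T_ <- sample(500:2000, 1)
    X <- matrix(stats::rnorm(M * T_), M)
    X[1, ] <- as.numeric(stats::filter(stats::rnorm(T_), 0.9,
                                       method = "recursive"))
    dec <- cca_fit(X)
    expect_lt(max(abs(dec$rho - cca_oracle_rho(X))), 1e-6)
    expect_true(all(diff(dec$rho) <= 1e-12))          # descending
    expect_true(all(dec$rho >= -1e-8 & dec$rho <= 1 + 1e-8))
    expect_lt(rel_err(cca_remix(dec, integer(0)), X), 1e-6)
  }
})

test_that("near-duplicate autocorrelated channels give a leading rho near 1", {
  set.seed(31)
  base <- as.numeric(stats::filter(stats::rnorm(1500), 0.995, method = "recursive"))
  X <- rbind(base + 1e-3 * stats::rnorm(1500),
             base + 1e-3 * stats::rnorm(1500))
  dec <- cca_fit(X)
  expect_gt(dec$rho[1], 0.99)
  expect_lt(rel_err(cca_remix(dec, integer(0)), X), 1e-6)
})

test_that("remix is linear and refuses total removal", {
  set.seed(32)
  X <- matrix(stats::rnorm(4 * 800), 4)
  dec <- cca_fit(X)
  full <- cca_remix(dec, integer(0))
  for (k in 1:4) {
    part <- cca_remix(dec, k)
    backproj <- dec$W_inv[, k, drop = FALSE] %*% dec$sources[k, , drop = FALSE]
    expect_equal(full - part, backproj, tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(cca_remix(dec, 1:4), "every component")
  expect_error(cca_remix(dec, c(1, 1)), "distinct")
  expect_error(cca_remix(dec, 9), "distinct|1..4")
})

test_that("removing the leading source recovers a planted smooth artifact", {
  set.seed(33)
  T_ <- 4000
  artifact <- as.numeric(stats::filter(stats::rnorm(T_), 0.999,
                                       method = "recursive"))
  artifact <- artifact - mean(artifact)  # means are restored by remix anyway
  artifact <- 5 * artifact / stats::sd(artifact)
  load <- c(1, 0.8, 0.6, 0.4)
  X <- matrix(stats::rnorm(4 * T_), 4) + outer(load, artifact)
  dec <- cca_fit(X)
  cleaned <- cca_remix(dec, 1L)
  planted_energy <- sum(outer(load, artifact)^2)
  resid <- cleaned - (X - outer(load, artifact))
  expect_lt(sum(resid^2), 0.2 * planted_energy)  # > 80% artifact energy gone
})

test_that("collapse matches the sub-band row-sum and is linear", {
  set.seed(34)
  x <- stats::rnorm(1200)
  sb <- wp_subbands(x, "db2", 3)
  dec <- cca_fit(t(sb$components))
  expect_lt(rel_err(cca_collapse(cca_remix(dec, integer(0))), x), 1e-6)
  expect_equal(cca_collapse(matrix(0, 3, 10)), rep(0, 10))
  # collapse after removing one source = original minus that source's
  # collapsed back-projection
  k <- 2L
  lhs <- cca_collapse(cca_remix(dec, k))
  rhs <- cca_collapse(cca_remix(dec, integer(0))) -
    colSums(dec$W_inv)[k] * dec$sources[k, ]
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("the delay surrogate ranks smooth sources first", {
  set.seed(35)
  T_ <- 3000
  smooth <- as.numeric(stats::filter(stats::rnorm(T_), 0.995, method = "recursive"))
  X <- rbind(smooth / stats::sd(smooth) * 3 + stats::rnorm(T_, sd = 0.05),
             stats::rnorm(T_),
             stats::rnorm(T_))
  dec <- cca_fit(X, surrogate = "delay")
  # leading source carries the smooth channel
  expect_gt(abs(stats::cor(dec$sources[1, ], smooth)), 0.9)
  expect_lt(rel_err(cca_remix(dec, integer(0)), X), 1e-6)
})
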
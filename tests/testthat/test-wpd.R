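test_that("filter banks satisfy the orthonormal QMF identities", {
  taps <- c(db1 = 2, db2 = 4, db3 = 6, sym4 = 8, sym5 = 10, sym6 = 12,
            coif1 = 6, coif2 = 12, coif3 = 18, fk4 = 4, fk6 = 6, fk8 = 8)
  for (nm in wp_wavelets()) {
    fb <- wp_filter_bank(nm)
    L <- length(fb$h)
    expect_identical(L, as.integer(taps[[nm]]))
    expect_lt(abs(sum(fb$h) - sqrt(2)), 1e-10)
    expect_lt(abs(sum(fb$h^2) - 1), 1e-10)
    expect_lt(abs(sum(fb$g)), 1e-10)
    k <- seq_len(L) - 1L
    expect_lt(max(abs(fb$g - (-1)^k * fb$h[L - k])), 1e-10)
  }
  expect_equal(wp_filter_bank("db1")$h, c(1, 1) / sqrt(2))
  expect_error(wp_filter_bank("db9"), "valid names")
})

test_that("Haar analysis of a constant block matches the hand computation", {
  tr <- wp_decompose(c(1, 1, 1, 1), "db1", 1)
  expect_equal(tr$nodes[[1]], c(sqrt(2), sqrt(2)))
  expect_equal(tr$nodes[[2]], c(0, 0))
})

test_that("vanishing moments put a constant signal entirely in the approximation", {
  for (nm in c("db2", "sym5", "coif2")) {
    tr <- wp_decompose(rep(2.5, 64), nm, 2)
    for (i in 2:4) expect_lt(max(abs(tr$nodes[[i]])), 1e-10)
  }
})

test_that("decompose/reconstruct is the identity for every bank and level", {
  set.seed(11)
  for (nm in wp_wavelets()) {
    for (j in 1:5) {
      for (n in c(2^j * 5, 2^j * 5 + 3)) {  # multiple and non-multiple lengths
        x <- stats::rnorm(n)
        tr <- wp_decompose(x, nm, j)
        expect_length(tr$nodes, 2L^j)
        expect_lt(rel_err(wp_reconstruct(tr), x), 1e-8)
      }
    }
  }
})

test_that("coefficient energy is conserved (Parseval) without padding", {
  set.seed(12)
  x <- stats::rnorm(1024)
  for (nm in c("db2", "sym6", "coif3", "fk8")) {
    tr <- wp_decompose(x, nm, 4)
    e <- sum(vapply(tr$nodes, function(n) sum(n^2), numeric(1)))
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("bank/tree mismatch and short signals are rejected", {
  x <- stats::rnorm(64)
  tr <- wp_decompose(x, "db2", 3)
  expect_error(wp_reconstruct(tr, "db3"), "does not match")
  expect_error(wp_decompose(stats::rnorm(7), "db1", 3), "shorter")
  tr0 <- wp_decompose(x, "db2", 3)
  for (i in seq_along(tr0$nodes)) tr0$nodes[[i]][] <- 0
  expect_equal(wp_reconstruct(tr0), rep(0, 64))
})

test_that("sub-band counts follow 2^j", {
  expect_identical(num_subbands(4), 16L)
  expect_identical(num_subbands(5), 32L)
  expect_identical(num_subbands(1), 2L)
  expect_error(num_subbands(0), "positive integer")
  set.seed(13)
  x <- stats::rnorm(512)
  expect_identical(ncol(wp_subbands(x, "db1", 4)$components), 16L)
  expect_identical(ncol(wp_subbands(x, "db1", 5)$components), 32L)
})

test_that("sub-band columns sum to the signal and are frequency ordered", {
  set.seed(14)
  x <- stats::rnorm(777)  # non-multiple length exercises the padding
  for (nm in c("db1", "db3", "fk6")) {
    sb <- wp_subbands(x, nm, 4)
    expect_lt(rel_err(rowSums(sb$components), x), 1e-8)
  }
  # approximation column has the lowest spectral centroid on broadband input
  sb <- wp_subbands(stats::rnorm(2048), "sym6", 3)
  centroid <- apply(sb$components, 2L, function(col) {
    p <- Mod(stats::fft(col))^2
    n <- length(p)
    f <- pmin((seq_len(n) - 1L), n - (seq_len(n) - 1L))
    sum(f * p) / sum(p)
  })
  expect_identical(unname(which.min(centroid)), 1L)
  expect_identical(sb$approx_index, 1L)
  expect_identical(colnames(sb$components)[1], "S7")
})

test_that("a pure tone lands in its nominal frequency-ordered column", {
  fs <- 256
  t <- (0:4095) / fs
  for (nm in wp_wavelets()) {
    for (f in c(4, 20, 44, 68, 92, 116)) {  # band centers at j = 4
      sb <- wp_subbands(sin(2 * pi * f * t), nm, 4)
      en <- colSums(sb$components^2)
      expect_identical(unname(which.max(en)), as.integer(f %/% 8) + 1L)
    }
  }
  # with >= 6-tap filters at shallow levels the concentration is >= 90%
  for (nm in c("sym6", "coif3")) {
    for (j in 1:2) {
      bw <- fs / 2^(j + 1)
      for (f in seq(bw / 2, fs / 2 - bw / 2, by = bw)) {
        sb <- wp_subbands(sin(2 * pi * f * t), nm, j)
        en <- colSums(sb$components^2)
        expect_gt(en[floor(f / bw) + 1] / sum(en), 0.9)
      }
    }
  }
})

test_that("keeping only the approximation reproduces a deep in-band tone", {
  t <- (0:4095) / 256
  x <- sin(2 * pi * 1 * t)  # 1 Hz, inside the 0-8 Hz approximation at j = 4
  sb <- wp_subbands(x, "db3", 4)
  approx_only <- sb$components[, sb$approx_index]
  expect_gt(stats::cor(approx_only, x), 0.99)
})
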
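test_that("Daubechies filter pairs satisfy the defining identities", {
  for (p in 1:10) {
    f <- daubechies_filters(p)
    expect_length(f$scaling, 2 * p)
    expect_equal(sum(f$scaling), 1, tolerance = 1e-12)
    expect_equal(sum(f$wavelet), 0, tolerance = 1e-12)
    # MODWT normalization: unit DWT energy scaled by 1/2
    expect_equal(sum(f$scaling^2), 0.5, tolerance = 1e-10)
    # quadrature mirror relation
    L <- 2 * p
    expect_equal(f$wavelet, (-1)^(0:(L - 1)) * rev(f$scaling), tolerance = 1e-14)
    # orthogonality to even shifts
    for (k in seq_len(p - 1)) {
      expect_equal(sum(f$scaling[seq_len(L - 2 * k)] *
                         f$scaling[seq_len(L - 2 * k) + 2 * k]),
                   0, tolerance = 1e-10)
    }
    # p vanishing moments of the wavelet filter (relative to the term scale,
    # since raw moments are ill-conditioned at high order)
    for (m in seq_len(p) - 1) {
      scale <- sum((0:(L - 1))^m * abs(f$wavelet))
      expect_lt(abs(sum((0:(L - 1))^m * f$wavelet)) / max(scale, 1), 1e-8)
    }
  }
  expect_error(daubechies_filters(0), "order")
  expect_error(daubechies_filters(11), "order")
})

test_that("db1 and db2 match their closed forms", {
  f1 <- daubechies_filters(1)
  expect_equal(f1$scaling, c(0.5, 0.5), tolerance = 1e-14)
  expect_equal(f1$wavelet, c(0.5, -0.5), tolerance = 1e-14)
  f2 <- daubechies_filters(2)
  expect_equal(f2$scaling,
               c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / 8,
               tolerance = 1e-12)
})

test_that("forward MODWT reproduces the Haar worked example and its identities", {
  out <- modwt_forward(c(1, 2, 3, 4), wavelet_spec(order = 1, J = 1))
  expect_equal(out$W[[1]], c(-1.5, 0.5, 0.5, 0.5))
  expect_equal(out$V, c(2.5, 1.5, 2.5, 3.5))

  # constant signal: all details vanish, smooth band carries the constant
  cst <- modwt_forward(rep(3.7, 40), wavelet_spec(order = 3, J = 3))
  for (w in cst$W) expect_lt(max(abs(w)), 1e-12)
  expect_equal(cst$V, rep(3.7, 40), tolerance = 1e-12)

  # energy preservation across random signals / specs
  set.seed(11)
  for (case in 1:5) {
    x <- rnorm(64 + case)
    spec <- wavelet_spec(order = sample(1:6, 1), J = sample(1:4, 1))
    fw <- modwt_forward(x, spec)
    expect_equal(sum(x^2),
                 sum(fw$V^2) + sum(vapply(fw$W, function(w) sum(w^2), 0)),
                 tolerance = 1e-10)
  }
})

test_that("MRA reproduces the Haar worked example and reconstructs perfectly", {
  m <- modwt_mra(c(1, 2, 3, 4), wavelet_spec(order = 1, J = 1))
  expect_equal(m$details[[1]], c(-1, 0, 0, 1), tolerance = 1e-12)
  expect_equal(m$smooth, c(2, 2, 3, 3), tolerance = 1e-12)

  set.seed(21)
  x <- rnorm(512)
  m4 <- modwt_mra(x, wavelet_spec(order = 4, J = 4))
  recon <- m4$smooth + Reduce(`+`, m4$details)
  expect_lt(max(abs(x - recon)), 1e-8)
  expect_length(m4$details, 4)
})

test_that("MODWT and MRA match the brute-force circulant oracle", {
  set.seed(33)
  for (n in c(8, 21, 33, 64)) {
    for (order in 1:2) {
      for (J in 1:3) {
        if (2^J > n) next
        x <- rnorm(n)
        got_f <- modwt_forward(x, wavelet_spec(order, J))
        exp_f <- oracle_modwt_forward(x, order, J)
        for (j in seq_len(J)) expect_equal(got_f$W[[j]], exp_f$W[[j]],
                                           tolerance = 1e-10)
        expect_equal(got_f$V, exp_f$V, tolerance = 1e-10)
        got_m <- modwt_mra(x, wavelet_spec(order, J))
        exp_m <- oracle_modwt_mra(x, order, J)
        for (j in seq_len(J)) expect_equal(got_m$details[[j]],
                                           exp_m$details[[j]],
                                           tolerance = 1e-10)
        expect_equal(got_m$smooth, exp_m$smooth, tolerance = 1e-10)
      }
    }
  }
})

test_that("MRA is shift invariant and linear", {
  set.seed(5)
  x <- rnorm(48)
  y <- rnorm(48)
  spec <- wavelet_spec(order = 2, J = 3)
  shift <- function(v, s) c(v[(s + 1):length(v)], v[seq_len(s)])
  m <- modwt_mra(x, spec)
  ms <- modwt_mra(shift(x, 7), spec)
  expect_equal(ms$smooth, shift(m$smooth, 7), tolerance = 1e-10)
  for (j in 1:3) expect_equal(ms$details[[j]], shift(m$details[[j]], 7),
                              tolerance = 1e-10)
  ma <- modwt_mra(2 * x - 3 * y, spec)
  mx <- modwt_mra(x, spec); my <- modwt_mra(y, spec)
  expect_equal(ma$smooth, 2 * mx$smooth - 3 * my$smooth, tolerance = 1e-10)
  for (j in 1:3) expect_equal(ma$details[[j]],
                              2 * mx$details[[j]] - 3 * my$details[[j]],
                              tolerance = 1e-10)
})

test_that("reflection boundary still reconstructs and damps wrap-around", {
  set.seed(9)
  x <- rnorm(100) + seq(0, 5, length.out = 100)  # strong trend
  m <- modwt_mra(x, wavelet_spec(order = 4, J = 3, boundary = "reflection"))
  recon <- m$smooth + Reduce(`+`, m$details)
  expect_lt(max(abs(x - recon)), 1e-8)
  expect_length(m$smooth, 100)
})

test_that("invalid inputs are rejected with clear errors", {
  expect_error(modwt_forward(1:4, wavelet_spec(order = 1, J = 3)),
               "level too deep")
  expect_error(modwt_forward(c(1, NA, 3, 4), wavelet_spec(1, 1)),
               "non-finite")
  expect_error(wavelet_spec(order = 12), "1..10")
  expect_error(wavelet_spec(J = 0), "positive")
})
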
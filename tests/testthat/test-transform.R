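# Forward/adjoint transforms and bandlimiting.

test_that("a unit impulse transforms into the spatial wavelets", {
  bank <- smallBank()
  f <- matrix(0, 16, 16); f[1, 1] <- 1
  Fs <- stackValues(se2Forward(f, bank))
  for (j in 1:3) {
    psij <- stats::fft(filters(bank)[, , j] + 0i, inverse = TRUE) / 256
    expect_equal(max(Mod(Fs[, , j] - psij)), 0, tolerance = 1e-14)
  }
})

test_that("the forward transform is linear", {
  bank <- smallBank()
  set.seed(4)
  f <- matrix(rnorm(256), 16); g <- matrix(rnorm(256), 16)
  a <- 2.3; b <- -0.7
  lhs <- stackValues(se2Forward(a * f + b * g, bank))
  rhs <- a * stackValues(se2Forward(f, bank)) +
         b * stackValues(se2Forward(g, bank))
  expect_equal(max(Mod(lhs - rhs)), 0, tolerance = 1e-12)
})

test_that("FFT forward agrees with the naive convolution oracle", {
  bank <- gaborBank(8, 3, 2.5, 2)
  set.seed(5)
  f <- matrix(rnorm(64), 8)
  got <- stackValues(se2Forward(f, bank))
  want <- naiveForward(f, bank)
  expect_lt(relErr(got, want), 1e-12)
})

test_that("stack energy obeys the Parseval identity with the Calderon weight", {
  bank <- gaborBank(8, 3, 2.5, 2)
  set.seed(6)
  f <- matrix(rnorm(64), 8)
  Fs <- stackValues(se2Forward(f, bank))
  # oracle: sum_xi |fhat|^2 C(xi) / N^2, fhat from a naive double-sum DFT
  idx <- 0:7
  W <- exp(-2i * pi * outer(idx, idx) / 8)
  fhat <- W %*% f %*% t(W)
  k <- c(0:3, -4:-1)
  th <- 2 * pi * (0:2) / 3
  C <- matrix(0, 8, 8)
  for (j in 1:3)
    C <- C + exp(-outer((k + 2 * cos(th[j]))^2,
                        (k + 2 * sin(th[j]))^2, "+") / 2.5^2)
  expect_equal(sum(Mod(Fs)^2), sum(Mod(fhat)^2 * C) / 64, tolerance = 1e-10)
})

test_that("the adjoint is the true adjoint of the forward transform", {
  bank <- gaborBank(8, 3, 2.5, 2)
  set.seed(7)
  f <- matrix(rnorm(64), 8)
  G <- randomStack(8, 3, seed = 8)
  lhs <- innerProd(stackValues(se2Forward(f, bank)), stackValues(G))
  rhs <- innerProd(f, se2Adjoint(G, bank))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("adjoint with the dual bank inverts the transform on bandlimited images", {
  bank <- smallBank(); dual <- smallDual()
  for (seed in 1:4) {
    f <- randomBandlimited(16, 6, seed)
    g <- se2Adjoint(se2Forward(f, bank), dual)
    expect_lt(relErr(g, gridValues(f)), 1e-10)
    expect_lt(max(abs(Im(g))), 1e-10 * max(abs(gridValues(f))))
  }
})

test_that("a zero stack maps to the zero image", {
  z <- new("TransformStack", values = array(0i, c(16, 16, 3)),
           N = 16L, M = 3L)
  expect_identical(max(Mod(se2Adjoint(z, smallDual()))), 0)
})

test_that("the frame inequality brackets the stack energy of bandlimited images", {
  bank <- smallBank()
  fb <- frameBounds(bank, 6)
  for (seed in 1:5) {
    f <- gridValues(randomBandlimited(16, 6, seed))
    e <- sum(Mod(stackValues(se2Forward(f, bank)))^2)
    expect_gte(e, fb$A * sum(f^2) * (1 - 1e-12))
    expect_lte(e, fb$B * sum(f^2) * (1 + 1e-12))
  }
})

test_that("rotating a bandlimited image by 90 degrees rotates and shifts the planes", {
  bank <- gaborBank(16, 4, 3, 4)
  set.seed(9)
  f <- gridValues(bandlimit(matrix(rnorm(256), 16), 6))
  Wf <- stackValues(se2Forward(f, bank))
  Wg <- stackValues(se2Forward(rot90torus(f), bank))
  for (j in 0:3) {
    jp <- (j - 1) %% 4
    expect_lt(max(Mod(Wg[, , j + 1] - rot90torus(Wf[, , jp + 1]))), 1e-12)
  }
})

test_that("bandlimiting is an idempotent spectral cutoff", {
  set.seed(10)
  f <- matrix(rnorm(256), 16)
  b1 <- bandlimit(f, 5)
  b2 <- bandlimit(b1, 5)
  expect_equal(gridValues(b2), gridValues(b1), tolerance = 1e-13)
  expect_identical(b1@bandlimitRadius, 5)
  # the DC component is inside every ball
  const <- matrix(7, 16, 16)
  expect_equal(gridValues(bandlimit(const, 0.5)), const, tolerance = 1e-12)
  # a pure wave at |xi| >= R is annihilated
  wave <- cos(2 * pi * 4 * (0:15) / 16) %o% rep(1, 16)
  expect_lt(max(abs(gridValues(bandlimit(wave, 4)))), 1e-12)
})

test_that("dimension mismatches are rejected", {
  bank <- smallBank()
  expect_error(se2Forward(matrix(0, 8, 8), bank), "match")
  G <- randomStack(8, 3, seed = 1)
  expect_error(se2Adjoint(G, bank), "match")
})
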
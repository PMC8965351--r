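# Orientation maps, pinwheel fields, singularity detection, selection.

test_that("random maps are uniform, in range, and seed-reproducible", {
  th <- randomMap(256, 12, seed = 21)
  v <- gridValues(th)
  expect_true(all(v %in% 0:11))
  expect_identical(gridValues(randomMap(256, 12, seed = 21)), v)
  expect_false(identical(gridValues(randomMap(256, 12, seed = 22)), v))
  pval <- chisq.test(tabulate(v + 1L, 12))$p.value
  expect_gt(pval, 0.001)
})

test_that("the pinwheel field reduces to the plain quadrature with zero phases", {
  fld <- pinwheelField(32, rho = 0.4, K = 64, gamma = rep(0, 64))
  expect_equal(gridValues(fld)[1, 1], 2 * pi + 0i, tolerance = 1e-12)
})

test_that("pinwheel fields are seed-reproducible and respect the Nyquist guard", {
  f1 <- pinwheelField(64, 0.4, seed = 23)
  f2 <- pinwheelField(64, 0.4, seed = 23)
  expect_identical(gridValues(f1), gridValues(f2))
  expect_error(pinwheelField(64, 3.5, seed = 1), "Nyquist")
  expect_error(pinwheelField(64, 0.4, K = 4, seed = 1), "K")
})

test_that("the field spectrum concentrates on the ring rho/(2 pi)", {
  fld <- pinwheelField(512, 0.4, seed = 24)
  P <- Mod(stats::fft(gridValues(fld)))^2
  k <- c(0:255, -256:-1)
  fr <- sqrt(outer(k^2, k^2, "+")) / 512        # cycles/pixel
  ring <- 0.4 / (2 * pi)
  inAnnulus <- fr >= 0.8 * ring & fr <= 1.2 * ring
  expect_gte(sum(P[inAnnulus]) / sum(P), 0.9)
})

test_that("phase quantization maps [0, 2 pi) onto 0..M-1 with edge guards", {
  mk <- function(z) new("PinwheelField",
                        values = matrix(z, 2, 2), rho = 1, K = 8L,
                        seed = 1L)
  expect_identical(gridValues(quantizeMap(mk(1 + 0i), 12))[1, 1], 0L)
  # phase just below 2 pi lands in the last bin
  expect_identical(gridValues(quantizeMap(mk(exp(1i * (2 * pi - 1e-9))), 12))[1, 1],
                   11L)
  # the phase of 0 is defined as 0
  expect_identical(gridValues(quantizeMap(mk(0 + 0i), 12))[1, 1], 0L)
  expect_identical(gridValues(quantizeMap(mk(exp(1i * pi)), 12))[1, 1], 6L)
})

test_that("a full-size quantized pinwheel map covers all orientations", {
  th <- quantizeMap(pinwheelField(512, 0.4, seed = 25), 12)
  expect_identical(sort(unique(as.vector(gridValues(th)))), 0:11)
})

test_that("quantized pinwheel maps are quasiperiodic at wavelength 2 pi / rho", {
  rho <- 0.4
  th <- quantizeMap(pinwheelField(256, rho, seed = 26), 12)
  z <- exp(2i * pi * gridValues(th) / 12)
  ac <- Re(stats::fft(stats::fft(z) * Conj(stats::fft(z)), inverse = TRUE)) /
    length(z)
  k <- c(0:127, -128:-1)
  r <- round(sqrt(outer(k^2, k^2, "+")))
  prof <- tapply(as.vector(ac), as.vector(r), mean)
  v <- as.numeric(prof); rr <- as.numeric(names(prof))
  peaks <- which(diff(sign(diff(v))) == -2) + 1   # local maxima
  firstRing <- rr[peaks[1]]
  expect_gt(firstRing, 0.8 * 2 * pi / rho)
  expect_lt(firstRing, 1.4 * 2 * pi / rho)
})

test_that("constant maps select exactly one convolution plane", {
  th <- constantMap(16, 3, j0 = 1)
  expect_true(all(gridValues(th) == 1L))
  expect_error(constantMap(16, 3, 3), "range")
  bank <- smallBank()
  set.seed(27)
  f <- matrix(rnorm(256), 16)
  Fs <- se2Forward(f, bank)
  sel <- applySelection(Fs, th)
  v <- stackValues(sel)
  expect_identical(max(Mod(v[, , 1])), 0)
  expect_identical(max(Mod(v[, , 3])), 0)
  # surviving plane is the single circular convolution f * psi_{theta_1}
  conv <- stats::fft(stats::fft(f + 0i) * filters(bank)[, , 2],
                     inverse = TRUE) / 256
  expect_lt(max(Mod(v[, , 2] - conv)), 1e-12)
})

test_that("a synthetic vortex is detected with the right winding", {
  N <- 32
  x <- matrix(0:(N - 1), N, N); y <- t(x)
  z <- (x - 15.5) + 1i * (y - 15.5)
  ps <- detectPinwheels(z)
  pts <- pinwheelPoints(ps)
  # away from the periodic wrap seam the only detection is the vortex core
  interior <- pts[pts$x1 > 2 & pts$x1 < N - 2 & pts$x2 > 2 & pts$x2 < N - 2, ]
  expect_identical(nrow(interior), 1L)
  expect_equal(interior$x1, 15.5)
  expect_equal(interior$x2, 15.5)
  expect_identical(interior$sign, 1)
  ptsC <- pinwheelPoints(detectPinwheels(Conj(z)))
  interiorC <- ptsC[ptsC$x1 > 2 & ptsC$x1 < N - 2 &
                      ptsC$x2 > 2 & ptsC$x2 < N - 2, ]
  expect_identical(interiorC$sign, -1)
})

test_that("pinwheel counts scale as rho squared", {
  n1 <- nrow(pinwheelPoints(detectPinwheels(pinwheelField(256, 0.2, seed = 28))))
  n2 <- nrow(pinwheelPoints(detectPinwheels(pinwheelField(256, 0.4, seed = 28))))
  expect_gt(n2 / n1, 4 * 0.6)
  expect_lt(n2 / n1, 4 * 1.4)
})

test_that("winding around every listed plaquette is +/- 2 pi", {
  fld <- pinwheelField(64, 0.4, seed = 29)
  ps <- detectPinwheels(fld)
  pts <- pinwheelPoints(ps)
  expect_gt(nrow(pts), 0)
  ph <- Arg(gridValues(fld))
  wrap <- function(d) (d + pi) %% (2 * pi) - pi
  for (i in seq_len(min(nrow(pts), 25))) {
    a <- pts$x1[i] - 0.5 + 1; b <- pts$x2[i] - 0.5 + 1
    a2 <- (a %% 64) + 1; b2 <- (b %% 64) + 1
    w <- wrap(ph[a2, b] - ph[a, b]) + wrap(ph[a2, b2] - ph[a2, b]) +
         wrap(ph[a, b2] - ph[a2, b2]) + wrap(ph[a, b] - ph[a, b2])
    expect_equal(w / (2 * pi), pts$sign[i], tolerance = 1e-9)
  }
})

test_that("selection is an idempotent self-adjoint 0/1 projection with N^2 survivors", {
  th <- randomMap(16, 3, seed = 30)
  G <- randomStack(16, 3, seed = 31)
  S1 <- applySelection(G, th)
  S2 <- applySelection(S1, th)
  expect_identical(stackValues(S1), stackValues(S2))
  expect_identical(sum(Mod(stackValues(S1)) > 0), 256L)
  H <- randomStack(16, 3, seed = 32)
  expect_equal(innerProd(stackValues(S1), stackValues(H)),
               innerProd(stackValues(G), stackValues(applySelection(H, th))),
               tolerance = 1e-12)
  # restrictStack is the same operator
  expect_identical(stackValues(restrictStack(G, th)), stackValues(S1))
  expect_error(applySelection(G, randomMap(16, 4, seed = 1)), "M")
})
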
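# Error metric, project-and-replace iteration, image read-out.

test_that("the percent error metric has its closed-form values", {
  expect_identical(errorDelta(matrix(7, 8, 8), matrix(7, 8, 8)), 0)
  expect_identical(errorDelta(matrix(255, 8, 8), matrix(0, 8, 8)), 100)
  a <- matrix(0, 512, 512); b <- a; b[17, 33] <- 255
  expect_equal(errorDelta(a, b), 100 / 512, tolerance = 1e-12)
  expect_error(errorDelta(matrix(0, 8, 8), matrix(0, 9, 9)), "dimensions")
})

test_that("the transform of the original image is a fixed point", {
  bank <- smallBank(); dual <- smallDual()
  f <- randomBandlimited(16, 6, seed = 41)
  th <- randomMap(16, 3, seed = 42)
  Ft <- se2Forward(f, bank)
  F0 <- restrictStack(Ft, th)
  # one manual step from the target: P fixes it, replacement restores F0
  H <- rkhsProject(Ft, bank, dual)
  vals <- stackValues(H)
  keep <- se2recon:::.graphIndices(th)
  vals[keep] <- stackValues(F0)[keep]
  expect_lt(relErr(vals, stackValues(Ft)), 1e-10)
})

test_that("iterates carry the data on the graph exactly at every step", {
  bank <- smallBank(); dual <- smallDual()
  f <- randomBandlimited(16, 6, seed = 43)
  th <- randomMap(16, 3, seed = 44)
  F0 <- restrictStack(se2Forward(f, bank), th)
  keep <- se2recon:::.graphIndices(th)
  for (n in c(1L, 3L, 7L)) {
    tr <- projectAndReplace(F0, th, bank, dual, nIter = n)
    expect_identical(tr@finalF[keep], stackValues(F0)[keep])
    # off the graph nothing of F0 remains unprojected: restriction recovers F0
    expect_identical(tr@finalF[-keep] * 0i, stackValues(F0)[-keep])
  }
})

test_that("the C++ loop and the pure-R loop produce identical trajectories", {
  bank <- smallBank(); dual <- smallDual()
  f <- randomBandlimited(16, 6, seed = 45)
  th <- randomMap(16, 3, seed = 46)
  F0 <- restrictStack(se2Forward(f, bank), th)
  tr <- projectAndReplace(F0, th, bank, dual, nIter = 25, recordStride = 1,
                          reference = f)
  rloop <- se2recon:::.projectAndReplaceR(F0, th, bank, dual, 25,
                                          reference = f)
  expect_lt(max(Mod(tr@finalF - stackValues(rloop$F))), 1e-12)
  expect_lt(max(Mod(tr@finalH - stackValues(rloop$H))), 1e-12)
  expect_equal(unname(deltas(tr)), rloop$deltas, tolerance = 1e-12)
})

test_that("recorded error traces are nonincreasing on solvable instances", {
  bank <- smallBank(); dual <- smallDual()
  set.seed(47)
  f <- bandlimit(imageGrid(matrix(runif(256, 0, 255), 16)), 6)
  for (seed in c(48, 49)) {
    th <- randomMap(16, 3, seed = seed)
    F0 <- restrictStack(se2Forward(f, bank), th)
    tr <- projectAndReplace(F0, th, bank, dual, nIter = 150,
                            recordStride = 1, reference = f)
    expect_true(all(diff(deltas(tr)) <= 1e-12))
    expect_lt(deltas(tr)[150], deltas(tr)[1])
  }
})

test_that("the trace length follows the recording stride contract", {
  bank <- smallBank(); dual <- smallDual()
  f <- randomBandlimited(16, 6, seed = 50)
  th <- randomMap(16, 3, seed = 51)
  F0 <- restrictStack(se2Forward(f, bank), th)
  for (case in list(c(10, 3), c(9, 3), c(20, 7), c(5, 1))) {
    tr <- projectAndReplace(F0, th, bank, dual, nIter = case[1],
                            recordStride = case[2], reference = f)
    expect_identical(length(deltas(tr)), as.integer(ceiling(case[1] / case[2])))
    expect_identical(tr@iterations[length(tr@iterations)], as.integer(case[1]))
  }
})

test_that("relabeling orientations consistently leaves the error trace unchanged", {
  bank <- smallBank(); dual <- smallDual()
  f <- randomBandlimited(16, 6, seed = 52)
  th <- randomMap(16, 3, seed = 53)
  F0 <- restrictStack(se2Forward(f, bank), th)
  tr <- projectAndReplace(F0, th, bank, dual, nIter = 30, recordStride = 5,
                          reference = f)
  # cyclic permutation j -> j + 1 of planes, map values, and filters
  perm <- c(2L, 3L, 1L)                      # new index of old plane j
  pb <- new("WaveletBank", N = 16L, M = 3L, s = bank@s, p = bank@p,
            filters = filters(bank)[, , order(perm)])
  pd <- dualBank(pb, 6)
  pth <- new("FeatureMap", values = matrix(perm[gridValues(th) + 1L] - 1L,
                                           16, 16),
             M = 3L, kind = "random", rho = NA_real_, seed = NA_integer_)
  pF0 <- restrictStack(se2Forward(f, pb), pth)
  ptr <- projectAndReplace(pF0, pth, pb, pd, nIter = 30, recordStride = 5,
                           reference = f)
  expect_equal(unname(deltas(ptr)), unname(deltas(tr)), tolerance = 1e-12)
})

test_that("data off the graph of the map is a precondition violation", {
  bank <- smallBank(); dual <- smallDual()
  th <- randomMap(16, 3, seed = 54)
  G <- randomStack(16, 3, seed = 55)     # dense: mass everywhere
  expect_error(projectAndReplace(G, th, bank, dual, nIter = 2), "graph")
})

test_that("image read-out is linear, exact on range stacks, and flags imaginary mass", {
  bank <- smallBank(); dual <- smallDual()
  f <- randomBandlimited(16, 6, seed = 56)
  Ft <- se2Forward(f, bank)
  out <- reconstructImage(Ft, dual)
  expect_lt(relErr(gridValues(out), gridValues(f)), 1e-10)
  expect_lt(attr(out, "imagResidual"), 1e-10)
  z <- new("TransformStack", values = array(0i, c(16, 16, 3)), N = 16L, M = 3L)
  expect_identical(max(abs(gridValues(reconstructImage(z, dual)))), 0)
  G1 <- randomStack(16, 3, seed = 57); G2 <- randomStack(16, 3, seed = 58)
  lin <- new("TransformStack",
             values = 2 * stackValues(G1) - 3 * stackValues(G2),
             N = 16L, M = 3L)
  expect_equal(gridValues(reconstructImage(lin, dual)),
               2 * gridValues(reconstructImage(G1, dual)) -
                 3 * gridValues(reconstructImage(G2, dual)),
               tolerance = 1e-11)
})

test_that("early stopping on stagnation truncates the trace", {
  bank <- smallBank(); dual <- smallDual()
  f <- randomBandlimited(16, 6, seed = 59)
  th <- randomMap(16, 3, seed = 60)
  F0 <- restrictStack(se2Forward(f, bank), th)
  tr <- projectAndReplace(F0, th, bank, dual, nIter = 500, recordStride = 1,
                          reference = f, stopTol = 1e-6)
  expect_lt(tr@nIter, 500L)
})
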
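# Shared fixtures and independent oracles. Everything is built in code;
# expensive objects (the full-size bank) are memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# Full-size parameter set used throughout the reference experiments:
# N = 512, M = 12 orientations, s = 51, p = 170, bandlimit R = 252.
refBank <- function() cached("refBank", gaborBank(512, 12, 51, 170))
refDual <- function() cached("refDual", dualBank(refBank(), 252))

# Small fixtures for oracle-level checks.
smallBank <- function() cached("smallBank", gaborBank(16, 3, 3, 4))
smallDual <- function() cached("smallDual", dualBank(smallBank(), 6))
deskBank <- function() cached("deskBank", gaborBank(8, 2, 2.5, 2))
deskDual <- function() cached("deskDual", dualBank(deskBank(), 3))

randomStack <- function(N, M, seed = 1) {
  set.seed(seed)
  new("TransformStack",
      values = array(complex(real = rnorm(N * N * M),
                             imaginary = rnorm(N * N * M)),
                     dim = c(N, N, M)),
      N = as.integer(N), M = as.integer(M))
}

randomBandlimited <- function(N, R, seed = 1) {
  set.seed(seed)
  bandlimit(imageGrid(matrix(rnorm(N * N), N, N)), R)
}

relErr <- function(got, want) {
  denom <- max(Mod(want))
  if (denom == 0) max(Mod(got)) else max(Mod(got - want)) / denom
}

# <a, b> = sum a * conj(b) over all entries (stacks, matrices, vectors).
innerProd <- function(a, b) sum(a * Conj(b))

# Independent slow-path oracle for the forward transform: naive O(N^4)
# circular convolution with spatial wavelets obtained by a naive double-sum
# inverse DFT of the frequency filters (no stats::fft anywhere).
naiveForward <- function(f, bank) {
  N <- nrow(f); M <- dim(filters(bank))[3]
  idx <- 0:(N - 1)
  W <- exp(2i * pi * outer(idx, idx) / N)    # inverse-DFT twiddle matrix
  out <- array(0i, dim = c(N, N, M))
  for (j in seq_len(M)) {
    psij <- (W %*% filters(bank)[, , j] %*% t(W)) / N^2   # spatial wavelet
    for (a in idx) for (b in idx) {
      acc <- 0i
      for (y1 in idx) for (y2 in idx) {
        acc <- acc + f[y1 + 1, y2 + 1] *
          psij[((a - y1) %% N) + 1, ((b - y2) %% N) + 1]
      }
      out[a + 1, b + 1, j] <- acc
    }
  }
  out
}

# Rotate a matrix by +90 degrees on the torus (0-based lattice):
# out(x) = in(r^{-1} x), r^{-1}(x1, x2) = (x2, -x1 mod N).
rot90torus <- function(m) {
  N <- nrow(m)
  out <- m
  for (a in 0:(N - 1)) for (b in 0:(N - 1))
    out[a + 1, b + 1] <- m[b + 1, ((-a) %% N) + 1]
  out
}

# Lattice-point count of the open ball |xi| < R on the centered lattice.
ballCount <- function(N, R) {
  k <- c(0:(N / 2 - 1), -(N / 2):-1)
  sum(outer(k^2, k^2, "+") < R^2)
}
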
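# Internal numerical helpers shared across modules.

# DFT index -> centered integer frequency, standard convention:
# array index k (0-based) maps to frequency k for k < N/2, else k - N.
.dftFreq <- function(N) c(0:(N / 2 - 1), -(N / 2):-1)

# Frequency lattice grids in DFT storage order. xi1 varies along rows,
# xi2 along columns, matching the spatial convention x = (row, col) - 1.
.freqGrid <- function(N) {
  k <- .dftFreq(N)
  xi1 <- matrix(k, N, N)
  xi2 <- matrix(k, N, N, byrow = TRUE)
  list(xi1 = xi1, xi2 = xi2, r2 = xi1^2 + xi2^2)
}

# Unnormalized forward / 1/N^2 inverse DFT pair, fixed once for the package.
.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Ball indicator on the frequency lattice; strict inequality |xi|^2 < R^2.
.ballMask <- function(N, R) .freqGrid(N)$r2 < R^2

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded generators do not perturb the global stream.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Extract a plain numeric matrix from an ImageGrid or matrix argument.
.asMatrix <- function(f) {
  if (is(f, "ImageGrid")) gridValues(f) else {
    if (!is.matrix(f)) .stopf("expected a matrix or ImageGrid")
    f
  }
}

# Relative spectral energy of `values` outside the radius-R ball.
.outOfBallEnergy <- function(values, R) {
  fhat <- .fft2(values)
  mask <- .ballMask(nrow(values), R)
  tot <- sum(Mod(fhat)^2)
  if (tot == 0) return(0)
  sum(Mod(fhat[!mask])^2) / tot
}
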
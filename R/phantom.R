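# 8-bit phantom images standing in for natural photographs: random-phase
# fields with isotropic power-law amplitude spectra, and geometric scenes.

#' Generate an 8-bit phantom image
#'
#' Three kinds:
#' \describe{
#'   \item{\code{powerlaw}}{a random-phase field with isotropic spectral
#'     amplitude proportional to \code{(1 + |xi|)^(-beta)}, the classical
#'     statistical model of natural-image spectra, rescaled to the full
#'     \code{0..255} range and quantized;}
#'   \item{\code{shapes}}{an anti-aliased geometric scene of disks, bars at
#'     several orientations, and a half-plane edge with randomized
#'     placement and intensities;}
#'   \item{\code{mixed}}{the sum of the two, rescaled and quantized.}
#' }
#' All kinds are deterministic given the seed.
#'
#' @param N side length (even).
#' @param kind \code{"powerlaw"}, \code{"shapes"} or \code{"mixed"}.
#' @param beta spectral amplitude decay exponent (positive; used by
#'   \code{powerlaw} and \code{mixed}). The default 1.2 gives
#'   natural-image-like \code{~1/|xi|} amplitude decay.
#' @param seed RNG seed.
#' @return An 8-bit [ImageGrid-class].
#'
#' @examples
#' img <- phantom(128, "powerlaw", seed = 1)
#'
#' @export
phantom <- function(N, kind = c("powerlaw", "shapes", "mixed"), beta = 1.2,
                    seed) {
  kind <- match.arg(kind)
  if (length(N) != 1L || !is.finite(N) || N < 4 || N %% 2 != 0)
    .stopf("invalid phantom spec: N must be a single even integer >= 4")
  if (kind != "shapes" && (length(beta) != 1L || !is.finite(beta) || beta <= 0))
    .stopf("invalid phantom spec: beta must be a single positive number")
  vals <- .withSeed(seed, switch(kind,
    powerlaw = .powerlawField(N, beta),
    shapes   = .shapesScene(N),
    mixed    = {
      a <- .powerlawField(N, beta)
      b <- .shapesScene(N)
      .unitScale(a) + .unitScale(b)
    }))
  rng <- range(vals)
  q <- if (rng[2] > rng[1]) (vals - rng[1]) / (rng[2] - rng[1]) else vals * 0
  new("ImageGrid", values = round(q * 255), bitDepth = "8bit",
      bandlimitRadius = NA_real_)
}

.unitScale <- function(v) {
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
}

# Random-phase field with amplitude (1 + |xi|)^(-beta); the real part of
# the inverse DFT Hermitian-symmetrizes the spectrum implicitly.
.powerlawField <- function(N, beta) {
  g <- .freqGrid(N)
  amp <- (1 + sqrt(g$r2))^(-beta)
  ph <- matrix(stats::runif(N * N, 0, 2 * pi), N, N)
  Re(.ifft2(amp * exp(1i * ph))) * N^2   # undo the 1/N^2 of the inverse
}

# Disks, oriented bars and an edge, anti-aliased with a 1-pixel soft ramp.
.shapesScene <- function(N) {
  xs <- matrix(0:(N - 1), N, N)
  ys <- matrix(0:(N - 1), N, N, byrow = TRUE)
  ramp <- function(d) pmin(pmax(d + 0.5, 0), 1)   # signed distance -> [0,1]
  img <- matrix(0, N, N)
  for (i in 1:3) {   # disks
    c1 <- stats::runif(1, 0.2, 0.8) * N; c2 <- stats::runif(1, 0.2, 0.8) * N
    r0 <- stats::runif(1, 0.08, 0.2) * N
    amp <- stats::runif(1, 0.3, 1)
    img <- img + amp * ramp(r0 - sqrt((xs - c1)^2 + (ys - c2)^2))
  }
  for (i in 1:3) {   # bars at assorted orientations
    th <- stats::runif(1, 0, pi)
    c1 <- stats::runif(1, 0.2, 0.8) * N; c2 <- stats::runif(1, 0.2, 0.8) * N
    u <- (xs - c1) * cos(th) + (ys - c2) * sin(th)
    v <- -(xs - c1) * sin(th) + (ys - c2) * cos(th)
    hw <- stats::runif(1, 0.01, 0.03) * N
    hl <- stats::runif(1, 0.15, 0.35) * N
    amp <- stats::runif(1, 0.3, 1)
    img <- img + amp * ramp(hw - abs(u)) * ramp(hl - abs(v))
  }
  th <- stats::runif(1, 0, pi)   # one straight edge
  off <- stats::runif(1, 0.3, 0.7) * N
  img + 0.5 * ramp((xs - off) * cos(th) + (ys - off) * sin(th))
}
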
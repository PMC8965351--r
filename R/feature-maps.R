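# Orientation-preference maps: generation, quantization, singularity
# detection, and the selection operator they induce on transform stacks.

#' Uniformly random orientation map
#'
#' Assigns to every pixel an orientation index drawn i.i.d. uniformly from
#' \code{0..M-1} — the salt-and-pepper arrangement reported for rodent
#' visual cortex.
#'
#' @param N side length.
#' @param M number of orientations.
#' @param seed RNG seed; the map is reproduced bit-exactly from it.
#' @return A [FeatureMap-class] of kind \code{"random"}.
#'
#' @examples
#' th <- randomMap(64, 12, seed = 1)
#'
#' @export
randomMap <- function(N, M, seed) {
  if (M < 1) .stopf("M must be at least 1")
  vals <- .withSeed(seed, matrix(sample.int(M, N * N, replace = TRUE) - 1L, N, N))
  new("FeatureMap", values = vals, M = as.integer(M), kind = "random",
      rho = NA_real_, seed = as.integer(seed))
}

#' Constant orientation map
#'
#' Every pixel selects the same orientation \code{j0}: restricting the
#' transform with this map keeps a single convolution plane, so
#' reconstruction becomes a deconvolution problem.
#'
#' @param N side length.
#' @param M number of orientations.
#' @param j0 the selected orientation index, in \code{0..M-1}.
#' @return A [FeatureMap-class] of kind \code{"constant"}.
#'
#' @examples
#' th <- constantMap(64, 12, j0 = 3)
#'
#' @export
constantMap <- function(N, M, j0) {
  if (length(j0) != 1L || j0 %% 1 != 0 || j0 < 0 || j0 >= M)
    .stopf("j0 = %s out of range 0..%d", toString(j0), M - 1)
  new("FeatureMap", values = matrix(as.integer(j0), N, N),
      M = as.integer(M), kind = "constant", rho = NA_real_,
      seed = NA_integer_)
}

#' Quasiperiodic pinwheel field
#'
#' Builds the complex field
#' \deqn{\phi_\rho(x) = \frac{2\pi}{K} \sum_{k=0}^{K-1}
#' \exp\left(i\left(\rho (x_1 \cos\alpha_k + x_2 \sin\alpha_k) +
#' \Gamma_k\right)\right), \qquad \alpha_k = 2\pi k/K,}
#' a quadrature discretization of a superposition of unit plane waves of
#' wave number \code{rho} over all directions with i.i.d. uniform random
#' phases \eqn{\Gamma_k}. Its spectrum concentrates on a ring of radius
#' \code{rho/(2*pi)} cycles/pixel and its phase carries the +/-1
#' singularities (pinwheels) characteristic of measured
#' orientation-preference maps.
#'
#' @param N side length.
#' @param rho wave number in radians per pixel; must not exceed the Nyquist
#'   limit \code{pi}.
#' @param K number of angular quadrature samples, at least 8.
#' @param seed RNG seed for the phases.
#' @param gamma optional length-\code{K} numeric vector of phases,
#'   overriding the random draw (used mainly for deterministic checks).
#' @return A [PinwheelField-class].
#'
#' @examples
#' fld <- pinwheelField(128, rho = 0.4, seed = 1)
#'
#' @export
pinwheelField <- function(N, rho, K = 64L, seed, gamma = NULL) {
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0)
    .stopf("rho must be a single positive number")
  if (rho / (2 * pi) > 0.5)
    .stopf("rho = %g exceeds the Nyquist limit: rho/(2*pi) must be <= 0.5 cycles/pixel",
           rho)
  if (K < 8L) .stopf("K must be at least 8")
  K <- as.integer(K)
  if (is.null(gamma)) {
    gamma <- .withSeed(seed, stats::runif(K, 0, 2 * pi))
  } else if (length(gamma) != K) {
    .stopf("gamma must have length K = %d", K)
  }
  x <- 0:(N - 1)
  alpha <- 2 * pi * (seq_len(K) - 1L) / K
  phi <- matrix(0i, N, N)
  for (k in seq_len(K)) {
    cx <- exp(1i * rho * cos(alpha[k]) * x)
    cy <- exp(1i * rho * sin(alpha[k]) * x)
    phi <- phi + exp(1i * gamma[k]) * outer(cx, cy)
  }
  new("PinwheelField", values = phi * (2 * pi / K), rho = as.numeric(rho),
      K = K, seed = as.integer(if (missing(seed)) NA else seed))
}

#' Quantize a pinwheel field into an orientation map
#'
#' Maps the phase of the field to an orientation index by
#' \eqn{\Theta_\rho(x) = \lfloor M\,\mathrm{angle}(\phi_\rho(x)) / (2\pi)
#' \rfloor} with the phase taken in \code{[0, 2*pi)}, followed by a
#' \code{mod M} guard for the floating-point edge at exactly \code{2*pi}.
#' A zero field value gets index 0 (the phase of 0 is defined as 0).
#'
#' @param field a [PinwheelField-class].
#' @param M number of orientations.
#' @return A [FeatureMap-class] of kind \code{"pinwheel"}.
#'
#' @examples
#' th <- quantizeMap(pinwheelField(128, 0.4, seed = 1), M = 12)
#'
#' @export
setMethod("quantizeMap", "PinwheelField", function(field, M, ...) {
  if (M < 1) .stopf("M must be at least 1")
  ang <- Arg(field@values)          # (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + 2 * pi
  ang[field@values == 0] <- 0
  idx <- floor(M * ang / (2 * pi)) %% M
  new("FeatureMap", values = matrix(as.integer(idx), nrow(ang), ncol(ang)),
      M = as.integer(M), kind = "pinwheel", rho = field@rho,
      seed = field@seed)
})

#' Detect pinwheel points of a complex field
#'
#' Lists every lattice plaquette around which the field's phase winds by
#' +/- 2*pi (periodic boundaries). Reported locations are the plaquette
#' centers: lower-left corner (0-based pixel coordinates) + (0.5, 0.5).
#'
#' @param field a [PinwheelField-class] or a complex matrix.
#' @return A [PinwheelSet-class].
#'
#' @examples
#' ps <- detectPinwheels(pinwheelField(128, 0.4, seed = 1))
#'
#' @export
setMethod("detectPinwheels", "ANY", function(field, ...) {
  if (is(field, "PinwheelField")) {
    vals <- field@values; rho <- field@rho
  } else {
    if (!is.matrix(field) || !is.complex(field))
      .stopf("field must be a PinwheelField or a complex matrix")
    vals <- field; rho <- NA_real_
  }
  N <- nrow(vals)
  ph <- Arg(vals)
  wrap <- function(d) (d + pi) %% (2 * pi) - pi
  s1 <- function(m) m[c(2:nrow(m), 1L), , drop = FALSE]   # x1 -> x1 + 1
  s2 <- function(m) m[, c(2:ncol(m), 1L), drop = FALSE]   # x2 -> x2 + 1
  d1 <- wrap(s1(ph) - ph)            # (x1,x2)     -> (x1+1,x2)
  d2 <- wrap(s2(s1(ph)) - s1(ph))    # (x1+1,x2)   -> (x1+1,x2+1)
  d3 <- wrap(s2(ph) - s2(s1(ph)))    # (x1+1,x2+1) -> (x1,x2+1)
  d4 <- wrap(ph - s2(ph))            # (x1,x2+1)   -> (x1,x2)
  w <- round((d1 + d2 + d3 + d4) / (2 * pi))
  hits <- which(w != 0, arr.ind = TRUE)
  pts <- data.frame(x1 = hits[, 1] - 1 + 0.5, x2 = hits[, 2] - 1 + 0.5,
                    sign = w[hits])
  new("PinwheelSet", points = pts, N = as.integer(N), rho = rho)
})

#' Pinwheel spacing statistics
#'
#' Summarizes the spatial arrangement of detected pinwheels: the mean
#' nearest-neighbour distance between singularities (toroidal metric) and
#' the density-implied mean spacing \code{1/sqrt(count/N^2)}. For
#' quasiperiodic maps of wave number \code{rho} the relevant comparison
#' scale is the column spacing \code{2*pi/rho}; note that +/- singularity
#' pairs typically sit closer together than that, so the nearest-neighbour
#' statistic is systematically smaller than the density-implied spacing.
#'
#' @param object a [PinwheelSet-class].
#' @return A list with \code{count}, \code{meanNN}, \code{densitySpacing},
#'   and \code{expectedSpacing} (= \code{2*pi/rho}, \code{NA} when rho is
#'   unknown).
#'
#' @examples
#' pinwheelSpacing(detectPinwheels(pinwheelField(128, 0.4, seed = 1)))
#'
#' @export
setMethod("pinwheelSpacing", "PinwheelSet", function(object, ...) {
  pts <- object@points
  n <- nrow(pts)
  meanNN <- NA_real_
  if (n >= 2) {
    dx <- abs(outer(pts$x1, pts$x1, "-")); dx <- pmin(dx, object@N - dx)
    dy <- abs(outer(pts$x2, pts$x2, "-")); dy <- pmin(dy, object@N - dy)
    d <- sqrt(dx^2 + dy^2); diag(d) <- Inf
    meanNN <- mean(apply(d, 1, min))
  }
  list(count = n,
       meanNN = meanNN,
       densitySpacing = if (n > 0) sqrt(object@N^2 / n) else NA_real_,
       expectedSpacing = if (is.na(object@rho)) NA_real_ else 2 * pi / object@rho)
})

#' Apply the feature-map selection operator
#'
#' Zeroes every stack entry off the graph of the map: entry \code{(x, j)}
#' is kept iff \code{j = Theta(x)}. This is the orthogonal projection onto
#' the stack entries "recorded by the simple cells" of the map; exactly
#' \code{N^2} entries of a dense stack survive.
#'
#' @param F a [TransformStack-class].
#' @param theta a [FeatureMap-class] with matching \code{N} and \code{M}.
#' @return The restricted [TransformStack-class].
#'
#' @examples
#' bank <- gaborBank(16, 3, 3, 4)
#' F <- se2Forward(imageGrid(matrix(rnorm(256), 16)), bank)
#' F0 <- applySelection(F, randomMap(16, 3, seed = 1))
#'
#' @export
setMethod("applySelection", "TransformStack", function(F, theta, ...) {
  stopifnot(is(theta, "FeatureMap"))
  if (nrow(theta@values) != F@N)
    .stopf("map side %d does not match stack N = %d", nrow(theta@values), F@N)
  if (theta@M != F@M)
    .stopf("map M = %d does not match stack M = %d", theta@M, F@M)
  keep <- .graphIndices(theta)
  vals <- array(0i, dim = dim(F@values))
  vals[keep] <- F@values[keep]
  new("TransformStack", values = vals, N = F@N, M = F@M)
})

# Linear indices (1-based, column-major over N x N x M) of the graph of a map.
.graphIndices <- function(theta) {
  N <- nrow(theta@values)
  seq_len(N * N) + as.vector(theta@values) * (N * N)
}

#' @describeIn applySelection alias: the restricted data \code{F0} of the
#'   reconstruction problem.
#' @export
setMethod("restrictStack", "TransformStack", function(F, theta, ...)
  applySelection(F, theta))

# -- accessors / show --------------------------------------------------------

#' @describeIn randomMap index matrix of a feature map.
#' @param x object to extract from.
#' @export
setMethod("gridValues", "FeatureMap", function(x) x@values)

#' @describeIn pinwheelField complex matrix of the field.
#' @param x object to extract from.
#' @export
setMethod("gridValues", "PinwheelField", function(x) x@values)

#' @describeIn detectPinwheels data.frame of locations and winding signs.
#' @param x a [PinwheelSet-class].
#' @export
setMethod("pinwheelPoints", "PinwheelSet", function(x) x@points)

setMethod("show", "FeatureMap", function(object) {
  cat(sprintf("FeatureMap: %d x %d, M = %d, kind = %s%s\n",
              nrow(object@values), ncol(object@values), object@M,
              object@kind,
              if (is.na(object@rho)) "" else sprintf(", rho = %g", object@rho)))
})

setMethod("show", "PinwheelField", function(object) {
  cat(sprintf("PinwheelField: %d x %d, rho = %g (ring %.4g cyc/px), K = %d\n",
              nrow(object@values), ncol(object@values), object@rho,
              object@rho / (2 * pi), object@K))
})

setMethod("show", "PinwheelSet", function(object) {
  np <- nrow(object@points)
  cat(sprintf("PinwheelSet: %d singularities on a %d x %d field (%d +, %d -)\n",
              np, object@N, object@N,
              sum(object@points$sign > 0), sum(object@points$sign < 0)))
})
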
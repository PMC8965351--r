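#' Build a Gabor filter bank
#'
#' Constructs the \code{M}-orientation frequency-domain Gabor bank that
#' discretizes the SE(2) wavelet transform: plane \code{j} holds
#' \deqn{\hat\psi_{\theta_j}(\xi) = \exp(-|\xi + p\,u_j|^2 / (2 s^2)),
#' \qquad u_j = (\cos\theta_j, \sin\theta_j),\ \theta_j = 2\pi j / M,}
#' on the centered integer frequency lattice, stored in standard DFT index
#' order (index \code{k} maps to frequency \code{k} for \code{k < N/2},
#' else \code{k - N}). Each filter is the Fourier transform of a rotated
#' complex modulated Gaussian — the classical simple-cell receptive-field
#' model — with the continuous normalization dropped so filters peak at 1.
#'
#' @param N grid side length in pixels; even, at least 4.
#' @param M number of orientations, at least 1.
#' @param s Gaussian width in DFT frequency-index units; positive.
#' @param p radial center frequency in DFT frequency-index units;
#'   nonnegative.
#'
#' @return A [WaveletBank-class].
#'
#' @examples
#' bank <- gaborBank(N = 64, M = 4, s = 10, p = 16)
#' bank
#'
#' @export
gaborBank <- function(N, M, s, p) {
  if (length(N) != 1L || !is.finite(N) || N < 4 || N %% 2 != 0)
    .stopf("invalid parameter N = %s: must be a single even integer >= 4",
           toString(N))
  if (length(M) != 1L || !is.finite(M) || M < 1 || M %% 1 != 0)
    .stopf("invalid parameter M = %s: must be a single integer >= 1",
           toString(M))
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    .stopf("invalid parameter s = %s: must be a single positive number",
           toString(s))
  if (length(p) != 1L || !is.finite(p) || p < 0)
    .stopf("invalid parameter p = %s: must be a single nonnegative number",
           toString(p))
  N <- as.integer(N); M <- as.integer(M)
  g <- .freqGrid(N)
  filt <- array(0, dim = c(N, N, M))
  for (j in seq_len(M) - 1L) {
    th <- 2 * pi * j / M
    filt[, , j + 1L] <-
      exp(-((g$xi1 + p * cos(th))^2 + (g$xi2 + p * sin(th))^2) / (2 * s^2))
  }
  new("WaveletBank", N = N, M = M, s = as.numeric(s), p = as.numeric(p),
      filters = filt)
}

#' Calderon function of a filter bank
#'
#' Computes \eqn{C(\xi) = \sum_j |\hat\psi_{\theta_j}(\xi)|^2}, the discrete
#' Calderon (admissibility) function. It is strictly positive everywhere on
#' the lattice, so the transform is injective on any bandlimited space at
#' finite \code{N}; its extrema over a frequency ball are the frame bounds.
#'
#' @param bank a [WaveletBank-class].
#' @return A [CalderonProfile-class] (bounds unset until [frameBounds()] is
#'   called).
#'
#' @examples
#' prof <- calderon(gaborBank(64, 4, 10, 16))
#'
#' @export
setMethod("calderon", "WaveletBank", function(bank, ...) {
  C <- matrix(0, bank@N, bank@N)
  for (j in seq_len(bank@M)) C <- C + bank@filters[, , j]^2
  new("CalderonProfile", values = C, R = NA_real_, A = NA_real_, B = NA_real_)
})

.frameBoundsCore <- function(C, R) {
  N <- nrow(C)
  if (length(R) != 1L || !is.finite(R) || R <= 0)
    .stopf("R must be a single positive number")
  mask <- .ballMask(N, R)
  if (!any(mask))
    .stopf("empty frequency ball: no lattice point satisfies |xi| < %g", R)
  A <- min(C[mask]); B <- max(C[mask])
  list(A = A, B = B, ratio = B / A, conditionNumber = sqrt(B / A))
}

#' Frame bounds over a frequency ball
#'
#' Evaluates the lower and upper frame bounds \code{A} and \code{B} of the
#' transform on images bandlimited to the open ball of radius \code{R}:
#' the minimum and maximum of the Calderon function over the lattice points
#' with \code{xi1^2 + xi2^2 < R^2}. The ratio \code{B/A} bounds the squared
#' norms, so the condition number of the transform is reported as
#' \code{sqrt(B/A)}.
#'
#' @param object a [CalderonProfile-class] or [WaveletBank-class].
#' @param R ball radius; the open ball must contain a lattice point.
#' @return A list with elements \code{A}, \code{B}, \code{ratio} (=B/A) and
#'   \code{conditionNumber} (=sqrt(B/A)).
#'
#' @examples
#' frameBounds(gaborBank(64, 4, 10, 16), R = 24)
#'
#' @export
setMethod("frameBounds", "CalderonProfile", function(object, R, ...) {
  .frameBoundsCore(object@values, R)
})

#' @rdname frameBounds
#' @export
setMethod("frameBounds", "WaveletBank", function(object, R, ...) {
  .frameBoundsCore(calderon(object)@values, R)
})

#' Dual filter bank
#'
#' Builds the reconstructing filters
#' \eqn{\hat\gamma_j(\xi) = \chi_{B_R}(\xi)\, \hat\psi_{\theta_j}(\xi) /
#' C(\xi)}: zero outside the open ball of radius \code{R}, and satisfying
#' \eqn{C(\xi)\hat\gamma_j(\xi) = \hat\psi_{\theta_j}(\xi)} inside it. The
#' adjoint transform taken with the dual bank inverts the forward transform
#' exactly on images bandlimited to \code{R}.
#'
#' @param bank a [WaveletBank-class].
#' @param R ball radius.
#' @return A [DualBank-class].
#'
#' @examples
#' dual <- dualBank(gaborBank(64, 4, 10, 16), R = 24)
#'
#' @export
setMethod("dualBank", "WaveletBank", function(bank, R, ...) {
  prof <- calderon(bank)
  fb <- .frameBoundsCore(prof@values, R)   # also validates R / nonempty ball
  if (fb$A <= 0)
    .stopf("degenerate Calderon function: lower frame bound is zero")
  mask <- .ballMask(bank@N, R)
  filt <- array(0, dim = dim(bank@filters))
  for (j in seq_len(bank@M)) {
    gj <- bank@filters[, , j] / prof@values
    gj[!mask] <- 0
    filt[, , j] <- gj
  }
  new("DualBank", N = bank@N, M = bank@M, s = bank@s, p = bank@p,
      R = as.numeric(R), filters = filt)
})

# -- accessors / show --------------------------------------------------------

#' @describeIn gaborBank bank parameters as a named list (N, M, s, p).
#' @param x a bank object.
#' @export
setMethod("bankParams", "WaveletBank", function(x)
  list(N = x@N, M = x@M, s = x@s, p = x@p))

#' @rdname dualBank
#' @param x a bank object.
#' @export
setMethod("bankParams", "DualBank", function(x)
  list(N = x@N, M = x@M, s = x@s, p = x@p, R = x@R))

#' @describeIn gaborBank the N x N x M array of frequency-domain filters.
#' @export
setMethod("filters", "WaveletBank", function(x) x@filters)

#' @rdname dualBank
#' @export
setMethod("filters", "DualBank", function(x) x@filters)

#' @describeIn calderon the Calderon matrix of a profile.
#' @export
setMethod("gridValues", "CalderonProfile", function(x) x@values)

setMethod("show", "WaveletBank", function(object) {
  cat(sprintf("WaveletBank: %d x %d grid, M = %d orientations, s = %g, p = %g\n",
              object@N, object@N, object@M, object@s, object@p))
})

setMethod("show", "DualBank", function(object) {
  cat(sprintf(
    "DualBank: %d x %d grid, M = %d, s = %g, p = %g, bandlimit R = %g\n",
    object@N, object@N, object@M, object@s, object@p, object@R))
})

setMethod("show", "CalderonProfile", function(object) {
  cat(sprintf("CalderonProfile: %d x %d lattice, range [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values), min(object@values), max(object@values)))
  if (!is.na(object@A))
    cat(sprintf("  frame bounds over |xi| < %g: A = %.4g, B = %.4g (B/A = %.4g)\n",
                object@R, object@A, object@B, object@B / object@A))
})
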
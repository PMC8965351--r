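#' Construct an image grid
#'
#' @param values square numeric matrix of pixel values.
#' @param bitDepth \code{"8bit"} (integers in 0..255) or \code{"float"}.
#' @param bandlimitRadius radius of the spectral ball the image is known to
#'   be supported in, or \code{NA}.
#' @return An [ImageGrid-class].
#'
#' @examples
#' img <- imageGrid(matrix(0, 16, 16), bitDepth = "8bit")
#'
#' @export
imageGrid <- function(values, bitDepth = c("float", "8bit"),
                      bandlimitRadius = NA_real_) {
  bitDepth <- match.arg(bitDepth)
  new("ImageGrid", values = values, bitDepth = bitDepth,
      bandlimitRadius = as.numeric(bandlimitRadius))
}

#' Forward SE(2) wavelet transform
#'
#' Circularly convolves the image with every rotated wavelet of the bank:
#' in the frequency domain \eqn{\hat F(\xi, j) = \hat f(\xi)\,
#' \hat\psi_{\theta_j}(\xi)}. The result is returned in the spatial domain
#' as a complex \code{N x N x M} stack.
#'
#' @param f an [ImageGrid-class] or square numeric matrix with side
#'   matching the bank.
#' @param bank a [WaveletBank-class].
#' @return A [TransformStack-class].
#'
#' @examples
#' bank <- gaborBank(16, 3, 3, 4)
#' F <- se2Forward(imageGrid(matrix(rnorm(256), 16)), bank)
#'
#' @export
setMethod("se2Forward", "ANY", function(f, bank, ...) {
  stopifnot(is(bank, "WaveletBank"))
  v <- .asMatrix(f)
  if (nrow(v) != bank@N || ncol(v) != bank@N)
    .stopf("image side %d x %d does not match bank grid N = %d",
           nrow(v), ncol(v), bank@N)
  fhat <- .fft2(v)
  vals <- array(0i, dim = c(bank@N, bank@N, bank@M))
  for (j in seq_len(bank@M))
    vals[, , j] <- .ifft2(fhat * bank@filters[, , j])
  new("TransformStack", values = vals, N = bank@N, M = bank@M)
})

#' Adjoint SE(2) wavelet transform
#'
#' Computes \eqn{\hat f(\xi) = \sum_j \hat F(\xi, j)\,
#' \overline{\hat\phi_j(\xi)}} where \eqn{\phi_j} are the filters of the
#' supplied bank, and returns the spatial-domain result. With a
#' [DualBank-class] this is the inverse transform on images bandlimited to
#' the dual's radius; with the analysis [WaveletBank-class] it is the plain
#' adjoint.
#'
#' The returned matrix is complex: the adjoint of an arbitrary stack need
#' not be real. Use [reconstructImage()] for the real-image read-out with
#' an imaginary-residual diagnostic.
#'
#' @param F a [TransformStack-class].
#' @param bank a [WaveletBank-class] or [DualBank-class] with matching
#'   dimensions.
#' @return A complex \code{N x N} matrix.
#'
#' @examples
#' bank <- gaborBank(16, 3, 3, 4)
#' dual <- dualBank(bank, R = 6)
#' f <- bandlimit(imageGrid(matrix(rnorm(256), 16)), 6)
#' g <- se2Adjoint(se2Forward(f, bank), dual)   # equals f up to roundoff
#'
#' @export
setMethod("se2Adjoint", "TransformStack", function(F, bank, ...) {
  if (!(is(bank, "WaveletBank") || is(bank, "DualBank")))
    .stopf("bank must be a WaveletBank or DualBank")
  if (F@N != bank@N || F@M != bank@M)
    .stopf("stack dimensions (%d, %d) do not match bank (%d, %d)",
           F@N, F@M, bank@N, bank@M)
  fhat <- matrix(0i, F@N, F@N)
  for (j in seq_len(F@M))
    fhat <- fhat + .fft2(F@values[, , j]) * Conj(bank@filters[, , j])
  .ifft2(fhat)
})

#' Bandlimit an image to a frequency ball
#'
#' Multiplies the image spectrum by the indicator of the open ball
#' \code{xi1^2 + xi2^2 < R^2} and records the radius. The output is a float
#' image (bandlimiting almost never preserves 8-bit integrality).
#'
#' @param f an [ImageGrid-class] or square numeric matrix.
#' @param R ball radius, positive.
#' @return An [ImageGrid-class] with \code{bandlimitRadius = R}.
#'
#' @examples
#' f <- bandlimit(imageGrid(matrix(rnorm(64), 8)), 3)
#'
#' @export
setMethod("bandlimit", "ANY", function(f, R, ...) {
  v <- .asMatrix(f)
  if (length(R) != 1L || !is.finite(R) || R <= 0)
    .stopf("R must be a single positive number")
  mask <- .ballMask(nrow(v), R)
  fhat <- .fft2(v)
  fhat[!mask] <- 0
  out <- Re(.ifft2(fhat))
  new("ImageGrid", values = out, bitDepth = "float",
      bandlimitRadius = as.numeric(R))
})

# -- accessors / show --------------------------------------------------------

#' @describeIn imageGrid pixel-value matrix of an image.
#' @export
setMethod("gridValues", "ImageGrid", function(x) x@values)

#' @describeIn se2Forward the complex N x N x M array of a stack.
#' @export
setMethod("stackValues", "TransformStack", function(x) x@values)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %d x %d, %s, range [%.4g, %.4g]%s\n",
              nrow(object@values), ncol(object@values), object@bitDepth,
              min(object@values), max(object@values),
              if (is.na(object@bandlimitRadius)) "" else
                sprintf(", bandlimited to R = %g", object@bandlimitRadius)))
})

setMethod("show", "TransformStack", function(object) {
  cat(sprintf("TransformStack: %d x %d x %d complex, energy %.6g\n",
              object@N, object@N, object@M, sum(Mod(object@values)^2)))
})
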
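# Orthogonal projection onto the range of the SE(2) transform (the
# reproducing-kernel subspace) and kernel visualization.

.checkBankDualMatch <- function(bank, dual) {
  if (bank@N != dual@N || bank@M != dual@M ||
      bank@s != dual@s || bank@p != dual@p)
    .stopf("dual bank was not built from this wavelet bank (parameter mismatch)")
}

#' Project a stack onto the reproducing-kernel subspace
#'
#' Applies the orthogonal projection of stack space onto the range of the
#' SE(2) transform on images bandlimited to the dual's radius. In the
#' frequency domain,
#' \deqn{\widehat{\mathbb{P}F}(\xi, j) = \frac{\chi_{B_R}(\xi)}{C(\xi)}
#' \hat\psi_{\theta_j}(\xi) \sum_\ell \hat F(\xi, \ell)\,
#' \overline{\hat\psi_{\theta_\ell}(\xi)},}
#' which equals \code{se2Forward(se2Adjoint(F, dual), bank)} under circular
#' convolution but costs a single frequency-domain pass. The operator is
#' idempotent, self-adjoint and non-expansive.
#'
#' @param F a [TransformStack-class].
#' @param bank the analysis [WaveletBank-class].
#' @param dual the [DualBank-class] built from \code{bank} (same N, M, s,
#'   p); its radius fixes the projection.
#' @return The projected [TransformStack-class].
#'
#' @examples
#' bank <- gaborBank(16, 3, 3, 4); dual <- dualBank(bank, 6)
#' F <- se2Forward(imageGrid(matrix(rnorm(256), 16)), bank)
#' P <- rkhsProject(F, bank, dual)   # = F: the stack is in the range
#'
#' @export
setMethod("rkhsProject", "TransformStack", function(F, bank, dual, ...) {
  stopifnot(is(bank, "WaveletBank"), is(dual, "DualBank"))
  .checkBankDualMatch(bank, dual)
  if (F@N != bank@N || F@M != bank@M)
    .stopf("stack dimensions (%d, %d) do not match bank (%d, %d)",
           F@N, F@M, bank@N, bank@M)
  mult <- .projMultiplier(bank, dual@R)
  S <- matrix(0i, F@N, F@N)
  for (j in seq_len(F@M))
    S <- S + .fft2(F@values[, , j]) * Conj(bank@filters[, , j])
  T <- S * mult
  vals <- array(0i, dim = dim(F@values))
  for (j in seq_len(F@M))
    vals[, , j] <- .ifft2(T * bank@filters[, , j])
  new("TransformStack", values = vals, N = F@N, M = F@M)
})

# chi_{B_R}/C on the lattice; shared by the projection and the C++ loop.
.projMultiplier <- function(bank, R) {
  C <- calderon(bank)@values
  mask <- .ballMask(bank@N, R)
  mult <- 1 / C
  mult[!mask] <- 0
  mult
}

#' Spatial slices of the reproducing kernel
#'
#' Returns the \code{M} spatial planes generated by projecting a unit
#' impulse placed at the origin of plane \code{jRef}: slice \code{j} is the
#' inverse DFT of \eqn{\chi_{B_R}\,\hat\psi_{\theta_j}\,
#' \overline{\hat\psi_{\theta_{jRef}}} / C}. These are the columns of the
#' reproducing kernel of the transform's range, useful for visualizing how
#' information spreads across positions and orientations.
#'
#' @param bank the analysis [WaveletBank-class].
#' @param dual the matching [DualBank-class].
#' @param jRef reference orientation index in \code{0..M-1}.
#' @return A complex \code{N x N x M} array.
#'
#' @examples
#' bank <- gaborBank(16, 3, 3, 4); dual <- dualBank(bank, 6)
#' ker <- kernelSlices(bank, dual, jRef = 0)
#'
#' @export
setMethod("kernelSlices", "WaveletBank", function(bank, dual, jRef, ...) {
  stopifnot(is(dual, "DualBank"))
  .checkBankDualMatch(bank, dual)
  if (length(jRef) != 1L || jRef %% 1 != 0 || jRef < 0 || jRef >= bank@M)
    .stopf("jRef = %s out of range 0..%d", toString(jRef), bank@M - 1L)
  ref <- dual@filters[, , jRef + 1L]   # chi * psi_jRef / C
  out <- array(0i, dim = c(bank@N, bank@N, bank@M))
  for (j in seq_len(bank@M))
    out[, , j] <- .ifft2(bank@filters[, , j] * Conj(ref))
  out
})
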
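# The project-and-replace iteration, its error metric, and image read-out.

#' Percent reconstruction error
#'
#' The rescaled Euclidean error
#' \deqn{\Delta = 100\,\|f_{\mathrm{ref}} - f_{\mathrm{rec}}\|_2 / (255 N),}
#' i.e. 100 times the root-mean-square pixel difference divided by the
#' 8-bit dynamic range: identical images give 0, full-range disagreement
#' on every pixel gives 100.
#'
#' @param reference,reconstruction [ImageGrid-class] objects or numeric
#'   matrices of the same side length.
#' @return The error, in percent of the 8-bit range.
#'
#' @examples
#' errorDelta(matrix(255, 8, 8), matrix(0, 8, 8))   # 100
#'
#' @export
setMethod("errorDelta", "ANY", function(reference, reconstruction, ...) {
  a <- .asMatrix(reference)
  b <- .asMatrix(reconstruction)
  if (!identical(dim(a), dim(b)))
    .stopf("image dimensions differ: %s vs %s",
           paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  100 * sqrt(mean((a - b)^2)) / 255
})

#' Read an image out of a transform stack
#'
#' Applies the adjoint transform with the dual bank and returns the real
#' part as a float [ImageGrid-class]. The maximum absolute imaginary part
#' — which is pure roundoff when the stack lies in the transform's range
#' over real images, but can be substantial otherwise — is attached as
#' attribute \code{imagResidual} rather than discarded silently.
#'
#' @param H a [TransformStack-class].
#' @param dual a [DualBank-class].
#' @return An [ImageGrid-class]; \code{attr(, "imagResidual")} holds the
#'   imaginary-part diagnostic.
#'
#' @examples
#' bank <- gaborBank(16, 3, 3, 4); dual <- dualBank(bank, 6)
#' f <- bandlimit(imageGrid(matrix(rnorm(256), 16)), 6)
#' out <- reconstructImage(se2Forward(f, bank), dual)
#'
#' @export
setMethod("reconstructImage", "TransformStack", function(H, dual, ...) {
  g <- se2Adjoint(H, dual)
  img <- imageGrid(Re(g), bitDepth = "float", bandlimitRadius = dual@R)
  attr(img, "imagResidual") <- max(abs(Im(g)))
  img
})

#' Project-and-replace reconstruction iteration
#'
#' Iterates, from the restricted data \code{F0} (the transform values
#' retained on the graph of the feature map),
#' \deqn{H_n = \mathbb{P} F_{n-1}, \qquad
#'       F_n = (1 - \mathbb{O}_\Theta) H_n + F_0,}
#' where \eqn{\mathbb{P}} is the reproducing-kernel projection and
#' \eqn{\mathbb{O}_\Theta} the selection operator: project the current
#' guess onto the range of the transform, then replace the entries on the
#' graph with the known data. When the kernel of the selection meets the
#' range of the projection only at zero, the iterates converge to the full
#' transform of the original (bandlimited) image, with errors decaying
#' geometrically at rate \code{||Q_perp P||} (see [checkUniqueness()]).
#'
#' When a \code{reference} image is supplied, the percent error
#' [errorDelta()] between it and the read-out \eqn{W^*_\gamma H_n} is
#' recorded every \code{recordStride} iterations (and always at the final
#' one).
#'
#' @param F0 the restricted [TransformStack-class]; must vanish off the
#'   graph of \code{theta}.
#' @param theta the [FeatureMap-class] that produced \code{F0}.
#' @param bank the analysis [WaveletBank-class].
#' @param dual the matching [DualBank-class]; its radius fixes the
#'   projection.
#' @param nIter number of iterations, at least 1.
#' @param recordStride record the error every this many iterations.
#' @param reference optional [ImageGrid-class] or matrix to measure the
#'   error against.
#' @param stopTol optional early-stop threshold on the stack change
#'   \code{||F_n - F_(n-1)||}; 0 (default) disables it.
#' @return A [ReconstructionTrace-class].
#'
#' @examples
#' bank <- gaborBank(16, 3, 3, 4); dual <- dualBank(bank, 6)
#' f <- bandlimit(imageGrid(matrix(rnorm(256), 16)), 6)
#' th <- randomMap(16, 3, seed = 1)
#' F0 <- restrictStack(se2Forward(f, bank), th)
#' tr <- projectAndReplace(F0, th, bank, dual, nIter = 20, reference = f)
#'
#' @export
setMethod("projectAndReplace", "TransformStack",
  function(F0, theta, bank, dual, nIter = 100L, recordStride = 1L,
           reference = NULL, stopTol = 0, ...) {
    stopifnot(is(theta, "FeatureMap"), is(bank, "WaveletBank"),
              is(dual, "DualBank"))
    .checkBankDualMatch(bank, dual)
    if (F0@N != bank@N || F0@M != bank@M)
      .stopf("stack dimensions (%d, %d) do not match bank (%d, %d)",
             F0@N, F0@M, bank@N, bank@M)
    if (nrow(theta@values) != F0@N || theta@M != F0@M)
      .stopf("feature map does not match the stack dimensions")
    if (nIter < 1) .stopf("nIter must be at least 1")
    if (recordStride < 1) .stopf("recordStride must be at least 1")
    keep <- .graphIndices(theta)
    off <- F0@values[-keep]
    if (length(off) && max(Mod(off)) > 0)
      .stopf("F0 has mass off the graph of the feature map (max |value| = %g); restrict it first",
             max(Mod(off)))
    refMat <- if (is.null(reference)) matrix(0, 0, 0) else .asMatrix(reference)
    if (nrow(refMat) > 0 && nrow(refMat) != F0@N)
      .stopf("reference side %d does not match N = %d", nrow(refMat), F0@N)

    res <- .cppProjectReplace(F0@values, bank@filters,
                              .projMultiplier(bank, dual@R),
                              keep - 1L, as.integer(nIter),
                              as.integer(recordStride), refMat,
                              as.numeric(stopTol))
    finalH <- new("TransformStack", values = res$H, N = F0@N, M = F0@M)
    img <- reconstructImage(finalH, dual)
    new("ReconstructionTrace",
        deltas = as.numeric(res$deltas),
        iterations = as.integer(res$iterations),
        finalH = res$H, finalF = res$F, finalImage = img,
        imagResidual = attr(img, "imagResidual"),
        nIter = as.integer(res$nIter))
  })

# Pure-R reference implementation of the same iteration, kept as executable
# documentation and cross-checked against the C++ path in the tests.
.projectAndReplaceR <- function(F0, theta, bank, dual, nIter,
                                reference = NULL, keepSteps = FALSE) {
  keep <- .graphIndices(theta)
  F0sel <- F0@values[keep]
  F <- F0
  deltas <- numeric(0)
  steps <- if (keepSteps) vector("list", nIter) else NULL
  H <- NULL
  for (n in seq_len(nIter)) {
    H <- rkhsProject(F, bank, dual)
    vals <- H@values
    vals[keep] <- F0sel
    F <- new("TransformStack", values = vals, N = F0@N, M = F0@M)
    if (!is.null(reference)) {
      rec <- Re(se2Adjoint(H, dual))
      deltas <- c(deltas, errorDelta(reference, rec))
    }
    if (keepSteps) steps[[n]] <- F
  }
  list(F = F, H = H, deltas = deltas, steps = steps)
}

# -- accessors / show --------------------------------------------------------

#' @describeIn projectAndReplace recorded percent errors of a trace.
#' @param x a [ReconstructionTrace-class].
#' @export
setMethod("deltas", "ReconstructionTrace", function(x) {
  stats::setNames(x@deltas, if (length(x@deltas)) x@iterations else NULL)
})

#' @describeIn projectAndReplace final read-out image of a trace.
#' @export
setMethod("finalImage", "ReconstructionTrace", function(x) x@finalImage)

setMethod("show", "ReconstructionTrace", function(object) {
  cat(sprintf("ReconstructionTrace: %d iterations, imaginary residual %.3g\n",
              object@nIter, object@imagResidual))
  if (length(object@deltas))
    cat(sprintf("  delta: %.4g%% at n = %d -> %.4g%% at n = %d\n",
                object@deltas[1], object@iterations[1],
                object@deltas[length(object@deltas)],
                object@iterations[length(object@iterations)]))
})
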
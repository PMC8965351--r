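#' @import methods
NULL

#' Gabor filter bank for the discrete SE(2) wavelet transform
#'
#' An \code{M}-orientation bank of real Gaussian filters in the frequency
#' domain. Plane \code{j} (0-based) holds
#' \code{exp(-|xi + p u_j|^2 / (2 s^2))} with \code{u_j = (cos(2*pi*j/M),
#' sin(2*pi*j/M))} on the centered integer frequency lattice
#' \code{\{-N/2, ..., N/2-1\}^2}, stored in standard DFT index order. These
#' are the Fourier transforms of rotated copies of a complex modulated
#' Gaussian, the classical model of a V1 simple-cell receptive field; the
#' continuous normalization factor is dropped so every filter peaks at 1.
#'
#' @slot N grid side length (pixels, even).
#' @slot M number of orientations.
#' @slot s Gaussian width, in DFT frequency-index units.
#' @slot p radial center frequency, in DFT frequency-index units.
#' @slot filters \code{N x N x M} real array of frequency-domain filters.
#'
#' @seealso [gaborBank()], [calderon()], [dualBank()], [se2Forward()]
#' @export
setClass("WaveletBank",
  representation(N = "integer", M = "integer", s = "numeric", p = "numeric",
                 filters = "array"),
  validity = function(object) {
    msg <- character()
    if (length(object@N) != 1L || object@N < 4L || object@N %% 2L != 0L)
      msg <- c(msg, "N must be a single even integer >= 4")
    if (length(object@M) != 1L || object@M < 1L)
      msg <- c(msg, "M must be a single integer >= 1")
    if (!identical(dim(object@filters), c(object@N, object@N, object@M)))
      msg <- c(msg, "filters must be an N x N x M array")
    if (any(!is.finite(object@filters)) ||
        any(object@filters <= 0) || any(object@filters > 1))
      msg <- c(msg, "filter values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Dual (reconstructing) filter bank
#'
#' Frequency-domain dual filters \code{gamma_j = chi_BR * psi_j / C} where
#' \code{C} is the Calderon function of the generating bank and
#' \code{chi_BR} the indicator of the open frequency ball of radius
#' \code{R}. The adjoint transform taken with this bank inverts the forward
#' transform exactly on images bandlimited to \code{R}.
#'
#' @slot N,M,s,p parameters of the generating [WaveletBank-class].
#' @slot R bandlimiting ball radius.
#' @slot filters \code{N x N x M} real array, zero outside the ball.
#'
#' @seealso [dualBank()], [se2Adjoint()]
#' @export
setClass("DualBank",
  representation(N = "integer", M = "integer", s = "numeric", p = "numeric",
                 R = "numeric", filters = "array"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@filters), c(object@N, object@N, object@M)))
      msg <- c(msg, "filters must be an N x N x M array")
    if (length(object@R) != 1L || !is.finite(object@R) || object@R <= 0)
      msg <- c(msg, "R must be a single positive number")
    if (any(!is.finite(object@filters)))
      msg <- c(msg, "filter values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Calderon function of a filter bank
#'
#' The Calderon (admissibility) function \code{C(xi) = sum_j |psi_j(xi)|^2}
#' on the frequency lattice, together with, once [frameBounds()] has been
#' evaluated, the ball radius \code{R} and the frame bounds \code{A}
#' (minimum of \code{C} over the open ball) and \code{B} (maximum). The
#' bounds govern invertibility of the transform on bandlimited images and
#' its numerical conditioning.
#'
#' @slot values the Calderon matrix, \code{N x N} positive, in DFT index order.
#' @slot R ball radius (\code{NA} until bounds are evaluated).
#' @slot A,B lower/upper frame bound over the ball (\code{NA} until
#'   evaluated).
#'
#' @seealso [calderon()], [frameBounds()]
#' @export
setClass("CalderonProfile",
  representation(values = "matrix", R = "numeric", A = "numeric", B = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@values)) || any(object@values <= 0))
      msg <- c(msg, "Calderon function must be strictly positive and finite")
    if (!is.na(object@A) && !is.na(object@B) &&
        !(object@A > 0 && object@A <= object@B))
      msg <- c(msg, "frame bounds must satisfy 0 < A <= B")
    if (length(msg)) msg else TRUE
  })

#' Square grayscale image
#'
#' A real \code{N x N} image. 8-bit images carry integer values in
#' \code{0..255}; float images arbitrary finite reals. If the image has
#' been bandlimited, the ball radius is recorded in
#' \code{bandlimitRadius}.
#'
#' @slot values \code{N x N} numeric matrix; row/column index minus one is
#'   the pixel coordinate.
#' @slot bitDepth \code{"8bit"} or \code{"float"}.
#' @slot bandlimitRadius radius of the spectral ball the image is supported
#'   in, or \code{NA} if none has been imposed.
#'
#' @seealso [imageGrid()], [bandlimit()], [phantom()]
#' @export
setClass("ImageGrid",
  representation(values = "matrix", bitDepth = "character",
                 bandlimitRadius = "numeric"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "image must be square")
    if (any(!is.finite(v))) msg <- c(msg, "image values must be finite")
    if (!object@bitDepth %in% c("8bit", "float"))
      msg <- c(msg, "bitDepth must be '8bit' or 'float'")
    if (object@bitDepth == "8bit" &&
        (any(v != round(v)) || any(v < 0) || any(v > 255)))
      msg <- c(msg, "8-bit images must hold integers in 0..255")
    if (length(msg)) msg else TRUE
  })

#' SE(2) transform stack
#'
#' A complex \code{N x N x M} array in the spatial domain: plane \code{j}
#' holds the circular convolution of an image with the rotated wavelet of
#' orientation \code{theta_j = 2*pi*j/M}. This is the object the forward
#' transform produces, the reproducing-kernel projection acts on, and the
#' project-and-replace iteration evolves.
#'
#' @slot values complex \code{N x N x M} array.
#' @slot N,M dimensions.
#'
#' @seealso [se2Forward()], [rkhsProject()], [projectAndReplace()]
#' @export
setClass("TransformStack",
  representation(values = "array", N = "integer", M = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), c(object@N, object@N, object@M)))
      msg <- c(msg, "values must be an N x N x M array")
    if (any(!is.finite(Re(object@values))) || any(!is.finite(Im(object@values))))
      msg <- c(msg, "stack entries must be finite")
    if (length(msg)) msg else TRUE
  })

#' Orientation-preference feature map
#'
#' An \code{N x N} assignment of one orientation index in \code{0..M-1} to
#' every pixel — the discrete analogue of the orientation-preference maps
#' measured in the primary visual cortex. Its graph is the set of stack
#' entries that the selection operator retains.
#'
#' @slot values integer \code{N x N} matrix with entries in \code{0..M-1}.
#' @slot M number of orientations.
#' @slot kind one of \code{"random"}, \code{"pinwheel"}, \code{"constant"}.
#' @slot rho spatial wave number of the generating pinwheel field
#'   (radians/pixel; \code{NA} for other kinds).
#' @slot seed RNG seed used to generate the map (\code{NA} for constant
#'   maps).
#'
#' @seealso [randomMap()], [quantizeMap()], [constantMap()],
#'   [applySelection()]
#' @export
setClass("FeatureMap",
  representation(values = "matrix", M = "integer", kind = "character",
                 rho = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "map must be square")
    if (any(v != round(v)) || any(v < 0) || any(v >= object@M))
      msg <- c(msg, "map values must be integers in 0..M-1")
    if (!object@kind %in% c("random", "pinwheel", "constant"))
      msg <- c(msg, "kind must be 'random', 'pinwheel' or 'constant'")
    if (length(msg)) msg else TRUE
  })

#' Complex pinwheel field
#'
#' A superposition of \code{K} unit-frequency plane waves with random
#' phases, all of spatial wave number \code{rho}: the classical
#' construction of a quasiperiodic orientation-preference map. Its phase
#' carries +/-1 singularities (pinwheels) and its spectrum concentrates on
#' a ring of continuous radius \code{rho/(2*pi)} cycles/pixel.
#'
#' @slot values complex \code{N x N} matrix.
#' @slot rho wave number, radians per pixel.
#' @slot K number of angular quadrature samples.
#' @slot seed RNG seed for the random phases.
#'
#' @seealso [pinwheelField()], [quantizeMap()], [detectPinwheels()]
#' @export
setClass("PinwheelField",
  representation(values = "matrix", rho = "numeric", K = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.complex(object@values)) msg <- c(msg, "values must be complex")
    if (nrow(object@values) != ncol(object@values))
      msg <- c(msg, "field must be square")
    if (object@rho <= 0) msg <- c(msg, "rho must be positive")
    if (object@K < 8L) msg <- c(msg, "K must be at least 8")
    if (length(msg)) msg else TRUE
  })

#' Detected phase singularities of a pinwheel field
#'
#' Locations (plaquette centers, 0-based pixel coordinates + 0.5) and
#' winding signs of the points around which the field's phase winds by
#' +/- 2*pi, computed with periodic boundaries.
#'
#' @slot points data.frame with columns \code{x1}, \code{x2},
#'   \code{sign} (+1 or -1).
#' @slot N side length of the generating field.
#' @slot rho wave number of the generating field.
#'
#' @seealso [detectPinwheels()], [pinwheelSpacing()]
#' @export
setClass("PinwheelSet",
  representation(points = "data.frame", N = "integer", rho = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(c("x1", "x2", "sign") %in% names(object@points)))
      msg <- c(msg, "points must have columns x1, x2, sign")
    if (nrow(object@points) &&
        !all(object@points$sign %in% c(-1, 1)))
      msg <- c(msg, "winding signs must be +1 or -1")
    if (length(msg)) msg else TRUE
  })

#' Dense matrix form of the projection and selection operators
#'
#' Explicit \code{(N^2 M) x (N^2 M)} matrix \code{P} of the
#' reproducing-kernel projection and the 0/1 diagonal of the feature-map
#' selection operator \code{Q}, for desk-scale instances. Stacks are
#' vectorised in column-major order, plane by plane, so the linear index of
#' entry \code{(x1, x2, j)} (0-based) is \code{x1 + N*x2 + N^2*j + 1}.
#'
#' @slot P complex projection matrix.
#' @slot qdiag logical vector, \code{TRUE} on the graph of the feature map.
#' @slot N,M,s,p,R generating parameters.
#' @slot theta the [FeatureMap-class] behind \code{Q}.
#'
#' @seealso [denseOperators()], [checkUniqueness()], [verifyTheorem5()]
#' @export
setClass("DenseOperators",
  representation(P = "matrix", qdiag = "logical", N = "integer",
                 M = "integer", s = "numeric", p = "numeric", R = "numeric",
                 theta = "FeatureMap"),
  validity = function(object) {
    n <- as.numeric(object@N)^2 * object@M
    msg <- character()
    if (!all(dim(object@P) == n))
      msg <- c(msg, "P must be (N^2 M) x (N^2 M)")
    if (length(object@qdiag) != n)
      msg <- c(msg, "qdiag must have length N^2 M")
    if (length(msg)) msg else TRUE
  })

#' Solvability verdict for the restricted reconstruction problem
#'
#' Reports whether the kernel of the selection operator meets the range of
#' the projection only at zero — the condition under which the restricted
#' data determine the stack uniquely and the project-and-replace iteration
#' converges — together with the smallest singular value of \code{Q}
#' restricted to \code{Ran(P)} and the contraction factor
#' \code{||Q_perp P||} that governs the convergence rate.
#'
#' @slot sigmaMin smallest singular value of \code{Q V}, \code{V} an
#'   orthonormal basis of \code{Ran(P)}.
#' @slot contraction spectral norm of \code{Q_perp P} (largest singular
#'   value; a per-step bound on the error recursion).
#' @slot asymptoticRate spectral radius of \code{Q_perp P}; the sharp
#'   asymptotic per-step decay rate of the iteration error (for products of
#'   orthogonal projections it equals the squared norm, generically).
#' @slot solvable \code{TRUE} when \code{sigmaMin} exceeds the tolerance.
#' @slot status \code{"solvable"}, \code{"ill-conditioned"} or
#'   \code{"not-solvable"}.
#' @slot rankP rank of the projection (count of eigenvalues above 1/2).
#' @slot dims ambient dimension \code{N^2 M}.
#'
#' @seealso [checkUniqueness()]
#' @export
setClass("SolvabilityReport",
  representation(sigmaMin = "numeric", contraction = "numeric",
                 asymptoticRate = "numeric", solvable = "logical",
                 status = "character", rankP = "integer", dims = "integer"))

#' Trace of a project-and-replace reconstruction run
#'
#' Holds the per-iteration percent errors (when a reference image was
#' supplied), the iterations at which they were recorded, the final
#' projected stack \code{H}, the final replaced stack \code{F}, the
#' read-out image, and the maximum absolute imaginary part discarded when
#' reading the image out.
#'
#' @slot deltas percent errors (may be empty when no reference was given).
#' @slot iterations iteration numbers at which deltas were recorded.
#' @slot finalH,finalF complex \code{N x N x M} arrays.
#' @slot finalImage the [ImageGrid-class] read out from \code{finalH}.
#' @slot imagResidual max absolute imaginary part of the read-out.
#' @slot nIter number of iterations actually performed.
#'
#' @seealso [projectAndReplace()], [saveTrace()]
#' @export
setClass("ReconstructionTrace",
  representation(deltas = "numeric", iterations = "integer",
                 finalH = "array", finalF = "array",
                 finalImage = "ImageGrid", imagResidual = "numeric",
                 nIter = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@deltas < 0)) msg <- c(msg, "deltas must be nonnegative")
    if (length(object@deltas) &&
        length(object@deltas) != length(object@iterations))
      msg <- c(msg, "deltas and iterations must have matching length")
    if (length(msg)) msg else TRUE
  })
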
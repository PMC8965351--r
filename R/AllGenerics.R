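# Generics. Implementations live in the topic files.

#' @export
setGeneric("calderon", function(bank, ...) standardGeneric("calderon"))

#' @export
setGeneric("frameBounds", function(object, R, ...) standardGeneric("frameBounds"))

#' @export
setGeneric("dualBank", function(bank, R, ...) standardGeneric("dualBank"))

#' @export
setGeneric("se2Forward", function(f, bank, ...) standardGeneric("se2Forward"))

#' @export
setGeneric("se2Adjoint", function(F, bank, ...) standardGeneric("se2Adjoint"))

#' @export
setGeneric("bandlimit", function(f, R, ...) standardGeneric("bandlimit"))

#' @export
setGeneric("rkhsProject", function(F, bank, dual, ...) standardGeneric("rkhsProject"))

#' @export
setGeneric("kernelSlices", function(bank, dual, jRef, ...) standardGeneric("kernelSlices"))

#' @export
setGeneric("quantizeMap", function(field, M, ...) standardGeneric("quantizeMap"))

#' @export
setGeneric("detectPinwheels", function(field, ...) standardGeneric("detectPinwheels"))

#' @export
setGeneric("pinwheelSpacing", function(object, ...) standardGeneric("pinwheelSpacing"))

#' @export
setGeneric("applySelection", function(F, theta, ...) standardGeneric("applySelection"))

#' @export
setGeneric("restrictStack", function(F, theta, ...) standardGeneric("restrictStack"))

#' @export
setGeneric("errorDelta", function(reference, reconstruction, ...) standardGeneric("errorDelta"))

#' @export
setGeneric("projectAndReplace", function(F0, theta, bank, dual, ...) standardGeneric("projectAndReplace"))

#' @export
setGeneric("reconstructImage", function(H, dual, ...) standardGeneric("reconstructImage"))

#' @export
setGeneric("denseOperators", function(bank, theta, R, ...) standardGeneric("denseOperators"))

#' @export
setGeneric("checkUniqueness", function(ops, ...) standardGeneric("checkUniqueness"))

#' @export
setGeneric("verifyTheorem5", function(ops, f, nIter, ...) standardGeneric("verifyTheorem5"))

# -- accessors ---------------------------------------------------------------

#' @export
setGeneric("bankParams", function(x) standardGeneric("bankParams"))

#' @export
setGeneric("filters", function(x) standardGeneric("filters"))

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @export
setGeneric("stackValues", function(x) standardGeneric("stackValues"))

#' @export
setGeneric("deltas", function(x) standardGeneric("deltas"))

#' @export
setGeneric("finalImage", function(x) standardGeneric("finalImage"))

#' @export
setGeneric("pinwheelPoints", function(x) standardGeneric("pinwheelPoints"))
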
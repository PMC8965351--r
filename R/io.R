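# Readers and writers: 8-bit grayscale PNG, 32-bit TIFF planes, multi-page
# TIFF transform stacks with JSON sidecars, CSV traces.

#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG (returned exactly) or a TIFF. Non-square
#' images are rejected; color inputs are converted to grayscale by channel
#' averaging with a warning.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @return An [ImageGrid-class] (\code{"8bit"} for PNG input, \code{"float"}
#'   for TIFF).
#'
#' @export
readImageGrid <- function(path) {
  if (!file.exists(path)) .stopf("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .stopf("unsupported image format '%s' for '%s'", ext, path))
  if (length(dim(v)) == 3L) {
    warning(sprintf("'%s' is not grayscale; averaging %d channels", path,
                    dim(v)[3]), call. = FALSE)
    v <- apply(v, c(1, 2), mean)
  }
  if (nrow(v) != ncol(v))
    .stopf("image '%s' is not square (%d x %d)", path, nrow(v), ncol(v))
  if (ext == "png") {
    imageGrid(round(v * 255), bitDepth = "8bit")
  } else {
    side <- .readSidecar(path)
    if (!is.null(side))
      v <- v * side$scale + side$offset
    imageGrid(v, bitDepth = "float")
  }
}

#' Write a grayscale image
#'
#' 8-bit PNG output clips to \code{[0, 255]} and rounds; TIFF output stores
#' 32-bit samples after affine rescaling into \code{[0, 1]}, with the scale
#' and offset recorded in a JSON sidecar (\code{<path>.json}) so
#' [readImageGrid()] restores the original values.
#'
#' @param img an [ImageGrid-class].
#' @param path output path (.png or .tif/.tiff).
#' @return \code{path}, invisibly.
#'
#' @export
writeImageGrid <- function(img, path) {
  stopifnot(is(img, "ImageGrid"))
  ext <- tolower(tools::file_ext(path))
  v <- img@values
  if (ext == "png") {
    png::writePNG(pmin(pmax(round(v), 0), 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    sc <- .affineTo01(v)
    tiff::writeTIFF(sc$x, path, bits.per.sample = 32L, reduce = FALSE)
    .writeSidecar(path, list(type = "image", scale = sc$scale,
                             offset = sc$offset))
  } else {
    .stopf("unsupported image format '%s' for '%s'", ext, path)
  }
  invisible(path)
}

.affineTo01 <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    list(x = (v - lo) / (hi - lo), scale = hi - lo, offset = lo)
  } else {
    list(x = v * 0, scale = 1, offset = lo)
  }
}

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, fields) {
  jsonlite::write_json(fields, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
}

#' Persist a transform stack as multi-page 32-bit TIFF
#'
#' Pages are ordered (orientation 0 real, orientation 0 imag, orientation 1
#' real, ...). Samples are stored at 32-bit precision after a global affine
#' rescale into \code{[0, 1]}; the scale, offset, dimensions and page order
#' are recorded in a JSON sidecar next to the file. Round-trip accuracy is
#' about 2.4e-10 of the stack's dynamic range.
#'
#' @param F a [TransformStack-class].
#' @param path output path (.tif/.tiff).
#' @return \code{path}, invisibly.
#'
#' @export
saveStack <- function(F, path) {
  stopifnot(is(F, "TransformStack"))
  planes <- vector("list", 2L * F@M)
  for (j in seq_len(F@M)) {
    planes[[2L * j - 1L]] <- Re(F@values[, , j])
    planes[[2L * j]] <- Im(F@values[, , j])
  }
  all <- unlist(planes)
  lo <- min(all); hi <- max(all)
  scale <- if (hi > lo) hi - lo else 1
  planes <- lapply(planes, function(m) (m - lo) / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  .writeSidecar(path, list(
    type = "transform-stack", N = F@N, M = F@M, scale = scale, offset = lo,
    pageOrder = "orientation-major, real then imaginary per orientation"))
  invisible(path)
}

#' @rdname saveStack
#' @param path path written by [saveStack()] (the sidecar must sit next to
#'   it).
#' @return For \code{loadStack}, the restored [TransformStack-class].
#' @export
loadStack <- function(path) {
  side <- .readSidecar(path)
  if (is.null(side) || !identical(side$type, "transform-stack"))
    .stopf("'%s' has no transform-stack sidecar ('%s')", path,
           .sidecarPath(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  M <- side$M; N <- side$N
  if (length(pages) != 2L * M)
    .stopf("'%s': expected %d pages, found %d", path, 2L * M, length(pages))
  vals <- array(0i, dim = c(N, N, M))
  for (j in seq_len(M)) {
    re <- pages[[2L * j - 1L]] * side$scale + side$offset
    im <- pages[[2L * j]] * side$scale + side$offset
    vals[, , j] <- complex(real = re, imaginary = im)
  }
  new("TransformStack", values = vals, N = as.integer(N), M = as.integer(M))
}

#' Save a feature map as PNG plus JSON sidecar
#'
#' The PNG stores the orientation index directly as the 8-bit pixel value;
#' the sidecar records kind, M, rho and seed so the map round-trips through
#' [loadFeatureMap()].
#'
#' @param theta a [FeatureMap-class] (requires \code{M <= 256}).
#' @param path output path (.png).
#' @return \code{path}, invisibly.
#'
#' @export
saveFeatureMap <- function(theta, path) {
  stopifnot(is(theta, "FeatureMap"))
  if (theta@M > 256L) .stopf("cannot store maps with M > 256 as 8-bit PNG")
  png::writePNG(theta@values / 255, path)
  .writeSidecar(path, list(type = "feature-map", kind = theta@kind,
                           M = theta@M, rho = theta@rho, seed = theta@seed))
  invisible(path)
}

#' @rdname saveFeatureMap
#' @return For \code{loadFeatureMap}, the restored [FeatureMap-class].
#' @export
loadFeatureMap <- function(path) {
  side <- .readSidecar(path)
  if (is.null(side) || !identical(side$type, "feature-map"))
    .stopf("'%s' has no feature-map sidecar", path)
  v <- round(png::readPNG(path) * 255)
  new("FeatureMap", values = matrix(as.integer(v), nrow(v), ncol(v)),
      M = as.integer(side$M), kind = side$kind,
      rho = if (is.null(side$rho)) NA_real_ else as.numeric(side$rho),
      seed = if (is.null(side$seed)) NA_integer_ else as.integer(side$seed))
}

#' Export a reconstruction trace as CSV
#'
#' Writes columns \code{iteration}, \code{delta_percent} (one row per
#' recorded iteration).
#'
#' @param trace a [ReconstructionTrace-class] recorded with a reference
#'   image.
#' @param path output path (.csv).
#' @return \code{path}, invisibly.
#'
#' @export
saveTrace <- function(trace, path) {
  stopifnot(is(trace, "ReconstructionTrace"))
  if (!length(trace@deltas))
    .stopf("trace has no recorded errors (run with a reference image)")
  utils::write.csv(data.frame(iteration = trace@iterations,
                              delta_percent = trace@deltas),
                   path, row.names = FALSE)
  invisible(path)
}
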
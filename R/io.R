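# Plain-text persistence (JSON with CSV-style spectra) for model objects,
# and optional TIFF input/output for hypercubes.

#' Write a reflectance look-up table to JSON
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param path output file path
#' @export
writeLUT <- function(lut, path) {
  jsonlite::write_json(list(
    tEpiAxis = lut@tEpiAxis, musAxis = lut@musAxis,
    muaEpiAxis = lut@muaEpiAxis, muaDermAxis = lut@muaDermAxis,
    dim = dim(lut@values), values = as.numeric(lut@values),
    meta = lut@meta), path, digits = NA, auto_unbox = TRUE)
}

#' Read a reflectance look-up table from JSON
#'
#' @param path file written by \code{\link{writeLUT}}
#' @return a \linkS4class{ReflectanceLUT}
#' @export
readLUT <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ReflectanceLUT", tEpiAxis = x$tEpiAxis, musAxis = x$musAxis,
      muaEpiAxis = x$muaEpiAxis, muaDermAxis = x$muaDermAxis,
      values = array(x$values, dim = x$dim), meta = as.list(x$meta))
}

#' Write a trained network to JSON
#'
#' @param model an \linkS4class{AnnModel}
#' @param path output file path
#' @export
writeAnnModel <- function(model, path) {
  jsonlite::write_json(list(
    W1 = model@W1, b1 = model@b1, W2 = as.numeric(model@W2), b2 = model@b2,
    input = "fully_normalized 16-band spectrum (band mean 1)",
    output = "SO2 percent, unclipped", meta = model@meta),
    path, digits = NA, auto_unbox = TRUE)
}

#' Read a trained network from JSON
#'
#' @param path file written by \code{\link{writeAnnModel}}
#' @return an \linkS4class{AnnModel}
#' @export
readAnnModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W1 <- as.matrix(x$W1)
  new("AnnModel", W1 = W1, b1 = as.numeric(x$b1),
      W2 = matrix(as.numeric(x$W2), 1), b2 = as.numeric(x$b2),
      meta = as.list(x$meta))
}

#' Write sensor, optics and noise models to JSON
#'
#' @param response a \linkS4class{SensorResponse}
#' @param optics an \linkS4class{OpticsModel}
#' @param noise a \linkS4class{NoiseModel}
#' @param path output file path
#' @export
writeCameraModel <- function(response, optics, noise, path) {
  jsonlite::write_json(list(
    response = response@r, response_meta = response@meta,
    Ftrans = optics@Ftrans@values, L = optics@L@values,
    deltaTMax = optics@deltaTMax@values,
    deltaThetaMax = optics@deltaThetaMax@values, k = optics@k,
    noise = list(a = noise@a, b = noise@b, iMax = noise@iMax)),
    path, digits = NA, auto_unbox = TRUE)
}

#' Read sensor, optics and noise models from JSON
#'
#' @param path file written by \code{\link{writeCameraModel}}
#' @return list with \code{response}, \code{optics}, \code{noise}
#' @export
readCameraModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(response = new("SensorResponse", r = as.matrix(x$response),
                      meta = as.list(x$response_meta)),
       optics = new("OpticsModel", Ftrans = Spectrum(x$Ftrans),
                    L = Spectrum(x$L), deltaTMax = Spectrum(x$deltaTMax),
                    deltaThetaMax = Spectrum(x$deltaThetaMax),
                    k = as.numeric(x$k)),
       noise = new("NoiseModel", a = as.numeric(x$noise$a),
                   b = as.numeric(x$noise$b), iMax = x$noise$iMax))
}

#' Write a hypercube as a multi-page TIFF
#'
#' One 32-bit float page per band. Requires the \pkg{tiff} package.
#'
#' @param cube a \linkS4class{Hypercube}
#' @param path output file path
#' @export
writeHypercubeTiff <- function(cube, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF output")
  pages <- lapply(seq_len(.NBANDS), function(b) cube@values[b, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
}

#' Read a hypercube from a multi-page TIFF
#'
#' @param path 16-page TIFF written by \code{\link{writeHypercubeTiff}}
#' @param state normalization state to record
#' @return a \linkS4class{Hypercube}
#' @export
readHypercubeTiff <- function(path, state = "raw") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF input")
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == .NBANDS)
  d <- dim(pages[[1]])
  vals <- array(NA_real_, c(.NBANDS, d[1], d[2]))
  for (b in seq_len(.NBANDS)) vals[b, , ] <- pages[[b]]
  new("Hypercube", values = vals, state = state, mask = matrix(TRUE, d[1], d[2]))
}
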
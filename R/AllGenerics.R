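#' @import methods
NULL

#' Wavelengths of a spectral object
#'
#' Returns the wavelength grid (nm) on which a spectral object is defined.
#' All spectral quantities in this package live on the canonical inclusive
#' integer grid 400..700 nm with 1 nm spacing (301 samples).
#'
#' @param x a spectral object (\linkS4class{Spectrum},
#'   \linkS4class{SensorResponse}, ...)
#' @return integer vector of wavelengths in nm
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Numeric values of a spectral object
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{MSISpectrum}
#' @return numeric vector of per-wavelength (or per-band) values
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))

#' Normalization state of a spectral container
#'
#' @param x an \linkS4class{MSISpectrum} or \linkS4class{Hypercube}
#' @return character scalar: one of \code{"raw"}, \code{"dark_corrected"},
#'   \code{"white_normalized"}, \code{"fully_normalized"}
#' @export
setGeneric("normState", function(x) standardGeneric("normState"))
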
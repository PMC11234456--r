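# Central S4 containers. The canonical wavelength grid is fixed (400..700 nm,
# 1 nm); every Spectrum carries exactly 301 values aligned to it.

.GRID <- 400:700
.NGRID <- length(.GRID)
.NBANDS <- 16L

#' Canonical wavelength grid
#'
#' The fixed wavelength grid shared by every spectral quantity in the package:
#' 400 to 700 nm inclusive in 1 nm steps (301 samples). Detected band
#' intensities are modeled as sums over this grid.
#'
#' @return integer vector of length 301
#' @examples
#' head(wavelengthGrid())
#' @export
wavelengthGrid <- function() .GRID

#' Per-wavelength spectrum on the canonical grid
#'
#' A numeric vector of length 301 aligned to \code{\link{wavelengthGrid}()}.
#' Units are context dependent: mm^-1 for absorption/scattering coefficients,
#' dimensionless in [0, 1] for transmission/reflectance, relative irradiance
#' for lamp emission.
#'
#' @slot values numeric(301), finite
#' @export
setClass("Spectrum", representation(values = "numeric"), validity = function(object) {
  if (length(object@values) != .NGRID)
    return(sprintf("values must have length %d (canonical grid)", .NGRID))
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' Construct a Spectrum
#'
#' @param values numeric vector of length 301 (recycled if scalar), aligned to
#'   \code{\link{wavelengthGrid}()}
#' @return a \linkS4class{Spectrum}
#' @examples
#' sp <- Spectrum(rep(1, 301))
#' @export
Spectrum <- function(values) {
  if (length(values) == 1L) values <- rep(as.numeric(values), .NGRID)
  new("Spectrum", values = as.numeric(values))
}

#' @describeIn Spectrum wavelength grid of the spectrum
#' @param x a Spectrum
#' @export
setMethod("wavelengths", "Spectrum", function(x) .GRID)

#' @describeIn Spectrum numeric values
#' @export
setMethod("specValues", "Spectrum", function(x) x@values)

setMethod("show", "Spectrum", function(object) {
  v <- object@values
  cat(sprintf("Spectrum on 400..700 nm (301 samples), range [%.4g, %.4g]\n",
              min(v), max(v)))
})

#' Whole-blood chromophore absorption spectra
#'
#' Absorption coefficients (mm^-1) of fully oxygenated and fully reduced whole
#' blood on the canonical grid, together with the hematological constants used
#' in the conversion from molar extinction.
#'
#' @slot muaOxy \linkS4class{Spectrum}, oxygenated whole-blood absorption, mm^-1
#' @slot muaRed \linkS4class{Spectrum}, reduced whole-blood absorption, mm^-1
#' @slot constants list with \code{hematocrit} (0.43), \code{hb_g_per_l_blood}
#'   (145), \code{mchc_g_per_l_rbc} (345), \code{hb_molar_mass} (64500 g/mol)
#' @export
setClass("ChromophoreSet",
         representation(muaOxy = "Spectrum", muaRed = "Spectrum", constants = "list"),
         validity = function(object) {
  if (any(object@muaOxy@values <= 0) || any(object@muaRed@values <= 0))
    return("chromophore absorption spectra must be positive over the grid")
  d <- abs(object@muaOxy@values - object@muaRed@values) / object@muaOxy@values
  win <- .GRID >= 500 & .GRID <= 600
  if (min(d[win]) > 0.05)
    return("oxy and red spectra must cross (isosbestic point) in 500-600 nm")
  TRUE
})

setMethod("show", "ChromophoreSet", function(object) {
  cat("ChromophoreSet: whole-blood mu_a, oxygenated and reduced [mm^-1]\n")
  cat(sprintf("  Hb %.0f g/l blood, hematocrit %.2f\n",
              object@constants$hb_g_per_l_blood, object@constants$hematocrit))
})

#' Two-layer skin tissue parameters
#'
#' The seven free parameters of the two-layer skin model: a melanin-bearing
#' epidermis of finite thickness over a semi-infinite blood-bearing dermis,
#' with a shared reduced-scattering power law.
#'
#' @slot tEpi epidermis thickness, mm (0.0025--0.49)
#' @slot fMel melanin tissue fraction in the epidermis, dimensionless
#' @slot fBlood blood tissue fraction in the dermis, dimensionless
#' @slot s blood oxygen saturation fraction; [0, 1] physiologically, the
#'   fitting range extends to [-0.2, 1.2]
#' @slot D mean vessel diameter, mm
#' @slot alpha reduced scattering coefficient at 600 nm, mm^-1
#' @slot beta scattering power, dimensionless
#' @export
setClass("TissueParams",
         representation(tEpi = "numeric", fMel = "numeric", fBlood = "numeric",
                        s = "numeric", D = "numeric", alpha = "numeric",
                        beta = "numeric"),
         validity = function(object) {
  for (nm in c("tEpi", "fMel", "fBlood", "s", "D", "alpha", "beta"))
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      return(sprintf("%s must be a finite scalar", nm))
  if (object@tEpi < 0.0025 || object@tEpi > 0.49)
    return("tEpi must lie in [0.0025, 0.49] mm")
  if (object@fMel < 0 || object@fMel > 1) return("fMel must lie in [0, 1]")
  if (object@fBlood < 0 || object@fBlood > 1) return("fBlood must lie in [0, 1]")
  if (object@s < -0.2 || object@s > 1.2) return("s must lie in [-0.2, 1.2]")
  if (object@D <= 0) return("D must be > 0")
  if (object@alpha <= 0) return("alpha must be > 0")
  mus <- object@alpha * (.GRID / 600)^(-object@beta)
  if (min(mus) < 1.0 - 1e-9 || max(mus) > 90.5 + 1e-9)
    return("mu_s' must lie in [1.0, 90.5] mm^-1 over 400-700 nm")
  TRUE
})

#' Construct TissueParams
#'
#' @param tEpi epidermis thickness, mm
#' @param fMel melanin tissue fraction
#' @param fBlood dermal blood tissue fraction
#' @param s blood oxygen saturation fraction
#' @param D mean vessel diameter, mm
#' @param alpha reduced scattering at 600 nm, mm^-1
#' @param beta scattering power
#' @return a \linkS4class{TissueParams}
#' @examples
#' tissueParams(tEpi = 0.1, fMel = 0.02, fBlood = 0.01, s = 0.7,
#'              D = 0.03, alpha = 2.5, beta = 1.3)
#' @export
tissueParams <- function(tEpi, fMel, fBlood, s, D, alpha, beta) {
  new("TissueParams", tEpi = tEpi, fMel = fMel, fBlood = fBlood, s = s,
      D = D, alpha = alpha, beta = beta)
}

setMethod("show", "TissueParams", function(object) {
  cat(sprintf(paste0("TissueParams: t_epi=%.4g mm, f_mel=%.4g, f_blood=%.4g, ",
                     "SO2=%.1f%%, D=%.4g mm, alpha=%.3g, beta=%.3g\n"),
              object@tEpi, object@fMel, object@fBlood, 100 * object@s,
              object@D, object@alpha, object@beta))
})

#' Per-layer optical coefficients
#'
#' @slot muaEpi epidermis absorption, mm^-1
#' @slot muaDerm dermis absorption, mm^-1
#' @slot musPrime reduced scattering, mm^-1 (shared by both layers)
#' @slot g scattering anisotropy (0.8)
#' @slot tEpi epidermis thickness, mm
#' @export
setClass("LayerOptics",
         representation(muaEpi = "Spectrum", muaDerm = "Spectrum",
                        musPrime = "Spectrum", g = "numeric", tEpi = "numeric"),
         validity = function(object) {
  if (any(object@muaEpi@values < 0) || any(object@muaDerm@values < 0) ||
      any(object@musPrime@values < 0))
    return("optical coefficient spectra must be nonnegative")
  TRUE
})

#' Four-dimensional tissue reflectance look-up table
#'
#' White Monte Carlo reflectance of the two-layer slab tabulated over
#' epidermis thickness, reduced scattering at 600 nm, epidermis absorption and
#' dermis absorption. Absorption is applied to the zero-absorption photon
#' paths with Beer-Lambert attenuation, so a single transport simulation per
#' (thickness, scattering) node fills both absorption axes.
#'
#' @slot tEpiAxis epidermis thickness nodes, mm, strictly increasing
#' @slot musAxis reduced scattering (600 nm) nodes, mm^-1, strictly increasing
#' @slot muaEpiAxis epidermis absorption nodes, mm^-1 (first node 0)
#' @slot muaDermAxis dermis absorption nodes, mm^-1 (first node 0)
#' @slot values 4-D array of detected reflectance in [0, 1], dimensions
#'   following the four axes in order
#' @slot meta list: photon budget, anisotropy, refractive index, seed,
#'   truncated-path fraction
#' @export
setClass("ReflectanceLUT",
         representation(tEpiAxis = "numeric", musAxis = "numeric",
                        muaEpiAxis = "numeric", muaDermAxis = "numeric",
                        values = "array", meta = "list"),
         validity = function(object) {
  for (nm in c("tEpiAxis", "musAxis", "muaEpiAxis", "muaDermAxis")) {
    ax <- slot(object, nm)
    if (any(diff(ax) <= 0)) return(sprintf("%s must be strictly increasing", nm))
  }
  dv <- dim(object@values)
  want <- c(length(object@tEpiAxis), length(object@musAxis),
            length(object@muaEpiAxis), length(object@muaDermAxis))
  if (!identical(as.integer(dv), as.integer(want)))
    return("values array dimensions must follow the four axes")
  if (min(object@values) < 0 || max(object@values) > 1 + 1e-9)
    return("reflectance values must lie in [0, 1]")
  TRUE
})

setMethod("show", "ReflectanceLUT", function(object) {
  cat(sprintf("ReflectanceLUT %dx%dx%dx%d (t_epi x mu_s' x mu_a,epi x mu_a,derm)\n",
              length(object@tEpiAxis), length(object@musAxis),
              length(object@muaEpiAxis), length(object@muaDermAxis)))
  cat(sprintf("  photons/node: %g detected, g=%.2f, n=%.2f, seed=%s\n",
              object@meta$n_photons %||% NA, object@meta$g %||% NA,
              object@meta$n_tissue %||% NA,
              as.character(object@meta$seed %||% NA)))
})

#' Sensor spectral response
#'
#' Per-band spectral response weights of the 16-band mosaic snapshot sensor,
#' one row per band on the canonical grid. Bands are indexed in mosaic
#' row-major order; nominal peak wavelengths live in \code{meta}.
#'
#' @slot r 16 x 301 nonnegative matrix of response weights per 1 nm bin
#' @slot meta list (e.g. nominal peak wavelengths)
#' @export
setClass("SensorResponse", representation(r = "matrix", meta = "list"),
         validity = function(object) {
  if (!identical(dim(object@r), c(.NBANDS, .NGRID)))
    return("r must be a 16 x 301 matrix")
  if (any(object@r < 0)) return("response weights must be nonnegative")
  TRUE
})

setMethod("show", "SensorResponse", function(object) {
  pk <- .GRID[apply(object@r, 1, which.max)]
  cat("SensorResponse: 16 bands on 400..700 nm; peak wavelengths (nm):\n ",
      paste(pk, collapse = " "), "\n")
})

#' Optics and illumination model
#'
#' Spectral transmission of optical components not included in the sensor
#' response (long-pass and polarizing filters), the stable lamp emission
#' spectrum, its maximal temporal-drift and angular deviation fractions, and
#' per-band pixel amplification coefficients.
#'
#' @slot Ftrans filter/polarizer transmission, in [0, 1]
#' @slot L stable lamp emission (0 deg, post warm-up), relative irradiance
#' @slot deltaTMax maximal temporal drift fraction spectrum
#' @slot deltaThetaMax maximal angular deviation fraction spectrum
#' @slot k per-band pixel amplification coefficients, length 16, > 0
#' @export
setClass("OpticsModel",
         representation(Ftrans = "Spectrum", L = "Spectrum",
                        deltaTMax = "Spectrum", deltaThetaMax = "Spectrum",
                        k = "numeric"),
         validity = function(object) {
  if (any(object@Ftrans@values < 0 | object@Ftrans@values > 1))
    return("Ftrans must lie in [0, 1]")
  if (any(object@L@values < 0)) return("L must be nonnegative")
  if (any(1 + object@deltaTMax@values <= 0) ||
      any(1 + object@deltaThetaMax@values <= 0))
    return("1 + delta_max must be positive elementwise")
  if (length(object@k) != .NBANDS || any(object@k <= 0))
    return("k must be 16 positive amplification coefficients")
  TRUE
})

#' Detector temporal-noise model
#'
#' The band-wise multiplicative detector noise factor is zero-mean Gaussian
#' with variance increasing linearly in detected intensity:
#' var(eps_n) = a_n + I[n] / b_n.
#'
#' @slot a per-band variance intercept (dimensionless variance of the
#'   multiplicative noise factor), length 16
#' @slot b per-band inverse slope (intensity units), length 16
#' @slot iMax maximum detectable intensity (ADC full scale)
#' @export
setClass("NoiseModel",
         representation(a = "numeric", b = "numeric", iMax = "numeric"),
         validity = function(object) {
  if (length(object@a) != .NBANDS || length(object@b) != .NBANDS)
    return("a and b must have length 16")
  if (any(object@a + object@iMax / object@b < 0))
    return("predicted variance a + I/b must be nonnegative on [0, iMax]")
  TRUE
})

#' A 16-band multispectral spectrum
#'
#' @slot values 16 band values
#' @slot state normalization state: \code{"raw"}, \code{"white_normalized"} or
#'   \code{"fully_normalized"} (band mean 1)
#' @export
setClass("MSISpectrum", representation(values = "numeric", state = "character"),
         validity = function(object) {
  if (length(object@values) != .NBANDS) return("values must have length 16")
  if (!object@state %in% c("raw", "white_normalized", "fully_normalized"))
    return("unknown normalization state")
  if (object@state == "fully_normalized" &&
      abs(mean(object@values) - 1) > 1e-12)
    return("fully_normalized spectra must have band mean 1")
  TRUE
})

#' Construct an MSISpectrum
#' @param values 16 band values
#' @param state normalization state
#' @return an \linkS4class{MSISpectrum}
#' @export
MSISpectrum <- function(values, state = "raw")
  new("MSISpectrum", values = as.numeric(values), state = state)

#' @describeIn MSISpectrum band values
#' @param x an MSISpectrum
#' @export
setMethod("specValues", "MSISpectrum", function(x) x@values)

#' @describeIn MSISpectrum normalization state
#' @export
setMethod("normState", "MSISpectrum", function(x) x@state)

setMethod("show", "MSISpectrum", function(object) {
  cat(sprintf("MSISpectrum (%s): ", object@state))
  cat(sprintf("%.4g", object@values), sep = " ")
  cat("\n")
})

#' Shallow feed-forward SO2 regression network
#'
#' A 16 -> H -> 1 network with hyperbolic-tangent hidden activation and linear
#' output, mapping a fully normalized 16-band spectrum to blood SO2 in
#' percent. The output is deliberately not clipped to [0, 100].
#'
#' @slot W1 hidden-layer weights, H x 16
#' @slot b1 hidden biases, length H
#' @slot W2 output weights, 1 x H
#' @slot b2 output bias, scalar
#' @slot meta list: hidden size, training seeds, validation/test performance
#' @export
setClass("AnnModel",
         representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                        b2 = "numeric", meta = "list"),
         validity = function(object) {
  H <- nrow(object@W1)
  if (ncol(object@W1) != .NBANDS) return("W1 must have 16 columns")
  if (length(object@b1) != H) return("b1 length must equal hidden size")
  if (!identical(dim(object@W2), c(1L, H))) return("W2 must be 1 x H")
  if (length(object@b2) != 1L) return("b2 must be scalar")
  TRUE
})

setMethod("show", "AnnModel", function(object) {
  cat(sprintf("AnnModel: 16 -> %d (tanh) -> 1 (linear), SO2 in %%\n",
              nrow(object@W1)))
  if (!is.null(object@meta$test_mse))
    cat(sprintf("  held-out test MSE: %.4g (%%-units^2)\n", object@meta$test_mse))
})

#' Synthetic training set of normalized MSI spectra
#'
#' @slot X n x 16 matrix of fully normalized spectra (row mean 1)
#' @slot y SO2 targets in percent
#' @slot params data.frame of the full tissue parameter set per sample
#' @slot split list of train/val/test index vectors (70/15/15, disjoint)
#' @export
setClass("TrainingSet",
         representation(X = "matrix", y = "numeric", params = "data.frame",
                        split = "list"),
         validity = function(object) {
  n <- nrow(object@X)
  if (ncol(object@X) != .NBANDS) return("X must have 16 columns")
  if (length(object@y) != n) return("y length must match rows of X")
  if (max(abs(rowMeans(object@X) - 1)) > 1e-9)
    return("each row of X must have mean 1")
  idx <- c(object@split$train, object@split$val, object@split$test)
  if (anyDuplicated(idx) || length(idx) != n)
    return("split indices must partition 1..n")
  TRUE
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d spectra (train %d / val %d / test %d)\n",
              nrow(object@X), length(object@split$train),
              length(object@split$val), length(object@split$test)))
})

#' Inverse Monte Carlo fit result
#'
#' @slot params fitted \linkS4class{TissueParams}
#' @slot residual per-band relative differences (model - meas)/meas
#' @slot mape mean absolute percentage error of the fit, percent
#' @slot converged logical convergence flag
#' @slot startPointsUsed number of start points evaluated
#' @slot iterations solver iterations of the winning start
#' @export
setClass("FitResult",
         representation(params = "TissueParams", residual = "numeric",
                        mape = "numeric", converged = "logical",
                        startPointsUsed = "numeric", iterations = "numeric"))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: SO2 = %.2f%%, mape = %.4g%%, converged = %s\n",
              100 * object@params@s, object@mape, object@converged))
})

#' Raw mosaic-sensor frame
#'
#' @slot pixels 2-D intensity matrix with a 4x4 repeating band mosaic;
#'   dimensions divisible by 4
#' @slot exposure exposure time, ms
#' @slot timestamp acquisition time, s
#' @slot kind one of \code{"measurement"}, \code{"white"}, \code{"dark"}
#' @export
setClass("RawFrame",
         representation(pixels = "matrix", exposure = "numeric",
                        timestamp = "numeric", kind = "character"),
         validity = function(object) {
  if (any(dim(object@pixels) %% 4L != 0L))
    return("frame dimensions must be divisible by 4")
  if (!object@kind %in% c("measurement", "white", "dark"))
    return("kind must be measurement, white or dark")
  TRUE
})

#' Multispectral hypercube
#'
#' @slot values 16 x height x width array (band axis first)
#' @slot state normalization state
#' @slot mask height x width logical matrix of valid pixels
#' @export
setClass("Hypercube",
         representation(values = "array", state = "character", mask = "matrix"),
         validity = function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != .NBANDS)
    return("values must be a 16 x H x W array")
  if (!identical(dim(object@mask), d[2:3])) return("mask must be H x W")
  if (!object@state %in% c("raw", "dark_corrected", "white_normalized",
                           "fully_normalized"))
    return("unknown normalization state")
  TRUE
})

#' @describeIn Hypercube normalization state
#' @param x a Hypercube
#' @export
setMethod("normState", "Hypercube", function(x) x@state)

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@values)
  cat(sprintf("Hypercube: 16 x %d x %d (%s), %d masked pixels\n",
              d[2], d[3], object@state, sum(!object@mask)))
})

#' Per-pixel SO2 map
#'
#' @slot so2 height x width matrix of SO2 in percent (unclipped)
#' @slot mask logical matrix of valid pixels
#' @export
setClass("So2Map", representation(so2 = "matrix", mask = "matrix"),
         validity = function(object) {
  if (!identical(dim(object@so2), dim(object@mask)))
    return("so2 and mask dimensions must agree")
  if (any(!is.finite(object@so2[object@mask])))
    return("so2 must be finite where mask is TRUE")
  TRUE
})

setMethod("show", "So2Map", function(object) {
  v <- object@so2[object@mask]
  cat(sprintf("So2Map %d x %d: SO2 median %.1f%%, range [%.1f, %.1f]%%\n",
              nrow(object@so2), ncol(object@so2), stats::median(v),
              min(v), max(v)))
})

#' Tunable-filter calibration sweep dataset
#'
#' Band intensities recorded while a narrowband (about 7 nm FWHM) tunable
#' filter sweeps 400..700 nm, together with the reference spectra seen by a
#' calibrated spectrometer at each setting. Both are dark-subtracted; the
#' reference spectra are resampled to the canonical grid.
#'
#' @slot I 16 x M matrix of band intensities (M sweep settings)
#' @slot R 301 x M matrix of reference spectra (columns = settings)
#' @slot settings tunable-filter center wavelengths, nm
#' @export
setClass("CalibrationDataset",
         representation(I = "matrix", R = "matrix", settings = "numeric"),
         validity = function(object) {
  if (nrow(object@I) != .NBANDS) return("I must have 16 rows")
  if (nrow(object@R) != .NGRID) return("R must have 301 rows")
  if (ncol(object@I) != ncol(object@R) ||
      ncol(object@I) != length(object@settings))
    return("I, R and settings must agree on the number of sweep settings")
  if (any(object@I < 0) || any(object@R < 0))
    return("intensities and reference spectra must be nonnegative")
  TRUE
})

setMethod("show", "CalibrationDataset", function(object) {
  cat(sprintf("CalibrationDataset: 16 bands x %d sweep settings (%g-%g nm)\n",
              ncol(object@I), min(object@settings), max(object@settings)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
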
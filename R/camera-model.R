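# Forward model of detected MSI band intensities: sensor response, optics,
# lamp, pixel amplification, detector noise, and the two normalizations.

#' Synthetic default sensor spectral response
#'
#' Sixteen Gaussian passbands with nominal peaks evenly spaced over 470 to
#' 650 nm (mosaic row-major band order) and about 16 nm FWHM; the four
#' longest-wavelength bands carry a weak secondary peak emulating the
#' second-order transmission of on-chip Fabry-Perot filters. Stands in for an
#' individually calibrated camera response in synthetic work.
#'
#' @param peaks optional 16 nominal peak wavelengths, nm
#' @param sigma Gaussian width, nm
#' @return a \linkS4class{SensorResponse}
#' @export
defaultSensorResponse <- function(peaks = seq(470, 650, length.out = 16),
                                  sigma = 7) {
  stopifnot(length(peaks) == .NBANDS)
  r <- t(vapply(seq_len(.NBANDS), function(n) {
    v <- exp(-(.GRID - peaks[n])^2 / (2 * sigma^2))
    if (n > 12)  # second-order leakage of the longest-wavelength filters
      v <- v + 0.12 * exp(-(.GRID - (peaks[n] - 165))^2 / (2 * (1.3 * sigma)^2))
    v
  }, numeric(.NGRID)))
  new("SensorResponse", r = r, meta = list(peaks_nm = peaks))
}

#' Synthetic default optics and illumination model
#'
#' The lamp is a white-LED double-Gaussian (blue die at 450 nm, broad
#' phosphor emission near 560 nm); the filter transmission combines a
#' long-pass edge at 470 nm, suppressing the blue LED peak, with a flat
#' polarizer loss. The maximal temporal drift and angular deviation spectra
#' are smooth curves with magnitudes of a few percent, emulating measured
#' warm-up and emission-angle behavior of LED ring lights. Pixel
#' amplification defaults to 1 for all bands (it cancels in the
#' normalization).
#'
#' @return an \linkS4class{OpticsModel}
#' @export
defaultOptics <- function() {
  lam <- .GRID
  L <- exp(-(lam - 450)^2 / (2 * 15^2)) + 0.85 * exp(-(lam - 560)^2 / (2 * 60^2))
  Ftrans <- 0.4 / (1 + exp(-(lam - 470) / 3))
  # white-LED warm-up and emission-angle variation are dominated by the
  # blue-die/phosphor balance: strongest near the 450 nm pump, a weak smooth
  # remainder across the phosphor band
  dT <- 0.05 * exp(-(lam - 450)^2 / (2 * 18^2)) + 0.01
  dTh <- 0.05 * exp(-(lam - 460)^2 / (2 * 22^2)) + 0.008 * (lam - 550) / 150
  new("OpticsModel", Ftrans = Spectrum(Ftrans), L = Spectrum(L),
      deltaTMax = Spectrum(dT), deltaThetaMax = Spectrum(dTh),
      k = rep(1, .NBANDS))
}

#' Default detector noise model
#'
#' var(eps_n) = a_n + I[n]/b_n for the multiplicative band noise factor. The
#' coefficients describe the noise of saved frames as the acquisition chain
#' delivers them: the camera averages eight consecutive raw frames on the fly
#' before a frame is stored, so the shot-noise-limited raw-sensor variance
#' (about 1.4 percent relative standard deviation at half scale for this
#' class of CMOS sensor) appears here divided by eight, i.e. about 0.5
#' percent at half the ADC full scale with a 0.1 percent floor.
#'
#' @param iMax ADC full scale (default 4095, 12-bit)
#' @param a per-band variance intercepts (dimensionless)
#' @param b per-band inverse slopes (intensity units)
#' @return a \linkS4class{NoiseModel}
#' @export
defaultNoiseModel <- function(iMax = 4095,
                              a = rep(1.25e-6, 16),
                              b = rep(iMax / 5e-5, 16)) {
  new("NoiseModel", a = a, b = b, iMax = iMax)
}

# 16 x 301 effective weighting matrix r * F (response times filter)
.bandWeights <- function(response, optics)
  response@r * rep(optics@Ftrans@values, each = .NBANDS)

#' Model detected MSI band intensities
#'
#' I_T[n] = k_n sum_lambda r_n(lambda) F(lambda) L(lambda) T(lambda) over the
#' canonical grid. With T(lambda) = 1 this yields the modeled white-reference
#' intensity I_W[n].
#'
#' @param response a \linkS4class{SensorResponse}
#' @param optics an \linkS4class{OpticsModel}
#' @param T tissue reflectance \linkS4class{Spectrum} (dimensionless)
#' @param L optional replacement lamp spectrum (e.g. a perturbed lamp);
#'   defaults to the stable lamp in \code{optics}
#' @return an \linkS4class{MSISpectrum} with state \code{"raw"}
#' @export
modelIntensity <- function(response, optics, T, L = NULL) {
  if (!is(T, "Spectrum")) stop("T must be a Spectrum on the canonical grid")
  Lv <- if (is.null(L)) optics@L@values else
    if (is(L, "Spectrum")) L@values else stop("L must be a Spectrum")
  I <- optics@k * as.numeric(.bandWeights(response, optics) %*% (Lv * T@values))
  MSISpectrum(I, "raw")
}

#' White-reference and intensity normalization
#'
#' N[n] = (I_T[n] / I_W[n]) / mean_n(I_T[n] / I_W[n]). The per-band
#' amplification k_n cancels exactly in the ratio, and the output band mean
#' is 1 by construction.
#'
#' @param IT raw tissue \linkS4class{MSISpectrum}
#' @param IW raw white-reference \linkS4class{MSISpectrum}, strictly positive
#' @return an \linkS4class{MSISpectrum} with state \code{"fully_normalized"}
#' @export
normalizeBands <- function(IT, IW) {
  stopifnot(normState(IT) == "raw", normState(IW) == "raw")
  if (any(IW@values <= 0))
    stop("degenerate white reference: nonpositive band intensity")
  ratio <- IT@values / IW@values
  MSISpectrum(ratio / mean(ratio), "fully_normalized")
}

#' Perturbed lamp emission spectrum
#'
#' L_ANN(lambda) = L(lambda) (1 + q_t delta_t,max(lambda))
#' (1 + q_theta delta_theta,max(lambda)), interpolating linearly between the
#' stable spectrum (q = 0) and the maximal temporal/angular deviations
#' (q = 1).
#'
#' @param optics an \linkS4class{OpticsModel}
#' @param qT temporal drift coordinate in [0, 1]
#' @param qTheta angular deviation coordinate in [0, 1]
#' @return a \linkS4class{Spectrum}
#' @export
perturbedLamp <- function(optics, qT, qTheta) {
  stopifnot(qT >= 0, qT <= 1, qTheta >= 0, qTheta <= 1)
  Spectrum(optics@L@values * (1 + qT * optics@deltaTMax@values) *
             (1 + qTheta * optics@deltaThetaMax@values))
}

#' Sample detector noise factors
#'
#' Draws the 16 band noise factors eps_n ~ Normal(0, a_n + I[n]/b_n)
#' independently. Draws are truncated at -0.999 so that (1 + eps) keeps
#' intensities positive.
#'
#' @param noise a \linkS4class{NoiseModel}
#' @param I 16 detected band intensities (nonnegative)
#' @param seed optional integer seed
#' @return numeric vector of 16 noise factors
#' @export
sampleNoise <- function(noise, I, seed = NULL) {
  stopifnot(length(I) == .NBANDS, all(I >= 0))
  v <- noise@a + I / noise@b
  if (any(v < 0)) stop("noise model predicts negative variance")
  if (!is.null(seed)) set.seed(seed)
  pmax(stats::rnorm(.NBANDS, 0, sqrt(v)), -0.999)
}

#' Model detected intensities with hardware variations
#'
#' I_T,ANN[n] = k_n (1 + eps_n) sum_lambda r_n F L_ANN T: the forward model
#' of \code{\link{modelIntensity}} evaluated with the perturbed lamp, then
#' multiplied per band by (1 + eps_n). With eps = 0 and q = 0 this reduces
#' exactly to \code{modelIntensity}.
#'
#' @param response a \linkS4class{SensorResponse}
#' @param optics an \linkS4class{OpticsModel}
#' @param noise a \linkS4class{NoiseModel} (unused when \code{eps} is given
#'   explicitly; kept for interface symmetry)
#' @param T tissue reflectance \linkS4class{Spectrum}
#' @param qT,qTheta lamp perturbation coordinates in [0, 1]
#' @param eps 16 noise factors (e.g. from \code{\link{sampleNoise}})
#' @return an \linkS4class{MSISpectrum} with state \code{"raw"}
#' @export
modelIntensityAnn <- function(response, optics, noise, T, qT = 0, qTheta = 0,
                              eps = rep(0, 16)) {
  stopifnot(length(eps) == .NBANDS)
  I0 <- modelIntensity(response, optics, T, L = perturbedLamp(optics, qT, qTheta))
  MSISpectrum(I0@values * (1 + eps), "raw")
}
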
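# Two-layer skin optical-property model: physiological parameters to
# per-wavelength absorption and scattering coefficients.

#' Reduced scattering power law
#'
#' mu_s'(lambda) = alpha * (lambda / 600)^(-beta), shared by epidermis and
#' dermis. \code{alpha} is the reduced scattering coefficient at the 600 nm
#' reference wavelength.
#'
#' @param alpha reduced scattering at 600 nm, mm^-1 (> 0)
#' @param beta scattering power (dimensionless)
#' @return a \linkS4class{Spectrum} in mm^-1
#' @examples
#' specValues(reducedScattering(3, 1.2))[wavelengthGrid() == 600]  # 3
#' @export
reducedScattering <- function(alpha, beta) {
  stopifnot(alpha > 0)
  Spectrum(alpha * (.GRID / 600)^(-beta))
}

#' Epidermal melanin absorption
#'
#' mu_a,epi(lambda) = f_mel * 39.0 mm^-1 * (lambda / 550)^-3, linear in the
#' melanin tissue fraction.
#'
#' @param fMel melanin tissue fraction (>= 0)
#' @return a \linkS4class{Spectrum} in mm^-1
#' @examples
#' specValues(epidermisAbsorption(1))[wavelengthGrid() == 550]  # 39.0
#' @export
epidermisAbsorption <- function(fMel) {
  stopifnot(fMel >= 0)
  Spectrum(fMel * 39.0 * (.GRID / 550)^(-3))
}

#' Whole-blood absorption at a given oxygen saturation
#'
#' mu_a,blood(lambda) = s * mu_a,oxy + (1 - s) * mu_a,red. The saturation may
#' run outside [0, 1] (fitting range [-0.2, 1.2]); estimated SO2 is
#' deliberately not clipped.
#'
#' @param s blood oxygen saturation fraction in [-0.2, 1.2]
#' @param chromophores a \linkS4class{ChromophoreSet}
#' @return a \linkS4class{Spectrum} in mm^-1
#' @export
bloodAbsorption <- function(s, chromophores) {
  stopifnot(s >= -0.2, s <= 1.2)
  Spectrum(s * chromophores@muaOxy@values + (1 - s) * chromophores@muaRed@values)
}

#' Vessel packaging correction factor
#'
#' Blood confined to discrete vessels of mean diameter D absorbs less than
#' homogeneously distributed blood; the correction is
#' cVD(lambda) = (1 - exp(-D * mu_a,blood)) / (D * mu_a,blood), in (0, 1],
#' approaching 1 as D -> 0. Evaluated by second-order series expansion when
#' D * mu_a,blood < 1e-6 to avoid cancellation.
#'
#' @param D mean vessel diameter, mm (> 0)
#' @param muaBlood whole-blood absorption \linkS4class{Spectrum}, mm^-1
#' @return a dimensionless \linkS4class{Spectrum} in (0, 1]
#' @export
vesselPackagingFactor <- function(D, muaBlood) {
  stopifnot(D > 0)
  x <- D * muaBlood@values
  c_vd <- ifelse(x < 1e-6, 1 - x / 2 + x^2 / 6, (1 - exp(-x)) / x)
  Spectrum(c_vd)
}

#' Dermal absorption with vessel packaging
#'
#' mu_a,derm(lambda) = f_blood * cVD(lambda) * mu_a,blood(lambda).
#'
#' @param params a \linkS4class{TissueParams}
#' @param chromophores a \linkS4class{ChromophoreSet}
#' @return a \linkS4class{Spectrum} in mm^-1
#' @export
dermisAbsorption <- function(params, chromophores) {
  muaB <- bloodAbsorption(params@s, chromophores)
  cvd <- vesselPackagingFactor(params@D, muaB)
  Spectrum(params@fBlood * cvd@values * muaB@values)
}

#' Full layer optics for a tissue parameter set
#'
#' Assembles epidermis/dermis absorption and the shared reduced scattering for
#' one parameter set. Anisotropy is fixed at g = 0.8 for all wavelengths; the
#' unreduced scattering coefficient, when needed by the transport simulation,
#' is mu_s = mu_s' / (1 - g) = 5 mu_s'.
#'
#' @param params a \linkS4class{TissueParams}
#' @param chromophores a \linkS4class{ChromophoreSet}
#' @return a \linkS4class{LayerOptics}
#' @export
layerOptics <- function(params, chromophores) {
  new("LayerOptics",
      muaEpi = epidermisAbsorption(params@fMel),
      muaDerm = dermisAbsorption(params, chromophores),
      musPrime = reducedScattering(params@alpha, params@beta),
      g = 0.8, tEpi = params@tEpi)
}

#' Serialize tissue parameters to a flat named list
#'
#' @param params a \linkS4class{TissueParams}
#' @return named list with keys t_epi_mm, f_mel, f_blood, so2, d_vessel_mm,
#'   alpha, beta (so2 as a fraction)
#' @export
tissueParamsToList <- function(params) {
  list(t_epi_mm = params@tEpi, f_mel = params@fMel, f_blood = params@fBlood,
       so2 = params@s, d_vessel_mm = params@D, alpha = params@alpha,
       beta = params@beta)
}

#' Deserialize tissue parameters from a flat named list
#'
#' @param x named list as produced by \code{\link{tissueParamsToList}}
#' @return a \linkS4class{TissueParams}
#' @export
tissueParamsFromList <- function(x) {
  tissueParams(tEpi = x$t_epi_mm, fMel = x$f_mel, fBlood = x$f_blood,
               s = x$so2, D = x$d_vessel_mm, alpha = x$alpha, beta = x$beta)
}
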
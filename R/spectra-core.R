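# Canonical-grid resampling and chromophore reference spectra.

#' Resample tabulated spectral data onto the canonical grid
#'
#' Smooths raw tabulated data with a 1 nm wide moving-average (boxcar) filter
#' to avoid aliasing, then linearly interpolates onto the canonical 400..700
#' nm, 1 nm grid. At the ends of the raw tabulation the boxcar window shrinks
#' (truncated window) rather than extrapolating. Data sampled at 1 nm or
#' coarser pass through the smoother unchanged (single-point window).
#'
#' @param wavelength strictly increasing raw wavelengths, nm; must cover
#'   [400, 700]
#' @param value raw values, same length as \code{wavelength}
#' @return a \linkS4class{Spectrum}
#' @examples
#' sp <- resampleToGrid(seq(390, 710, by = 0.5), rep(2, 641))
#' all(specValues(sp) == 2)
#' @export
resampleToGrid <- function(wavelength, value) {
  stopifnot(length(wavelength) == length(value))
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("raw wavelengths must be strictly increasing")
  if (min(wavelength) > 400 || max(wavelength) < 700)
    stop("raw data must cover the canonical grid range [400, 700] nm")
  dx <- stats::median(diff(wavelength))
  half <- floor(0.5 / dx + 1e-9)          # points within +-0.5 nm
  sm <- if (half >= 1L) .boxcar(value, half) else value
  v <- stats::approx(wavelength, sm, xout = .GRID, rule = 1)$y
  Spectrum(v)
}

# Truncated-window moving average: mean over indices [i-half, i+half]
# clipped to the data range.
.boxcar <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Load whole-blood chromophore absorption spectra
#'
#' Reads the bundled molar-extinction tabulations for oxygenated and reduced
#' hemoglobin, interpolates them onto the canonical grid, and converts them to
#' whole-blood absorption coefficients in mm^-1 using
#' mu_a = ln(10) * epsilon * c / M / 10, with hemoglobin blood concentration
#' c (g/l blood) and hemoglobin molar mass M = 64500 g/mol. The bundled
#' tables are an approximate reconstruction of the standard public
#' compilations (see the files' headers); conversion is linear in \code{hbConc}.
#'
#' @param oxyFile,redFile optional CSV paths (columns wavelength_nm, value);
#'   default to the bundled tables
#' @param hbConc hemoglobin concentration in g/l blood (default 145)
#' @return a \linkS4class{ChromophoreSet}
#' @examples
#' ch <- loadChromophores()
#' range(specValues(ch@muaOxy))
#' @export
loadChromophores <- function(oxyFile = NULL, redFile = NULL, hbConc = 145) {
  oxyFile <- oxyFile %||%
    system.file("extdata", "hbo2_extinction_synthetic.csv", package = "msiSO2")
  redFile <- redFile %||%
    system.file("extdata", "hb_extinction_synthetic.csv", package = "msiSO2")
  conv <- function(path) {
    if (!nzchar(path) || !file.exists(path))
      stop("chromophore reference table not found: ", path)
    tab <- utils::read.csv(path, comment.char = "#")
    if (ncol(tab) < 2L || nrow(tab) < 10L)
      stop("corrupt chromophore table: ", path)
    eps <- resampleToGrid(tab[[1]], tab[[2]])
    # epsilon [cm^-1/M] -> mu_a [mm^-1] at concentration hbConc g/l
    Spectrum(log(10) * eps@values * hbConc / 64500 / 10)
  }
  new("ChromophoreSet", muaOxy = conv(oxyFile), muaRed = conv(redFile),
      constants = list(hematocrit = 0.43, hb_g_per_l_blood = hbConc,
                       mchc_g_per_l_rbc = 345, hb_molar_mass = 64500))
}
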
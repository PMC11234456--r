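# Sensor spectral-response estimation from tunable-filter sweeps, and
# detector-noise / lamp-variation model fitting.

#' Construct a CalibrationDataset
#'
#' @param I 16 x M matrix of dark-subtracted band intensities
#' @param R 301 x M matrix of dark-subtracted reference spectra on the
#'   canonical grid
#' @param settings tunable-filter center wavelengths, nm
#' @return a \linkS4class{CalibrationDataset}
#' @export
calibrationDataset <- function(I, R, settings)
  new("CalibrationDataset", I = I, R = R, settings = as.numeric(settings))

#' Solver result of the sensor-response estimation
#'
#' @slot rStar estimated \linkS4class{SensorResponse}
#' @slot residualNorm summed squared penalty over all bands
#' @slot report per-band data.frame: iterations, convergence flag, residual
#'   norm
#' @export
setClass("CalibrationResult",
         representation(rStar = "SensorResponse", residualNorm = "numeric",
                        report = "data.frame"))

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: ||penalty||^2 = %.4g; %d/%d bands converged\n",
              object@residualNorm, sum(object@report$converged),
              nrow(object@report)))
})

#' Penalty vector for one band's response estimate
#'
#' Concatenates (i) the intensity residuals
#' I[n,m]/mean(I) - I_C[n,m] for every sweep setting m, where the measured
#' intensities are normalized by the grand mean over all bands and settings
#' (making the fit insensitive to overall lamp intensity, exposure and gain)
#' and I_C is the forward model sum_lambda r_n(lambda) R_m(lambda); and (ii)
#' the weighted smoothness terms 0.2 * Delta_r(lambda_i) for every adjacent
#' wavelength pair, with the amplitude-normalized derivative
#' Delta_r = (r_{i+1} - r_i) / (0.5 r_i + 0.5 r_{i+1} + mean(r)). A zero
#' response (zero denominator) contributes zero smoothness residual.
#'
#' @param r candidate response, numeric(301), nonnegative
#' @param dataset a \linkS4class{CalibrationDataset}
#' @param band band index 1..16
#' @param grandMean optional precomputed grand mean of \code{dataset@I}
#' @return numeric vector of length M + 300
#' @export
penaltyVector <- function(r, dataset, band, grandMean = NULL) {
  gm <- grandMean %||% mean(dataset@I)
  data_res <- dataset@I[band, ] / gm - as.numeric(crossprod(dataset@R, r))
  den <- 0.5 * r[-.NGRID] + 0.5 * r[-1] + mean(r)
  smooth_res <- ifelse(den > 0, (r[-1] - r[-.NGRID]) / den, 0)
  c(data_res, 0.2 * smooth_res)
}

# Analytic Jacobian of penaltyVector with respect to r.
.penaltyJacobian <- function(r, dataset, band, grandMean) {
  M <- ncol(dataset@R)
  Jdata <- -t(dataset@R)                       # M x 301
  dr <- r[-1] - r[-.NGRID]
  den <- 0.5 * r[-.NGRID] + 0.5 * r[-1] + mean(r)
  ok <- den > 0
  Js <- matrix(0, .NGRID - 1L, .NGRID)
  i <- which(ok)
  if (length(i)) {
    # numerator term
    Js[cbind(i, i)] <- Js[cbind(i, i)] - 1 / den[i]
    Js[cbind(i, i + 1L)] <- Js[cbind(i, i + 1L)] + 1 / den[i]
    # denominator term: d(den)/dr_j = 0.5 (j = i, i+1) + 1/301 (all j)
    fac <- -dr[i] / den[i]^2
    Js[i, ] <- Js[i, ] + fac %o% rep(1 / .NGRID, .NGRID)
    Js[cbind(i, i)] <- Js[cbind(i, i)] + 0.5 * fac
    Js[cbind(i, i + 1L)] <- Js[cbind(i, i + 1L)] + 0.5 * fac
  }
  rbind(Jdata, 0.2 * Js)
}

#' Estimate the sensor spectral response from a sweep dataset
#'
#' Minimizes the squared penalty of \code{\link{penaltyVector}} independently
#' per band (bands couple only through the grand-mean normalization, which is
#' computed once and held fixed), subject to r >= 0, using
#' Levenberg-Marquardt nonlinear least squares with an analytic Jacobian.
#' Initial guesses default to a ridge-regularized linear inversion of the
#' forward model, clipped at zero (the model is linear in r; the
#' nonlinearity enters only through the rational smoothness penalty).
#'
#' @param dataset a \linkS4class{CalibrationDataset} covering 400-700 nm
#' @param init optional 16 x 301 matrix of initial responses
#' @param bands bands to estimate (default all 16)
#' @param maxIter maximum solver iterations per band (default 400)
#' @param relTol relative convergence tolerance (default 1e-8)
#' @return a \linkS4class{CalibrationResult}; non-converged bands are flagged
#'   in the report and carry the best iterate
#' @export
estimateResponse <- function(dataset, init = NULL, bands = seq_len(16),
                             maxIter = 400, relTol = 1e-8) {
  if (min(dataset@settings) > 400 || max(dataset@settings) < 700)
    stop("calibration sweep must cover 400-700 nm")
  gm <- mean(dataset@I)
  rstar <- matrix(0, .NBANDS, .NGRID)
  rep_rows <- list()
  total <- 0
  RRt <- tcrossprod(dataset@R)                 # 301 x 301
  ridge <- diag(1e-4 * mean(diag(RRt)), .NGRID)
  for (n in bands) {
    r0 <- if (!is.null(init)) init[n, ] else {
      y <- dataset@I[n, ] / gm
      r0 <- tryCatch(as.numeric(solve(RRt + ridge, dataset@R %*% y)),
                     error = function(e) rep(mean(y), .NGRID))
      pmax(r0, 0)
    }
    if (all(r0 == 0)) r0 <- rep(1e-3, .NGRID)
    fit <- minpack.lm::nls.lm(
      par = r0,
      lower = rep(0, .NGRID),
      fn = function(r) penaltyVector(r, dataset, n, gm),
      jac = function(r) .penaltyJacobian(r, dataset, n, gm),
      control = minpack.lm::nls.lm.control(
        maxiter = maxIter, ftol = relTol, ptol = relTol, gtol = 0))
    rstar[n, ] <- pmax(fit$par, 0)
    rn <- sum(fit$fvec^2)
    total <- total + rn
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(band = n, iterations = fit$niter,
                 converged = fit$info %in% 1:4, residual_norm = rn)
  }
  new("CalibrationResult",
      rStar = new("SensorResponse", r = rstar,
                  meta = list(source = "tunable-filter sweep estimate")),
      residualNorm = total, report = do.call(rbind, rep_rows))
}

#' Fit the detector noise model from repeated white measurements
#'
#' For each band, the variance of the relative temporal fluctuation
#' I_t/mean(I_t) - 1 is computed at every intensity level and regressed
#' linearly on the mean intensity, giving var(eps) = a + I/b.
#'
#' @param whiteStack list over intensity levels; each element an
#'   nRepeats x 16 matrix of band intensities over time (>= 2 levels,
#'   >= 30 repeats each)
#' @param iMax ADC full scale recorded in the model (default 4095)
#' @return a \linkS4class{NoiseModel}
#' @export
fitNoiseModel <- function(whiteStack, iMax = 4095) {
  if (length(whiteStack) < 2)
    stop("at least two intensity levels are required to fit the noise model")
  if (any(vapply(whiteStack, nrow, 0L) < 30))
    stop("at least 30 repeats per level are required")
  mI <- t(vapply(whiteStack, colMeans, numeric(.NBANDS)))      # levels x 16
  vE <- t(vapply(whiteStack, function(m) {
    apply(m, 2, function(col) stats::var(col / mean(col) - 1))
  }, numeric(.NBANDS)))                                        # levels x 16
  a <- numeric(.NBANDS); b <- numeric(.NBANDS)
  for (n in seq_len(.NBANDS)) {
    # a variance estimate scatters proportionally to its value, so the
    # regression is weighted by 1/variance^2; this keeps the low-intensity
    # levels, which identify the intercept, from being drowned out
    wts <- 1 / pmax(vE[, n], .Machine$double.eps)^2
    co <- stats::coef(stats::lm(vE[, n] ~ mI[, n], weights = wts))
    a[n] <- max(co[1], 0)
    slope <- max(co[2], 0)
    b[n] <- if (slope > 0) 1 / slope else Inf
  }
  new("NoiseModel", a = a, b = b, iMax = iMax)
}

#' Fit the lamp variation model from warm-up and angle series
#'
#' The stable lamp spectrum is the emission at the end of the warm-up period
#' (t = 60 min, 0 deg). The maximal temporal deviation is
#' delta_t,max = L(t=0)/L(t=60) - 1 and the maximal angular deviation is
#' delta_theta,max = L(22 deg)/L(0 deg) - 1; intermediate spectra scale
#' linearly between the extremes (see \code{\link{lampScaleFactor}}).
#'
#' @param Lseries list of \code{list(t = minutes, L = Spectrum)} warm-up
#'   spectra; must include t = 0 and t = 60
#' @param Langles list with elements \code{deg0} and \code{deg22}
#'   (\linkS4class{Spectrum})
#' @return list with \code{L}, \code{deltaTMax}, \code{deltaThetaMax}
#'   (all \linkS4class{Spectrum})
#' @export
fitLampVariation <- function(Lseries, Langles) {
  tt <- vapply(Lseries, `[[`, 0, "t")
  i0 <- which(tt == 0); i60 <- which(tt == 60)
  if (!length(i0) || !length(i60))
    stop("warm-up series must include t = 0 and t = 60 min spectra")
  L <- Lseries[[i60[1]]]$L
  L0 <- Lseries[[i0[1]]]$L
  list(L = L,
       deltaTMax = Spectrum(L0@values / L@values - 1),
       deltaThetaMax = Spectrum(Langles$deg22@values / Langles$deg0@values - 1))
}

#' Recover the lamp perturbation coordinate of an observed spectrum
#'
#' Least-squares estimate of q in L_obs = L (1 + q delta_max): projects the
#' observed relative deviation onto the maximal deviation spectrum.
#'
#' @param Lobs observed \linkS4class{Spectrum}
#' @param L stable lamp \linkS4class{Spectrum}
#' @param deltaMax maximal deviation \linkS4class{Spectrum}
#' @return scalar q
#' @export
lampScaleFactor <- function(Lobs, L, deltaMax) {
  dev <- Lobs@values / L@values - 1
  sum(dev * deltaMax@values) / sum(deltaMax@values^2)
}
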
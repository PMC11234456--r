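# Synthetic MSI spectrum generation: tissue parameter sampling, the six-step
# spectrum synthesis with hardware variations, training sets, and synthetic
# fixtures (tunable-filter sweeps, white stacks, phantom hypercube movies).

#' Bundle the forward-model components
#'
#' Collects the look-up table, chromophores, sensor response, optics and
#' noise model used by the spectrum synthesizer and the estimators.
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param chromophores a \linkS4class{ChromophoreSet}
#' @param response a \linkS4class{SensorResponse}
#' @param optics an \linkS4class{OpticsModel}
#' @param noise a \linkS4class{NoiseModel}
#' @return a named list of the five components
#' @export
forwardModels <- function(lut, chromophores = loadChromophores(),
                          response = defaultSensorResponse(),
                          optics = defaultOptics(),
                          noise = defaultNoiseModel()) {
  list(lut = lut, chromophores = chromophores, response = response,
       optics = optics, noise = noise)
}

#' Default tissue parameter distribution
#'
#' Sampling laws emulating the parameter variation of real skin tissue:
#' epidermis thickness log-uniform on [0.025, 0.3] mm; melanin amount (the
#' product f_mel * t_epi, which is what varies physiologically) log-uniform
#' on [2e-4, 0.01] mm, giving melanin fractions up to about 0.4; dermal blood
#' fraction log-uniform on [0.001, 0.1]; SO2 uniform on [0, 1]; vessel
#' diameter log-uniform on [0.005, 0.3] mm; alpha log-uniform on [1, 6]
#' mm^-1 and beta uniform on [0.5, 2.5], rejection-sampled so that
#' mu_s'(lambda) stays within the simulated range [1.0, 90.5] mm^-1.
#'
#' @param ... named overrides; each entry a list(law, min, max) with law one
#'   of \code{"loguniform"}, \code{"uniform"}, \code{"point"} (use min for the
#'   point value)
#' @return a named list of sampling laws (class \code{"ParamDistribution"})
#' @export
defaultParamDistribution <- function(...) {
  dist <- list(
    tEpi = list(law = "loguniform", min = 0.025, max = 0.3),
    melAmount = list(law = "loguniform", min = 2e-4, max = 0.01),
    fBlood = list(law = "loguniform", min = 0.001, max = 0.1),
    s = list(law = "uniform", min = 0, max = 1),
    D = list(law = "loguniform", min = 0.005, max = 0.3),
    alpha = list(law = "loguniform", min = 1.0, max = 6.0),
    beta = list(law = "uniform", min = 0.5, max = 2.5))
  over <- list(...)
  for (nm in names(over)) dist[[nm]] <- over[[nm]]
  class(dist) <- "ParamDistribution"
  dist
}

.drawLaw <- function(spec, n) {
  switch(spec$law,
         uniform = stats::runif(n, spec$min, spec$max),
         loguniform = exp(stats::runif(n, log(spec$min), log(spec$max))),
         point = rep(spec$min, n),
         stop("unknown sampling law: ", spec$law))
}

#' Sample tissue parameter sets
#'
#' Draws n parameter sets from the distribution. The melanin amount
#' (f_mel * t_epi) is sampled and divided by the epidermis thickness to give
#' the melanin fraction. Draws violating the simulated scattering range are
#' rejected and redrawn.
#'
#' @param dist a distribution from \code{\link{defaultParamDistribution}}
#' @param n number of parameter sets
#' @param seed optional integer seed
#' @return data.frame with columns tEpi, fMel, fBlood, s, D, alpha, beta,
#'   melAmount
#' @export
sampleParams <- function(dist, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(m) {
    d <- data.frame(tEpi = .drawLaw(dist$tEpi, m),
                    melAmount = .drawLaw(dist$melAmount, m),
                    fBlood = .drawLaw(dist$fBlood, m),
                    s = .drawLaw(dist$s, m),
                    D = .drawLaw(dist$D, m),
                    alpha = .drawLaw(dist$alpha, m),
                    beta = .drawLaw(dist$beta, m))
    d$fMel <- d$melAmount / d$tEpi
    d
  }
  out <- draw(n)
  ok <- function(d) {
    mus400 <- d$alpha * (400 / 600)^(-d$beta)
    mus700 <- d$alpha * (700 / 600)^(-d$beta)
    d$fMel <= 1 & pmax(mus400, mus700) <= 90.5 & pmin(mus400, mus700) >= 1.0
  }
  bad <- !ok(out)
  while (any(bad)) {
    out[bad, ] <- draw(sum(bad))
    bad <- !ok(out)
  }
  out[c("tEpi", "fMel", "fBlood", "s", "D", "alpha", "beta", "melAmount")]
}

# truncated draws of the target mean detected intensity (step 3)
.drawRI <- function(n, iMax) {
  out <- stats::rnorm(n, iMax / 2, 0.2 * iMax)
  bad <- out <= 0.05 * iMax | out > iMax
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), iMax / 2, 0.2 * iMax)
    bad <- out <= 0.05 * iMax | out > iMax
  }
  out
}

# Vectorized synthesis core. params: data.frame as from sampleParams.
# Returns the n x 16 matrix of normalized spectra N_ANN.
.synthesizeMatrix <- function(params, models, noise = TRUE, sharedQ = FALSE,
                              qT = NULL, qTheta = NULL, qTW = NULL,
                              qThetaW = NULL, chunk = 512L) {
  n <- nrow(params)
  lam <- .GRID
  ch <- models$chromophores
  M0 <- .bandWeights(models$response, models$optics)        # 16 x 301
  Lv <- models$optics@L@values
  dT <- models$optics@deltaTMax@values
  dTh <- models$optics@deltaThetaMax@values
  nm <- models$noise
  epiBase <- 39.0 * (lam / 550)^(-3)
  logl <- log(lam / 600)

  recy <- function(q) if (length(q) == 1L) rep(q, n) else q
  qt_t <- recy(qT %||% stats::runif(n))
  qh_t <- recy(qTheta %||% stats::runif(n))
  if (sharedQ) {
    qt_w <- qt_t; qh_w <- qh_t
  } else {
    qt_w <- recy(qTW %||% stats::runif(n))
    qh_w <- recy(qThetaW %||% stats::runif(n))
  }

  X <- matrix(NA_real_, n, .NBANDS)
  for (i0 in seq(1L, n, by = chunk)) {
    ix <- i0:min(i0 + chunk - 1L, n)
    m <- length(ix)
    p <- params[ix, , drop = FALSE]
    muaB <- outer(p$s, ch@muaOxy@values) + outer(1 - p$s, ch@muaRed@values)
    x <- p$D * muaB
    cvd <- ifelse(x < 1e-6, 1 - x / 2 + x^2 / 6, (1 - exp(-x)) / x)
    muaD <- p$fBlood * cvd * muaB
    muaE <- outer(p$fMel, epiBase)
    mus <- p$alpha * exp(outer(-p$beta, logl))
    # step 1: tissue reflectance, queried per wavelength
    Tm <- matrix(.interpTvec(models$lut,
                             rep(p$tEpi, .NGRID),
                             as.numeric(mus), as.numeric(muaE),
                             as.numeric(muaD)), m, .NGRID)
    # step 2: perturbed lamp, tissue and white passes
    lampT <- (1 + outer(qt_t[ix], dT)) * (1 + outer(qh_t[ix], dTh))
    lampW <- (1 + outer(qt_w[ix], dT)) * (1 + outer(qh_w[ix], dTh))
    Lmat <- matrix(Lv, m, .NGRID, byrow = TRUE)
    IT0 <- (Tm * Lmat * lampT) %*% t(M0)                    # m x 16
    IW0 <- (Lmat * lampW) %*% t(M0)
    if (noise) {
      # steps 3-6 for the tissue pass, then independently for the white pass
      scaleTo <- function(I0) {
        RI <- .drawRI(m, nm@iMax)
        RI * I0 / rowMeans(I0)
      }
      addNoise <- function(I) {
        v <- matrix(nm@a, m, .NBANDS, byrow = TRUE) +
          sweep(I, 2, nm@b, "/")
        eps <- matrix(stats::rnorm(m * .NBANDS, 0, sqrt(pmax(as.numeric(v), 0))),
                      m, .NBANDS)
        I * (1 + pmax(eps, -0.999))
      }
      IT <- addNoise(scaleTo(IT0))
      IW <- addNoise(scaleTo(IW0))
    } else {
      IT <- IT0; IW <- IW0
    }
    ratio <- IT / IW
    X[ix, ] <- ratio / rowMeans(ratio)
  }
  X
}

#' Synthesize one normalized MSI spectrum
#'
#' Executes the six-step synthesis for a single tissue parameter set:
#' (1) MC tissue reflectance from the look-up table; (2) a perturbed lamp
#' spectrum with q_t, q_theta ~ U[0, 1]; (3) a target mean intensity R_I
#' drawn from Normal(I_max/2, 0.2 I_max) truncated to (0.05 I_max, I_max];
#' (4) intensity scaling to R_I; (5) detector noise factors with
#' intensity-dependent variance; (6) the noisy band intensities. A white
#' spectrum is generated the same way with T = 1 (independent draws unless
#' \code{sharedQ}), and the ratio is mean-normalized so the output band mean
#' is exactly 1.
#'
#' @param params a \linkS4class{TissueParams}
#' @param models forward-model bundle from \code{\link{forwardModels}}
#' @param seed optional integer seed (same seed, same output)
#' @param noise logical; disable to obtain the noiseless deterministic
#'   reduction (steps 3-6 skipped)
#' @param sharedQ share the lamp perturbation coordinates between tissue and
#'   white passes
#' @param qT,qTheta optional explicit lamp coordinates (scalars)
#' @return list with \code{N} (fully normalized \linkS4class{MSISpectrum})
#'   and \code{so2} (target SO2 in percent)
#' @export
synthesizeSpectrum <- function(params, models, seed = NULL, noise = TRUE,
                               sharedQ = FALSE, qT = NULL, qTheta = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(tissueParamsToList(params))
  names(df) <- c("tEpi", "fMel", "fBlood", "s", "D", "alpha", "beta")
  X <- .synthesizeMatrix(df, models, noise = noise, sharedQ = sharedQ,
                         qT = qT, qTheta = qTheta)
  list(N = MSISpectrum(X[1, ], "fully_normalized"), so2 = 100 * params@s)
}

#' Shuffled 70/15/15 split indices
#'
#' @param n number of samples
#' @param seed optional integer seed
#' @return list with disjoint index vectors \code{train}, \code{val},
#'   \code{test} of sizes round(0.70 n) / round(0.15 n) / remainder
#' @export
makeSplit <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  nTrain <- round(0.70 * n)
  nVal <- round(0.15 * n)
  list(train = idx[seq_len(nTrain)],
       val = idx[nTrain + seq_len(nVal)],
       test = idx[(nTrain + nVal + 1L):n])
}

#' Generate a synthetic training set
#'
#' Samples n tissue parameter sets, synthesizes their normalized MSI spectra
#' with the full noise model, and splits them 70/15/15 into training,
#' validation and test partitions.
#'
#' @param dist parameter distribution
#' @param models forward-model bundle
#' @param n number of spectra (default 50000)
#' @param seed integer seed
#' @param noise logical, passed to the synthesizer
#' @return a \linkS4class{TrainingSet}
#' @export
generateTrainingSet <- function(dist, models, n = 50000, seed = 1,
                                noise = TRUE) {
  set.seed(seed)
  params <- sampleParams(dist, n)
  X <- .synthesizeMatrix(params, models, noise = noise)
  # exact mean-1 contract against accumulated floating-point round-off
  X <- X / rowMeans(X)
  new("TrainingSet", X = X, y = 100 * params$s, params = params,
      split = makeSplit(n))
}

#' Generate a synthetic occlusion-release SO2 trace
#'
#' Synthesizes a sequence of ROI-averaged normalized MSI spectra whose
#' per-frame SO2 follows an occlusion-release trajectory (baseline 60
#' percent, decay to 0 during occlusion, reactive-hyperemia peak at 85,
#' return to baseline) with the other tissue parameters fixed at mid-range.
#' The sequence emulates the measurement chain of an in-vivo recording with
#' a warmed-up lamp: the temporal lamp coordinate is 0 for both tissue and
#' white passes, and the angular coordinate is drawn once per recording and
#' shared between the two passes — the emission-angle deviation is a
#' property of the position in the field of view, and the white reference is
#' recorded with the same camera geometry, so at a fixed ROI it cancels in
#' the white normalization (set \code{sharedAngle = FALSE} to emulate a
#' misaligned white recording instead). Detector noise carries the effective
#' spatial averaging of an ROI of \code{roiPixels} pixels. Training data, in
#' contrast, use the full independent-q single-pixel noise model.
#'
#' @param models forward-model bundle from \code{\link{forwardModels}}
#' @param nFrames number of frames (default 100)
#' @param baseParams \linkS4class{TissueParams} supplying the non-SO2
#'   parameters (default mid-range skin values; its \code{s} slot is ignored)
#' @param sTrajectory optional explicit SO2 fractions per frame
#' @param roiPixels ROI size in pixels for noise averaging (default 25, a
#'   5 x 5 region)
#' @param seed optional integer seed
#' @return list with \code{X} (nFrames x 16 normalized spectra), \code{so2}
#'   (true SO2 in percent), \code{qTheta} (scene and white draws)
#' @export
generateOcclusionTrace <- function(models, nFrames = 100,
                                   baseParams = tissueParams(0.08, 0.05, 0.01,
                                                             0.6, 0.03, 2.5, 1.3),
                                   sTrajectory = NULL, roiPixels = 25,
                                   sharedAngle = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sTrajectory)) {
    n1 <- round(0.4 * nFrames); n2 <- round(0.2 * nFrames)
    n3 <- nFrames - n1 - n2
    sTrajectory <- c(seq(0.6, 0, length.out = n1),
                     seq(0.02, 0.85, length.out = n2),
                     seq(0.84, 0.6, length.out = n3))
  }
  stopifnot(length(sTrajectory) == nFrames)
  nz <- models$noise
  modsROI <- models
  modsROI$noise <- new("NoiseModel", a = nz@a / roiPixels,
                       b = nz@b * roiPixels, iMax = nz@iMax)
  qScene <- stats::runif(1)
  qWhite <- if (sharedAngle) qScene else stats::runif(1)
  p <- data.frame(tEpi = baseParams@tEpi, fMel = baseParams@fMel,
                  fBlood = baseParams@fBlood, s = sTrajectory,
                  D = baseParams@D, alpha = baseParams@alpha,
                  beta = baseParams@beta)
  X <- .synthesizeMatrix(p, modsROI, noise = TRUE, qT = 0, qTheta = qScene,
                         qTW = 0, qThetaW = qWhite)
  list(X = X / rowMeans(X), so2 = 100 * sTrajectory,
       qTheta = c(scene = qScene, white = qWhite))
}

#' Generate a synthetic tunable-filter calibration sweep
#'
#' Builds Gaussian narrowband reference spectra of the stated FWHM centered
#' at each sweep setting (400..700 nm in 1 nm steps), illuminated by a broad
#' calibration lamp, and forward-models the band intensities from a known
#' ground-truth response, optionally adding relative Gaussian noise to the
#' measured intensities. Closes the loop with
#' \code{\link{estimateResponse}}, whose recovered response can be compared
#' against \code{trueResponse}.
#'
#' @param trueResponse ground-truth \linkS4class{SensorResponse}
#' @param lamp calibration lamp \linkS4class{Spectrum} (must be positive over
#'   the grid); default a broad white spectrum
#' @param fwhm filter full width at half maximum, nm (default 7)
#' @param noiseLevel relative standard deviation of intensity noise
#'   (default 0)
#' @param seed optional integer seed
#' @return a \linkS4class{CalibrationDataset} with 301 settings
#' @export
generateLctfFixture <- function(trueResponse, lamp = NULL, fwhm = 7,
                                noiseLevel = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lampV <- if (is.null(lamp)) 0.3 + defaultOptics()@L@values else lamp@values
  stopifnot(all(lampV > 0))
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  settings <- .GRID
  R <- vapply(settings, function(m) lampV * exp(-(.GRID - m)^2 / (2 * sig^2)),
              numeric(.NGRID))                               # 301 x 301
  I <- trueResponse@r %*% R                                  # 16 x 301
  if (noiseLevel > 0)
    I <- I * (1 + matrix(stats::rnorm(length(I), 0, noiseLevel),
                         nrow(I), ncol(I)))
  calibrationDataset(pmax(I, 0), R, settings)
}

#' Generate a synthetic white measurement stack
#'
#' Repeated white-reference band intensities over time at several intensity
#' levels, with noise drawn from a known model; the fixture for
#' \code{\link{fitNoiseModel}}.
#'
#' @param noise ground-truth \linkS4class{NoiseModel}
#' @param levels intensity levels; the default spans 2 to 70 percent of the
#'   ADC range with a log-like spacing, so the lowest levels identify the
#'   variance intercept while the highest pin down the slope
#' @param nRepeats repeats per level (default 200)
#' @param seed optional integer seed
#' @return list over levels of nRepeats x 16 intensity matrices
#' @export
generateWhiteStack <- function(noise, levels = NULL, nRepeats = 200,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  levels <- levels %||% (noise@iMax * c(0.02, 0.05, 0.12, 0.3, 0.7))
  lapply(levels, function(I0) {
    sdv <- sqrt(noise@a + I0 / noise@b)
    eps <- matrix(stats::rnorm(nRepeats * .NBANDS, 0,
                               rep(sdv, each = nRepeats)),
                  nRepeats, .NBANDS)
    I0 * (1 + pmax(eps, -0.999))
  })
}

#' Generate a synthetic phantom hypercube movie
#'
#' Produces mosaic-patterned raw frames for a time-varying SO2 scene through
#' the full forward model with per-pixel detector noise, paired with white
#' and dark frames, emulating an acquisition that the preprocessing pipeline
#' can consume end to end.
#'
#' @param scene list with \code{so2Frames} (list of H x W matrices of SO2
#'   fractions, one per time point, H and W being hypercube dimensions),
#'   \code{baseParams} (a \linkS4class{TissueParams} supplying the non-SO2
#'   parameters), optional \code{darkOffset} (ADC counts, default 40) and
#'   \code{whiteLevel} (fraction of full scale, default 0.6)
#' @param models forward-model bundle
#' @param seed optional integer seed
#' @return list with \code{frames} (list of measurement
#'   \linkS4class{RawFrame}s), \code{white} (white \linkS4class{RawFrame}),
#'   \code{dark} (dark \linkS4class{RawFrame}), \code{layout} (mosaic band
#'   map)
#' @export
generatePhantomMovie <- function(scene, models, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offset <- scene$darkOffset %||% 40
  whiteLevel <- scene$whiteLevel %||% 0.6
  lay <- mosaicLayout()
  bp <- scene$baseParams
  nmod <- models$noise
  M0 <- .bandWeights(models$response, models$optics)
  dims <- dim(scene$so2Frames[[1]])
  H <- dims[1]; W <- dims[2]

  bandIntensities <- function(sMap, qT, qTheta) {
    # 16 x H x W band intensities before amplification noise
    su <- sort(unique(as.numeric(sMap)))
    Lp <- perturbedLamp(models$optics, qT, qTheta)
    Iu <- vapply(su, function(s) {
      p <- tissueParams(bp@tEpi, bp@fMel, bp@fBlood, s, bp@D, bp@alpha, bp@beta)
      Tc <- tissueReflectance(models$lut, p, models$chromophores)
      as.numeric(M0 %*% (Lp@values * Tc@values))
    }, numeric(.NBANDS))                                     # 16 x n_unique
    idx <- match(as.numeric(sMap), su)
    array(Iu[, idx], dim = c(.NBANDS, H, W))
  }

  toMosaic <- function(cube, scaleTo) {
    # scale so the spatial/band mean hits scaleTo, sample the mosaic sites,
    # add per-pixel noise and the dark offset
    cube <- cube * (scaleTo / mean(cube))
    px <- matrix(NA_real_, 4L * H, 4L * W)
    for (di in 1:4) for (dj in 1:4) {
      b <- lay[di, dj]
      px[seq(di, 4L * H, by = 4L), seq(dj, 4L * W, by = 4L)] <- cube[b, , ]
    }
    # per-pixel band-dependent noise variance a_n + I/b_n
    bmap <- lay[cbind(as.integer((row(px) - 1L) %% 4L + 1L),
                      as.integer((col(px) - 1L) %% 4L + 1L))]
    vv <- nmod@a[bmap] + px / nmod@b[bmap]
    eps <- matrix(stats::rnorm(length(px), 0, sqrt(pmax(vv, 0))), nrow(px))
    px * (1 + pmax(eps, -0.999)) + offset
  }

  frames <- lapply(scene$so2Frames, function(sMap) {
    cube <- bandIntensities(sMap, stats::runif(1), stats::runif(1))
    new("RawFrame", pixels = toMosaic(cube, whiteLevel * nmod@iMax * 0.7),
        exposure = 20, timestamp = 0, kind = "measurement")
  })
  for (i in seq_along(frames)) frames[[i]]@timestamp <- i - 1
  whiteCube <- {
    Lp <- perturbedLamp(models$optics, stats::runif(1), stats::runif(1))
    Iw <- as.numeric(M0 %*% Lp@values)
    array(Iw, dim = c(.NBANDS, H, W))
  }
  white <- new("RawFrame", pixels = toMosaic(whiteCube, whiteLevel * nmod@iMax),
               exposure = 20, timestamp = -1, kind = "white")
  dark <- new("RawFrame", pixels = matrix(offset, 4L * H, 4L * W),
              exposure = 20, timestamp = -2, kind = "dark")
  list(frames = frames, white = white, dark = dark, layout = lay)
}
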
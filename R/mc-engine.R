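# White Monte Carlo engine and the 4-D reflectance look-up table.

#' Run a white Monte Carlo simulation
#'
#' Launches a pencil beam of photons normally into a semi-infinite two-layer
#' slab with zero absorption and Henyey-Greenstein scattering, and records
#' per-photon epidermis and dermis pathlengths for photons exiting the top
#' surface. Both layers share the (unreduced) scattering coefficient and
#' anisotropy, so the layer boundary only partitions pathlengths. Fresnel
#' reflection at the tissue-air boundary is sampled probabilistically;
#' photons whose total pathlength exceeds \code{maxPath} are terminated and
#' counted.
#'
#' Reproducibility follows R's RNG: call \code{set.seed()} (or pass
#' \code{seed}) before running.
#'
#' @param tEpi epidermis thickness, mm
#' @param muS unreduced scattering coefficient, mm^-1 (= 5 mu_s' at g = 0.8)
#' @param g scattering anisotropy (default 0.8)
#' @param nPhotons number of launched photons
#' @param seed optional integer seed
#' @param nTissue tissue refractive index relative to air (1.4; use 1 for a
#'   matched boundary with no Fresnel reflection)
#' @param maxPath maximum total pathlength, mm (default 400)
#' @return list with \code{records} (matrix with columns path_epi, path_derm,
#'   weight; one row per detected photon), \code{n_launched},
#'   \code{n_truncated}
#' @examples
#' wmc <- runWhiteMC(0.1, muS = 10, nPhotons = 1000, seed = 1, nTissue = 1)
#' nrow(wmc$records) / wmc$n_launched  # close to 1: all photons return
#' @export
runWhiteMC <- function(tEpi, muS, g = 0.8, nPhotons, seed = NULL,
                       nTissue = 1.4, maxPath = 400) {
  if (tEpi <= 0 || muS <= 0 || nPhotons < 1 || g <= -1 || g >= 1 ||
      nTissue < 1 || maxPath <= 0)
    stop("non-physical white MC inputs")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_white_mc(tEpi, muS, g, as.integer(nPhotons), nTissue, maxPath)
  list(records = res$records, n_launched = res$n_launched,
       n_truncated = res$n_truncated)
}

#' Apply Beer-Lambert absorption to white MC photon records
#'
#' T = (1/N) sum_i w_i exp(-mu_a,epi l_epi,i - mu_a,derm l_derm,i) over the
#' detected photons, N the number of launched photons.
#'
#' @param records photon record matrix (or the list returned by
#'   \code{\link{runWhiteMC}})
#' @param muaEpi epidermis absorption coefficient, mm^-1 (scalar)
#' @param muaDerm dermis absorption coefficient, mm^-1 (scalar)
#' @param nLaunched number of launched photons (taken from the list when
#'   \code{records} is a \code{runWhiteMC} result)
#' @return detected reflectance T, dimensionless
#' @export
applyAbsorption <- function(records, muaEpi, muaDerm, nLaunched = NULL) {
  if (is.list(records)) {
    nLaunched <- records$n_launched
    records <- records$records
  }
  stopifnot(muaEpi >= 0, muaDerm >= 0, !is.null(nLaunched))
  cpp_absorption_grid(records[, 1], records[, 2], records[, 3],
                      nLaunched, muaEpi, muaDerm)[1, 1]
}

#' Default look-up table axes
#'
#' Epidermis thickness log-spaced on [0.0025, 0.49] mm (9 nodes); reduced
#' scattering at 600 nm log-spaced on [1.0, 90.5] mm^-1 (9 nodes); both
#' absorption axes log-spaced on [1e-4, 1e2] mm^-1 (24 nodes) plus an exact
#' zero node. Reflectance is smooth in these log coordinates and the ranges
#' bracket the physiological parameter space of the tissue model.
#'
#' @param nTEpi,nMus,nMua node counts per axis
#' @return list of the four axis vectors
#' @export
defaultLutAxes <- function(nTEpi = 9, nMus = 9, nMua = 24) {
  list(tEpi = exp(seq(log(0.0025), log(0.49), length.out = nTEpi)),
       mus = exp(seq(log(1.0), log(90.5), length.out = nMus)),
       muaEpi = c(0, 10^seq(-4, 2, length.out = nMua)),
       muaDerm = c(0, 10^seq(-4, 2, length.out = nMua)))
}

#' Build the 4-D reflectance look-up table
#'
#' Runs one white MC simulation per (epidermis thickness, reduced scattering)
#' node and fills the two absorption axes by Beer-Lambert post-processing of
#' the recorded photon pathlengths.
#'
#' @param axes axis specification as from \code{\link{defaultLutAxes}}
#' @param nPhotons photons launched per node (the photon budget is recorded
#'   in the metadata; interpolation noise scales as 1/sqrt(nPhotons))
#' @param seed integer seed making the build reproducible
#' @param g anisotropy (0.8)
#' @param nTissue relative refractive index (1.4)
#' @param maxPath pathlength cap, mm
#' @param verbose print per-node progress
#' @return a \linkS4class{ReflectanceLUT}
#' @export
buildLUT <- function(axes = defaultLutAxes(), nPhotons = 30000, seed = 1,
                     g = 0.8, nTissue = 1.4, maxPath = 400, verbose = FALSE) {
  set.seed(seed)
  nt <- length(axes$tEpi); ns <- length(axes$mus)
  na <- length(axes$muaEpi); nb <- length(axes$muaDerm)
  vals <- array(NA_real_, dim = c(nt, ns, na, nb))
  truncated <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(ns)) {
      muS <- axes$mus[j] / (1 - g)
      wmc <- cpp_white_mc(axes$tEpi[i], muS, g, as.integer(nPhotons),
                          nTissue, maxPath)
      truncated <- truncated + wmc$n_truncated
      rec <- wmc$records
      vals[i, j, , ] <- cpp_absorption_grid(rec[, 1], rec[, 2], rec[, 3],
                                            wmc$n_launched,
                                            axes$muaEpi, axes$muaDerm)
      if (verbose)
        message(sprintf("LUT node t_epi=%.4g mm, mu_s'=%.3g mm^-1: T0=%.3f",
                        axes$tEpi[i], axes$mus[j], vals[i, j, 1, 1]))
    }
  }
  new("ReflectanceLUT", tEpiAxis = axes$tEpi, musAxis = axes$mus,
      muaEpiAxis = axes$muaEpi, muaDermAxis = axes$muaDerm,
      values = pmin(vals, 1),
      meta = list(n_photons = nPhotons, g = g, n_tissue = nTissue,
                  max_path_mm = maxPath, seed = seed,
                  truncated_fraction = truncated / (nPhotons * nt * ns),
                  build_date = format(Sys.time(), "%Y-%m-%d")))
}

# transformed interpolation coordinate per axis
.lutCoord <- function(ax, x, name) {
  if (name %in% c("muaEpi", "muaDerm")) {
    off <- ax[ax > 0][1]  # first positive node handles the exact-zero node
    list(nodes = log(ax + off), q = log(x + off))
  } else {
    list(nodes = log(ax), q = log(x))
  }
}

# Vectorized multilinear interpolation in transformed coordinates.
# All four query vectors must have equal length.
.interpTvec <- function(lut, tEpi, mus, muaEpi, muaDerm) {
  qs <- list(tEpi = tEpi, mus = mus, muaEpi = muaEpi, muaDerm = muaDerm)
  axs <- list(tEpi = lut@tEpiAxis, mus = lut@musAxis,
              muaEpi = lut@muaEpiAxis, muaDerm = lut@muaDermAxis)
  n <- length(tEpi)
  lo <- matrix(0L, n, 4); w <- matrix(0, n, 4)
  for (k in seq_along(qs)) {
    nm <- names(qs)[k]
    tol <- 1e-9 * max(abs(axs[[nm]]), 1)
    bad <- qs[[nm]] < min(axs[[nm]]) - tol | qs[[nm]] > max(axs[[nm]]) + tol
    if (any(bad))
      stop(sprintf("LUT query outside axis hull for %s: value %.4g not in [%.4g, %.4g]",
                   nm, qs[[nm]][which(bad)[1]], min(axs[[nm]]), max(axs[[nm]])))
    tr <- .lutCoord(axs[[nm]], pmin(pmax(qs[[nm]], min(axs[[nm]])),
                                    max(axs[[nm]])), nm)
    i <- findInterval(tr$q, tr$nodes, all.inside = TRUE)
    lo[, k] <- i
    w[, k] <- (tr$q - tr$nodes[i]) / (tr$nodes[i + 1L] - tr$nodes[i])
  }
  w <- pmin(pmax(w, 0), 1)
  d <- dim(lut@values)
  out <- numeric(n)
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) for (c4 in 0:1) {
    wt <- (if (c1) w[, 1] else 1 - w[, 1]) *
          (if (c2) w[, 2] else 1 - w[, 2]) *
          (if (c3) w[, 3] else 1 - w[, 3]) *
          (if (c4) w[, 4] else 1 - w[, 4])
    idx <- (lo[, 1] + c1) +
      d[1] * ((lo[, 2] + c2 - 1L) +
      d[2] * ((lo[, 3] + c3 - 1L) +
      d[3] * (lo[, 4] + c4 - 1L)))
    out <- out + wt * lut@values[idx]
  }
  out
}

#' Interpolate tissue reflectance from the look-up table
#'
#' Per-wavelength multilinear interpolation of the detected reflectance
#' T(lambda) in transformed (log) coordinates. The scattering axis of the
#' table is scalar while mu_s'(lambda) follows the power law, so the table is
#' queried independently at every wavelength with the local mu_s'(lambda).
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param tEpi epidermis thickness, mm (scalar)
#' @param musPrime reduced scattering \linkS4class{Spectrum} (or scalar,
#'   taken constant over the grid), mm^-1
#' @param muaEpi epidermis absorption \linkS4class{Spectrum}, mm^-1
#' @param muaDerm dermis absorption \linkS4class{Spectrum}, mm^-1
#' @return a \linkS4class{Spectrum} of tissue reflectance T(lambda) in [0, 1]
#' @export
interpolateT <- function(lut, tEpi, musPrime, muaEpi, muaDerm) {
  asv <- function(x) if (is(x, "Spectrum")) x@values else
    if (length(x) == 1L) rep(x, .NGRID) else x
  mus <- asv(musPrime); mae <- asv(muaEpi); mad <- asv(muaDerm)
  Spectrum(.interpTvec(lut, rep(tEpi, .NGRID), mus, mae, mad))
}

#' Tissue reflectance spectrum for a parameter set
#'
#' Convenience wrapper: builds the layer optics for \code{params} and queries
#' the look-up table.
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param params a \linkS4class{TissueParams}
#' @param chromophores a \linkS4class{ChromophoreSet}
#' @return a \linkS4class{Spectrum} of T(lambda)
#' @export
tissueReflectance <- function(lut, params, chromophores) {
  opt <- layerOptics(params, chromophores)
  interpolateT(lut, params@tEpi, opt@musPrime, opt@muaEpi, opt@muaDerm)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Draws deflection-angle cosines from the Henyey-Greenstein phase function,
#' whose mean cosine equals the anisotropy g. Exposed for distributional
#' checks of the transport kernel.
#'
#' @param n number of draws
#' @param g anisotropy in (-1, 1)
#' @param seed optional integer seed
#' @return numeric vector of cosines in [-1, 1]
#' @export
sampleHG <- function(n, g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_hg_sample(as.integer(n), g)
}
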
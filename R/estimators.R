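# The two SO2 estimators: a shallow feed-forward network trained with
# Levenberg-Marquardt, and iterative inverse Monte Carlo spectral fitting.

.annForward <- function(W1, b1, W2, b2, X) {
  # X: n x 16; returns n predictions
  Z <- tcrossprod(X, W1) + rep(b1, each = nrow(X))
  H <- tanh(Z)
  as.numeric(H %*% t(W2)) + b2
}

#' Predict SO2 with a trained network
#'
#' Forward pass tanh(W1 x + b1) followed by a linear readout. The input
#' contract is a fully normalized spectrum (band mean 1); the output is SO2
#' in percent and is deliberately not clipped to [0, 100].
#'
#' @param model an \linkS4class{AnnModel}
#' @param N a fully normalized \linkS4class{MSISpectrum}, or an n x 16 matrix
#'   of such spectra (row means 1)
#' @return SO2 in percent (scalar or vector)
#' @export
annPredict <- function(model, N) {
  if (is(N, "MSISpectrum")) {
    if (normState(N) != "fully_normalized")
      stop("annPredict requires a fully_normalized spectrum")
    X <- matrix(N@values, 1)
  } else {
    X <- as.matrix(N)
    if (ncol(X) != .NBANDS) stop("input must have 16 bands")
    if (max(abs(rowMeans(X) - 1)) > 1e-6)
      stop("annPredict requires fully normalized spectra (row mean 1)")
  }
  .annForward(model@W1, model@b1, model@W2, model@b2, X)
}

# residual Jacobian of the network output wrt the flattened weights
.annJacobian <- function(W1, b1, W2, b2, X) {
  n <- nrow(X); H <- nrow(W1)
  Z <- tcrossprod(X, W1) + rep(b1, each = n)
  Th <- tanh(Z)
  A <- (1 - Th^2) * rep(as.numeric(W2), each = n)   # n x H
  J <- matrix(0, n, H * .NBANDS + 2L * H + 1L)
  for (j in seq_len(H))                              # d/dW1[j, ]
    J[, (j - 1L) * .NBANDS + seq_len(.NBANDS)] <- A[, j] * X
  J[, H * .NBANDS + seq_len(H)] <- A                 # d/db1
  J[, H * .NBANDS + H + seq_len(H)] <- Th            # d/dW2
  J[, H * .NBANDS + 2L * H + 1L] <- 1                # d/db2
  J
}

.annUnpack <- function(theta, H) {
  list(W1 = matrix(theta[seq_len(H * .NBANDS)], H, .NBANDS, byrow = TRUE),
       b1 = theta[H * .NBANDS + seq_len(H)],
       W2 = matrix(theta[H * .NBANDS + H + seq_len(H)], 1, H),
       b2 = theta[H * .NBANDS + 2L * H + 1L])
}

# a fixed number of plain LM steps on the training SSE (used for the
# initialization warm-up)
.lmSteps <- function(theta, H, X, y, nSteps = 5, mu = 1e-3) {
  npar <- length(theta)
  w <- .annUnpack(theta, H)
  err <- .annForward(w$W1, w$b1, w$W2, w$b2, X) - y
  sse <- sum(err^2)
  for (k in seq_len(nSteps)) {
    J <- .annJacobian(w$W1, w$b1, w$W2, w$b2, X)
    g <- crossprod(J, err)
    Hm <- crossprod(J)
    repeat {
      step <- tryCatch(solve(Hm + diag(mu, npar), -g), error = function(e) NULL)
      if (!is.null(step)) {
        th2 <- theta + as.numeric(step)
        w2 <- .annUnpack(th2, H)
        err2 <- .annForward(w2$W1, w2$b1, w2$W2, w2$b2, X) - y
        sse2 <- sum(err2^2)
        if (is.finite(sse2) && sse2 < sse) {
          theta <- th2; w <- w2; err <- err2; sse <- sse2
          mu <- max(mu * 0.1, 1e-12)
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e10) return(list(theta = theta, sse = sse))
    }
  }
  list(theta = theta, sse = sse)
}

#' Train the SO2 regression network
#'
#' Levenberg-Marquardt minimization of the mean-square training error over
#' the flattened network weights (per-sample errors as the residual vector,
#' analytic Jacobian). After every accepted step the validation error is
#' evaluated; training stops when it has failed to improve for
#' \code{patience} consecutive steps, and the weights with the best
#' validation error are returned together with the test-split performance.
#'
#' @param trainSet a \linkS4class{TrainingSet}
#' @param H hidden layer size, one of 5, 10, 15, 20
#' @param seed integer seed for the random weight initialization
#' @param maxEpochs maximum accepted LM steps (default 100)
#' @param patience validation-failure patience (default 6)
#' @return an \linkS4class{AnnModel}; \code{meta} holds the hidden size,
#'   seed, epochs run, best validation MSE and test MSE (%-units squared)
#' @export
trainAnn <- function(trainSet, H = 15, seed = 1, maxEpochs = 100,
                     patience = 6) {
  stopifnot(H %in% c(5, 10, 15, 20))
  Xtr <- trainSet@X[trainSet@split$train, , drop = FALSE]
  ytr <- trainSet@y[trainSet@split$train]
  Xva <- trainSet@X[trainSet@split$val, , drop = FALSE]
  yva <- trainSet@y[trainSet@split$val]
  Xte <- trainSet@X[trainSet@split$test, , drop = FALSE]
  yte <- trainSet@y[trainSet@split$test]
  if (stats::var(ytr) == 0)
    warning("constant training targets: network degenerates to a constant predictor")

  set.seed(seed)
  npar <- H * .NBANDS + 2L * H + 1L
  # Nguyen-Widrow-style initialization adapted to the data: random hidden
  # directions rescaled so each unit's pre-activation has unit spread over
  # the training inputs, centered at the input mean (band means sit near 1,
  # far from zero), with thresholds spread to partition the active region.
  drawInit <- function() {
    W1i <- matrix(stats::rnorm(H * .NBANDS), H, .NBANDS)
    xbar <- colMeans(Xtr)
    z0 <- tcrossprod(sweep(Xtr, 2, xbar), W1i)
    sdz <- pmax(apply(z0, 2, stats::sd), 1e-8)
    W1i <- W1i / sdz
    b1i <- -as.numeric(W1i %*% xbar) + stats::runif(H, -1.5, 1.5)
    W2i <- stats::rnorm(H, 0, max(stats::sd(ytr), 1) / sqrt(H))
    c(as.numeric(t(W1i)), b1i, W2i, mean(ytr))
  }
  # brief warm-up: a few candidate draws, five LM steps each; continue the
  # best (guards a session against a poor basin without changing the
  # session's independence)
  cands <- lapply(seq_len(5), function(i) drawInit())
  warm <- lapply(cands, function(th) .lmSteps(th, H, Xtr, ytr, nSteps = 10))
  best0 <- which.min(vapply(warm, `[[`, 0, "sse"))
  theta <- warm[[best0]]$theta
  w <- .annUnpack(theta, H)
  err <- .annForward(w$W1, w$b1, w$W2, w$b2, Xtr) - ytr
  sse <- sum(err^2)
  valMse <- mean((.annForward(w$W1, w$b1, w$W2, w$b2, Xva) - yva)^2)
  best <- list(theta = theta, valMse = valMse)
  mu <- 1e-3
  epochs <- 0L
  fails <- 0L
  while (epochs < maxEpochs && fails < patience && mu < 1e10) {
    J <- .annJacobian(w$W1, w$b1, w$W2, w$b2, Xtr)
    g <- crossprod(J, err)
    Hm <- crossprod(J)
    accepted <- FALSE
    while (!accepted && mu < 1e10) {
      step <- tryCatch(solve(Hm + diag(mu, npar), -g),
                       error = function(e) NULL)
      if (is.null(step)) { mu <- mu * 10; next }
      th2 <- theta + as.numeric(step)
      w2 <- .annUnpack(th2, H)
      err2 <- .annForward(w2$W1, w2$b1, w2$W2, w2$b2, Xtr) - ytr
      sse2 <- sum(err2^2)
      if (is.finite(sse2) && sse2 < sse) {
        theta <- th2; w <- w2; err <- err2; sse <- sse2
        mu <- max(mu * 0.1, 1e-12)
        accepted <- TRUE
      } else {
        mu <- mu * 10
      }
    }
    if (!accepted) break
    epochs <- epochs + 1L
    valMse <- mean((.annForward(w$W1, w$b1, w$W2, w$b2, Xva) - yva)^2)
    if (valMse < best$valMse) {
      best <- list(theta = theta, valMse = valMse)
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
  }
  wb <- .annUnpack(best$theta, H)
  testMse <- mean((.annForward(wb$W1, wb$b1, wb$W2, wb$b2, Xte) - yte)^2)
  new("AnnModel", W1 = wb$W1, b1 = wb$b1, W2 = wb$W2, b2 = wb$b2,
      meta = list(H = H, seed = seed, epochs = epochs,
                  val_mse = best$valMse, test_mse = testMse,
                  train_mse = sse / length(ytr)))
}

#' Repeated network training with randomized initialization
#'
#' Trains \code{nRepeats} networks on the same data with distinct
#' initialization seeds and reports the spread of their predictions on a
#' common test set: the per-sample standard deviation across networks and
#' its average.
#'
#' @param trainSet a \linkS4class{TrainingSet} (reused across repeats;
#'   supply \code{datasets} for per-repeat regeneration)
#' @param nRepeats number of training repetitions (default 10)
#' @param H hidden layer size (default 15)
#' @param seed base seed; repeat i uses seed + 1000 * (i - 1)
#' @param testX optional common test matrix (default: the test split of
#'   \code{trainSet})
#' @param datasets optional list of \code{nRepeats} TrainingSets, one per
#'   repeat
#' @param ... passed to \code{\link{trainAnn}}
#' @return list with \code{models}, \code{predictions} (nTest x nRepeats),
#'   \code{perSampleStd}, \code{meanStd}, \code{bestModel} (lowest
#'   validation MSE)
#' @export
repeatTrain <- function(trainSet, nRepeats = 10, H = 15, seed = 1,
                        testX = NULL, datasets = NULL, ...) {
  testX <- testX %||% trainSet@X[trainSet@split$test, , drop = FALSE]
  models <- vector("list", nRepeats)
  for (i in seq_len(nRepeats)) {
    ts_i <- if (is.null(datasets)) trainSet else datasets[[i]]
    models[[i]] <- trainAnn(ts_i, H = H, seed = seed + 1000L * (i - 1L), ...)
  }
  preds <- vapply(models, function(m) annPredict(m, testX),
                  numeric(nrow(testX)))
  perStd <- if (nRepeats == 1) rep(0, nrow(testX)) else apply(preds, 1, stats::sd)
  vb <- which.min(vapply(models, function(m) m@meta$val_mse, 0))
  list(models = models, predictions = preds, perSampleStd = perStd,
       meanStd = mean(perStd), bestModel = models[[vb]])
}

# default inverse-fit bounds: full validated tissue-model ranges, SO2
# extended below 0 and above 1. The alpha lower bound 1.5 keeps
# mu_s'(700) = alpha (7/6)^(-beta) >= 1 for every beta in [0, 2.5], so any
# point in the box is a valid parameter set.
.fitBounds <- function() {
  list(lower = c(tEpi = 0.0025, fMel = 0, fBlood = 0, s = -0.2,
                 D = 0.001, alpha = 1.5, beta = 0.0),
       upper = c(tEpi = 0.49, fMel = 0.95, fBlood = 0.5, s = 1.2,
                 D = 0.5, alpha = 10, beta = 2.5))
}

# model a fully normalized spectrum from a parameter vector (plain forward
# model with the stable lamp, no noise); scattering/absorption queries are
# clamped to the LUT hull so the solver can roam the full bound box
.modelNormalized <- function(theta, models) {
  lut <- models$lut
  ch <- models$chromophores
  muaB <- theta["s"] * ch@muaOxy@values + (1 - theta["s"]) * ch@muaRed@values
  x <- theta["D"] * muaB
  cvd <- ifelse(abs(x) < 1e-6, 1 - x / 2, (1 - exp(-x)) / x)
  muaD <- theta["fBlood"] * cvd * muaB
  muaE <- theta["fMel"] * 39.0 * (.GRID / 550)^(-3)
  mus <- theta["alpha"] * (.GRID / 600)^(-theta["beta"])
  clamp <- function(v, ax) pmin(pmax(v, min(ax)), max(ax))
  Tv <- .interpTvec(lut, rep(clamp(theta["tEpi"], lut@tEpiAxis), .NGRID),
                    clamp(mus, lut@musAxis),
                    clamp(pmax(muaE, 0), lut@muaEpiAxis),
                    clamp(pmax(muaD, 0), lut@muaDermAxis))
  M0 <- .bandWeights(models$response, models$optics)
  IT <- as.numeric(M0 %*% (models$optics@L@values * Tv))
  IW <- as.numeric(M0 %*% models$optics@L@values)
  ratio <- IT / IW
  ratio / mean(ratio)
}

#' Inverse Monte Carlo spectral fit
#'
#' Nonlinear least squares on the per-band relative differences
#' (N_model - N_meas)/N_meas over the seven tissue parameters within their
#' validated bounds. Without a warm start, multiple Latin-hypercube start
#' points are tried and the best-residual solution returned; with a warm
#' start (e.g. the previous time point's solution) a single start is used.
#'
#' @param N measured fully normalized \linkS4class{MSISpectrum}
#' @param models forward-model bundle from \code{\link{forwardModels}}
#' @param starts number of multi-start points (default 8)
#' @param warmStart optional \linkS4class{TissueParams} start point
#' @param seed seed for the start-point design (default 1)
#' @param maxIter solver iterations per start (default 100)
#' @return a \linkS4class{FitResult}
#' @export
inverseMcFit <- function(N, models, starts = 8, warmStart = NULL, seed = 1,
                         maxIter = 100) {
  stopifnot(is(N, "MSISpectrum"), normState(N) == "fully_normalized")
  meas <- N@values
  bounds <- .fitBounds()
  resfun <- function(theta) {
    names(theta) <- names(bounds$lower)
    (.modelNormalized(theta, models) - meas) / meas
  }
  startMat <- if (!is.null(warmStart)) {
    matrix(c(warmStart@tEpi, warmStart@fMel, warmStart@fBlood, warmStart@s,
             warmStart@D, warmStart@alpha, warmStart@beta), 1)
  } else {
    set.seed(seed)
    u <- lhs::randomLHS(starts, 7)
    # log-scaled design for the scale-like parameters, uniform otherwise
    lo <- c(0.005, 1e-3, 1e-3, 0.0, 0.002, 1.2, 0.5)
    hi <- c(0.45, 0.5, 0.3, 1.0, 0.3, 6.0, 2.5)
    logmap <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
    t(apply(u, 1, function(row) ifelse(logmap,
      exp(log(lo) + row * (log(hi) - log(lo))), lo + row * (hi - lo))))
  }
  best <- NULL
  for (k in seq_len(nrow(startMat))) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = startMat[k, ], lower = bounds$lower, upper = bounds$upper,
      fn = resfun,
      control = minpack.lm::nls.lm.control(maxiter = maxIter))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("all inverse MC start points failed")
  p <- best$fit$par
  names(p) <- names(bounds$lower)
  res <- resfun(p)
  new("FitResult",
      params = tissueParams(tEpi = unname(p["tEpi"]), fMel = unname(p["fMel"]),
                            fBlood = unname(p["fBlood"]), s = unname(p["s"]),
                            D = unname(p["D"]), alpha = unname(p["alpha"]),
                            beta = unname(p["beta"])),
      residual = res, mape = mean(abs(res)) * 100,
      converged = best$fit$info %in% 1:4,
      startPointsUsed = nrow(startMat), iterations = best$fit$niter)
}

#' Estimate an SO2 time series
#'
#' Per-frame SO2 estimates for a sequence of normalized spectra. The network
#' estimator is frame-independent; the inverse MC estimator uses multi-start
#' optimization for the first frame and chains each solution as the warm
#' start of the next.
#'
#' @param spectra list of fully normalized \linkS4class{MSISpectrum}s, or an
#'   n x 16 matrix
#' @param estimator \code{"ann"} or \code{"inverse_mc"}
#' @param model an \linkS4class{AnnModel} (for \code{"ann"})
#' @param models forward-model bundle (for \code{"inverse_mc"})
#' @param warmIter iteration cap for warm-started frames (after the first):
#'   warm starts are already near the optimum, and leaving the solver at a
#'   loose stop gives the mild temporal inertia the reference solver shows on
#'   recordings instead of amplifying frame noise into parameter scatter
#' @param ... passed to \code{\link{inverseMcFit}} (first, cold-started frame)
#' @return numeric vector of SO2 in percent; for \code{"inverse_mc"} the
#'   per-frame fits are attached as attribute \code{"fits"}
#' @export
estimateTimeseries <- function(spectra, estimator = c("ann", "inverse_mc"),
                               model = NULL, models = NULL, warmIter = 10,
                               ...) {
  estimator <- match.arg(estimator)
  if (is.matrix(spectra))
    spectra <- lapply(seq_len(nrow(spectra)), function(i)
      MSISpectrum(spectra[i, ] / mean(spectra[i, ]), "fully_normalized"))
  if (estimator == "ann") {
    X <- do.call(rbind, lapply(spectra, specValues))
    return(annPredict(model, X / rowMeans(X)))
  }
  out <- numeric(length(spectra))
  fits <- vector("list", length(spectra))
  warm <- NULL
  for (i in seq_along(spectra)) {
    fits[[i]] <- if (is.null(warm))
      inverseMcFit(spectra[[i]], models, ...)
    else
      inverseMcFit(spectra[[i]], models, warmStart = warm, maxIter = warmIter)
    warm <- fits[[i]]@params
    out[i] <- 100 * warm@s
  }
  attr(out, "fits") <- fits
  out
}
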
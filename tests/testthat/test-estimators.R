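# Network and inverse-MC SO2 estimators.

toyTrainingSet <- function(n = 600, seed = 1, noiseSd = 0) {
  # targets are an affine function of the spectrum: representable exactly
  set.seed(seed)
  X <- matrix(rnorm(n * 16, 0, 0.2), n, 16) + 1
  X <- X / rowMeans(X)
  w <- seq(-20, 20, length.out = 16)
  y <- as.numeric(X %*% w) + 50 + rnorm(n, 0, noiseSd)
  new("TrainingSet", X = X, y = y,
      params = data.frame(row.names = seq_len(n)),
      split = makeSplit(n, seed = seed + 1))
}

test_that("network prediction is an exact forward pass", {
  # constant networks
  mz <- new("AnnModel", W1 = matrix(0, 5, 16), b1 = rep(0, 5),
            W2 = matrix(0, 1, 5), b2 = 42, meta = list())
  N <- MSISpectrum(rep(1, 16), "fully_normalized")
  expect_equal(annPredict(mz, N), 42)
  mz2 <- new("AnnModel", W1 = matrix(rnorm(80), 5, 16), b1 = rnorm(5),
             W2 = matrix(0, 1, 5), b2 = -3, meta = list())
  expect_equal(annPredict(mz2, N), -3)
  # two-node toy network against a hand-computed pass
  W1 <- rbind(c(1, -1, rep(0, 14)), c(rep(0, 15), 2))
  m2 <- new("AnnModel", W1 = W1, b1 = c(0.5, -1), W2 = matrix(c(3, -2), 1),
            b2 = 10, meta = list())
  x <- rep(1, 16); x[1] <- 1.2; x[2] <- 0.9; x[16] <- 0.9
  x <- x / mean(x)
  h1 <- tanh(x[1] - x[2] + 0.5)
  h2 <- tanh(2 * x[16] - 1)
  expect_equal(annPredict(m2, MSISpectrum(x, "fully_normalized")),
               3 * h1 - 2 * h2 + 10, tolerance = 1e-12)
  # the input contract is enforced
  expect_error(annPredict(mz, MSISpectrum(rep(2, 16), "raw")),
               "fully_normalized")
})

test_that("training represents affine maps and is deterministic", {
  ts <- toyTrainingSet()
  # noiseless representable targets: patience must not cut off the long
  # convergence tail, so it is widened here
  m <- trainAnn(ts, H = 5, seed = 3, maxEpochs = 300, patience = 30)
  expect_lt(m@meta$test_mse, 1e-4)
  m2 <- trainAnn(ts, H = 5, seed = 3, maxEpochs = 300, patience = 30)
  expect_identical(m@W1, m2@W1)
  expect_identical(m@b2, m2@b2)
  expect_warning(trainAnn(new("TrainingSet", X = ts@X, y = rep(1, 600),
                              params = ts@params, split = ts@split),
                          H = 5, seed = 3, maxEpochs = 3), "constant")
})

test_that("prediction is Lipschitz-bounded by the weight norms", {
  set.seed(4)
  m <- new("AnnModel", W1 = matrix(rnorm(15 * 16), 15, 16), b1 = rnorm(15),
           W2 = matrix(rnorm(15), 1), b2 = 0, meta = list())
  bound <- sqrt(sum(m@W2^2)) * norm(m@W1, "2")
  for (i in 1:20) {
    x <- 1 + rnorm(16, 0, 0.1); x <- x / mean(x)
    d <- rnorm(16, 0, 1e-4)
    num <- abs(.subset2(list(msiSO2:::.annForward(m@W1, m@b1, m@W2, m@b2,
                                                  rbind(x + d, x))), 1))
    diffPred <- diff(msiSO2:::.annForward(m@W1, m@b1, m@W2, m@b2,
                                          rbind(x + d, x)))
    expect_lte(abs(diffPred), bound * sqrt(sum(d^2)) * (1 + 1e-9))
  }
})

test_that("repeat training reports inter-network spread correctly", {
  ts <- toyTrainingSet(n = 300, noiseSd = 2)
  one <- repeatTrain(ts, nRepeats = 1, H = 5, seed = 5, maxEpochs = 30)
  expect_equal(one$meanStd, 0)
  same <- lapply(1:2, function(i) trainAnn(ts, H = 5, seed = 77,
                                           maxEpochs = 30))
  expect_identical(same[[1]]@W1, same[[2]]@W1)
  three <- repeatTrain(ts, nRepeats = 3, H = 5, seed = 6, maxEpochs = 30)
  expect_length(three$models, 3)
  expect_true(three$meanStd >= 0)
  expect_s4_class(three$bestModel, "AnnModel")
})

test_that("inverse MC recovers SO2 from noiseless spectra", {
  mods <- testModels()
  truth <- c(0.15, 0.5, 0.85)
  for (s in truth) {
    syn <- synthesizeSpectrum(midParams(s), mods, noise = FALSE,
                              sharedQ = TRUE, qT = 0, qTheta = 0)
    fit <- inverseMcFit(syn$N, mods, starts = 16, seed = 31, maxIter = 200)
    expect_lt(abs(100 * fit@params@s - 100 * s), 1.0)
    expect_lt(fit@mape, 0.5)
  }
})

test_that("the fit residual vanishes at the true parameters", {
  mods <- testModels()
  p <- midParams(0.6)
  syn <- synthesizeSpectrum(p, mods, noise = FALSE, sharedQ = TRUE,
                            qT = 0, qTheta = 0)
  meas <- specValues(syn$N)
  theta <- c(tEpi = p@tEpi, fMel = p@fMel, fBlood = p@fBlood, s = p@s,
             D = p@D, alpha = p@alpha, beta = p@beta)
  modeled <- msiSO2:::.modelNormalized(theta, mods)
  mape <- mean(abs((modeled - meas) / meas)) * 100
  expect_lt(mape, 0.01)
})

test_that("warm starts reuse the previous solution efficiently", {
  mods <- testModels()
  syn1 <- synthesizeSpectrum(midParams(0.6), mods, noise = FALSE,
                             sharedQ = TRUE, qT = 0, qTheta = 0)
  cold <- inverseMcFit(syn1$N, mods, starts = 8, seed = 32)
  syn2 <- synthesizeSpectrum(midParams(0.62), mods, noise = FALSE,
                             sharedQ = TRUE, qT = 0, qTheta = 0)
  warm <- inverseMcFit(syn2$N, mods, warmStart = cold@params)
  expect_equal(warm@startPointsUsed, 1)
  # a chained warm start lands on the nearby optimum accurately
  expect_lt(abs(100 * warm@params@s - 62), 1.0)
  # descent property: the solution's objective is at least as good as the
  # warm start's
  thetaStart <- c(tEpi = cold@params@tEpi, fMel = cold@params@fMel,
                  fBlood = cold@params@fBlood, s = cold@params@s,
                  D = cold@params@D, alpha = cold@params@alpha,
                  beta = cold@params@beta)
  meas <- specValues(syn2$N)
  sseStart <- sum(((msiSO2:::.modelNormalized(thetaStart, mods) - meas) /
                     meas)^2)
  sseEnd <- sum(warm@residual^2)
  expect_lte(sseEnd, sseStart + 1e-12)
})

test_that("time series estimation chains warm starts and matches the network", {
  mods <- testModels()
  X <- do.call(rbind, lapply(c(0.5, 0.5, 0.5), function(s)
    specValues(synthesizeSpectrum(midParams(s), mods, noise = FALSE,
                                  sharedQ = TRUE, qT = 0, qTheta = 0)$N)))
  mc <- estimateTimeseries(X, "inverse_mc", models = mods, starts = 8,
                           seed = 33)
  # constant input gives a constant trace within solver tolerance
  expect_lt(max(mc) - min(mc), 0.5)
  set.seed(34)
  m <- new("AnnModel", W1 = matrix(rnorm(80, 0, 0.3), 5, 16), b1 = rnorm(5),
           W2 = matrix(rnorm(5), 1), b2 = 50, meta = list())
  annTrace <- estimateTimeseries(X, "ann", model = m)
  expect_equal(annTrace, annPredict(m, X / rowMeans(X)))
})
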
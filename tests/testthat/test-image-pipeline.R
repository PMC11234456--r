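# Demosaicing, preprocessing, ROI extraction, SO2 mapping and temporal
# averaging.

mkFrame <- function(px, kind = "measurement", ts = 0)
  new("RawFrame", pixels = px, exposure = 20, timestamp = ts, kind = kind)

test_that("demosaicing reproduces constant and affine images exactly", {
  const <- mkFrame(matrix(3.5, 32, 32))
  cube <- demosaic(const)
  expect_equal(dim(cube@values), c(16L, 8L, 8L))
  expect_equal(as.numeric(cube@values), rep(3.5, 16 * 64))
  # an affine ramp is reproduced exactly in every band (bilinear exactness)
  px <- outer(seq_len(32), seq_len(32), function(i, j) 2 * i - 0.5 * j + 7)
  ramp <- demosaic(mkFrame(px))
  want <- outer(seq_len(8), seq_len(8),
                function(i, j) 2 * (4 * (i - 1) + 2.5) - 0.5 * (4 * (j - 1) + 2.5) + 7)
  for (b in 1:16)
    expect_equal(ramp@values[b, , ], want, tolerance = 1e-12)
  expect_error(demosaic(mkFrame(matrix(0, 30, 32))), "divisible")
})

test_that("demosaicing tracks a smooth image within 1% away from borders", {
  n <- 64
  img <- outer(seq_len(n), seq_len(n),
               function(i, j) 2 + sin(i / 25) * cos(j / 30))
  cube <- demosaic(mkFrame(img))
  H <- n / 4
  want <- outer(seq_len(H), seq_len(H),
                function(i, j) 2 + sin((4 * (i - 1) + 2.5) / 25) *
                  cos((4 * (j - 1) + 2.5) / 30))
  inner <- 3:(H - 2)
  for (b in c(1, 6, 16)) {
    rel <- abs(cube@values[b, inner, inner] - want[inner, inner]) /
      want[inner, inner]
    expect_lt(max(rel), 0.01)
  }
})

test_that("preprocessing executes the four steps and normalizes per pixel", {
  set.seed(21)
  dark <- mkFrame(matrix(40, 32, 32), kind = "dark")
  whitePx <- matrix(40 + 800, 32, 32)
  white <- processWhite(mkFrame(whitePx, kind = "white"), dark)
  expect_identical(normState(white), "dark_corrected")
  # measurement identical to the white recording gives an all-ones cube
  cube <- preprocess(mkFrame(whitePx), dark, white)
  expect_identical(normState(cube), "fully_normalized")
  expect_equal(as.numeric(cube@values), rep(1, 16 * 64), tolerance = 1e-12)
  # per-pixel band mean is 1 for arbitrary measurements
  meas <- mkFrame(matrix(40 + runif(32 * 32, 100, 900), 32, 32))
  cube2 <- preprocess(meas, dark, white)
  expect_equal(as.numeric(apply(cube2@values, c(2, 3), mean)),
               rep(1, 64), tolerance = 1e-12)
  # global intensity rescaling of measurement and white cancels
  meas3 <- mkFrame(40 + 3 * (meas@pixels - 40))
  white3 <- processWhite(mkFrame(40 + 3 * (whitePx - 40), kind = "white"), dark)
  cube3 <- preprocess(meas3, dark, white3)
  expect_equal(cube3@values, cube2@values, tolerance = 1e-10)
})

test_that("nearest dark selection breaks ties toward the earlier frame", {
  darks <- list(mkFrame(matrix(1, 4, 4), "dark", ts = 0),
                mkFrame(matrix(2, 4, 4), "dark", ts = 10),
                mkFrame(matrix(3, 4, 4), "dark", ts = 20))
  expect_equal(nearestDark(mkFrame(matrix(0, 4, 4), ts = 12), darks)@pixels[1],
               2)
  expect_equal(nearestDark(mkFrame(matrix(0, 4, 4), ts = 15), darks)@pixels[1],
               2)   # tie 10 vs 20: earlier wins
})

test_that("ROI averaging respects bounds and reduces noise with size", {
  set.seed(22)
  vals <- array(1, dim = c(16, 30, 30)) +
    array(rnorm(16 * 900, 0, 0.05), dim = c(16, 30, 30))
  vals <- sweep(vals, c(2, 3), apply(vals, c(2, 3), mean), "/")
  cube <- new("Hypercube", values = vals, state = "fully_normalized",
              mask = matrix(TRUE, 30, 30))
  one <- roiAverage(cube, c(4, 5, 5, 6))
  px <- cube@values[, 5, 6]
  expect_equal(specValues(one), px / mean(px), tolerance = 1e-12)
  expect_error(roiAverage(cube, c(0, 0, 31, 5)), "bounds")
  # larger ROIs average down the band noise
  sd5 <- sd(specValues(roiAverage(cube, c(0, 0, 5, 5))))
  sd25 <- sd(specValues(roiAverage(cube, c(0, 0, 25, 25))))
  expect_lt(sd25, sd5)
  # a uniform cube gives the same spectrum for any ROI
  uni <- new("Hypercube", values = array(rep(seq(0.5, 1.5, length.out = 16),
                                             900), dim = c(16, 30, 30)),
             state = "fully_normalized", mask = matrix(TRUE, 30, 30))
  expect_equal(specValues(roiAverage(uni, c(0, 0, 3, 3))),
               specValues(roiAverage(uni, c(10, 10, 30, 30))))
})

test_that("SO2 maps agree with per-pixel prediction and handle uniformity", {
  set.seed(23)
  m <- new("AnnModel", W1 = matrix(rnorm(80, 0, 0.3), 5, 16), b1 = rnorm(5),
           W2 = matrix(rnorm(5), 1), b2 = 50, meta = list())
  sp <- seq(0.8, 1.2, length.out = 16)
  sp <- sp / mean(sp)
  vals <- array(rep(sp, 36), dim = c(16, 6, 6))
  cube <- new("Hypercube", values = vals, state = "fully_normalized",
              mask = matrix(TRUE, 6, 6))
  map <- so2Map(cube, m)
  expect_equal(max(map@so2) - min(map@so2), 0, tolerance = 1e-12)
  expect_equal(map@so2[1, 1],
               annPredict(m, MSISpectrum(sp, "fully_normalized")))
  # consistency with 1x1 ROI averaging on a non-uniform cube
  set.seed(24)
  vals2 <- vals * array(exp(rnorm(16 * 36, 0, 0.05)), dim = dim(vals))
  vals2 <- sweep(vals2, c(2, 3), apply(vals2, c(2, 3), mean), "/")
  cube2 <- new("Hypercube", values = vals2, state = "fully_normalized",
               mask = matrix(TRUE, 6, 6))
  map2 <- so2Map(cube2, m)
  expect_equal(map2@so2[3, 4],
               annPredict(m, roiAverage(cube2, c(2, 3, 3, 4))))
})

test_that("temporal averaging reduces variance by the window length", {
  set.seed(25)
  frames <- lapply(1:16, function(i)
    mkFrame(matrix(100 + rnorm(16 * 16, 0, 5), 16, 16), ts = i))
  expect_identical(temporalAverage(frames, 1)@pixels, frames[[1]]@pixels)
  avg8 <- temporalAverage(frames, 8)
  v1 <- var(as.numeric(frames[[1]]@pixels))
  v8 <- var(as.numeric(avg8@pixels))
  expect_lt(abs(v8 / (v1 / 8) - 1), 0.35)
  const <- lapply(1:8, function(i) mkFrame(matrix(7, 8, 8), ts = i))
  expect_equal(as.numeric(temporalAverage(const, 8)@pixels), rep(7, 64))
})

test_that("phantom movies survive the full pipeline round trip", {
  mods <- testModels()
  scene <- list(so2Frames = list(matrix(0.3, 12, 12)),
                baseParams = midParams(), darkOffset = 40)
  mv <- generatePhantomMovie(scene, mods, seed = 26)
  white <- processWhite(mv$white, mv$dark)
  cube <- preprocess(mv$frames[[1]], mv$dark, white)
  got <- roiAverage(cube, c(2, 2, 10, 10))
  # direct synthesis at the same parameters, noiseless reference
  p <- midParams(0.3)
  ref <- synthesizeSpectrum(p, mods, noise = FALSE, sharedQ = TRUE,
                            qT = 0, qTheta = 0)
  # same tissue spectrum up to lamp-perturbation mismatch and noise
  expect_lt(max(abs(specValues(got) - specValues(ref$N))), 0.08)
  # a two-region scene shows the SO2 step
  scene2 <- list(so2Frames = list(cbind(matrix(0.2, 12, 6),
                                        matrix(0.8, 12, 6))),
                 baseParams = midParams(), darkOffset = 40)
  mv2 <- generatePhantomMovie(scene2, mods, seed = 27)
  cube2 <- preprocess(mv2$frames[[1]], mv2$dark,
                      processWhite(mv2$white, mv2$dark))
  left <- specValues(roiAverage(cube2, c(3, 0, 9, 5)))
  right <- specValues(roiAverage(cube2, c(3, 7, 9, 12)))
  expect_gt(max(abs(left - right)), 0.02)
})
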
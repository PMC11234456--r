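# Hypercube preprocessing: dark correction, demosaicing, white and intensity
# normalization, ROI extraction and per-pixel SO2 mapping.

#' Mosaic band layout
#'
#' Band index at each position of the repeating 4x4 filter mosaic, row-major:
#' position (i, j) of the pattern carries band 4 (i - 1) + j. The physical
#' assignment of a given sensor is configurable by passing a permuted matrix
#' to the demosaicing and phantom-generation functions.
#'
#' @return 4 x 4 integer matrix of band indices 1..16
#' @export
mosaicLayout <- function() matrix(1:16, 4, 4, byrow = TRUE)

# 1-D linear interpolation of v at positions (index + f), with linear
# extrapolation from the end segments; exact on affine sequences.
.shiftLinear <- function(v, f) {
  K <- length(v)
  if (K == 1L) return(v)
  p <- seq_len(K) + f
  k0 <- pmin(pmax(floor(p), 1L), K - 1L)
  w <- p - k0
  v[k0] * (1 - w) + v[k0 + 1L] * w
}

#' Demosaic a raw frame into a hypercube
#'
#' Each band's sparse mosaic samples (one per 4x4 block) are aligned to the
#' common block-center grid by distance-weighted bilinear interpolation on
#' the band's own subsampled lattice, applied separably along rows and
#' columns with linear extrapolation at the borders. Constant and affine
#' images are reproduced exactly.
#'
#' @param frame a \linkS4class{RawFrame} (dimensions divisible by 4)
#' @param layout 4 x 4 band map (default \code{\link{mosaicLayout}})
#' @return a \linkS4class{Hypercube} with state \code{"raw"} (or
#'   \code{"dark_corrected"} if \code{state} says so)
#' @param state normalization state to record on the output
#' @export
demosaic <- function(frame, layout = mosaicLayout(), state = "raw") {
  px <- frame@pixels
  if (any(dim(px) %% 4L != 0L)) stop("frame dimensions must be divisible by 4")
  H <- nrow(px) %/% 4L
  W <- ncol(px) %/% 4L
  cube <- array(NA_real_, dim = c(.NBANDS, H, W))
  for (di in 1:4) for (dj in 1:4) {
    b <- layout[di, dj]
    sub <- px[seq(di, nrow(px), by = 4L), seq(dj, ncol(px), by = 4L),
              drop = FALSE]
    # band sample k sits at mosaic coordinate 4(k-1)+d; the block center is
    # at 4(i-1)+2.5, i.e. lattice position i + (2.5-d)/4
    fr <- (2.5 - di) / 4
    fc <- (2.5 - dj) / 4
    sub <- apply(sub, 2, .shiftLinear, f = fr)
    sub <- t(apply(sub, 1, .shiftLinear, f = fc))
    cube[b, , ] <- sub
  }
  new("Hypercube", values = cube, state = state,
      mask = matrix(TRUE, H, W))
}

#' Nearest-in-time dark frame
#'
#' @param frame a measurement or white \linkS4class{RawFrame}
#' @param darks list of dark \linkS4class{RawFrame}s
#' @return the dark frame with the closest timestamp (ties broken toward the
#'   earlier frame)
#' @export
nearestDark <- function(frame, darks) {
  dt <- vapply(darks, function(d) abs(d@timestamp - frame@timestamp), 0)
  ts <- vapply(darks, function(d) d@timestamp, 0)
  cand <- which(dt == min(dt))
  darks[[cand[which.min(ts[cand])]]]
}

# dark-subtract (clipping negatives at zero) and demosaic
.darkCorrectCube <- function(frame, dark, layout) {
  if (is.list(dark)) dark <- nearestDark(frame, dark)
  corrected <- frame@pixels - dark@pixels
  nneg <- sum(corrected < 0)
  corrected[corrected < 0] <- 0
  cube <- demosaic(new("RawFrame", pixels = corrected, exposure = frame@exposure,
                       timestamp = frame@timestamp, kind = frame@kind),
                   layout, state = "dark_corrected")
  attr(cube, "n_clipped") <- nneg
  cube
}

#' Process a white recording into a reference hypercube
#'
#' Applies the first two preprocessing steps (dark subtraction, demosaicing)
#' to a white-reference frame.
#'
#' @param whiteFrame white \linkS4class{RawFrame}
#' @param dark dark \linkS4class{RawFrame} (or list, nearest-in-time chosen)
#' @param layout mosaic band map
#' @return a dark-corrected \linkS4class{Hypercube}
#' @export
processWhite <- function(whiteFrame, dark, layout = mosaicLayout())
  .darkCorrectCube(whiteFrame, dark, layout)

#' Preprocess a raw measurement frame to a normalized hypercube
#'
#' Executes the four preprocessing steps in order: (1) ambient-light
#' correction by subtracting the nearest-in-time dark frame (negatives
#' clipped at zero); (2) demosaicing into a hypercube; (3) white
#' normalization with a dark-corrected white-reference hypercube; (4)
#' intensity normalization by the per-pixel average over bands, so every
#' valid pixel's 16-band mean is 1. Pixels with a nonpositive white band are
#' masked out with a warning.
#'
#' @param frame measurement \linkS4class{RawFrame}
#' @param dark dark \linkS4class{RawFrame} or list of darks
#' @param whiteCube dark-corrected white \linkS4class{Hypercube} from
#'   \code{\link{processWhite}}
#' @param layout mosaic band map
#' @return a fully normalized \linkS4class{Hypercube}
#' @export
preprocess <- function(frame, dark, whiteCube, layout = mosaicLayout()) {
  stopifnot(is(whiteCube, "Hypercube"), normState(whiteCube) == "dark_corrected")
  cube <- .darkCorrectCube(frame, dark, layout)
  bad <- apply(whiteCube@values <= 0, c(2, 3), any)
  if (any(bad))
    warning(sprintf("%d pixels masked: nonpositive white reference", sum(bad)))
  vals <- cube@values / whiteCube@values
  vals[!is.finite(vals)] <- NA_real_
  pm <- apply(vals, c(2, 3), mean)
  zero <- !is.na(pm) & pm <= 0
  bad <- bad | zero
  vals <- sweep(vals, c(2, 3), pm, "/")
  mask <- cube@mask & !bad
  vals[rep(bad, each = .NBANDS)] <- NA_real_
  new("Hypercube", values = vals, state = "fully_normalized", mask = mask)
}

#' Average a spectrum over a region of interest
#'
#' Spatial mean of the per-pixel spectra inside a rectangular ROI, followed
#' by re-normalization to band mean 1. ROI rectangles are 0-based and
#' half-open: rows r0 <= r < r1, columns c0 <= c < c1.
#'
#' @param cube a fully normalized \linkS4class{Hypercube}
#' @param roi integer vector c(r0, c0, r1, c1)
#' @return a fully normalized \linkS4class{MSISpectrum}
#' @export
roiAverage <- function(cube, roi) {
  stopifnot(normState(cube) == "fully_normalized", length(roi) == 4)
  d <- dim(cube@values)
  r0 <- roi[1]; c0 <- roi[2]; r1 <- roi[3]; c1 <- roi[4]
  if (r0 < 0 || c0 < 0 || r1 > d[2] || c1 > d[3] || r1 <= r0 || c1 <= c0)
    stop("ROI outside image bounds")
  sub <- cube@values[, (r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  sp <- apply(sub, 1, mean, na.rm = TRUE)
  MSISpectrum(sp / mean(sp), "fully_normalized")
}

#' Per-pixel SO2 map
#'
#' Vectorized network prediction over all valid pixels of a normalized
#' hypercube.
#'
#' @param cube a fully normalized \linkS4class{Hypercube}
#' @param model an \linkS4class{AnnModel}
#' @return an \linkS4class{So2Map} (SO2 in percent, unclipped)
#' @export
so2Map <- function(cube, model) {
  stopifnot(normState(cube) == "fully_normalized")
  d <- dim(cube@values)
  X <- t(matrix(cube@values, .NBANDS, d[2] * d[3]))
  ok <- as.numeric(cube@mask) & stats::complete.cases(X)
  out <- matrix(NA_real_, d[2], d[3])
  if (any(ok)) {
    Xok <- X[ok, , drop = FALSE]
    out[ok] <- .annForward(model@W1, model@b1, model@W2, model@b2,
                           Xok / rowMeans(Xok))
  }
  new("So2Map", so2 = out, mask = cube@mask & matrix(ok, d[2], d[3]))
}

#' Temporal average of consecutive raw frames
#'
#' Elementwise mean of a window of consecutive frames, reducing temporal
#' noise variance by the window length.
#'
#' @param frames list of \linkS4class{RawFrame}s of equal geometry
#' @param window number of frames to average (default 8)
#' @return a \linkS4class{RawFrame} with the mean pixel values
#' @export
temporalAverage <- function(frames, window = 8) {
  stopifnot(window >= 1, length(frames) >= window)
  acc <- frames[[1]]@pixels * 0
  for (i in seq_len(window)) acc <- acc + frames[[i]]@pixels
  new("RawFrame", pixels = acc / window, exposure = frames[[1]]@exposure,
      timestamp = mean(vapply(frames[seq_len(window)],
                              function(f) f@timestamp, 0)),
      kind = frames[[1]]@kind)
}
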
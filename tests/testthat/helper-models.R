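# Shared fixtures, built once per test run. The unit-test look-up table is
# deliberately coarse (5 nodes per transport axis, 5000 photons per node):
# both estimators query the same table, so its Monte Carlo noise cancels in
# consistency checks.

.fixtures <- new.env(parent = emptyenv())

testLut <- function() {
  if (is.null(.fixtures$lut))
    .fixtures$lut <- buildLUT(defaultLutAxes(nTEpi = 5, nMus = 5, nMua = 12),
                              nPhotons = 5000, seed = 7)
  .fixtures$lut
}

testModels <- function() {
  if (is.null(.fixtures$models))
    .fixtures$models <- forwardModels(testLut())
  .fixtures$models
}

testChrom <- function() {
  if (is.null(.fixtures$chrom)) .fixtures$chrom <- loadChromophores()
  .fixtures$chrom
}

midParams <- function(s = 0.7)
  tissueParams(tEpi = 0.08, fMel = 0.05, fBlood = 0.01, s = s,
               D = 0.03, alpha = 2.5, beta = 1.3)

# Independent slow-path reference MC: one-layer (or two-layer) transport in
# plain R with absorption applied during propagation (weight attenuation).
# Used as an oracle against the compiled white-MC + Beer-Lambert path.
absorbingMcR <- function(muS, muaEpi, muaDerm, tEpi, g = 0.8, nPhotons = 400,
                         maxPath = 400, seed = 1) {
  set.seed(seed)
  total <- 0
  for (ph in seq_len(nPhotons)) {
    u <- c(0, 0, 1); z <- 0; w <- 1; path <- 0
    repeat {
      s <- -log(runif(1)) / muS
      z2 <- z + u[3] * s
      if (z2 < 0) {
        sb <- -z / u[3]
        seg <- segSplit(z, 0, sb, tEpi)
        w <- w * exp(-muaEpi * seg[1] - muaDerm * seg[2])
        path <- path + sb
        if (path > maxPath) break
        total <- total + w   # matched boundary: photon exits
        break
      }
      seg <- segSplit(z, z2, s, tEpi)
      w <- w * exp(-muaEpi * seg[1] - muaDerm * seg[2])
      path <- path + s
      z <- z2
      if (path > maxPath || w < 1e-12) break
      # Henyey-Greenstein deflection
      ct <- if (abs(g) < 1e-8) 2 * runif(1) - 1 else {
        f <- (1 - g^2) / (1 - g + 2 * g * runif(1))
        max(-1, min(1, (1 + g^2 - f^2) / (2 * g)))
      }
      st <- sqrt(1 - ct^2); phi <- 2 * pi * runif(1)
      if (abs(u[3]) > 0.99999) {
        u <- c(st * cos(phi), st * sin(phi), ct * sign(u[3]))
      } else {
        den <- sqrt(1 - u[3]^2)
        u <- c(st * (u[1] * u[3] * cos(phi) - u[2] * sin(phi)) / den + u[1] * ct,
               st * (u[2] * u[3] * cos(phi) + u[1] * sin(phi)) / den + u[2] * ct,
               -st * cos(phi) * den + u[3] * ct)
      }
    }
  }
  total / nPhotons
}

segSplit <- function(z1, z2, seg, tEpi) {
  lo <- min(z1, z2); hi <- max(z1, z2)
  if (hi == lo) return(if (z1 < tEpi) c(seg, 0) else c(0, seg))
  inEpi <- max(0, min(hi, tEpi) - max(lo, 0)) / (hi - lo) * seg
  c(inEpi, seg - inEpi)
}
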
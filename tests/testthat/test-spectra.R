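# Amplitudes, rendering and the two emission processes on small chains
# (d^1 and d^9 grounds keep every diagonalization under a second).

test_that("transition amplitudes respect spin blocks, vacancies and configuration chains", {
  sc <- atomicSC()
  gE <- diagonalizeAndLabel(ModelSpec(Configuration(2, 6, 1), sc))
  iE <- diagonalizeAndLabel(ModelSpec(Configuration(1, 6, 2), sc))
  A <- transitionAmplitudes(gE, iE, "absorb_1s3d")
  # spin-conserving operator: zero blocks between different total spins
  gg <- eigenGroups(gE); gi <- eigenGroups(iE)
  Sg <- rep(gg$S, gg$degeneracy); Si <- rep(gi$S, gi$degeneracy)
  mism <- outer(Si, Sg, function(a, b) abs(a - b) > 1e-6)
  for (q in 1:5) expect_lt(max(Mod(A[, , q])[mism]), 1e-10)
  # closed-shell d^10: no 3d vacancy, all amplitudes vanish
  g10 <- diagonalizeAndLabel(ModelSpec(Configuration(2, 6, 9), sc))
  i10 <- diagonalizeAndLabel(ModelSpec(Configuration(1, 6, 10), sc))
  A10 <- transitionAmplitudes(g10, i10, "absorb_1s3d")
  expect_gt(max(Mod(A10)), 0)  # d^9 still has one vacancy
  # configuration mismatch is rejected
  expect_error(transitionAmplitudes(gE, g10, "absorb_1s3d"), "mismatch")
})

test_that("high-spin d^5 resonant intermediates keep the ground total spin (beta-only absorption)", {
  sc <- atomicSC()
  gE <- diagonalizeAndLabel(ModelSpec(Configuration(2, 6, 5), sc))
  iE <- diagonalizeAndLabel(ModelSpec(Configuration(1, 6, 6), sc))
  A <- transitionAmplitudes(gE, iE, "absorb_1s3d")
  gIdx <- seq_len(eigenGroups(gE)$last[1])
  w <- rowSums(abs(A[, gIdx, , drop = FALSE])^2)
  gi <- eigenGroups(iE)
  reached <- vapply(seq_len(nrow(gi)), function(k)
    sum(w[gi$first[k]:gi$last[k]]) > 1e-8 * max(w), logical(1))
  # every populated intermediate group is a sextet (S = 5/2, the ground spin)
  expect_true(all(abs(gi$S[reached] - 2.5) < 1e-6))
  expect_setequal(gi$term[reached], "6D")
})

test_that("stick rendering conserves weight, has the Lorentzian width and bins at zero widths", {
  g <- seq(-20, 20, by = 0.01)
  s <- broadenSticks(data.frame(energy = 0.3, weight = 1), g,
                     lorentzian = 2, gaussian = 0)
  half <- range(s@energy[s@intensity >= max(s@intensity) / 2])
  expect_equal(diff(half), 2, tolerance = 0.02)
  expect_equal(trapzArea(s), 1, tolerance = 1e-3)
  # two sticks, Voigt-like, grid spanning +-20 gamma: area within 1e-3
  g2 <- seq(-40, 40, by = 0.02)
  s2 <- broadenSticks(data.frame(energy = c(-1, 2), weight = c(0.3, 0.7)),
                      g2, lorentzian = 2, gaussian = 1)
  expect_equal(sum(s2@intensity) * 0.02, 1, tolerance = 1e-3)
  # zero widths: nearest-node binning, weight preserved
  s3 <- broadenSticks(data.frame(energy = c(0.26, 1), weight = c(2, 1)),
                      seq(0, 2, 0.5), lorentzian = 0, gaussian = 0)
  expect_equal(s3@intensity * 0.5, c(0, 2, 1, 0, 0))
  expect_error(broadenSticks(data.frame(energy = 1, weight = 1),
                             numeric(0)), "2 points")
})

test_that("non-resonant XES of a closed 3d shell is a single unsplit line", {
  # d^10: no 3p-3d exchange partner
  sc <- SlaterCondonSet(F2dd = 11, F4dd = 7, F2pd = 12, G1pd = 14, G3pd = 8)
  x <- nonresonantKbetaXES(ModelSpec(Configuration(2, 6, 10), sc))
  pk <- findSpectralPeaks(x)
  expect_equal(nrow(pk$maxima), 1L)
  expect_error(nonresonantKbetaXES(ModelSpec(Configuration(2, 5, 10), sc)),
               "1s pair")
})

test_that("doubling the pd exchange integrals widens the mainline exchange separation", {
  mkSplit <- function(f) {
    sc <- SlaterCondonSet(F2pd = 6, G1pd = 8 * f, G3pd = 5 * f)
    x <- nonresonantKbetaXES(ModelSpec(Configuration(2, 6, 1), sc))
    exchangeSplitting(x, method = "cluster")$splitting
  }
  expect_gt(mkSplit(2), mkSplit(1))
})

test_that("the RXES plane matches an independent brute-force Kramers-Heisenberg triple sum", {
  sc <- SlaterCondonSet(F2dd = 10, F4dd = 6, F2pd = 11, G1pd = 13, G3pd = 8)
  ch <- rxesChain(ModelSpec(Configuration(2, 6, 8), sc))
  ch@offsets <- CalibrationOffsets(7112, 7060)
  br <- BroadeningSpec(1.25, 0.8, 0)   # Gaussian off for pointwise check
  plane <- rxesPlane(ch, br, incident = seq(7108, 7118, 0.5),
                     emission = seq(7040, 7075, 0.5))
  expect_true(all(plane@intensity >= 0))
  gE <- diagonalizeAndLabel(ch@ground)
  iE <- diagonalizeAndLabel(ch@intermediate)
  fE <- diagonalizeAndLabel(ch@final)
  Ab <- transitionAmplitudes(gE, iE, "absorb_1s3d")
  Em <- transitionAmplitudes(iE, fE, "emit_3p1s")
  Eg0 <- min(gE@energies)
  gIdx <- which(gE@energies - Eg0 < 1e-6)
  set.seed(42)
  pts <- cbind(sample(length(plane@incident), 20, replace = TRUE),
               sample(length(plane@emission), 20, replace = TRUE))
  for (k in 1:20) {
    OmP <- plane@incident[pts[k, 1]] - 7112
    omP <- plane@emission[pts[k, 2]] - 7060
    tot <- 0
    for (f in seq_along(fE@energies)) {
      s <- 0
      for (gi in gIdx) for (qa in 1:5) for (qe in 1:3) {
        amp <- sum(Em[f, , qe] * Ab[, gi, qa] /
                     (Eg0 + OmP - iE@energies + 1i * br@gammaIntermediate / 2))
        s <- s + Mod(amp)^2
      }
      x <- OmP - omP - (fE@energies[f] - Eg0)
      tot <- tot + s / length(gIdx) *
        (br@gammaFinal / 2 / pi) / (x^2 + (br@gammaFinal / 2)^2)
    }
    expect_equal(plane@intensity[pts[k, 1], pts[k, 2]], tot,
                 tolerance = 1e-10)
  }
})

test_that("plane cuts return grid rows/columns verbatim and reject out-of-range energies", {
  z <- new("RXESPlane", incident = 1:5 + 0, emission = seq(0, 2, 0.5),
           intensity = matrix(runif(25), 5, 5), metadata = list())
  ct <- cieCut(z, 3.2)
  expect_equal(ct@intensity, z@intensity[3, ])
  hf <- herfdCut(z, 1.01)
  expect_equal(hf@intensity, z@intensity[, 3])
  expect_error(cieCut(z, 9), "outside")
  expect_error(herfdCut(z, -1), "outside")
  z0 <- new("RXESPlane", incident = 1:3 + 0, emission = 1:4 + 0,
            intensity = matrix(0, 3, 4), metadata = list())
  expect_equal(max(cieCut(z0, 2)@intensity), 0)
  expect_equal(max(herfdCut(z0, 2)@intensity), 0)
})

test_that("rising-edge excitation reproduces the non-resonant spectrum exactly", {
  gm <- ModelSpec(Configuration(2, 6, 1), smallSC())
  a <- rxesEmissionCut(gm, "rising_edge")
  b <- nonresonantKbetaXES(xesChain(gm))
  expect_identical(a@intensity, b@intensity)
})

test_that("calibration offsets shift axes rigidly without touching splittings or ratios", {
  gm <- ModelSpec(Configuration(2, 6, 1), smallSC())
  ch1 <- rxesChain(gm)
  ch2 <- rxesChain(gm)
  # offsets commensurate with the 0.1 eV grid step, so both cuts sample the
  # line shapes at identical relative positions
  ch2@offsets <- CalibrationOffsets(103.2, -55.3)
  c1 <- rxesEmissionCut(NULL, "preedge", chainRXES = ch1)
  c2 <- rxesEmissionCut(NULL, "preedge", chainRXES = ch2)
  p1 <- findSpectralPeaks(c1)$maxima
  p2 <- findSpectralPeaks(c2)$maxima
  expect_equal(diff(p1$energy), diff(p2$energy), tolerance = 1e-12)
  expect_equal(p1$height / max(p1$height), p2$height / max(p2$height),
               tolerance = 1e-9)
})

test_that("HERFD pre-edge trace is at least as sharp as the lifetime-broadened absorption", {
  gm <- ModelSpec(Configuration(2, 6, 1), smallSC())
  ch <- rxesChain(gm)
  br <- BroadeningSpec(1.25, 1.6, 0)
  plane <- rxesPlane(ch, br)
  j <- which.max(apply(plane@intensity, 2, max))
  tr <- herfdCut(plane, plane@emission[j])
  absn <- absorptionProfile(ch, br)
  fwhm <- function(s) {
    top <- which.max(s@intensity)
    half <- s@intensity >= s@intensity[top] / 2
    # width of the contiguous half-maximum region around the main peak
    runs <- rle(half)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    k <- which(runs$values & starts <= top & ends >= top)
    diff(range(s@energy[starts[k]:ends[k]]))
  }
  expect_lte(fwhm(tr), fwhm(absn) + 1e-9)
})
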
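mkGauss <- function(centers, heights, grid = seq(0, 30, 0.05), sd = 1) {
  y <- rowSums(vapply(seq_along(centers), function(i)
    heights[i] * exp(-0.5 * ((grid - centers[i]) / sd)^2),
    numeric(length(grid))))
  Spectrum1D(grid, y)
}

test_that("normalization is idempotent, scale-invariant and mode-correct", {
  s <- mkGauss(c(10, 20), c(1, 2))
  a1 <- normalizeSpectrum(s, "area")
  expect_equal(trapzArea(a1), 1, tolerance = 1e-12)
  expect_equal(normalizeSpectrum(a1, "area")@intensity, a1@intensity,
               tolerance = 1e-12)
  s7 <- Spectrum1D(s@energy, 7 * s@intensity)
  expect_equal(normalizeSpectrum(s7, "area")@intensity, a1@intensity,
               tolerance = 1e-12)
  m <- normalizeSpectrum(s, "max")
  expect_equal(max(m@intensity), 1)
  expect_error(normalizeSpectrum(Spectrum1D(1:10, rep(0, 10)), "area"),
               "norm")
  expect_error(normalizeSpectrum(s, "area", window = c(100, 200)), "window")
})

test_that("difference spectra vanish on identity, are linear, and refuse disjoint grids", {
  s <- mkGauss(c(10, 20), c(1, 2))
  r <- mkGauss(c(12, 20), c(1.5, 1))
  d0 <- differenceSpectrum(s, s, "area")
  expect_equal(max(abs(d0@intensity)), 0, tolerance = 1e-14)
  # mixture linearity under area normalization (operands share unit area)
  ns <- normalizeSpectrum(s, "area"); nr <- normalizeSpectrum(r, "area")
  for (w in c(0.25, 0.5, 0.8)) {
    mix <- Spectrum1D(s@energy, w * ns@intensity + (1 - w) * nr@intensity)
    dm <- differenceSpectrum(mix, nr, "area")
    dp <- differenceSpectrum(ns, nr, "area")
    expect_equal(dm@intensity, w * dp@intensity, tolerance = 1e-10)
  }
  # resampling onto the intersection grid
  r2 <- Spectrum1D(seq(5, 25, 0.075), approx(r@energy, r@intensity,
                                             seq(5, 25, 0.075))$y)
  d2 <- differenceSpectrum(s, r2, "area")
  expect_gte(min(d2@energy), 5); expect_lte(max(d2@energy), 25)
  far <- Spectrum1D(seq(100, 110, 0.1), rep(1, 101))
  expect_error(differenceSpectrum(s, far), "disjoint")
  expect_s4_class(d2, "DifferenceSpectrum")
  expect_equal(d2@mode, "area")
})

test_that("peak detection finds well-separated components and respects prominence", {
  s <- mkGauss(c(10, 16), c(1, 0.8), sd = 1.5)  # 3 sigma apart -> 2 maxima
  pk <- findSpectralPeaks(s)
  expect_equal(nrow(pk$maxima), 2L)
  expect_equal(pk$maxima$energy, c(10, 16), tolerance = 0.1)
  expect_equal(pk$splitting, 6, tolerance = 0.2)
  mono <- Spectrum1D(seq(0, 10, 0.1), exp(seq(0, 10, 0.1)))
  expect_equal(nrow(findSpectralPeaks(mono)$maxima), 0L)
  # a 2% bump on a large peak is dropped at 5% prominence
  s2 <- mkGauss(c(10, 15), c(1, 0.02), sd = 1)
  expect_equal(nrow(findSpectralPeaks(s2, minProminence = 0.05)$maxima), 1L)
  # unresolved partner on the flank appears as a shoulder
  s3 <- mkGauss(c(10, 12.1), c(1, 0.45), sd = 1)
  pk3 <- findSpectralPeaks(s3)
  expect_equal(nrow(pk3$maxima), 1L)
  expect_gte(nrow(pk3$shoulders), 1L)
  expect_error(findSpectralPeaks(Spectrum1D(1:2, 1:2)), "3 grid points")
})

test_that("peak positions are stable under grid refinement", {
  coarse <- mkGauss(c(10, 16), c(1, 0.8), grid = seq(0, 30, 0.2))
  fine <- mkGauss(c(10, 16), c(1, 0.8), grid = seq(0, 30, 0.1))
  pc <- findSpectralPeaks(coarse)$maxima$energy
  pf <- findSpectralPeaks(fine)$maxima$energy
  expect_equal(length(pc), length(pf))
  expect_true(all(abs(pc - pf) < 0.2))
})

test_that("exchange splitting measures separated groups and flags symmetric single peaks", {
  grid <- seq(7030, 7070, 0.05)
  two <- broadenSticks(data.frame(energy = c(7045, 7059), weight = c(1, 3)),
                       grid, lorentzian = 1, gaussian = 0.5)
  es <- exchangeSplitting(two)
  expect_true(es$resolved)
  expect_equal(es$splitting, 14, tolerance = 0.1)
  expect_equal(exchangeSplitting(two, method = "cluster")$splitting, 14,
               tolerance = 0.1)
  one <- broadenSticks(data.frame(energy = 7055, weight = 1), grid,
                       lorentzian = 1, gaussian = 0.5)
  es1 <- exchangeSplitting(one)
  expect_false(es1$resolved)
  expect_lt(es1$splitting, 0.5)
  expect_equal(exchangeSplitting(one, method = "cluster")$splitting, 0,
               tolerance = 1e-9)
})

test_that("a unit-scaling covalency scan reproduces the unscaled simulation", {
  gm <- ModelSpec(Configuration(2, 6, 1), smallSC())
  res <- covalencyScan(gm, 1.0)
  direct <- rxesEmissionCut(gm, "preedge")
  expect_equal(res$spectra[[1]]@intensity, direct@intensity,
               tolerance = 1e-12)
  expect_error(covalencyScan(gm, c(0.5, 1)), "descending")
  expect_error(covalencyScan(gm, 1.2), "0, 1")
})
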
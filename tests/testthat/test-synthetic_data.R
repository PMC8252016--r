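test_that("presets carry the documented d-counts and covalency scalings", {
  fer <- presetParameters("ferrous_td_chloride")
  fec <- presetParameters("ferric_td_chloride")
  expect_equal(fer@dCount, 6L); expect_equal(fer@slaterCondon@scaling, 0.60)
  expect_equal(fec@dCount, 5L); expect_equal(fec@slaterCondon@scaling, 0.45)
  expect_equal(presetParameters("ferrous_sulfide_site")@slaterCondon@scaling,
               0.50)
  expect_equal(presetParameters("ferric_sulfide_site")@slaterCondon@scaling,
               0.40)
  expect_error(presetParameters("ferrous_oh_oxide"), "unknown preset")
  expect_match(fer@metadata$provenance, "assumption")
})

test_that("mixtures are normalized, linear, order-independent and convex", {
  fer <- presetParameters("ferrous_td_chloride")
  fec <- presetParameters("ferric_td_chloride")
  expect_error(MixtureSpec(list(fer), 0), "positive sum")
  m <- MixtureSpec(list(fer, fec), c(4, 3))
  expect_equal(sum(m@weights), 1)
  expect_equal(m@weights, c(4, 3) / 7)
  grid <- seq(7040, 7075, 0.2)
  one <- mixtureSpectrum(MixtureSpec(list(fer), 1), "xes",
                         emissionGrid = grid)
  direct <- normalizeSpectrum(nonresonantKbetaXES(presetChain(fer, "xes"),
                                                  grid = grid), "area")
  expect_equal(one@intensity, direct@intensity, tolerance = 1e-12)
  ab <- mixtureSpectrum(MixtureSpec(list(fer, fec), c(0.3, 0.7)), "xes",
                        emissionGrid = grid)
  ba <- mixtureSpectrum(MixtureSpec(list(fec, fer), c(0.7, 0.3)), "xes",
                        emissionGrid = grid)
  expect_equal(ab@intensity, ba@intensity, tolerance = 1e-12)
  # FeMoco-like 4:3 ferrous:ferric weighting is bounded by the pure sites
  pureF <- mixtureSpectrum(MixtureSpec(list(fer), 1), "xes",
                           emissionGrid = grid)
  pureR <- mixtureSpectrum(MixtureSpec(list(fec), 1), "xes",
                           emissionGrid = grid)
  mix43 <- mixtureSpectrum(MixtureSpec(list(fer, fec), c(4, 3)), "xes",
                           emissionGrid = grid)
  lowB <- pmin(pureF@intensity, pureR@intensity)
  hiB <- pmax(pureF@intensity, pureR@intensity)
  expect_true(all(mix43@intensity >= lowB - 1e-12))
  expect_true(all(mix43@intensity <= hiB + 1e-12))
})

test_that("pseudo-measurements are seed-reproducible and converge at high counts", {
  grid <- seq(0, 10, 0.1)
  s <- Spectrum1D(grid, dnorm(grid, 5, 1))
  n1 <- synthesizeMeasurement(s, NoiseSpec(seed = 7))
  n2 <- synthesizeMeasurement(s, NoiseSpec(seed = 7))
  expect_identical(n1@intensity, n2@intensity)
  n3 <- synthesizeMeasurement(s, NoiseSpec(seed = 8))
  expect_false(identical(n1@intensity, n3@intensity))
  # calibration shift moves the axis only
  sh <- synthesizeMeasurement(s, NoiseSpec(seed = 7, calibrationShift = 1.3))
  expect_equal(sh@energy, s@energy + 1.3)
  expect_identical(sh@intensity, n1@intensity)
  # law-of-large-numbers limit
  big <- synthesizeMeasurement(s, NoiseSpec(scale = 1e9, seed = 3))
  expect_lt(max(abs(big@intensity - s@intensity)) / max(s@intensity), 1e-3)
  expect_error(synthesizeMeasurement(s, NoiseSpec(scale = -1)), "scale")
})

test_that("Poisson noise reproduces the counting variance at the peak", {
  grid <- seq(0, 10, 0.25)
  s <- Spectrum1D(grid, dnorm(grid, 5, 1))
  peakIdx <- which.max(s@intensity)
  N <- 400
  counts <- vapply(1:300, function(sd)
    synthesizeMeasurement(s, NoiseSpec(scale = N, seed = sd))@intensity[peakIdx] /
      max(s@intensity) * N, numeric(1))
  expect_equal(var(counts), N, tolerance = 0.25)
})

test_that("the preset pipeline runs presets -> mixtures -> noise -> analysis end to end", {
  fer <- presetParameters("ferrous_td_chloride")
  fec <- presetParameters("ferric_td_chloride")
  grid <- seq(7040, 7075, 0.1)
  mix <- mixtureSpectrum(MixtureSpec(list(fer, fec), c(0.5, 0.5)),
                         "rxes_preedge_cut", emissionGrid = grid)
  noisy <- synthesizeMeasurement(mix, NoiseSpec(scale = 1e5, seed = 20210323))
  pk <- findSpectralPeaks(noisy)
  expect_gte(nrow(pk$maxima), 2L)   # ferrous doublet survives the mixture
  d <- differenceSpectrum(noisy,
                          mixtureSpectrum(MixtureSpec(list(fec), 1),
                                          "rxes_preedge_cut",
                                          emissionGrid = grid), "area")
  expect_s4_class(d, "DifferenceSpectrum")
  expect_gt(max(d@intensity), 0)
})
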
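test_that("determinant bases have the binomial dimensions in a stable canonical order", {
  expect_equal(basisDimension(buildBasis(Configuration(2, 6, 6))), 210L)
  expect_equal(basisDimension(buildBasis(Configuration(1, 6, 7))), 240L)
  expect_equal(basisDimension(buildBasis(Configuration(2, 5, 7))), 720L)
  b1 <- buildBasis(Configuration(1, 3, 2))
  b2 <- buildBasis(Configuration(1, 3, 2))
  expect_identical(b1@masks, b2@masks)
  expect_false(is.unsorted(b1@masks))
  expect_error(buildBasis(Configuration(3, 6, 0)))
})

test_that("d^2 Coulomb eigenvalues equal the Condon-Shortley closed forms", {
  F2 <- 10; F4 <- 6
  es <- diagonalizeAndLabel(ModelSpec(Configuration(0, 0, 2),
                                      SlaterCondonSet(F2dd = F2, F4dd = F4)))
  g <- eigenGroups(es)
  f2 <- F2 / 49; f4 <- F4 / 441
  closed <- c(`3F` = -8 * f2 - 9 * f4, `3P` = 7 * f2 - 84 * f4,
              `1G` = 4 * f2 + f4, `1D` = -3 * f2 + 36 * f4,
              `1S` = 14 * f2 + 126 * f4)
  expect_setequal(g$term, names(closed))
  for (tm in names(closed))
    expect_equal(g$energy[g$term == tm], unname(closed[tm]),
                 tolerance = 1e-10)
})

test_that("degenerate Coulomb limits: zero set, monopole shift", {
  b <- buildBasis(Configuration(0, 0, 2))
  expect_equal(max(Mod(coulombMatrix(b, SlaterCondonSet()))), 0)
  cm <- coulombMatrix(b, SlaterCondonSet(F0dd = 3))
  expect_equal(max(Mod(cm - diag(3 + 0i, nrow(cm)))), 0, tolerance = 1e-12)
})

test_that("spin-orbit operator gives the closed-form p-hole splitting and is traceless", {
  es <- diagonalizeAndLabel(ModelSpec(Configuration(0, 5, 0),
                                      spinOrbit = SpinOrbitSet(zeta3p = 1)))
  g <- eigenGroups(es)
  expect_equal(g$degeneracy, c(4L, 2L))
  expect_equal(diff(g$energy), 1.5, tolerance = 1e-10)
  b <- buildBasis(Configuration(0, 3, 2))
  so <- spinOrbitMatrix(b, SpinOrbitSet(0.8, 0.3))
  expect_equal(sum(diag(so)), 0 + 0i, tolerance = 1e-10)
  expect_equal(max(Mod(spinOrbitMatrix(b, SpinOrbitSet(0, 0)))), 0)
})

test_that("ligand-field operator splits d^1 by barycenter algebra and is traceless", {
  es <- diagonalizeAndLabel(ModelSpec(Configuration(0, 0, 1),
                                      ligandField = LigandFieldSpec("Td", 1)))
  g <- eigenGroups(es)
  expect_equal(g$energy, c(-0.6, 0.4), tolerance = 1e-10)
  expect_equal(g$degeneracy, c(4L, 6L))
  esOh <- diagonalizeAndLabel(ModelSpec(Configuration(0, 0, 1),
                                        ligandField = LigandFieldSpec("Oh", 1)))
  expect_equal(eigenGroups(esOh)$energy, c(-0.4, 0.6), tolerance = 1e-10)
  b <- buildBasis(Configuration(0, 0, 3))
  lf <- ligandFieldMatrix(b, LigandFieldSpec("Td", 2.3))
  expect_equal(sum(diag(lf)), 0 + 0i, tolerance = 1e-10)
  expect_equal(max(Mod(ligandFieldMatrix(b, LigandFieldSpec("Td", 0)))), 0)
  expect_error(LigandFieldSpec("C2v", 1), "symmetry")
})

test_that("assembled Hamiltonians are Hermitian and complete", {
  for (spec in list(
    ModelSpec(Configuration(2, 5, 1), atomicSC()),
    ModelSpec(Configuration(1, 6, 2), atomicSC(), SpinOrbitSet(0.9, 0.05),
              LigandFieldSpec("Td", 0.6), energyOffset = 2.5))) {
    b <- buildBasis(spec@configuration)
    H <- assembleHamiltonian(spec, b)
    expect_lt(max(Mod(H - Conj(t(H)))), 1e-12)
    es <- diagonalizeAndLabel(spec)
    expect_equal(sum(eigenGroups(es)$degeneracy), basisDimension(b))
  }
})

test_that("atomic-limit Hamiltonians commute with total S^2 and L^2", {
  for (cfg in list(Configuration(0, 0, 3), Configuration(2, 5, 2))) {
    b <- buildBasis(cfg)
    H <- assembleHamiltonian(ModelSpec(cfg, atomicSC()), b)
    lad <- rxesim:::.ladderMatrices(b)
    S2 <- t(lad$Sp) %*% lad$Sp + diag(lad$Sz^2 + lad$Sz)
    L2 <- t(lad$Lp) %*% lad$Lp + diag(lad$Lz^2 + lad$Lz)
    expect_lt(max(Mod(H %*% S2 - S2 %*% H)), 1e-8)
    expect_lt(max(Mod(H %*% L2 - L2 %*% H)), 1e-8)
  }
})

test_that("atomic eigen-group multisets equal the enumerated terms with matching degeneracies", {
  for (cfg in list(Configuration(0, 0, 2), Configuration(0, 0, 3),
                   Configuration(0, 0, 4), Configuration(2, 5, 1),
                   Configuration(2, 5, 2), Configuration(2, 5, 3))) {
    es <- diagonalizeAndLabel(ModelSpec(cfg, atomicSC()))
    g <- eigenGroups(es)
    expect_false(any(g$term == "mixed"), label = rxesim:::.configKey(cfg))
    expect_equal(g$degeneracy, (2 * g$S + 1) * (2 * g$L + 1))
    tab <- enumerateTerms(cfg)
    expect_identical(sort(g$term), sort(rep(tab$term, tab$count)),
                     label = rxesim:::.configKey(cfg))
  }
})

test_that("one-electron terms change no state counts and Coulomb spectra scale linearly", {
  cfg <- Configuration(0, 0, 2)
  esA <- diagonalizeAndLabel(ModelSpec(cfg, atomicSC()))
  esB <- diagonalizeAndLabel(ModelSpec(cfg, atomicSC(),
                                       SpinOrbitSet(0, 0.3),
                                       LigandFieldSpec("Td", 1.1)))
  expect_equal(length(eigenEnergies(esA)), length(eigenEnergies(esB)))
  # scaling all SC parameters by lambda scales eigenvalue differences
  lam <- 0.37
  sc1 <- SlaterCondonSet(F2dd = 11, F4dd = 7, F2pd = 12, G1pd = 14,
                         G3pd = 8)
  sc2 <- SlaterCondonSet(F2dd = 11, F4dd = 7, F2pd = 12, G1pd = 14,
                         G3pd = 8, scaling = lam, scalingDD = lam)
  e1 <- eigenEnergies(diagonalizeAndLabel(ModelSpec(Configuration(2, 5, 1), sc1)))
  e2 <- eigenEnergies(diagonalizeAndLabel(ModelSpec(Configuration(2, 5, 1), sc2)))
  expect_equal(e2 - min(e2), lam * (e1 - min(e1)), tolerance = 1e-9)
})

test_that("Hund ground groups and the low-lying 4P of d^7 come out of the diagonalization", {
  g5 <- eigenGroups(diagonalizeAndLabel(ModelSpec(Configuration(2, 6, 5), atomicSC())))
  g6 <- eigenGroups(diagonalizeAndLabel(ModelSpec(Configuration(2, 6, 6), atomicSC())))
  g7 <- eigenGroups(diagonalizeAndLabel(ModelSpec(Configuration(2, 6, 7), atomicSC())))
  expect_equal(g5$term[1], "6S"); expect_equal(g5$degeneracy[1], 6L)
  expect_equal(g6$term[1], "5D"); expect_equal(g6$degeneracy[1], 25L)
  expect_equal(g7$term[1], "4F"); expect_equal(g7$degeneracy[1], 28L)
  expect_true("4P" %in% g7$term)
  expect_gt(g7$energy[g7$term == "4P"][1], g7$energy[1])
})
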
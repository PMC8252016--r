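test_that("term symbols format and parse consistently", {
  expect_equal(termSymbol(5, 2), "5D")
  expect_equal(termSymbol(1, 0), "1S")
  expect_equal(termSymbol(3, 13), "3[L=13]")
  expect_equal(parseTermSymbol("6S"), list(mult = 6L, L = 0L))
  expect_equal(parseTermSymbol("3[L=13]"), list(mult = 3L, L = 13L))
  expect_error(parseTermSymbol("Dx5"), "malformed")
})

test_that("Wigner 3j matches reference values frozen from an independent computer-algebra evaluation", {
  w3j <- rxesim:::wigner3j
  cases <- list(
    c(1, 2, 1, 0, 0, 0, 0.3651483716701107),
    c(2, 2, 2, 0, 0, 0, -0.23904572186687872),
    c(2, 2, 4, 1, -2, 1, -0.0890870806374748),
    c(2, 3, 5, 2, -1, -1, 0.08058229640253803),
    c(1, 1, 2, 1, 1, -2, 0.4472135954999579),
    c(2, 4, 2, -2, 2, 0, 0.1543033499620919),
    c(3, 2, 1, 1, 0, -1, 0.23904572186687872),
    c(0.5, 0.5, 1, 0.5, -0.5, 0, 0.408248290463863),
    c(2, 2, 3, 1, 1, -2, 0),      # zero by symmetry
    c(1, 2, 3, -1, -2, 3, 0.37796447300922725))
  for (cs in cases)
    expect_equal(w3j(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6]), cs[7],
                 tolerance = 1e-12)
})

test_that("d^n enumeration reproduces closed shells, d^2 and the Hund terms", {
  expect_equal(termsAsList(enumerateTerms(Configuration(0, 0, 0))),
               list(`1S` = 1L))
  expect_equal(termsAsList(enumerateTerms(Configuration(2, 6, 0))),
               list(`1S` = 1L))
  d2 <- enumerateTerms(Configuration(0, 0, 2))
  expect_setequal(d2$term, c("3F", "3P", "1G", "1D", "1S"))
  expect_true(all(d2$count == 1L))
  expect_equal(hundGroundTerm(6), "5D")
  expect_equal(hundGroundTerm(7), "4F")
  expect_equal(hundGroundTerm(10), "1S")
  expect_error(hundGroundTerm(11), "0..10")
  expect_error(enumerateTerms(Configuration(0, 0, 11)))
})

test_that("enumeration matches the brute-force microstate-peeling oracle over all shells", {
  for (n in 0:10) {
    cfg <- Configuration(0L, 0L, n)
    expectSameMultiset(termsAsList(enumerateTerms(cfg)),
                       bruteForceTerms(0L, 0L, n), label = paste0("d^", n))
  }
  for (m in 0:6) {
    cfg <- Configuration(0L, m, 0L)
    expectSameMultiset(termsAsList(enumerateTerms(cfg)),
                       bruteForceTerms(0L, m, 0L), label = paste0("p^", m))
  }
  for (n in 0:10) {
    cfg <- Configuration(2L, 5L, n)
    expectSameMultiset(termsAsList(enumerateTerms(cfg)),
                       bruteForceTerms(2L, 5L, n), label = paste0("p^5 d^", n))
  }
})

test_that("degeneracy sums equal the exact binomial microstate counts", {
  for (cfg in list(Configuration(2, 6, 6), Configuration(1, 6, 7),
                   Configuration(2, 5, 7), Configuration(1, 3, 4))) {
    tab <- enumerateTerms(cfg)
    expect_equal(sum(tab$count * tab$degeneracy), basisDimension(cfg))
  }
})

test_that("term coupling follows the angular-momentum product rule and conserves degeneracy", {
  c1 <- coupleTerms("5D", "2P")
  expect_setequal(c1$term, c("4P", "4D", "4F", "6P", "6D", "6F"))
  quint <- coupleTerms("4F", "2P")
  expect_setequal(quint$term[quint$mult == 5], c("5D", "5F", "5G"))
  expect_equal(coupleTerms("1S", "2S")$term, "2S")
  # degeneracy conservation on random term pairs
  set.seed(11)
  for (k in 1:20) {
    m1 <- sample(1:6, 1); L1 <- sample(0:4, 1)
    m2 <- sample(1:4, 1); L2 <- sample(0:3, 1)
    cc <- coupleTerms(termSymbol(m1, L1), termSymbol(m2, L2))
    expect_equal(sum(cc$degeneracy),
                 m1 * (2 * L1 + 1) * m2 * (2 * L2 + 1))
  }
})

test_that("high-spin spectral-class rules match the d-count groupings", {
  tab <- spectralClassTable(1:9)
  expect_equal(tab$dn[tab$rxes_kbeta13_split], c(1L, 2L, 6L, 7L))
  expect_equal(tab$dn[tab$preedge_kbeta_prime_absent], 5:9)
  expect_equal(tab$dn[tab$nonresonant_kbeta13_split], c(2L, 3L, 7L, 8L))
  p6 <- predictSpectralClass(6)
  expect_equal(p6$intermediateTerm, "4F")
  expect_true(p6$rxesKbeta13Split)
  expect_true(p6$preedgeKbetaPrimeAbsent)
  expect_false(predictSpectralClass(5)$rxesKbeta13Split)
  expect_error(predictSpectralClass(0), "1..9")
})
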
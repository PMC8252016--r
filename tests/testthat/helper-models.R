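# Shared fixtures: parameter sets and small utilities. Heavy eigen-solutions
# are memoized inside the package for the duration of the test run.

# Fe-like atomic Slater-Condon set used across the suite
atomicSC <- function(scaling = 1) {
  SlaterCondonSet(F2dd = 11, F4dd = 7, F2pd = 12, G1pd = 14, G3pd = 8,
                  scaling = scaling)
}

# small pd-only set for fast d^1-chain spectra
smallSC <- function() {
  SlaterCondonSet(F0dd = 0, F2dd = 0, F4dd = 0, F2pd = 6, G1pd = 8,
                  G3pd = 5)
}

trapzArea <- function(s) {
  sum(diff(s@energy) * (head(s@intensity, -1) + tail(s@intensity, -1)) / 2)
}

windowMass <- function(s, lo, hi) {
  i <- s@energy >= lo & s@energy <= hi
  if (!any(i)) return(0)
  sum(s@intensity[i]) * mean(diff(s@energy))
}

# independent brute-force term enumeration: explicit microstate table with
# repeated (M_L, M_S) corner peeling (a different algorithm from the
# package's inclusion-exclusion ladder counting)
bruteForceTerms <- function(n1s, n3p, n3d) {
  shells <- list(list(l = 0L, n = n1s), list(l = 1L, n = n3p),
                 list(l = 2L, n = n3d))
  states <- data.frame(ML = 0L, MS2 = 0L)
  for (sh in shells) {
    if (sh$n == 0L) next
    nso <- 2L * (2L * sh$l + 1L)
    ml <- rep(seq(-sh$l, sh$l), each = 2L)
    ms2 <- rep(c(1L, -1L), 2L * sh$l + 1L)
    cmb <- utils::combn(nso, sh$n)
    shellStates <- data.frame(
      ML = colSums(matrix(ml[cmb], nrow = sh$n)),
      MS2 = colSums(matrix(ms2[cmb], nrow = sh$n)))
    states <- data.frame(
      ML = rep(states$ML, times = nrow(shellStates)) +
        rep(shellStates$ML, each = nrow(states)),
      MS2 = rep(states$MS2, times = nrow(shellStates)) +
        rep(shellStates$MS2, each = nrow(states)))
  }
  out <- list()
  repeat {
    if (nrow(states) == 0L) break
    L <- max(states$ML)
    S2 <- max(states$MS2[states$ML == L])
    # remove one microstate at every (ML, MS) covered by this term
    for (ml in seq(-L, L)) for (ms2 in seq(-S2, S2, by = 2L)) {
      hit <- which(states$ML == ml & states$MS2 == ms2)[1]
      stopifnot(!is.na(hit))
      states <- states[-hit, , drop = FALSE]
    }
    key <- termSymbol(S2 + 1L, L)
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# term multiset of enumerateTerms() as a named count list for comparison
termsAsList <- function(tab) {
  out <- list()
  for (i in seq_len(nrow(tab))) out[[tab$term[i]]] <- tab$count[i]
  out
}

# order-insensitive multiset comparison (term -> count)
expectSameMultiset <- function(a, b, label = NULL) {
  a <- a[order(names(a))]
  b <- b[order(names(b))]
  testthat::expect_identical(a, b, label = label)
}
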
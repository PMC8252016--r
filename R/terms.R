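## Russell-Saunders term algebra: enumeration by M_L/M_S counting, core-hole
## coupling, Hund ground terms and the qualitative d^n spectral-class rules.

.termLetters <- c("S", "P", "D", "F", "G", "H", "I", "K", "L", "M", "N",
                  "O", "Q")

#' Format a Russell-Saunders term symbol
#'
#' @param mult spin multiplicity 2S+1 (integer >= 1)
#' @param L total orbital angular momentum (integer >= 0)
#' @return character like "5D"; L beyond the letter table (L > 12) is
#'   rendered numerically as e.g. "3[L=13]"
#' @export
termSymbol <- function(mult, L) {
  stopifnot(mult >= 1, L >= 0)
  letter <- if (L <= 12) .termLetters[L + 1] else sprintf("[L=%d]", L)
  paste0(mult, letter)
}

#' Parse a term symbol into (2S+1, L)
#' @param term character like "5D" or "3[L=13]"
#' @return list with elements mult and L
#' @export
parseTermSymbol <- function(term) {
  m <- regmatches(term, regexec("^([0-9]+)([A-Z]|\\[L=([0-9]+)\\])$", term))[[1]]
  if (length(m) == 0) stop("malformed term symbol: ", term)
  mult <- as.integer(m[2])
  L <- if (m[4] != "") as.integer(m[4]) else match(m[3], .termLetters) - 1L
  if (is.na(L)) stop("unknown orbital letter in term symbol: ", term)
  list(mult = mult, L = L)
}

# (M_L, 2M_S) microstate distribution of one open shell with n electrons.
# Returns a matrix with dimnames ML and MS2 (twice M_S).
.shellDistribution <- function(l, n) {
  nso <- 2L * (2L * l + 1L)
  stopifnot(n >= 0, n <= nso)
  ml <- rep(seq(-l, l), each = 2L)
  ms2 <- rep(c(1L, -1L), 2L * l + 1L)
  if (n == 0L) {
    D <- matrix(1L, 1, 1, dimnames = list(ML = "0", MS2 = "0"))
    return(D)
  }
  combos <- utils::combn(nso, n)
  ML <- colSums(matrix(ml[combos], nrow = n))
  MS2 <- colSums(matrix(ms2[combos], nrow = n))
  mlr <- seq(min(ML), max(ML))
  msr <- seq(min(MS2), max(MS2), by = 2L)
  D <- matrix(0L, length(mlr), length(msr),
              dimnames = list(ML = mlr, MS2 = msr))
  for (i in seq_along(ML))
    D[as.character(ML[i]), as.character(MS2[i])] <-
      D[as.character(ML[i]), as.character(MS2[i])] + 1L
  D
}

# Convolution of two (M_L, 2M_S) distributions (joint shells).
.convolveDistributions <- function(A, B) {
  mlA <- as.integer(rownames(A)); msA <- as.integer(colnames(A))
  mlB <- as.integer(rownames(B)); msB <- as.integer(colnames(B))
  mlr <- seq(min(mlA) + min(mlB), max(mlA) + max(mlB))
  msr <- seq(min(msA) + min(msB), max(msA) + max(msB), by = 2L)
  if (length(msr) == 0) msr <- min(msA) + min(msB)
  C <- matrix(0L, length(mlr), length(msr),
              dimnames = list(ML = mlr, MS2 = msr))
  for (i in seq_along(mlA)) for (j in seq_along(msA)) {
    if (A[i, j] == 0L) next
    rows <- as.character(mlA[i] + mlB)
    cols <- as.character(msA[j] + msB)
    C[rows, cols] <- C[rows, cols] + A[i, j] * B
  }
  C
}

#' Enumerate the Russell-Saunders terms of a shell configuration
#'
#' Counts every many-electron term of the joint 1s/3p/3d configuration by
#' descending-ladder counting on the exact (M_L, M_S) microstate table: the
#' number of terms with quantum numbers (L, S) is
#' N(L, S) - N(L+1, S) - N(L, S+1) + N(L+1, S+1), where N is the microstate
#' count at that exact projection. The multiset satisfies
#' sum(count * (2S+1)(2L+1)) = product of shell binomials.
#'
#' @param configuration a [Configuration-class]
#' @return data.frame with columns term, mult (2S+1), L, count, degeneracy
#'   ((2S+1)(2L+1) per term), ordered by descending multiplicity then
#'   descending L (Hund order: the first row is the Hund ground term)
#' @examples
#' enumerateTerms(Configuration(2, 6, 2))  # d^2: 3F 3P 1G 1D 1S
#' @export
enumerateTerms <- function(configuration) {
  stopifnot(is(configuration, "Configuration"))
  validObject(configuration)
  D <- .shellDistribution(0L, configuration@n1s)
  D <- .convolveDistributions(D, .shellDistribution(1L, configuration@n3p))
  D <- .convolveDistributions(D, .shellDistribution(2L, configuration@n3d))
  getN <- function(ml, ms2) {
    r <- as.character(ml); c <- as.character(ms2)
    if (r %in% rownames(D) && c %in% colnames(D)) D[r, c] else 0L
  }
  Lmax <- max(as.integer(rownames(D)))
  S2max <- max(as.integer(colnames(D)))
  out <- list()
  for (L in Lmax:0) for (S2 in seq(S2max, S2max %% 2L, by = -2L)) {
    cnt <- getN(L, S2) - getN(L + 1L, S2) - getN(L, S2 + 2L) +
      getN(L + 1L, S2 + 2L)
    if (cnt > 0L)
      out[[length(out) + 1L]] <- data.frame(
        term = termSymbol(S2 + 1L, L), mult = S2 + 1L, L = L,
        count = cnt, degeneracy = (S2 + 1L) * (2L * L + 1L),
        stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(-tab$mult, -tab$L), , drop = FALSE]
  rownames(tab) <- NULL
  stopifnot(sum(tab$count * tab$degeneracy) ==
              basisDimension(configuration))
  tab
}

#' Couple two Russell-Saunders terms
#'
#' Angular-momentum product rule: total spins range over |S1-S2|..S1+S2 and
#' orbital momenta over |L1-L2|..L1+L2, all combinations once. Total
#' degeneracy is conserved.
#'
#' @param valence,core term symbols (character, e.g. "5D", "2P")
#' @return data.frame with columns term, mult, L, count (= 1), degeneracy,
#'   Hund-ordered
#' @examples
#' coupleTerms("5D", "2P")  # 4,6 x P,D,F
#' @export
coupleTerms <- function(valence, core) {
  a <- parseTermSymbol(valence)
  b <- parseTermSymbol(core)
  S1 <- (a$mult - 1) / 2; S2 <- (b$mult - 1) / 2
  Ss <- seq(abs(S1 - S2), S1 + S2)
  Ls <- seq(abs(a$L - b$L), a$L + b$L)
  tab <- expand.grid(S = Ss, L = Ls)
  tab <- data.frame(term = mapply(termSymbol, 2 * tab$S + 1, tab$L),
                    mult = as.integer(2 * tab$S + 1), L = as.integer(tab$L),
                    count = 1L,
                    degeneracy = as.integer((2 * tab$S + 1) * (2 * tab$L + 1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mult, -tab$L), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Hund ground term of a d^n configuration
#'
#' Maximum-S then maximum-L member of the d^n term multiset.
#'
#' @param dn 3d electron count (0..10)
#' @return term symbol (character)
#' @examples
#' hundGroundTerm(6)  # "5D"
#' hundGroundTerm(7)  # "4F"
#' @export
hundGroundTerm <- function(dn) {
  if (dn < 0 || dn > 10) stop("dn must lie in 0..10")
  tab <- enumerateTerms(Configuration(0L, 0L, as.integer(dn)))
  tab$term[1]
}

#' Qualitative spectral-class prediction for a high-spin d^n ion
#'
#' Encodes the high-spin grouping rules relating the d-count to the
#' resonant/non-resonant Kbeta multiplet structure: (i) the pre-edge 1s3p
#' RXES Kbeta_1,3 feature is split whenever the d^(n+1) intermediate state
#' carries an F term (the Hund term of d^(n+1) has L = 3), because a
#' low-lying same-multiplicity partner term then mixes in by configuration
#' interaction -- true for d^1, d^2, d^6, d^7; (ii) for d^n >= 5 no alpha 3d
#' hole exists, only beta 1s->3d excitation is spin-allowed, and the
#' resonant spectrum loses its Kbeta' satellite; (iii) the non-resonant
#' Kbeta_1,3 is split for F-ground-term ions (d^2, d^3, d^7, d^8).
#'
#' @param dn ground-state 3d count (1..9), high-spin assumed
#' @return list with elements dn, intermediateTerm (Hund term of d^(n+1)),
#'   rxesKbeta13Split, preedgeKbetaPrimeAbsent, nonresonantKbeta13Split
#' @export
predictSpectralClass <- function(dn) {
  if (dn < 1 || dn > 9) stop("dn must lie in 1..9")
  it <- hundGroundTerm(dn + 1)
  gt <- hundGroundTerm(dn)
  list(dn = as.integer(dn),
       intermediateTerm = it,
       rxesKbeta13Split = parseTermSymbol(it)$L == 3L,
       preedgeKbetaPrimeAbsent = dn >= 5,
       nonresonantKbeta13Split = parseTermSymbol(gt)$L == 3L)
}

#' Tabulate spectral-class predictions for a range of d-counts
#'
#' @param dns integer vector of d-counts (default 1..9)
#' @return data.frame, one row per d-count
#' @export
spectralClassTable <- function(dns = 1:9) {
  rows <- lapply(dns, function(d) {
    p <- predictSpectralClass(d)
    data.frame(dn = p$dn, intermediate_term = p$intermediateTerm,
               rxes_kbeta13_split = p$rxesKbeta13Split,
               preedge_kbeta_prime_absent = p$preedgeKbetaPrimeAbsent,
               nonresonant_kbeta13_split = p$nonresonantKbeta13Split,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
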
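#' Wigner 3j symbol
#'
#' Closed-form (Racah sum) evaluation of the Wigner 3j symbol for integer or
#' half-integer angular momenta. Arguments outside the triangle rule or with
#' non-conserved projections return 0. Only small arguments (j <= 6 or so)
#' arise in this package, where double precision is exact to ~1e-14.
#'
#' @param j1,j2,j3 angular momenta (nonnegative, integer or half-integer)
#' @param m1,m2,m3 projections
#' @return numeric scalar
#' @keywords internal
wigner3j <- function(j1, j2, j3, m1, m2, m3) {
  if (abs(m1 + m2 + m3) > 1e-9) return(0)
  if (j3 < abs(j1 - j2) - 1e-9 || j3 > j1 + j2 + 1e-9) return(0)
  if (abs(m1) > j1 + 1e-9 || abs(m2) > j2 + 1e-9 || abs(m3) > j3 + 1e-9) return(0)
  # all of j1+j2-j3 etc. and j-m must be nonnegative integers
  ints <- c(j1 + j2 - j3, j1 - j2 + j3, -j1 + j2 + j3,
            j1 - m1, j1 + m1, j2 - m2, j2 + m2, j3 - m3, j3 + m3)
  if (any(abs(ints - round(ints)) > 1e-9) || any(round(ints) < 0)) return(0)
  lf <- function(n) lgamma(round(n) + 1)
  delta <- 0.5 * (lf(j1 + j2 - j3) + lf(j1 - j2 + j3) + lf(-j1 + j2 + j3) -
                    lf(j1 + j2 + j3 + 1))
  tmin <- max(0, j2 - j3 - m1, j1 - j3 + m2)
  tmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  tmin <- round(tmin); tmax <- round(tmax)
  if (tmax < tmin) return(0)
  s <- 0
  for (t in tmin:tmax) {
    lnum <- delta + 0.5 * (lf(j1 - m1) + lf(j1 + m1) + lf(j2 - m2) +
                             lf(j2 + m2) + lf(j3 - m3) + lf(j3 + m3))
    lden <- lf(t) + lf(j3 - j2 + m1 + t) + lf(j3 - j1 - m2 + t) +
      lf(j1 + j2 - j3 - t) + lf(j1 - m1 - t) + lf(j2 + m2 - t)
    s <- s + (-1)^t * exp(lnum - lden)
  }
  (-1)^round(j1 - j2 - m3) * s
}

#' Gaunt coefficient c^k(l m; l' m')
#'
#' Condon-Shortley angular coefficient entering two-electron Coulomb matrix
#' elements in the complex spherical-harmonic basis,
#' c^k(lm, l'm') = (-1)^m sqrt((2l+1)(2l'+1)) (l k l'; 0 0 0)
#'                 (l k l'; -m, m-m', m').
#'
#' @keywords internal
gauntCk <- function(k, l, m, lp, mp) {
  (-1)^m * sqrt((2 * l + 1) * (2 * lp + 1)) *
    wigner3j(l, k, lp, 0, 0, 0) *
    wigner3j(l, k, lp, -m, m - mp, mp)
}

# Spatial orbital table for the 1s/3p/3d model space: index 1..9.
.rxesimOrbitals <- data.frame(
  idx = 1:9,
  shell = c("s", "p", "p", "p", "d", "d", "d", "d", "d"),
  l = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
  m = c(0L, -1L, 0L, 1L, -2L, -1L, 0L, 1L, 2L),
  stringsAsFactors = FALSE
)

# Precomputed c^k table: ckTable[[k+1]][a, b] = c^k(l_a m_a; l_b m_b)
.rxesimCkTable <- local({
  orb <- .rxesimOrbitals
  lapply(0:4, function(k) {
    M <- matrix(0, 9, 9)
    for (a in 1:9) for (b in 1:9)
      M[a, b] <- gauntCk(k, orb$l[a], orb$m[a], orb$l[b], orb$m[b])
    M
  })
})
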
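## Hamiltonian assembly: Slater-Condon Coulomb operator, spin-orbit, cubic
## ligand field; dense diagonalization and degeneracy-group term labeling.

# Effective radial integral R^k for the orbital quadruple <ab|cd>, given the
# shells (l values) of the four orbitals. Direct integrals require
# l_a == l_c and l_b == l_d, exchange integrals l_a == l_d and l_b == l_c.
# Only the 3d-3d and 3p-3d interactions are parameterized: s-shell Coulomb
# terms and the pd/pp monopoles are constant within a configuration and are
# absorbed into the configuration energy offset.
.radialRk <- function(la, lb, lc, ld, k, sc) {
  if (la == lc && lb == ld) {
    if (la == 2L && lb == 2L) {
      if (k == 0L) return(sc@F0dd)
      if (k == 2L) return(sc@F2dd * sc@scalingDD)
      if (k == 4L) return(sc@F4dd * sc@scalingDD)
    } else if ((la == 1L && lb == 2L) || (la == 2L && lb == 1L)) {
      if (k == 2L) return(sc@F2pd * sc@scaling)
    }
  }
  if (la == ld && lb == lc && la != lb) {
    if ((la == 1L && lb == 2L) || (la == 2L && lb == 1L)) {
      if (k == 1L) return(sc@G1pd * sc@scaling)
      if (k == 3L) return(sc@G3pd * sc@scaling)
    }
  }
  0
}

# Spatial two-electron integrals <ab|1/r12|cd> (physicist notation) over the
# 9 spatial orbitals, from Gaunt coefficients and Slater-Condon radials:
# <ab|cd> = delta(ma+mb, mc+md) sum_k c^k(la ma; lc mc) c^k(ld md; lb mb) R^k
.spatialERI <- function(sc) {
  orb <- .rxesimOrbitals
  V <- array(0, c(9, 9, 9, 9))
  for (a in 1:9) for (b in 1:9) for (c in 1:9) for (d in 1:9) {
    if (orb$m[a] + orb$m[b] != orb$m[c] + orb$m[d]) next
    v <- 0
    for (k in 0:4) {
      R <- .radialRk(orb$l[a], orb$l[b], orb$l[c], orb$l[d], k, sc)
      if (R == 0) next
      v <- v + .rxesimCkTable[[k + 1]][a, c] * .rxesimCkTable[[k + 1]][d, b] * R
    }
    V[a, b, c, d] <- v
  }
  V
}

# cached index grids for expanding spatial ERIs to antisymmetrized
# spin-orbital ERIs
.soGrid <- local({
  g <- expand.grid(p = 1:18, q = 1:18, r = 1:18, s = 1:18)
  list(ap = .bitOrbital[g$p], aq = .bitOrbital[g$q],
       ar = .bitOrbital[g$r], as = .bitOrbital[g$s],
       sp = .bitSpin[g$p], sq = .bitSpin[g$q],
       sr = .bitSpin[g$r], ss = .bitSpin[g$s])
})

# Antisymmetrized spin-orbital integrals <pq||rs> as a flat vector indexed
# ((p*18+q)*18+r)*18+s (0-based), ready for the C++ builder.
.antisymERI <- function(sc) {
  V <- .spatialERI(sc)
  g <- .soGrid
  direct <- V[cbind(g$ap, g$aq, g$ar, g$as)] *
    (g$sp == g$sr) * (g$sq == g$ss)
  exch <- V[cbind(g$ap, g$aq, g$as, g$ar)] *
    (g$sp == g$ss) * (g$sq == g$sr)
  direct - exch
}

#' Coulomb operator matrix in the determinant basis
#'
#' Two-electron Coulomb operator built from Slater-Condon radial parameters
#' and closed-form Gaunt angular factors for the dd and pd interactions, in
#' the complex spherical-harmonic orbital basis.
#'
#' @param basis a [DeterminantBasis-class]
#' @param sc a [SlaterCondonSet-class]
#' @return Hermitian complex matrix (here real-valued)
#' @export
coulombMatrix <- function(basis, sc) {
  stopifnot(is(basis, "DeterminantBasis"), is(sc, "SlaterCondonSet"))
  z <- matrix(0, 18, 18)
  cpp_build_hamiltonian(basis@masks, z, z, .antisymERI(sc))
}

# one-electron spin-orbit operator zeta l.s on the 18 spin-orbitals (real)
.spinOrbitH1 <- function(so) {
  h <- matrix(0, 18, 18)
  addShell <- function(h, l, orbitals, zeta) {
    if (zeta == 0) return(h)
    for (i in seq_along(orbitals)) {
      m <- i - 1L - l
      o <- orbitals[i]
      for (sp in 0:1) {
        b <- .soBit(o, sp) + 1L
        h[b, b] <- h[b, b] + zeta * m * (if (sp == 0L) 0.5 else -0.5)
      }
      # (1/2) zeta l+ s-: (m, alpha) -> (m+1, beta)
      if (m < l) {
        b1 <- .soBit(o, 0L) + 1L
        b2 <- .soBit(orbitals[i + 1L], 1L) + 1L
        v <- 0.5 * zeta * sqrt((l - m) * (l + m + 1))
        h[b2, b1] <- h[b2, b1] + v
        h[b1, b2] <- h[b1, b2] + v
      }
    }
    h
  }
  h <- addShell(h, 1L, 2:4, so@zeta3p)
  h <- addShell(h, 2L, 5:9, so@zeta3d)
  h
}

# complex-basis 5x5 ligand-field matrix on the 3d orbitals (m = -2..2)
.ligandFieldD <- function(lf) {
  if (lf@symmetry == "spherical" || lf@tenDq == 0) return(matrix(0, 5, 5))
  s2 <- 1 / sqrt(2)
  # rows: z2, x2-y2, xy, xz, yz; cols: m = -2..2
  U <- rbind(
    c(0, 0, 1, 0, 0),
    c(s2, 0, 0, 0, s2),
    c(1i * s2, 0, 0, 0, -1i * s2),
    c(0, s2, 0, -s2, 0),
    c(0, 1i * s2, 0, 1i * s2, 0))
  d <- abs(lf@tenDq)
  eE <- if (lf@symmetry == "Td") -0.6 * d else 0.6 * d
  eT2 <- if (lf@symmetry == "Td") 0.4 * d else -0.4 * d
  E <- c(eE, eE, eT2, eT2, eT2)
  Conj(t(U)) %*% (E * U)
}

#' Spin-orbit operator matrix in the determinant basis
#'
#' One-electron zeta l.s operator for the open 3p/3d shells; Hermitian and
#' traceless.
#'
#' @param basis a [DeterminantBasis-class]
#' @param so a [SpinOrbitSet-class]
#' @return complex matrix
#' @export
spinOrbitMatrix <- function(basis, so) {
  stopifnot(is(basis, "DeterminantBasis"), is(so, "SpinOrbitSet"))
  h <- .spinOrbitH1(so)
  cpp_build_hamiltonian(basis@masks, h, matrix(0, 18, 18),
                        numeric(18^4))
}

#' Ligand-field operator matrix in the determinant basis
#'
#' One-electron 3d orbital-energy operator splitting e/t2 by |10Dq| with the
#' barycenter preserved (traceless over the shell); Td places e below t2.
#'
#' @param basis a [DeterminantBasis-class]
#' @param lf a [LigandFieldSpec-class]
#' @return complex matrix
#' @export
ligandFieldMatrix <- function(basis, lf) {
  stopifnot(is(basis, "DeterminantBasis"), is(lf, "LigandFieldSpec"))
  h1 <- .oneBodyH1(SpinOrbitSet(0, 0), lf)
  cpp_build_hamiltonian(basis@masks, Re(h1), Im(h1), numeric(18^4))
}

# full 18x18 one-electron operator: spin-orbit + ligand field
.oneBodyH1 <- function(so, lf) {
  h <- .spinOrbitH1(so) + 0i
  D <- .ligandFieldD(lf)
  for (i in 1:5) for (j in 1:5) {
    if (D[i, j] == 0) next
    for (sp in 0:1) {
      bi <- .soBit(4L + i, sp) + 1L
      bj <- .soBit(4L + j, sp) + 1L
      h[bi, bj] <- h[bi, bj] + D[i, j]
    }
  }
  h
}

#' Assemble the full Hamiltonian of a model specification
#'
#' Coulomb + spin-orbit + ligand field + scalar configuration offset, as a
#' dense Hermitian matrix in the determinant basis.
#'
#' @param spec a [ModelSpec-class]
#' @param basis optional pre-built [DeterminantBasis-class]
#' @return complex Hermitian matrix
#' @export
assembleHamiltonian <- function(spec, basis = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  if (is.null(basis)) basis <- .cachedBasis(spec@configuration)
  h1 <- .oneBodyH1(spec@spinOrbit, spec@ligandField)
  H <- cpp_build_hamiltonian(basis@masks, Re(h1), Im(h1),
                             .antisymERI(spec@slaterCondon))
  if (spec@energyOffset != 0)
    diag(H) <- diag(H) + spec@energyOffset
  if (max(abs(H - Conj(t(H)))) > 1e-9)
    stop("internal consistency error: assembled Hamiltonian is not Hermitian")
  H
}

# many-body ladder matrices L+ and S+ for a basis (real, dense)
.ladderMatrices <- function(basis) {
  key <- paste0("ladder|", .configKey(basis@configuration))
  .cacheGet(key, function() {
    aL <- integer(); bL <- integer(); cL <- numeric()
    for (sh in list(list(l = 1L, orbs = 2:4), list(l = 2L, orbs = 5:9))) {
      l <- sh$l
      for (i in seq_along(sh$orbs)) {
        m <- i - 1L - l
        if (m >= l) next
        for (sp in 0:1) {
          aL <- c(aL, .soBit(sh$orbs[i + 1L], sp))
          bL <- c(bL, .soBit(sh$orbs[i], sp))
          cL <- c(cL, sqrt((l - m) * (l + m + 1)))
        }
      }
    }
    Lp <- cpp_one_body(basis@masks, basis@masks, aL, bL, cL)
    aS <- .soBit(1:9, 0L); bS <- .soBit(1:9, 1L)
    Sp <- cpp_one_body(basis@masks, basis@masks, aS, bS, rep(1, 9))
    list(Lp = Lp, Sp = Sp,
         Lz = .maskSums(basis@masks, .bitM),
         Sz = .maskSums(basis@masks, .bitMs2) / 2)
  })
}

# per-state <S^2> and <L^2> expectation values for eigenvector columns V
.angularExpectations <- function(basis, V) {
  lad <- .ladderMatrices(basis)
  p2 <- function(M, z) {
    Mv <- M %*% V
    colSums(abs(Mv)^2) + colSums((z^2 + z) * abs(V)^2)
  }
  list(L2 = Re(p2(lad$Lp, lad$Lz)), S2 = Re(p2(lad$Sp, lad$Sz)))
}

# apply the Casimir J^2 = J- J+ + Jz^2 + Jz to eigenvector columns
.applyCasimir <- function(Jp, Jz, V) {
  W <- Jp %*% V
  t(Jp) %*% W + (Jz^2 + Jz) * V
}

# Within each energy cluster, simultaneously diagonalize S^2 then L^2 so
# that accidentally degenerate terms (equal Coulomb energy, different S/L)
# are resolved into separate, properly labeled groups. Returns the rotated
# states and per-state (S2, L2) expectations.
.resolveAtomicClusters <- function(basis, V, first, last) {
  lad <- .ladderMatrices(basis)
  S2 <- numeric(ncol(V)); L2 <- numeric(ncol(V))
  for (g in seq_along(first)) {
    idx <- first[g]:last[g]
    Vc <- V[, idx, drop = FALSE]
    if (length(idx) > 1) {
      CS <- .applyCasimir(lad$Sp, lad$Sz, Vc)
      M <- Conj(t(Vc)) %*% CS
      eS <- eigen((M + Conj(t(M))) / 2, symmetric = TRUE)
      ordS <- order(round(eS$values, 6))
      Vc <- Vc %*% eS$vectors[, ordS, drop = FALSE]
      sv <- eS$values[ordS]
      # within each S block, diagonalize L^2
      sg <- cumsum(c(1, diff(round(sv, 6)) != 0))
      for (sb in unique(sg)) {
        j <- which(sg == sb)
        Vs <- Vc[, j, drop = FALSE]
        if (length(j) > 1) {
          CL <- .applyCasimir(lad$Lp, lad$Lz, Vs)
          Ml <- Conj(t(Vs)) %*% CL
          eL <- eigen((Ml + Conj(t(Ml))) / 2, symmetric = TRUE)
          ordL <- order(round(eL$values, 6))
          Vs <- Vs %*% eL$vectors[, ordL, drop = FALSE]
          Vc[, j] <- Vs
        }
      }
      V[, idx] <- Vc
    }
    ae <- .angularExpectations(basis, V[, idx, drop = FALSE])
    S2[idx] <- ae$S2; L2[idx] <- ae$L2
  }
  list(V = V, S2 = S2, L2 = L2)
}

# quantum number from a Casimir expectation x = q(q+1)
.casimirToQ <- function(x) (-1 + sqrt(pmax(0, 1 + 4 * x))) / 2

#' Diagonalize a model and label degeneracy groups
#'
#' Full dense spectrum of the assembled Hamiltonian. Eigenvalues are
#' clustered into degeneracy groups (energy tolerance \code{tol}); in the
#' spherical, zero-spin-orbit limit each group is labeled by (S, L) from
#' total-spin/orbital Casimir expectation values and matched to a
#' Russell-Saunders term symbol, otherwise the label is "mixed".
#'
#' @param spec a [ModelSpec-class]
#' @param tol energy-clustering tolerance (eV)
#' @param labelTol rounding tolerance on the S/L expectation values
#' @return a [LabeledEigenset-class]
#' @examples
#' \donttest{
#' es <- diagonalizeAndLabel(ModelSpec(Configuration(0, 0, 2),
#'   SlaterCondonSet(F2dd = 10, F4dd = 6)))
#' eigenGroups(es)
#' }
#' @export
diagonalizeAndLabel <- function(spec, tol = 1e-6, labelTol = 1e-3) {
  stopifnot(is(spec, "ModelSpec"))
  key <- paste0("eigen|", .specKey(spec))
  .cacheGet(key, function() {
    basis <- .cachedBasis(spec@configuration)
    H <- assembleHamiltonian(spec, basis)
    ed <- eigen(H, symmetric = TRUE)
    ord <- order(ed$values)
    energies <- ed$values[ord]
    V <- ed$vectors[, ord, drop = FALSE]
    # degeneracy clustering
    n <- length(energies)
    grp <- cumsum(c(1, diff(energies) > tol))
    first <- match(unique(grp), grp)
    last <- c(first[-1] - 1L, n)
    atomic <- spec@ligandField@symmetry == "spherical" &&
      spec@spinOrbit@zeta3p == 0 && spec@spinOrbit@zeta3d == 0
    if (atomic) {
      res <- .resolveAtomicClusters(basis, V, first, last)
      V <- res$V
      # re-split energy clusters by the resolved (S, L) quantum numbers
      Sq <- .casimirToQ(res$S2); Lq <- .casimirToQ(res$L2)
      keyS <- round(2 * Sq) / 2; keyL <- round(Lq)
      cluster <- rep(seq_along(first), times = last - first + 1L)
      splitKey <- paste(cluster, keyS, keyL)
      newGrp <- cumsum(c(TRUE, splitKey[-1] != splitKey[-n]))
      first <- match(unique(newGrp), newGrp)
      last <- c(first[-1] - 1L, n)
    }
    Sv <- Lv <- rep(NA_real_, length(first))
    terms <- rep("mixed", length(first))
    if (atomic) {
      for (g in seq_along(first)) {
        idx <- first[g]:last[g]
        S <- .casimirToQ(mean(res$S2[idx]))
        L <- .casimirToQ(mean(res$L2[idx]))
        okS <- abs(S - round(2 * S) / 2) < labelTol
        okL <- abs(L - round(L)) < labelTol
        if (okS && okL) {
          S <- round(2 * S) / 2; L <- round(L)
          Sv[g] <- S; Lv[g] <- L
          if ((last[g] - first[g] + 1L) == (2 * S + 1) * (2 * L + 1))
            terms[g] <- termSymbol(as.integer(2 * S + 1), as.integer(L))
        }
      }
    }
    groups <- data.frame(first = first, last = last,
                         energy = vapply(seq_along(first), function(g)
                           mean(energies[first[g]:last[g]]), numeric(1)),
                         degeneracy = last - first + 1L,
                         S = Sv, L = Lv, term = terms,
                         stringsAsFactors = FALSE)
    new("LabeledEigenset", spec = spec, basis = basis, energies = energies,
        states = V, groups = groups)
  })
}
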
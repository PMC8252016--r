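## Spectrum rendering and the two emission processes: sudden-approximation
## non-resonant Kbeta XES and Kramers-Heisenberg 1s3p RXES planes with
## constant-incident-energy and HERFD cuts.

.lorentz <- function(x, fwhm) {
  g2 <- fwhm / 2
  (g2 / pi) / (x^2 + g2^2)
}

# discrete Gaussian convolution along a uniform grid; kernel renormalized to
# unit sum so in-grid mass is conserved away from the edges
.gaussConvolve <- function(y, step, fwhm) {
  if (fwhm <= 0 || length(y) < 2) return(y)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(6 * sigma / step))
  x <- seq(-half, half) * step
  k <- exp(-0.5 * (x / sigma)^2)
  k <- k / sum(k)
  full <- stats::convolve(y, rev(k), type = "open")
  full[(half + 1):(half + length(y))]
}

#' Render a stick spectrum on a grid
#'
#' Each stick is rendered as a Lorentzian of FWHM \code{lorentzian} by exact
#' per-bin integration of its cumulative distribution, renormalized over the
#' grid span so every stick contributes exactly its weight to the in-grid
#' area (heavy Lorentzian tails outside the window are folded back
#' proportionally); a Gaussian instrumental convolution of FWHM
#' \code{gaussian} is applied last. Zero widths reduce to nearest-node
#' binning.
#'
#' @param sticks data.frame with columns energy, weight
#' @param grid strictly increasing, uniform energy grid (eV)
#' @param broadening a [BroadeningSpec-class]; the Lorentzian FWHM used is
#'   \code{gammaIntermediate + gammaFinal} (initial and final core-hole
#'   lifetimes add in an emission line)
#' @param lorentzian,gaussian explicit FWHM overrides (eV)
#' @return a [Spectrum1D-class] whose integral equals the summed stick
#'   weights
#' @export
broadenSticks <- function(sticks, grid, broadening = NULL,
                          lorentzian = NULL, gaussian = NULL) {
  if (length(grid) < 2) stop("grid must have at least 2 points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (!is.null(broadening)) {
    if (is.null(lorentzian))
      lorentzian <- broadening@gammaIntermediate + broadening@gammaFinal
    if (is.null(gaussian)) gaussian <- broadening@sigmaInstrumental
  }
  if (is.null(lorentzian)) lorentzian <- 0
  if (is.null(gaussian)) gaussian <- 0
  step <- mean(diff(grid))
  edges <- c(grid[1] - step / 2, grid + step / 2)
  y <- numeric(length(grid))
  if (nrow(sticks) > 0) {
    for (i in seq_len(nrow(sticks))) {
      E <- sticks$energy[i]; w <- sticks$weight[i]
      if (w == 0) next
      if (lorentzian > 0) {
        cdf <- atan(2 * (edges - E) / lorentzian) / pi
        mass <- diff(cdf)
        tot <- cdf[length(cdf)] - cdf[1]
        if (tot > 0) y <- y + w * mass / tot
      } else {
        j <- which.min(abs(grid - E))
        y[j] <- y[j] + w
      }
    }
  }
  y <- y / step
  y <- .gaussConvolve(y, step, gaussian)
  y[y < 0] <- 0
  Spectrum1D(grid, y, sticks = sticks,
             metadata = list(lorentzian_fwhm_eV = lorentzian,
                             gaussian_fwhm_eV = gaussian))
}

# uniform grid spanning the given stick energies with padding (eV)
.autoGrid <- function(energies, pad = 3, step = 0.1) {
  if (length(energies) == 0) return(seq(-1, 1, by = step))
  lo <- floor((min(energies) - pad) / step) * step
  hi <- ceiling((max(energies) + pad) / step) * step
  seq(lo, hi, by = step)
}

# indices of the lowest-energy degeneracy group
.groundGroup <- function(es) {
  g <- es@groups
  seq.int(g$first[1], g$last[1])
}

# derive the XES / RXES configuration chains from a ground ModelSpec by
# moving the appropriate electron, keeping all coupling parameters
.withConfiguration <- function(spec, cfg) {
  ModelSpec(cfg, spec@slaterCondon, spec@spinOrbit, spec@ligandField,
            spec@energyOffset)
}

#' Build the non-resonant (XES) chain from a ground-state model
#'
#' Ground 1s^2 3p^6 3d^n, 1s-ionized intermediate 1s^1 3p^6 3d^n, and
#' 3p-hole final 1s^2 3p^5 3d^n, all sharing the ground model's coupling
#' parameters.
#' @param ground a [ModelSpec-class] with a filled 1s and 3p shell
#' @param name chain identifier
#' @param offsets a [CalibrationOffsets-class]
#' @return a [ModelChain-class]
#' @export
xesChain <- function(ground, name = "xes", offsets = CalibrationOffsets()) {
  cfg <- ground@configuration
  if (cfg@n1s != 2L || cfg@n3p != 6L)
    stop("XES ground configuration needs a 1s pair and a filled 3p shell")
  ModelChain(name, ground,
             .withConfiguration(ground, Configuration(1L, 6L, cfg@n3d)),
             .withConfiguration(ground, Configuration(2L, 5L, cfg@n3d)),
             offsets)
}

#' Build the resonant (1s3p RXES) chain from a ground-state model
#'
#' Ground 1s^2 3p^6 3d^n, resonantly excited intermediate 1s^1 3p^6 3d^(n+1),
#' and final 1s^2 3p^5 3d^(n+1).
#' @inheritParams xesChain
#' @return a [ModelChain-class]
#' @export
rxesChain <- function(ground, name = "rxes", offsets = CalibrationOffsets()) {
  cfg <- ground@configuration
  if (cfg@n1s != 2L || cfg@n3p != 6L)
    stop("RXES ground configuration needs a 1s pair and a filled 3p shell")
  if (cfg@n3d >= 10L) stop("RXES needs a 3d vacancy (n3d <= 9)")
  ModelChain(name, ground,
             .withConfiguration(ground, Configuration(1L, 6L, cfg@n3d + 1L)),
             .withConfiguration(ground, Configuration(2L, 5L, cfg@n3d + 1L)),
             offsets)
}

# sudden-approximation ionization populations of the 1s-hole eigenstates:
# w_n = (1/g) sum_{sigma, g} |<n| c_{1s sigma} |g>|^2
.ionizationWeights <- function(groundES, holeES) {
  gIdx <- .groundGroup(groundES)
  Vg <- groundES@states[, gIdx, drop = FALSE]
  w <- numeric(length(holeES@energies))
  for (sp in 0:1) {
    M <- cpp_annihilate(holeES@basis@masks, groundES@basis@masks,
                        .soBit(1L, sp))
    amp <- Conj(t(holeES@states)) %*% (M %*% Vg)
    w <- w + rowSums(abs(amp)^2)
  }
  w / length(gIdx)
}

#' Non-resonant Kbeta XES spectrum
#'
#' Sudden approximation: the 1s-ionized intermediate eigenstates are
#' populated with spin-statistical ionization weights (both alpha and beta
#' 1s channels), then every 3p->1s emission stick is weighted by the
#' population times the squared many-body amplitude, summed incoherently
#' over the three 3p orbital components, and rendered on the emission grid.
#' Only the ground-state degeneracy group is populated (no thermal excited
#' states).
#'
#' @param chain a [ModelChain-class] from [xesChain], or a ground
#'   [ModelSpec-class] (the chain is derived with the same parameters)
#' @param broadening a [BroadeningSpec-class]
#' @param offsets a [CalibrationOffsets-class]; default: the chain's
#' @param grid emission-energy grid (eV); NULL derives a 0.1 eV grid
#'   spanning the stick spectrum (under the calibrated presets this is the
#'   conventional 7040-7075 eV window)
#' @param weightTol intermediate populations below \code{weightTol * max}
#'   are dropped (exact zeros only at the default)
#' @return a [Spectrum1D-class] (emission-energy axis)
#' @export
nonresonantKbetaXES <- function(chain, broadening = BroadeningSpec(),
                                offsets = NULL, grid = NULL,
                                weightTol = 1e-12) {
  if (is(chain, "ModelSpec")) chain <- xesChain(chain)
  stopifnot(is(chain, "ModelChain"))
  if (chain@intermediate@configuration@n1s != 1L ||
      chain@final@configuration@n3p != 5L ||
      chain@intermediate@configuration@n3d != chain@ground@configuration@n3d)
    stop("invalid configuration chain for non-resonant Kbeta XES")
  if (is.null(offsets)) offsets <- chain@offsets
  gE <- diagonalizeAndLabel(chain@ground)
  iE <- diagonalizeAndLabel(chain@intermediate)
  fE <- diagonalizeAndLabel(chain@final)
  w <- .ionizationWeights(gE, iE)
  keep <- which(w > weightTol * max(w))
  Em <- transitionAmplitudes(iE, fE, "emit_3p1s")
  inten <- matrix(0, dim(Em)[1], length(keep))
  for (comp in seq_len(dim(Em)[3]))
    inten <- inten + abs(Em[, keep, comp, drop = FALSE][, , 1])^2
  stickE <- offsets@emissionOrigin +
    outer(-fE@energies, iE@energies[keep], "+")  # E_n - E_f
  stickW <- sweep(inten, 2, w[keep], "*")
  nz <- which(stickW > weightTol * max(stickW))
  sticks <- data.frame(energy = stickE[nz], weight = stickW[nz])
  sticks <- sticks[order(sticks$energy), ]
  rownames(sticks) <- NULL
  if (is.null(grid)) grid <- .autoGrid(sticks$energy, pad = 5)
  s <- broadenSticks(sticks, grid, broadening = broadening)
  s@metadata <- c(s@metadata,
                  list(process = "nonresonant_kbeta_xes",
                       chain = chain@name,
                       emission_origin_eV = offsets@emissionOrigin))
  s
}

# absorption routing: amplitudes from the ground group into the intermediate
# eigenstates, pruned to the reachable set
.absorptionRoute <- function(gE, iE, tol = 1e-12) {
  Ab <- transitionAmplitudes(gE, iE, "absorb_1s3d")
  gIdx <- .groundGroup(gE)
  Ab <- Ab[, gIdx, , drop = FALSE]
  str <- apply(abs(Ab), 1, max)
  keep <- which(str > tol * max(str))
  list(Ab = Ab[keep, , , drop = FALSE], keep = keep, gIdx = gIdx,
       strength = rowSums(abs(Ab)^2))
}

#' Total 1s->3d absorption profile (pre-edge region)
#'
#' Lorentzian-broadened (1s core-hole width) absorption cross-section into
#' the resonant intermediate states; used to locate the pre-edge resonance.
#'
#' @inheritParams rxesPlane
#' @param grid incident-energy grid (eV); NULL derives one from the
#'   absorption sticks
#' @return a [Spectrum1D-class] (incident-energy axis)
#' @export
absorptionProfile <- function(chain, broadening = BroadeningSpec(),
                              offsets = NULL, grid = NULL) {
  stopifnot(is(chain, "ModelChain"))
  if (is.null(offsets)) offsets <- chain@offsets
  gE <- diagonalizeAndLabel(chain@ground)
  iE <- diagonalizeAndLabel(chain@intermediate)
  route <- .absorptionRoute(gE, iE)
  Eg <- gE@energies[route$gIdx[1]]
  w <- rowSums(abs(route$Ab)^2) / length(route$gIdx)
  sticks <- data.frame(
    energy = offsets@absorptionOrigin + iE@energies[route$keep] - Eg,
    weight = w)
  if (is.null(grid))
    grid <- .autoGrid(sticks$energy, pad = 2 + 2 * broadening@gammaIntermediate)
  s <- broadenSticks(sticks, grid, lorentzian = broadening@gammaIntermediate,
                     gaussian = 0)
  s@metadata <- c(s@metadata, list(process = "absorption_1s3d"))
  s
}

#' Pre-edge resonance energy of a chain
#'
#' Incident energy of the pre-edge 1s->3d resonance: the lowest-energy local
#' maximum of the absorption profile carrying at least 20% of the profile
#' maximum (higher-lying multiplet resonances are not the pre-edge); falls
#' back to the global maximum when no such feature is resolved.
#'
#' @inheritParams absorptionProfile
#' @return incident energy (eV)
#' @export
preedgeResonance <- function(chain, broadening = BroadeningSpec(),
                             offsets = NULL, grid = NULL) {
  p <- absorptionProfile(chain, broadening, offsets, grid)
  pk <- findSpectralPeaks(p, minProminence = 0.02)
  cand <- pk$maxima[pk$maxima$height >= 0.2 * max(p@intensity), ,
                    drop = FALSE]
  if (nrow(cand) > 0) cand$energy[1] else p@energy[which.max(p@intensity)]
}

#' Kramers-Heisenberg 1s3p RXES plane
#'
#' For each final state the coherent sum over intermediate states of
#' (emission amplitude x absorption amplitude) / (E_g + Omega' - E_n +
#' i Gamma_i/2) is squared and summed incoherently over the ground-state
#' degeneracy and the absorption/emission orbital components (isotropic
#' average), then multiplied by an energy-conservation Lorentzian of FWHM
#' Gamma_f in (Omega' - omega') - (E_f - E_g). The Gaussian instrumental
#' convolution is applied last, along the emission axis only. Primed
#' energies are measured from the calibration origins.
#'
#' @param chain a [ModelChain-class] from [rxesChain] (or a ground
#'   [ModelSpec-class])
#' @param broadening a [BroadeningSpec-class]
#' @param offsets a [CalibrationOffsets-class]; default: the chain's
#' @param incident,emission axis grids (eV); NULL derives 0.1 eV grids
#'   spanning the stick spectra (the conventional 7108-7118 / 7040-7075 eV
#'   windows under the calibrated presets)
#' @param coherent keep interference between intermediate states (default);
#'   FALSE sums intermediate-state pathways incoherently (diagnostic)
#' @return an [RXESPlane-class]
#' @export
rxesPlane <- function(chain, broadening = BroadeningSpec(), offsets = NULL,
                      incident = NULL, emission = NULL, coherent = TRUE) {
  if (is(chain, "ModelSpec")) chain <- rxesChain(chain)
  stopifnot(is(chain, "ModelChain"))
  cfgG <- chain@ground@configuration
  cfgI <- chain@intermediate@configuration
  cfgF <- chain@final@configuration
  if (cfgI@n1s != cfgG@n1s - 1L || cfgI@n3d != cfgG@n3d + 1L ||
      cfgF@n3p != cfgG@n3p - 1L || cfgF@n3d != cfgG@n3d + 1L ||
      cfgF@n1s != cfgG@n1s)
    stop("invalid configuration chain for 1s3p RXES")
  if (is.null(offsets)) offsets <- chain@offsets
  gE <- diagonalizeAndLabel(chain@ground)
  iE <- diagonalizeAndLabel(chain@intermediate)
  fE <- diagonalizeAndLabel(chain@final)
  route <- .absorptionRoute(gE, iE)
  Ab <- route$Ab                      # [nKept, nG, 5]
  Em <- transitionAmplitudes(iE, fE, "emit_3p1s")[, route$keep, , drop = FALSE]
  # prune finals never reached through the kept intermediates
  fStr <- apply(abs(Em), 1, max)
  fKeep <- which(fStr > 1e-12 * max(fStr))
  Em <- Em[fKeep, , , drop = FALSE]
  AbMat <- matrix(Ab, nrow = dim(Ab)[1])  # nKept x (nG*5)
  Eg <- gE@energies[route$gIdx[1]]
  En <- iE@energies[route$keep]
  dEf <- fE@energies[fKeep] - Eg
  Gi2 <- broadening@gammaIntermediate / 2
  Gf <- broadening@gammaFinal
  if (is.null(incident))
    incident <- .autoGrid(offsets@absorptionOrigin + En - Eg,
                          pad = 2 + 2 * broadening@gammaIntermediate)
  if (is.null(emission)) {
    emSticks <- offsets@emissionOrigin +
      range(outer(En, fE@energies[fKeep], "-"))
    emission <- .autoGrid(emSticks, pad = 3 + 2 * broadening@gammaFinal)
  }
  if (length(incident) < 1 || length(emission) < 2)
    stop("empty axis grids")
  omegaP <- emission - offsets@emissionOrigin
  step <- mean(diff(emission))
  plane <- matrix(0, length(incident), length(emission))
  A <- matrix(0, length(fKeep), length(incident))
  for (io in seq_along(incident)) {
    OmP <- incident[io] - offsets@absorptionOrigin
    den <- 1 / (Eg + OmP - En + 1i * Gi2)
    if (coherent) {
      W <- AbMat * den
      for (qe in seq_len(dim(Em)[3])) {
        amp <- Em[, , qe, drop = FALSE][, , 1, drop = FALSE]
        amp <- matrix(amp, nrow = length(fKeep)) %*% W
        A[, io] <- A[, io] + rowSums(abs(amp)^2)
      }
    } else {
      W2 <- abs(AbMat)^2 * abs(den)^2
      for (qe in seq_len(dim(Em)[3])) {
        E2 <- abs(matrix(Em[, , qe, drop = FALSE][, , 1, drop = FALSE],
                         nrow = length(fKeep)))^2
        A[, io] <- A[, io] + rowSums(E2 %*% W2)
      }
    }
    x <- OmP - rep(omegaP, each = length(fKeep)) - dEf
    dim(x) <- c(length(fKeep), length(omegaP))
    if (Gf > 0) {
      L <- .lorentz(x, Gf)
    } else {
      L <- matrix(0, length(fKeep), length(omegaP))
      j <- max.col(-abs(x))
      L[cbind(seq_along(j), j)] <- 1 / step
    }
    plane[io, ] <- colSums((A[, io] / length(route$gIdx)) * L)
  }
  for (io in seq_along(incident))
    plane[io, ] <- .gaussConvolve(plane[io, ], step,
                                  broadening@sigmaInstrumental)
  plane[plane < 0] <- 0
  new("RXESPlane", incident = incident, emission = emission,
      intensity = plane,
      metadata = list(chain = chain@name, coherent = coherent,
                      absorption_origin_eV = offsets@absorptionOrigin,
                      emission_origin_eV = offsets@emissionOrigin,
                      # final-state transition strengths per incident node
                      # (stick provenance for cuts, free of lifetime tails)
                      finalDeltaE = dEf,
                      finalStrengths = A / length(route$gIdx)))
}

#' Constant-incident-energy cut through an RXES plane
#'
#' Emission spectrum at fixed incident energy (nearest grid node).
#' @param plane an [RXESPlane-class]
#' @param incident incident energy (eV); must lie within the grid span
#' @return a [Spectrum1D-class]
#' @export
cieCut <- function(plane, incident) {
  stopifnot(is(plane, "RXESPlane"))
  if (incident < min(plane@incident) - 1e-9 ||
      incident > max(plane@incident) + 1e-9)
    stop("incident energy outside the plane grid")
  i <- which.min(abs(plane@incident - incident))
  md <- plane@metadata
  sticks <- data.frame(energy = numeric(), weight = numeric())
  if (!is.null(md$finalDeltaE)) {
    # energy-conservation stick positions at this incident energy
    en <- (plane@incident[i] - (md$absorption_origin_eV %||% 0)) -
      md$finalDeltaE + (md$emission_origin_eV %||% 0)
    sticks <- data.frame(energy = en, weight = md$finalStrengths[, i])
    sticks <- sticks[order(sticks$energy), ]
    rownames(sticks) <- NULL
    md$finalDeltaE <- NULL; md$finalStrengths <- NULL
  }
  Spectrum1D(plane@emission, plane@intensity[i, ], sticks = sticks,
             metadata = c(md, list(cut = "constant_incident",
                                   incident_eV = plane@incident[i])))
}

#' HERFD trace through an RXES plane
#'
#' Incident-energy profile at fixed emission energy (nearest grid node):
#' the Kbeta-detected absorption analogue.
#' @param plane an [RXESPlane-class]
#' @param emission emission energy (eV); must lie within the grid span
#' @return a [Spectrum1D-class] (incident-energy axis)
#' @export
herfdCut <- function(plane, emission) {
  stopifnot(is(plane, "RXESPlane"))
  if (emission < min(plane@emission) - 1e-9 ||
      emission > max(plane@emission) + 1e-9)
    stop("emission energy outside the plane grid")
  j <- which.min(abs(plane@emission - emission))
  md <- plane@metadata
  md$finalDeltaE <- NULL; md$finalStrengths <- NULL
  Spectrum1D(plane@incident, plane@intensity[, j],
             metadata = c(md, list(cut = "herfd",
                                   emission_eV = plane@emission[j])))
}

#' Emission cut of the resonant process at a chosen excitation regime
#'
#' \code{incident = "preedge"} computes the RXES plane and cuts it at the
#' pre-edge resonance maximum; a numeric incident energy cuts there.
#' \code{incident = "rising_edge"} models excitation into high-lying
#' continuum-like orbitals, which leaves the 3p-3d coupling of the Kbeta
#' mainline untouched: the returned spectrum is the non-resonant Kbeta XES
#' of the same parameter set (separate code path, identical shape by
#' construction).
#'
#' @param ground a ground [ModelSpec-class] or prebuilt chains via
#'   \code{chainRXES}/\code{chainXES}
#' @param incident "preedge", "rising_edge", or a numeric incident energy
#' @param broadening a [BroadeningSpec-class]
#' @param offsets a [CalibrationOffsets-class]
#' @param incidentGrid,emissionGrid axis grids (eV; NULL derives them)
#' @param chainRXES optional [ModelChain-class] for the resonant process
#' @param chainXES optional [ModelChain-class] for the non-resonant process
#' @return a [Spectrum1D-class]
#' @export
rxesEmissionCut <- function(ground, incident = "preedge",
                            broadening = BroadeningSpec(), offsets = NULL,
                            incidentGrid = NULL, emissionGrid = NULL,
                            chainRXES = NULL, chainXES = NULL) {
  if (identical(incident, "rising_edge")) {
    if (is.null(chainXES)) chainXES <- xesChain(ground)
    return(nonresonantKbetaXES(chainXES, broadening, offsets,
                               grid = emissionGrid))
  }
  if (is.null(chainRXES)) chainRXES <- rxesChain(ground)
  at <- if (identical(incident, "preedge"))
    preedgeResonance(chainRXES, broadening, offsets, grid = incidentGrid)
  else as.numeric(incident)
  # only the cut is needed: evaluate the plane at the single incident energy
  plane <- rxesPlane(chainRXES, broadening, offsets,
                     incident = at, emission = emissionGrid)
  cieCut(plane, at)
}
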
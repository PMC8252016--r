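#' @import methods
NULL

#' Shell configuration of the 1s/3p/3d model space
#'
#' Occupations of the three shells that take part in the Kbeta emission and
#' 1s3p resonant emission processes. A process is described by a chain of
#' configurations with fixed total electron count, e.g. for ferrous RXES
#' ground 1s^2 3p^6 3d^6, intermediate 1s^1 3p^6 3d^7, final 1s^2 3p^5 3d^7.
#'
#' @slot n1s,n3p,n3d integer occupations (capacities 2, 6, 10)
#' @export
setClass("Configuration",
  representation(n1s = "integer", n3p = "integer", n3d = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@n1s) != 1L || object@n1s < 0L || object@n1s > 2L)
      msg <- c(msg, "n1s must be a single integer in 0..2")
    if (length(object@n3p) != 1L || object@n3p < 0L || object@n3p > 6L)
      msg <- c(msg, "n3p must be a single integer in 0..6")
    if (length(object@n3d) != 1L || object@n3d < 0L || object@n3d > 10L)
      msg <- c(msg, "n3d must be a single integer in 0..10")
    if (length(msg)) msg else TRUE
  })

#' @param n1s,n3p,n3d shell occupations
#' @rdname Configuration-class
#' @export
Configuration <- function(n1s = 2L, n3p = 6L, n3d = 0L) {
  new("Configuration", n1s = as.integer(n1s), n3p = as.integer(n3p),
      n3d = as.integer(n3d))
}

setMethod("show", "Configuration", function(object) {
  cat(sprintf("Configuration: 1s^%d 3p^%d 3d^%d (%d determinants)\n",
              object@n1s, object@n3p, object@n3d, basisDimension(object)))
})

#' Slater-Condon radial integral set
#'
#' Radial Coulomb parameters (eV) for the 3d-3d and 3p-3d interactions.
#' \code{F0dd} is a pure monopole shift within a configuration; the direct
#' 1s-3d/1s-3p monopoles and the 1s exchange integrals are absorbed into the
#' configuration energy offset (the spectral structure is carried entirely by
#' the 3p-3d and 3d-3d multipole/exchange terms). \code{scaling} multiplies
#' the 3p-3d parameters (F2pd, G1pd, G3pd) -- the covalency knob -- while
#' \code{scalingDD} independently scales F2dd/F4dd. F0dd is never scaled.
#'
#' @slot F0dd,F2dd,F4dd d-d direct Slater integrals (eV)
#' @slot F2pd p-d direct Slater integral (eV)
#' @slot G1pd,G3pd p-d exchange Slater integrals (eV)
#' @slot scaling covalency reduction factor in (0, 1] applied to pd terms
#' @slot scalingDD reduction factor in (0, 1] applied to F2dd/F4dd
#' @export
setClass("SlaterCondonSet",
  representation(F0dd = "numeric", F2dd = "numeric", F4dd = "numeric",
                 F2pd = "numeric", G1pd = "numeric", G3pd = "numeric",
                 scaling = "numeric", scalingDD = "numeric"),
  validity = function(object) {
    vals <- c(object@F0dd, object@F2dd, object@F4dd, object@F2pd,
              object@G1pd, object@G3pd)
    msg <- character()
    if (any(!is.finite(vals)) || any(vals < 0))
      msg <- c(msg, "all radial integrals must be finite and >= 0")
    if (object@scaling <= 0 || object@scaling > 1)
      msg <- c(msg, "scaling must lie in (0, 1]")
    if (object@scalingDD <= 0 || object@scalingDD > 1)
      msg <- c(msg, "scalingDD must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' @param F0dd,F2dd,F4dd,F2pd,G1pd,G3pd radial integrals (eV)
#' @param scaling,scalingDD covalency reduction factors in (0, 1]
#' @rdname SlaterCondonSet-class
#' @export
SlaterCondonSet <- function(F0dd = 0, F2dd = 0, F4dd = 0, F2pd = 0,
                            G1pd = 0, G3pd = 0, scaling = 1, scalingDD = 1) {
  new("SlaterCondonSet", F0dd = F0dd, F2dd = F2dd, F4dd = F4dd, F2pd = F2pd,
      G1pd = G1pd, G3pd = G3pd, scaling = scaling, scalingDD = scalingDD)
}

setMethod("show", "SlaterCondonSet", function(object) {
  cat(sprintf(
    "SlaterCondonSet (eV): F0dd=%.3f F2dd=%.3f F4dd=%.3f | F2pd=%.3f G1pd=%.3f G3pd=%.3f\n",
    object@F0dd, object@F2dd, object@F4dd, object@F2pd, object@G1pd,
    object@G3pd))
  cat(sprintf("  pd scaling %.0f%%, dd scaling %.0f%%\n",
              100 * object@scaling, 100 * object@scalingDD))
})

#' Spin-orbit coupling constants
#'
#' One-electron zeta l.s couplings for the open 3p and 3d shells (eV).
#'
#' @slot zeta3p,zeta3d coupling constants (eV, >= 0)
#' @export
setClass("SpinOrbitSet",
  representation(zeta3p = "numeric", zeta3d = "numeric"),
  validity = function(object) {
    if (object@zeta3p < 0 || object@zeta3d < 0)
      "zeta3p and zeta3d must be >= 0" else TRUE
  })

#' @param zeta3p,zeta3d coupling constants (eV)
#' @rdname SpinOrbitSet-class
#' @export
SpinOrbitSet <- function(zeta3p = 0, zeta3d = 0) {
  new("SpinOrbitSet", zeta3p = zeta3p, zeta3d = zeta3d)
}

#' Cubic ligand-field specification
#'
#' One-parameter e/t2 splitting of the 3d shell with barycenter preserved.
#' Tetrahedral coordination places e below t2 (e at -0.6 Dq10, t2 at
#' +0.4 Dq10); octahedral is the inverse. "spherical" ignores the splitting.
#'
#' @slot symmetry one of "spherical", "Td", "Oh"
#' @slot tenDq magnitude of the e/t2 splitting (eV)
#' @export
setClass("LigandFieldSpec",
  representation(symmetry = "character", tenDq = "numeric"),
  validity = function(object) {
    if (!object@symmetry %in% c("spherical", "Td", "Oh"))
      return("symmetry must be one of 'spherical', 'Td', 'Oh'")
    if (!is.finite(object@tenDq)) return("tenDq must be finite")
    TRUE
  })

#' @param symmetry "spherical", "Td" or "Oh"
#' @param tenDq splitting magnitude (eV)
#' @rdname LigandFieldSpec-class
#' @export
LigandFieldSpec <- function(symmetry = "spherical", tenDq = 0) {
  new("LigandFieldSpec", symmetry = symmetry, tenDq = tenDq)
}

#' Full model specification for one electronic configuration
#'
#' Everything needed to assemble and diagonalize one Hamiltonian: the shell
#' configuration, Coulomb (Slater-Condon) parameters, spin-orbit constants,
#' ligand field, and a scalar configuration energy offset that absorbs the
#' core-level monopole energies a semi-empirical model cannot produce.
#'
#' @slot configuration a [Configuration-class]
#' @slot slaterCondon a [SlaterCondonSet-class]
#' @slot spinOrbit a [SpinOrbitSet-class]
#' @slot ligandField a [LigandFieldSpec-class]
#' @slot energyOffset scalar diagonal shift (eV)
#' @export
setClass("ModelSpec",
  representation(configuration = "Configuration",
                 slaterCondon = "SlaterCondonSet",
                 spinOrbit = "SpinOrbitSet",
                 ligandField = "LigandFieldSpec",
                 energyOffset = "numeric"),
  validity = function(object) {
    if (length(object@energyOffset) != 1L || !is.finite(object@energyOffset))
      "energyOffset must be a finite scalar" else TRUE
  })

#' @param configuration,slaterCondon,spinOrbit,ligandField,energyOffset see slots
#' @rdname ModelSpec-class
#' @export
ModelSpec <- function(configuration,
                      slaterCondon = SlaterCondonSet(),
                      spinOrbit = SpinOrbitSet(),
                      ligandField = LigandFieldSpec(),
                      energyOffset = 0) {
  new("ModelSpec", configuration = configuration, slaterCondon = slaterCondon,
      spinOrbit = spinOrbit, ligandField = ligandField,
      energyOffset = energyOffset)
}

setMethod("show", "ModelSpec", function(object) {
  show(object@configuration)
  show(object@slaterCondon)
  cat(sprintf("  zeta3p=%.3f zeta3d=%.3f eV; ligand field %s, 10Dq=%.3f eV; offset %.3f eV\n",
              object@spinOrbit@zeta3p, object@spinOrbit@zeta3d,
              object@ligandField@symmetry, object@ligandField@tenDq,
              object@energyOffset))
})

#' Determinant basis of a configuration
#'
#' All Slater determinants of a shell configuration over the 18 spin-orbitals
#' (1s x2, 3p x6, 3d x10), each encoded as an 18-bit occupation mask.
#' Spin-orbital index (0-based bit) is 2*(orbital-1) + spin with orbitals
#' ordered s, p(-1..1), d(-2..2) and spin 0 = alpha, 1 = beta. The order is
#' canonical (ascending mask value) and stable across runs.
#'
#' @slot configuration the generating [Configuration-class]
#' @slot masks integer vector of occupation bit masks
#' @export
setClass("DeterminantBasis",
  representation(configuration = "Configuration", masks = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@masks)) return("determinant masks must be unique")
    if (length(object@masks) != basisDimension(object@configuration))
      return("mask count does not match the configuration dimension")
    TRUE
  })

setMethod("show", "DeterminantBasis", function(object) {
  cat(sprintf("DeterminantBasis: 1s^%d 3p^%d 3d^%d, dimension %d\n",
              object@configuration@n1s, object@configuration@n3p,
              object@configuration@n3d, length(object@masks)))
})

#' Labeled eigen-decomposition of one configuration
#'
#' Dense spectrum of one multiplet Hamiltonian with eigenvalues clustered
#' into degeneracy groups. In the spherical, zero-spin-orbit limit each group
#' is labeled with total spin/orbital quantum numbers from <S^2>/<L^2>
#' expectation values and matched to a Russell-Saunders term symbol;
#' otherwise the term label is "mixed".
#'
#' @slot spec the generating [ModelSpec-class]
#' @slot basis the [DeterminantBasis-class]
#' @slot energies eigenvalues (eV), ascending
#' @slot states complex eigenvector matrix (columns)
#' @slot groups data.frame: first, last (state index range), energy,
#'   degeneracy, S, L, term
#' @export
setClass("LabeledEigenset",
  representation(spec = "ModelSpec", basis = "DeterminantBasis",
                 energies = "numeric", states = "matrix",
                 groups = "data.frame"),
  validity = function(object) {
    if (is.unsorted(object@energies, strictly = FALSE))
      return("energies must be ascending")
    if (ncol(object@states) != length(object@energies))
      return("states/energies dimension mismatch")
    if (sum(object@groups$degeneracy) != length(object@energies))
      return("group degeneracies must sum to the basis dimension")
    TRUE
  })

setMethod("show", "LabeledEigenset", function(object) {
  cat(sprintf("LabeledEigenset: %d states in %d degeneracy groups\n",
              length(object@energies), nrow(object@groups)))
  print(utils::head(object@groups, 8))
  if (nrow(object@groups) > 8) cat("  ...\n")
})

#' Line-shape widths for rendering spectra
#'
#' Lorentzian core-hole lifetime widths and the Gaussian instrumental width,
#' all as FWHM in eV. \code{gammaIntermediate} is the 1s core-hole width
#' entering the Kramers-Heisenberg denominator, \code{gammaFinal} the 3p
#' core-hole width of the final state.
#'
#' @slot gammaIntermediate,gammaFinal Lorentzian FWHM (eV)
#' @slot sigmaInstrumental Gaussian FWHM (eV)
#' @export
setClass("BroadeningSpec",
  representation(gammaIntermediate = "numeric", gammaFinal = "numeric",
                 sigmaInstrumental = "numeric"),
  validity = function(object) {
    if (object@gammaIntermediate < 0 || object@gammaFinal < 0 ||
        object@sigmaInstrumental < 0)
      "all widths must be >= 0" else TRUE
  })

#' @param gammaIntermediate,gammaFinal Lorentzian FWHM (eV); defaults are
#'   the tabulated Fe K (1s) and M2,3 (3p) core-hole lifetime widths
#' @param sigmaInstrumental Gaussian FWHM (eV)
#' @rdname BroadeningSpec-class
#' @export
BroadeningSpec <- function(gammaIntermediate = 1.25, gammaFinal = 1.6,
                           sigmaInstrumental = 0.7) {
  new("BroadeningSpec", gammaIntermediate = gammaIntermediate,
      gammaFinal = gammaFinal, sigmaInstrumental = sigmaInstrumental)
}

#' Energy-axis calibration offsets
#'
#' Rigid shifts placing the model's relative energies on the experimental
#' scale: \code{absorptionOrigin} is added to incident (absorption) energies,
#' \code{emissionOrigin} to emission energies. They affect axis placement
#' only; every splitting and intensity ratio is independent of them.
#'
#' @slot absorptionOrigin,emissionOrigin origins (eV)
#' @export
setClass("CalibrationOffsets",
  representation(absorptionOrigin = "numeric", emissionOrigin = "numeric"))

#' @param absorptionOrigin,emissionOrigin origins (eV)
#' @rdname CalibrationOffsets-class
#' @export
CalibrationOffsets <- function(absorptionOrigin = 0, emissionOrigin = 0) {
  new("CalibrationOffsets", absorptionOrigin = absorptionOrigin,
      emissionOrigin = emissionOrigin)
}

#' One-dimensional spectrum
#'
#' Broadened intensity versus energy with the underlying stick spectrum kept
#' as provenance. The energy grid is strictly increasing and uniform;
#' intensity is nonnegative.
#'
#' @slot energy energy grid (eV)
#' @slot intensity intensity (arbitrary units)
#' @slot sticks data.frame with columns energy, weight
#' @slot metadata free-form list (axis kind, normalization, seed, ...)
#' @export
setClass("Spectrum1D",
  representation(energy = "numeric", intensity = "numeric",
                 sticks = "data.frame", metadata = "list"),
  validity = function(object) {
    if (length(object@energy) != length(object@intensity))
      return("energy/intensity length mismatch")
    if (length(object@energy) > 1 && any(diff(object@energy) <= 0))
      return("energy grid must be strictly increasing")
    if (any(!is.finite(object@intensity)))
      return("intensity must be finite")
    TRUE
  })

#' @param energy,intensity,sticks,metadata see slots
#' @rdname Spectrum1D-class
#' @export
Spectrum1D <- function(energy, intensity,
                       sticks = data.frame(energy = numeric(),
                                           weight = numeric()),
                       metadata = list()) {
  new("Spectrum1D", energy = as.numeric(energy),
      intensity = as.numeric(intensity), sticks = sticks, metadata = metadata)
}

setMethod("show", "Spectrum1D", function(object) {
  cat(sprintf("Spectrum1D: %d points, %.2f..%.2f eV, max intensity %.4g\n",
              length(object@energy), min(object@energy), max(object@energy),
              if (length(object@intensity)) max(object@intensity) else NA))
})

#' Resonant X-ray emission plane
#'
#' Intensity over the (incident energy, emission energy) grid from the
#' Kramers-Heisenberg double sum.
#'
#' @slot incident incident-energy grid (eV)
#' @slot emission emission-energy grid (eV)
#' @slot intensity matrix, rows = incident, cols = emission, >= 0
#' @slot metadata free-form list
#' @export
setClass("RXESPlane",
  representation(incident = "numeric", emission = "numeric",
                 intensity = "matrix", metadata = "list"),
  validity = function(object) {
    if (nrow(object@intensity) != length(object@incident) ||
        ncol(object@intensity) != length(object@emission))
      return("intensity dimensions must match the axis grids")
    if (any(object@intensity < -1e-12))
      return("intensity must be nonnegative")
    TRUE
  })

setMethod("show", "RXESPlane", function(object) {
  cat(sprintf("RXESPlane: %d x %d (incident %.1f..%.1f, emission %.1f..%.1f eV)\n",
              length(object@incident), length(object@emission),
              min(object@incident), max(object@incident),
              min(object@emission), max(object@emission)))
})

#' Three-configuration model chain for one scattering process
#'
#' Ground, core-excited intermediate, and final [ModelSpec-class] of one
#' process (electron count conserved for resonant chains, reduced by the
#' ionized electron for non-resonant chains), plus the calibration offsets
#' used to place the simulated axes on the experimental eV scale.
#'
#' @slot name identifier
#' @slot ground,intermediate,final the three [ModelSpec-class] objects
#' @slot offsets a [CalibrationOffsets-class]
#' @export
setClass("ModelChain",
  representation(name = "character", ground = "ModelSpec",
                 intermediate = "ModelSpec", final = "ModelSpec",
                 offsets = "CalibrationOffsets"),
  validity = function(object) {
    tot <- function(s) s@configuration@n1s + s@configuration@n3p +
      s@configuration@n3d
    # resonant chains conserve the electron count; ionized (non-resonant)
    # chains lose one electron to the continuum between ground and
    # intermediate and keep the count thereafter
    if (tot(object@intermediate) != tot(object@final))
      return("intermediate and final configurations must share the electron count")
    if (!tot(object@ground) %in% (tot(object@intermediate) + c(0L, 1L)))
      return("ground configuration inconsistent with the process chain")
    TRUE
  })

#' @param name,ground,intermediate,final,offsets see slots
#' @rdname ModelChain-class
#' @export
ModelChain <- function(name, ground, intermediate, final,
                       offsets = CalibrationOffsets()) {
  new("ModelChain", name = name, ground = ground, intermediate = intermediate,
      final = final, offsets = offsets)
}

setMethod("show", "ModelChain", function(object) {
  cfg <- function(s) sprintf("1s^%d3p^%d3d^%d", s@configuration@n1s,
                             s@configuration@n3p, s@configuration@n3d)
  cat(sprintf("ModelChain '%s': %s -> %s -> %s\n", object@name,
              cfg(object@ground), cfg(object@intermediate),
              cfg(object@final)))
})

#' Single-site parameter preset
#'
#' A named iron site (ferrous/ferric chloride- or sulfide-like) carrying the
#' Slater-Condon set, spin-orbit constants, ligand field and covalency
#' scaling needed to build both the non-resonant (XES) and resonant (RXES)
#' model chains. Parameter values are standard atomic Hartree-Fock
#' magnitudes for Fe, recorded in \code{metadata} as assumptions.
#'
#' @slot name preset identifier
#' @slot dCount ground-state 3d count (5 ferric, 6 ferrous)
#' @slot slaterCondon a [SlaterCondonSet-class] (scaling included)
#' @slot spinOrbit a [SpinOrbitSet-class]
#' @slot ligandField a [LigandFieldSpec-class]
#' @slot offsets a [CalibrationOffsets-class]
#' @slot metadata provenance notes
#' @export
setClass("SitePreset",
  representation(name = "character", dCount = "integer",
                 slaterCondon = "SlaterCondonSet", spinOrbit = "SpinOrbitSet",
                 ligandField = "LigandFieldSpec",
                 offsets = "CalibrationOffsets", metadata = "list"))

setMethod("show", "SitePreset", function(object) {
  cat(sprintf("SitePreset '%s': d^%d, pd scaling %.0f%%, %s 10Dq=%.2f eV\n",
              object@name, object@dCount, 100 * object@slaterCondon@scaling,
              object@ligandField@symmetry, object@ligandField@tenDq))
})

#' Weighted multi-site mixture
#'
#' Incoherent weighted superposition of single-site presets standing in for
#' mixed-valent dimers, cubanes and MoFe-protein-like ferrous/ferric
#' mixtures. Weights are normalized to sum to 1.
#'
#' @slot components list of [SitePreset-class]
#' @slot weights normalized nonnegative weights
#' @export
setClass("MixtureSpec",
  representation(components = "list", weights = "numeric"),
  validity = function(object) {
    if (length(object@components) < 1L) return("mixture needs >= 1 component")
    if (length(object@weights) != length(object@components))
      return("weights/components length mismatch")
    if (any(object@weights < 0)) return("weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-9)
      return("weights must sum to 1")
    TRUE
  })

#' @param components list of [SitePreset-class]
#' @param weights nonnegative weights (normalized internally)
#' @rdname MixtureSpec-class
#' @export
MixtureSpec <- function(components, weights) {
  if (sum(weights) <= 0) stop("mixture weights must have positive sum")
  new("MixtureSpec", components = components,
      weights = weights / sum(weights))
}

#' Counting-noise specification for pseudo-measurements
#'
#' @slot model "poisson_counts" (scale = peak counts) or "gaussian"
#'   (scale = additive sigma relative to peak height)
#' @slot scale positive noise scale
#' @slot seed integer RNG seed (bit-for-bit reproducible)
#' @slot calibrationShift rigid energy shift (eV)
#' @export
setClass("NoiseSpec",
  representation(model = "character", scale = "numeric", seed = "integer",
                 calibrationShift = "numeric"),
  validity = function(object) {
    if (!object@model %in% c("poisson_counts", "gaussian"))
      return("model must be 'poisson_counts' or 'gaussian'")
    if (object@scale <= 0) return("scale must be > 0")
    TRUE
  })

#' @param model,scale,seed,calibrationShift see slots
#' @rdname NoiseSpec-class
#' @export
NoiseSpec <- function(model = "poisson_counts", scale = 1e4,
                      seed = 20210323L, calibrationShift = 0) {
  new("NoiseSpec", model = model, scale = scale, seed = as.integer(seed),
      calibrationShift = calibrationShift)
}
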
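## Parameter presets for the studied iron sites, axis calibration, weighted
## multi-site mixtures, and seeded pseudo-measurement generation.

# Preset numbers are standard atomic Hartree-Fock magnitudes for Fe ions
# (Slater-Condon integrals, spin-orbit constants) combined with a
# one-parameter tetrahedral ligand field and a covalency scaling of the
# 3p-3d parameters: 60%/45% for the ferrous/ferric chlorides, and a
# stronger 50%/40% reduction standing in for the more covalent sulfide
# sites. They are assumptions recorded as such, not fitted values.
.presetTable <- list(
  ferrous_td_chloride = list(
    dCount = 6L, F2dd = 10.966, F4dd = 6.815, F2pd = 11.0, G1pd = 13.6,
    G3pd = 8.3, zeta3p = 0.9, zeta3d = 0.052, tenDq = 0.65, scaling = 0.60,
    preedge_eV = 7112.0, kbeta_rxes_eV = 7059.3, kbeta_xes_eV = 7060.2),
  ferric_td_chloride = list(
    dCount = 5L, F2dd = 12.043, F4dd = 7.535, F2pd = 12.4, G1pd = 15.2,
    G3pd = 9.2, zeta3p = 1.0, zeta3d = 0.059, tenDq = 0.75, scaling = 0.45,
    preedge_eV = 7113.2, kbeta_rxes_eV = 7060.6, kbeta_xes_eV = 7059.8),
  ferrous_sulfide_site = list(
    dCount = 6L, F2dd = 10.966, F4dd = 6.815, F2pd = 11.0, G1pd = 13.6,
    G3pd = 8.3, zeta3p = 0.9, zeta3d = 0.052, tenDq = 0.60, scaling = 0.50,
    preedge_eV = 7111.8, kbeta_rxes_eV = 7058.8, kbeta_xes_eV = 7060.0),
  ferric_sulfide_site = list(
    dCount = 5L, F2dd = 12.043, F4dd = 7.535, F2pd = 12.4, G1pd = 15.2,
    G3pd = 9.2, zeta3p = 1.0, zeta3d = 0.059, tenDq = 0.70, scaling = 0.40,
    preedge_eV = 7113.0, kbeta_rxes_eV = 7060.4, kbeta_xes_eV = 7059.6))

#' Named single-site parameter presets
#'
#' Fully populated ferrous/ferric site models: chloride-like sites carry the
#' 60% (ferrous) and 45% (ferric) 3p-3d Slater-Condon reductions, sulfide
#' sites a stronger 50%/40% reduction as a covalency stand-in. All radial
#' integrals are standard atomic Hartree-Fock magnitudes for Fe, recorded in
#' the preset metadata as assumptions.
#'
#' @param name one of "ferrous_td_chloride", "ferric_td_chloride",
#'   "ferrous_sulfide_site", "ferric_sulfide_site"
#' @return a [SitePreset-class]
#' @examples
#' presetParameters("ferrous_td_chloride")
#' @export
presetParameters <- function(name) {
  p <- .presetTable[[name]]
  if (is.null(p))
    stop("unknown preset name: ", name, " (known: ",
         paste(names(.presetTable), collapse = ", "), ")")
  new("SitePreset", name = name, dCount = p$dCount,
      slaterCondon = SlaterCondonSet(
        F0dd = 0, F2dd = p$F2dd, F4dd = p$F4dd, F2pd = p$F2pd,
        G1pd = p$G1pd, G3pd = p$G3pd, scaling = p$scaling),
      spinOrbit = SpinOrbitSet(p$zeta3p, p$zeta3d),
      ligandField = LigandFieldSpec("Td", p$tenDq),
      offsets = CalibrationOffsets(),
      metadata = list(
        provenance = "standard atomic Hartree-Fock magnitudes for Fe; assumption, not fitted data",
        preedge_eV = p$preedge_eV, kbeta_rxes_eV = p$kbeta_rxes_eV,
        kbeta_xes_eV = p$kbeta_xes_eV))
}

#' All known preset names
#' @return character vector
#' @export
presetNames <- function() names(.presetTable)

# ground ModelSpec of a preset
.presetGround <- function(preset) {
  ModelSpec(Configuration(2L, 6L, preset@dCount), preset@slaterCondon,
            preset@spinOrbit, preset@ligandField)
}

# calibrated chain: calibration offsets are computed from the diagonalized
# chain so the strongest feature lands at the preset's target energies
.calibrateChain <- function(chain, targetPreedge, targetKbeta) {
  gE <- diagonalizeAndLabel(chain@ground)
  iE <- diagonalizeAndLabel(chain@intermediate)
  fE <- diagonalizeAndLabel(chain@final)
  gIdx <- .groundGroup(gE)
  Eg <- gE@energies[gIdx[1]]
  resonant <- chain@intermediate@configuration@n3d >
    chain@ground@configuration@n3d
  if (resonant) {
    route <- .absorptionRoute(gE, iE)
    str <- rowSums(abs(route$Ab)^2)
    nRes <- route$keep[which.max(str)]
    absOrigin <- targetPreedge - (iE@energies[nRes] - Eg)
    Em <- transitionAmplitudes(iE, fE, "emit_3p1s")
    wf <- numeric(dim(Em)[1])
    for (q in seq_len(dim(Em)[3])) wf <- wf + abs(Em[, nRes, q])^2
    # weight by how strongly each intermediate near the resonance is pumped
    fStar <- which.max(wf)
    emOrigin <- targetKbeta - (iE@energies[nRes] - fE@energies[fStar])
  } else {
    w <- .ionizationWeights(gE, iE)
    Em <- transitionAmplitudes(iE, fE, "emit_3p1s")
    inten <- matrix(0, dim(Em)[1], dim(Em)[2])
    for (q in seq_len(dim(Em)[3])) inten <- inten + abs(Em[, , q])^2
    inten <- sweep(inten, 2, w, "*")
    ij <- arrayInd(which.max(inten), dim(inten))
    absOrigin <- 0
    emOrigin <- targetKbeta - (iE@energies[ij[2]] - fE@energies[ij[1]])
  }
  chain@offsets <- CalibrationOffsets(absOrigin, emOrigin)
  chain
}

#' Calibrated model chain of a preset
#'
#' Builds the resonant (RXES) or non-resonant (XES) configuration chain of
#' a site preset, with calibration offsets computed so the strongest
#' simulated feature lands at the preset's target energies (pre-edge and
#' Kbeta_1,3). Offsets shift axes rigidly and carry no physics.
#'
#' @param preset a [SitePreset-class] (or preset name)
#' @param process "rxes" or "xes"
#' @return a calibrated [ModelChain-class]
#' @export
presetChain <- function(preset, process = c("rxes", "xes")) {
  process <- match.arg(process)
  if (is.character(preset)) preset <- presetParameters(preset)
  key <- paste0("chain|", preset@name, "|", process)
  .cacheGet(key, function() {
    ground <- .presetGround(preset)
    if (process == "rxes") {
      .calibrateChain(rxesChain(ground, paste0(preset@name, ":rxes")),
                      preset@metadata$preedge_eV,
                      preset@metadata$kbeta_rxes_eV)
    } else {
      .calibrateChain(xesChain(ground, paste0(preset@name, ":xes")),
                      preset@metadata$preedge_eV,
                      preset@metadata$kbeta_xes_eV)
    }
  })
}

#' Spectrum of a weighted multi-site mixture
#'
#' Incoherent weighted sum of per-site spectra, standing in for mixed-valent
#' dimers, cubanes, and MoFe-protein-like ferrous/ferric mixtures.
#' Inter-site coupling is deliberately ignored. In
#' \code{mode = "rxes_preedge_cut"} every site is cut at the same incident
#' energy, the pre-edge resonance of the first ferrous (d^6) component (the
#' measurement protocol for mixed-valence samples); per-site spectra are
#' normalized (\code{normalize}, default unit area) before weighting, so the
#' mixture operator is linear in the normalized component spectra.
#'
#' @param mix a [MixtureSpec-class]
#' @param mode "xes" or "rxes_preedge_cut"
#' @param broadening a [BroadeningSpec-class]
#' @param incidentGrid,emissionGrid axis grids (eV)
#' @param normalize per-site normalization: "area", "max" or "none"
#' @param incidentEnergy optional fixed incident energy (eV) overriding the
#'   ferrous-resonance protocol (e.g. to cut a pure ferric reference at the
#'   same energy as a mixture it is subtracted from)
#' @return a [Spectrum1D-class]
#' @export
mixtureSpectrum <- function(mix, mode = c("rxes_preedge_cut", "xes"),
                            broadening = BroadeningSpec(),
                            incidentGrid = NULL,
                            emissionGrid = seq(7040, 7075, by = 0.1),
                            normalize = c("area", "max", "none"),
                            incidentEnergy = NULL) {
  mode <- match.arg(mode)
  if (is.null(emissionGrid)) emissionGrid <- seq(7040, 7075, by = 0.1)
  normalize <- match.arg(normalize)
  stopifnot(is(mix, "MixtureSpec"))
  components <- mix@components
  sites <- lapply(components, function(p)
    if (is.character(p)) presetParameters(p) else p)
  y <- NULL
  if (mode == "rxes_preedge_cut") {
    if (!is.null(incidentEnergy)) {
      cutAt <- as.numeric(incidentEnergy)
    } else {
      ferrous <- which(vapply(sites, function(p) p@dCount == 6L, logical(1)))
      refSite <- if (length(ferrous)) ferrous[1] else 1L
      refChain <- presetChain(sites[[refSite]], "rxes")
      cutAt <- preedgeResonance(refChain, broadening, grid = incidentGrid)
    }
  }
  for (i in seq_along(sites)) {
    if (mode == "xes") {
      s <- nonresonantKbetaXES(presetChain(sites[[i]], "xes"), broadening,
                               grid = emissionGrid)
    } else {
      plane <- rxesPlane(presetChain(sites[[i]], "rxes"), broadening,
                         incident = cutAt, emission = emissionGrid)
      s <- cieCut(plane, cutAt)
    }
    if (normalize != "none") s <- normalizeSpectrum(s, normalize)
    y <- if (is.null(y)) mix@weights[i] * s@intensity
    else y + mix@weights[i] * s@intensity
  }
  Spectrum1D(emissionGrid, y,
             metadata = list(
               id = paste0("mixture(",
                           paste(sprintf("%s:%.3f",
                                         vapply(sites, function(p) p@name,
                                                character(1)),
                                         mix@weights), collapse = "+"), ")"),
               mode = mode, normalize = normalize,
               incident_eV = if (mode == "rxes_preedge_cut") cutAt else NA))
}

#' Generate a noisy pseudo-measurement from a model spectrum
#'
#' Applies a rigid calibration shift and seeded counting noise. The Poisson
#' model scales the spectrum so its maximum equals \code{scale} counts,
#' draws counts per grid point, and rescales back; the Gaussian model adds
#' white noise of standard deviation \code{scale} times the peak height.
#' Output is bit-for-bit reproducible for a given seed.
#'
#' @param s a [Spectrum1D-class]
#' @param noise a [NoiseSpec-class]
#' @return a [Spectrum1D-class]
#' @export
synthesizeMeasurement <- function(s, noise = NoiseSpec()) {
  stopifnot(is(s, "Spectrum1D"), is(noise, "NoiseSpec"))
  validObject(noise)
  peak <- max(s@intensity)
  if (peak <= 0) stop("cannot add counting noise to an all-zero spectrum")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise@seed)
  y <- if (noise@model == "poisson_counts") {
    stats::rpois(length(s@intensity), s@intensity / peak * noise@scale) *
      peak / noise@scale
  } else {
    s@intensity + stats::rnorm(length(s@intensity), 0, noise@scale * peak)
  }
  Spectrum1D(s@energy + noise@calibrationShift, pmax(y, 0),
             sticks = s@sticks,
             metadata = c(s@metadata,
                          list(noise_model = noise@model,
                               noise_scale = noise@scale,
                               seed = noise@seed,
                               calibration_shift_eV = noise@calibrationShift)))
}
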
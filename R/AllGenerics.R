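#' Number of Slater determinants of a configuration
#'
#' @param x a [Configuration-class] or [DeterminantBasis-class]
#' @return integer dimension, the product of binomial coefficients
#'   C(2, n1s) C(6, n3p) C(10, n3d)
#' @export
setGeneric("basisDimension", function(x) standardGeneric("basisDimension"))

#' @rdname basisDimension
setMethod("basisDimension", "Configuration", function(x) {
  as.integer(choose(2, x@n1s) * choose(6, x@n3p) * choose(10, x@n3d))
})

#' @rdname basisDimension
setMethod("basisDimension", "DeterminantBasis", function(x) {
  length(x@masks)
})

#' Energy grid accessor
#' @param x a [Spectrum1D-class]
#' @export
setGeneric("energyGrid", function(x) standardGeneric("energyGrid"))

#' @rdname energyGrid
setMethod("energyGrid", "Spectrum1D", function(x) x@energy)

#' Intensity accessor
#' @param x a [Spectrum1D-class] or [RXESPlane-class]
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname intensityValues
setMethod("intensityValues", "Spectrum1D", function(x) x@intensity)

#' @rdname intensityValues
setMethod("intensityValues", "RXESPlane", function(x) x@intensity)

#' Stick-spectrum provenance accessor
#' @param x a [Spectrum1D-class]
#' @export
setGeneric("spectrumSticks", function(x) standardGeneric("spectrumSticks"))

#' @rdname spectrumSticks
setMethod("spectrumSticks", "Spectrum1D", function(x) x@sticks)

#' Eigenvalue accessor
#' @param x a [LabeledEigenset-class]
#' @export
setGeneric("eigenEnergies", function(x) standardGeneric("eigenEnergies"))

#' @rdname eigenEnergies
setMethod("eigenEnergies", "LabeledEigenset", function(x) x@energies)

#' Degeneracy-group table accessor
#'
#' @param x a [LabeledEigenset-class]
#' @return data.frame with columns first, last, energy, degeneracy, S, L, term
#' @export
setGeneric("eigenGroups", function(x) standardGeneric("eigenGroups"))

#' @rdname eigenGroups
setMethod("eigenGroups", "LabeledEigenset", function(x) x@groups)

#' Plot a 1D spectrum
#'
#' @param x a [Spectrum1D-class]
#' @param y ignored
#' @param ... passed to [graphics::plot]
#' @export
setMethod("plot", signature("Spectrum1D", "missing"), function(x, y, ...) {
  graphics::plot(x@energy, x@intensity, type = "l",
                 xlab = "Energy (eV)", ylab = "Intensity (arb. units)", ...)
})

#' Plot an RXES plane as a filled image
#'
#' @param x an [RXESPlane-class]
#' @param y ignored
#' @param ... passed to [graphics::image]
#' @export
setMethod("plot", signature("RXESPlane", "missing"), function(x, y, ...) {
  graphics::image(x@incident, x@emission, x@intensity,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "Incident energy (eV)",
                  ylab = "Emission energy (eV)", ...)
})
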
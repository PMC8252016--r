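## Determinant basis construction and spin-orbital bookkeeping.

# 0-based bit index of spin-orbital (orbital 1..9, spin 0 = alpha, 1 = beta)
.soBit <- function(orbital, spin) 2L * (orbital - 1L) + spin

# bit positions of each shell's spin-orbitals
.shellBits <- list(s = 0:1, p = 2:7, d = 8:17)

# spatial orbital (1..9) and spin (0/1) of each bit 0..17
.bitOrbital <- rep(1:9, each = 2L)
.bitSpin <- rep(c(0L, 1L), 9L)
# per-bit quantum numbers
.bitM <- .rxesimOrbitals$m[.bitOrbital]
.bitL <- .rxesimOrbitals$l[.bitOrbital]
.bitMs2 <- ifelse(.bitSpin == 0L, 1L, -1L)  # twice m_s

# all n-subsets of the given bit positions, as masks (ascending)
.shellMasks <- function(bits, n) {
  if (n == 0L) return(0L)
  combos <- utils::combn(bits, n)
  if (is.null(dim(combos))) combos <- matrix(combos, nrow = n)
  sort(as.integer(colSums(matrix(2^combos, nrow = n))))
}

#' Build the determinant basis of a configuration
#'
#' Enumerates every Slater determinant of the configuration in a canonical,
#' run-stable order (ascending occupation-mask value).
#'
#' @param configuration a [Configuration-class]
#' @return a [DeterminantBasis-class]
#' @examples
#' basisDimension(buildBasis(Configuration(2, 6, 6)))  # 210
#' @export
buildBasis <- function(configuration) {
  stopifnot(is(configuration, "Configuration"))
  validObject(configuration)
  ms <- .shellMasks(.shellBits$s, configuration@n1s)
  mp <- .shellMasks(.shellBits$p, configuration@n3p)
  md <- .shellMasks(.shellBits$d, configuration@n3d)
  masks <- as.integer(sort(outer(outer(ms, mp, "+"), md, "+")))
  new("DeterminantBasis", configuration = configuration, masks = masks)
}

# diagonal of a per-bit quantity summed over occupied spin-orbitals
.maskSums <- function(masks, perBit) {
  vapply(masks, function(m) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, 0:17)) != 0L)
    sum(perBit[bits])
  }, numeric(1))
}

# package-level cache (bases, eigensets, amplitude matrices)
.rxesimCache <- new.env(parent = emptyenv())

.cacheGet <- function(key, build) {
  if (!exists(key, envir = .rxesimCache, inherits = FALSE))
    assign(key, build(), envir = .rxesimCache)
  get(key, envir = .rxesimCache, inherits = FALSE)
}

#' Empty the in-session result cache
#'
#' Diagonalizations and amplitude matrices are memoized per session; this
#' drops them (mainly useful to bound memory in long scans).
#' @return invisible NULL
#' @export
clearRxesimCache <- function() {
  rm(list = ls(envir = .rxesimCache), envir = .rxesimCache)
  invisible(NULL)
}

.configKey <- function(cfg) sprintf("%d.%d.%d", cfg@n1s, cfg@n3p, cfg@n3d)

.specKey <- function(spec) {
  sc <- spec@slaterCondon
  paste(.configKey(spec@configuration),
        paste(format(c(sc@F0dd, sc@F2dd, sc@F4dd, sc@F2pd, sc@G1pd, sc@G3pd,
                       sc@scaling, sc@scalingDD, spec@spinOrbit@zeta3p,
                       spec@spinOrbit@zeta3d, spec@ligandField@tenDq,
                       spec@energyOffset), digits = 17), collapse = ","),
        spec@ligandField@symmetry, sep = "|")
}

.cachedBasis <- function(configuration) {
  .cacheGet(paste0("basis|", .configKey(configuration)),
            function() buildBasis(configuration))
}
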
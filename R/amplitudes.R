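## Spin-conserving one-electron transition amplitudes between eigen-solutions
## of two configurations (1s->3d absorption, 3p->1s emission).

.channelInfo <- function(channel) {
  switch(channel,
    absorb_1s3d = list(
      # adds a 3d electron, removes the 1s electron; 5 orbital components
      components = 5L,
      terms = function(comp) {
        list(a = .soBit(4L + comp, 0:1), b = .soBit(1L, 0:1))
      },
      deltas = c(n1s = -1L, n3p = 0L, n3d = +1L)),
    emit_3p1s = list(
      components = 3L,
      terms = function(comp) {
        list(a = .soBit(1L, 0:1), b = .soBit(1L + comp, 0:1))
      },
      deltas = c(n1s = +1L, n3p = -1L, n3d = 0L)),
    stop("unknown channel: ", channel))
}

#' Many-body transition amplitudes for a one-electron channel
#'
#' Matrix elements of the spin-conserving one-electron transition operator
#' between the eigenstates of two configurations, kept per orbital component
#' (m of the 3d orbital for 1s->3d absorption, m of the 3p orbital for
#' 3p->1s emission); intensities are formed downstream as incoherent sums
#' over components, i.e. an isotropic orientation average. The operator is
#' diagonal in spin, so amplitudes between states of different total spin
#' vanish identically.
#'
#' @param initial [LabeledEigenset-class] of the initial configuration
#' @param final [LabeledEigenset-class] of the configuration reached
#' @param channel "absorb_1s3d" or "emit_3p1s"
#' @return complex array \code{[nFinal, nInitial, nComponents]} with
#'   attribute \code{channel}
#' @export
transitionAmplitudes <- function(initial, final,
                                 channel = c("absorb_1s3d", "emit_3p1s")) {
  channel <- match.arg(channel)
  info <- .channelInfo(channel)
  ci <- initial@basis@configuration
  cf <- final@basis@configuration
  if (cf@n1s != ci@n1s + info$deltas["n1s"] ||
      cf@n3p != ci@n3p + info$deltas["n3p"] ||
      cf@n3d != ci@n3d + info$deltas["n3d"])
    stop("configuration mismatch for channel ", channel)
  key <- paste0("amp|", channel, "|", .specKey(initial@spec), "|",
                .specKey(final@spec))
  .cacheGet(key, function() {
    nF <- length(final@energies); nI <- length(initial@energies)
    T <- array(0i, c(nF, nI, info$components))
    VfH <- Conj(t(final@states))
    for (comp in seq_len(info$components)) {
      tt <- info$terms(comp)
      M <- cpp_one_body(final@basis@masks, initial@basis@masks,
                        tt$a, tt$b, rep(1, length(tt$a)))
      T[, , comp] <- VfH %*% (M %*% initial@states)
    }
    attr(T, "channel") <- channel
    T
  })
}
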
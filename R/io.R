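## Text I/O: TSV spectrum/plane files with '#' headers, YAML run
## configuration with validation and defaults.

.fmt17 <- function(x) sprintf("%.17g", x)

# tiny polynomial hash of a config for artifact stamping
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a spectrum to a two-column TSV file
#'
#' Header lines are prefixed with \code{#} and record units plus any scalar
#' metadata (normalization, seed, config hash); data lines are
#' \code{energy_eV<TAB>intensity} at full double precision, so
#' \code{readSpectrum(writeSpectrum(s))} round-trips exactly. The stick
#' provenance can be written to a sidecar file.
#'
#' @param s a [Spectrum1D-class]
#' @param path output file
#' @param sticksPath optional sidecar TSV for the stick list
#' @return invisibly, \code{path}
#' @export
writeSpectrum <- function(s, path, sticksPath = NULL) {
  stopifnot(is(s, "Spectrum1D"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rxesim Spectrum1D", con)
  writeLines("# columns: energy_eV intensity", con)
  meta <- s@metadata
  for (k in names(meta)) {
    v <- meta[[k]]
    if (length(v) == 1 && (is.character(v) || is.numeric(v) || is.logical(v)))
      writeLines(sprintf("# %s=%s", k,
                         if (is.numeric(v)) .fmt17(v) else as.character(v)),
                 con)
  }
  writeLines(paste(.fmt17(s@energy), .fmt17(s@intensity), sep = "\t"), con)
  if (!is.null(sticksPath) && nrow(s@sticks) > 0) {
    writeLines(c("# rxesim sticks", "# columns: energy_eV weight",
                 paste(.fmt17(s@sticks$energy), .fmt17(s@sticks$weight),
                       sep = "\t")),
               sticksPath)
  }
  invisible(path)
}

#' Read a spectrum written by [writeSpectrum]
#'
#' @param path input file
#' @return a [Spectrum1D-class]; \code{#} header key=value pairs are
#'   restored into the metadata
#' @export
readSpectrum <- function(path) {
  lines <- readLines(path)
  isHeader <- grepl("^#", lines)
  meta <- list()
  for (h in lines[isHeader]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)=(.*)$", h))[[1]]
    if (length(m) == 3) {
      v <- m[3]
      nv <- suppressWarnings(as.numeric(v))
      meta[[m[2]]] <- if (!is.na(nv)) nv else v
    }
  }
  dataLines <- which(!isHeader & nzchar(trimws(lines)))
  if (length(dataLines) == 0)
    stop("no data rows in spectrum file (header-only or empty): ", path)
  E <- numeric(length(dataLines)); I <- numeric(length(dataLines))
  for (i in seq_along(dataLines)) {
    ln <- dataLines[i]
    parts <- strsplit(trimws(lines[ln]), "[\t ]+")[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed spectrum file %s: expected 2 columns on line %d, found %d",
                   path, ln, length(parts)))
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop(sprintf("malformed spectrum file %s: non-numeric value on line %d",
                   path, ln))
    E[i] <- vals[1]; I[i] <- vals[2]
  }
  Spectrum1D(E, I, metadata = meta)
}

#' Write an RXES plane as long-form TSV
#'
#' Columns incident_eV, emission_eV, intensity (row-major over the incident
#' grid) at full precision; round-trips exactly through [readRXESPlane].
#'
#' @param plane an [RXESPlane-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeRXESPlane <- function(plane, path) {
  stopifnot(is(plane, "RXESPlane"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rxesim RXESPlane",
               "# columns: incident_eV emission_eV intensity"), con)
  om <- rep(plane@incident, each = length(plane@emission))
  em <- rep(plane@emission, length(plane@incident))
  iv <- as.vector(t(plane@intensity))
  writeLines(paste(.fmt17(om), .fmt17(em), .fmt17(iv), sep = "\t"), con)
  invisible(path)
}

#' Read an RXES plane written by [writeRXESPlane]
#' @param path input file
#' @return an [RXESPlane-class]
#' @export
readRXESPlane <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("incident", "emission", "intensity"))
  inc <- unique(tab$incident); em <- unique(tab$emission)
  M <- matrix(tab$intensity, nrow = length(inc), ncol = length(em),
              byrow = TRUE)
  new("RXESPlane", incident = inc, emission = em, intensity = M,
      metadata = list(source = path))
}

## Run configuration ---------------------------------------------------------

.runConfigDefaults <- function() {
  list(
    preset = NULL,
    model = NULL,             # explicit ground-model block (overrides preset)
    mixture = NULL,           # list of list(preset=, weight=)
    process = "rxes",
    incident_grid = NULL,
    emission_grid = NULL,
    broadening = list(gamma_intermediate = 1.25, gamma_final = 1.6,
                      sigma_instrumental = 0.7),
    offsets = NULL,           # list(absorption_origin=, emission_origin=)
    analysis = list(min_prominence = 0.02, kbeta_prime_window = c(8, 20)),
    scan_scalings = seq(1, 0.4, by = -0.1),
    noise = list(model = "poisson_counts", scale = 1e4, seed = 20210323,
                 calibration_shift = 0),
    seed = 20210323,
    out_dir = ".",
    log_level = "info")
}

.modelKeys <- c("n1s", "n3p", "n3d", "F0dd", "F2dd", "F4dd", "F2pd", "G1pd",
                "G3pd", "scaling", "scalingDD", "zeta3p", "zeta3d",
                "symmetry", "tenDq", "energy_offset")

.validateRunConfig <- function(cfg) {
  defaults <- .runConfigDefaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  # explicit nulls (e.g. from a saved config) mean "use the default"
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  out <- utils::modifyList(defaults, cfg)
  if (!is.null(out$model)) {
    badm <- setdiff(names(out$model), .modelKeys)
    if (length(badm))
      stop("unknown model keys: ", paste(badm, collapse = ", "))
  }
  b <- out$broadening
  for (k in c("gamma_intermediate", "gamma_final", "sigma_instrumental"))
    if (!is.null(b[[k]]) && b[[k]] < 0)
      stop("broadening field must be >= 0: ", k)
  for (g in c("incident_grid", "emission_grid")) {
    gr <- out[[g]]
    if (is.null(gr)) next
    if (length(gr) != 3 || gr[2] <= gr[1] || gr[3] <= 0)
      stop("grid must be c(min, max, step) with max > min, step > 0: ", g)
  }
  if (!is.null(out$preset) && !out$preset %in% presetNames())
    stop("unknown preset in config: ", out$preset)
  if (!is.null(out$mixture)) {
    for (comp in out$mixture)
      if (is.null(comp$preset) || is.null(comp$weight))
        stop("each mixture component needs 'preset' and 'weight'")
  }
  structure(out, class = "RunConfig")
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys are filled with package defaults.
#' A saved configuration reloads to an equal object, so a run is
#' reproducible from its config file alone.
#'
#' @param path YAML file
#' @return a validated list of class "RunConfig"
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  for (g in c("incident_grid", "emission_grid", "scan_scalings"))
    if (!is.null(cfg[[g]])) cfg[[g]] <- as.numeric(unlist(cfg[[g]]))
  if (!is.null(cfg$analysis$kbeta_prime_window))
    cfg$analysis$kbeta_prime_window <-
      as.numeric(unlist(cfg$analysis$kbeta_prime_window))
  .validateRunConfig(cfg)
}

#' Save a run configuration as YAML
#' @param cfg a "RunConfig" list
#' @param path output file
#' @return invisibly, \code{path}
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ground ModelSpec from a config (explicit model block wins over preset)
.configGround <- function(cfg) {
  if (!is.null(cfg$model)) {
    m <- utils::modifyList(
      list(n1s = 2, n3p = 6, n3d = 5, F0dd = 0, F2dd = 0, F4dd = 0,
           F2pd = 0, G1pd = 0, G3pd = 0, scaling = 1, scalingDD = 1,
           zeta3p = 0, zeta3d = 0, symmetry = "spherical", tenDq = 0,
           energy_offset = 0),
      cfg$model)
    return(ModelSpec(Configuration(m$n1s, m$n3p, m$n3d),
                     SlaterCondonSet(m$F0dd, m$F2dd, m$F4dd, m$F2pd,
                                     m$G1pd, m$G3pd, m$scaling, m$scalingDD),
                     SpinOrbitSet(m$zeta3p, m$zeta3d),
                     LigandFieldSpec(m$symmetry, m$tenDq),
                     m$energy_offset))
  }
  if (!is.null(cfg$preset)) return(.presetGround(presetParameters(cfg$preset)))
  stop("config must provide either 'preset' or 'model'")
}

.configBroadening <- function(cfg) {
  b <- cfg$broadening
  BroadeningSpec(b$gamma_intermediate, b$gamma_final, b$sigma_instrumental)
}

.configOffsets <- function(cfg) {
  if (is.null(cfg$offsets)) return(CalibrationOffsets())
  CalibrationOffsets(cfg$offsets$absorption_origin %||% 0,
                     cfg$offsets$emission_origin %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.gridSeq <- function(g) if (is.null(g)) NULL else seq(g[1], g[2], by = g[3])
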
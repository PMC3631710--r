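# Constants registry: Debye-Hueckel coefficients, Henry constants, Setchenow
# coefficients, molar masses, species charges / ion sizes / phases and
# standard formation values, loaded from a YAML file shipped with the package.

.lithomet_env <- new.env(parent = emptyenv())

#' Load a physical-chemistry constants file
#'
#' Reads the YAML constants registry (Debye-Hueckel A/B coefficients, ion-size
#' parameters, Henry's-law constants at 0 degC, Setchenow coefficients, molar
#' masses, and per-species charge, phase, element composition and standard
#' formation values at 25 degC).
#'
#' @param path path to a YAML constants file; default is the file shipped
#'   with the package.
#' @return a list with class \code{"lithoConstants"}.
#' @export
loadConstants <- function(path = system.file("extdata", "constants.yaml",
                                             package = "LithoMet")) {
  stopifnot(file.exists(path))
  cn <- yaml::read_yaml(path)
  required <- c("gas_constant_kj", "debye_huckel", "setchenow", "henry_0C",
                "molar_mass", "species", "atmosphere")
  miss <- setdiff(required, names(cn))
  if (length(miss))
    stop("constants file missing sections: ", paste(miss, collapse = ", "))
  class(cn) <- "lithoConstants"
  cn
}

#' Default constants registry (cached)
#'
#' @return the shipped constants, loaded once per session.
#' @export
defaultConstants <- function() {
  if (is.null(.lithomet_env$constants))
    .lithomet_env$constants <- loadConstants()
  .lithomet_env$constants
}

speciesInfo <- function(species, constants = defaultConstants()) {
  info <- constants$species[[species]]
  if (is.null(info))
    stop("unknown species '", species, "': not in the constants registry")
  info
}

#' Charge of a chemical species
#'
#' @param species species name as used in the constants registry.
#' @param constants constants registry.
#' @return integer charge.
#' @export
speciesCharge <- function(species, constants = defaultConstants()) {
  info <- speciesInfo(species, constants)
  if (is.null(info$charge)) 0L else as.integer(info$charge)
}

speciesPhase <- function(species, constants = defaultConstants()) {
  info <- speciesInfo(species, constants)
  if (is.null(info$phase)) "aqueous" else info$phase
}
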
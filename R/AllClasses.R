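#' @import methods
NULL

#' Water or deposit chemistry sample
#'
#' An S4 container for one field-chemistry record: a species table of
#' concentration intervals (mol/L) with measurement status, plus pH,
#' temperature, alkalinity and dissolved organic carbon. Species that were
#' below the instrument detection limit are represented as intervals from a
#' small floor concentration (default 1e-12 mol/L, i.e. effectively zero) up
#' to the detection limit.
#'
#' @slot name sample label.
#' @slot species data.frame with columns \code{species}, \code{status}
#'   (\code{"measured"} or \code{"below_detection"}), \code{low}, \code{high}
#'   (mol/L).
#' @slot pH field pH (dimensionless).
#' @slot pHsd stated pH uncertainty (0 if none).
#' @slot temperatureC temperature in degrees Celsius.
#' @slot alkalinity alkalinity in mg/L on the basis given by
#'   \code{alkalinityBasis}.
#' @slot alkalinityBasis \code{"HCO3"} or \code{"CaCO3"}.
#' @slot DOC dissolved organic carbon, mg C/L.
#'
#' @seealso [readChemistry()], [ionicStrength()], [sampleActivities()]
#' @export
setClass("ChemSample", representation(
  name = "character",
  species = "data.frame",
  pH = "numeric",
  pHsd = "numeric",
  temperatureC = "numeric",
  alkalinity = "numeric",
  alkalinityBasis = "character",
  DOC = "numeric"
))

setValidity("ChemSample", function(object) {
  msg <- character()
  sp <- object@species
  need <- c("species", "status", "low", "high")
  if (!all(need %in% names(sp)))
    msg <- c(msg, sprintf("species table must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(sp$species))
      msg <- c(msg, "each species may appear at most once")
    bad <- !(is.na(sp$low) | is.na(sp$high)) & (sp$low > sp$high | sp$low < 0)
    if (any(bad))
      msg <- c(msg, sprintf("species intervals must satisfy 0 <= low <= high (%s)",
                            paste(sp$species[bad], collapse = ", ")))
    if (!all(sp$status %in% c("measured", "below_detection")))
      msg <- c(msg, "status must be 'measured' or 'below_detection'")
  }
  if (length(object@pH) == 1 && is.finite(object@pH) &&
      (object@pH < 0 || object@pH > 14))
    msg <- c(msg, "pH must lie in [0, 14]")
  if (!is.finite(object@temperatureC))
    msg <- c(msg, "temperature must be finite")
  if (!object@alkalinityBasis %in% c("HCO3", "CaCO3"))
    msg <- c(msg, "alkalinityBasis must be 'HCO3' or 'CaCO3'")
  if (length(msg)) msg else TRUE
})

#' Construct a ChemSample
#'
#' @param name sample label.
#' @param species data.frame with columns \code{species}, \code{status},
#'   \code{low}, \code{high} (mol/L).
#' @param pH field pH.
#' @param temperatureC temperature, degrees C.
#' @param alkalinity alkalinity mg/L (see \code{alkalinityBasis}).
#' @param DOC dissolved organic carbon, mg C/L.
#' @param pHsd stated pH uncertainty.
#' @param alkalinityBasis \code{"HCO3"} (default) or \code{"CaCO3"}.
#' @return a [ChemSample-class] object.
#' @export
ChemSample <- function(name, species, pH, temperatureC,
                       alkalinity = 0, DOC = 0, pHsd = 0,
                       alkalinityBasis = "HCO3") {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  new("ChemSample", name = name, species = species, pH = pH, pHsd = pHsd,
      temperatureC = temperatureC, alkalinity = alkalinity,
      alkalinityBasis = alkalinityBasis, DOC = DOC)
}

#' @describeIn ChemSample sample label accessor
#' @param object a \code{ChemSample}.
#' @export
setGeneric("sampleName", function(object) standardGeneric("sampleName"))

#' @rdname ChemSample
#' @export
setMethod("sampleName", "ChemSample", function(object) object@name)

#' @describeIn ChemSample species concentration table accessor
#' @export
setGeneric("speciesTable", function(object) standardGeneric("speciesTable"))

#' @rdname ChemSample
#' @export
setMethod("speciesTable", "ChemSample", function(object) object@species)

setMethod("show", "ChemSample", function(object) {
  cat("ChemSample:", object@name, "\n")
  cat(sprintf("  pH %.2f (+/- %.2f), %.1f degC, alkalinity %.3g mg/L as %s, DOC %.3g mg C/L\n",
              object@pH, object@pHsd, object@temperatureC,
              object@alkalinity, object@alkalinityBasis, object@DOC))
  n <- nrow(object@species)
  nb <- sum(object@species$status == "below_detection")
  cat(sprintf("  %d species (%d below detection)\n", n, nb))
})

#' Catabolic reaction
#'
#' A redox reaction over named chemical species. Stoichiometric coefficients
#' are signed (products positive, reactants negative); phases (aqueous,
#' dissolved gas, solid, water) are taken from the species registry in the
#' constants file. Thermodynamics come either from a tabulated logK at a
#' stated temperature or are derived from standard formation values.
#'
#' @slot id short reaction label used for ranking/tie-breaks.
#' @slot name human-readable name.
#' @slot stoich named numeric vector of signed coefficients.
#' @slot electrons moles of electrons transferred per formula unit.
#' @slot logK tabulated log10 equilibrium constant (NA if derived from
#'   formation values).
#' @slot logKTemperatureK temperature (K) at which \code{logK} applies.
#' @export
setClass("Reaction", representation(
  id = "character",
  name = "character",
  stoich = "numeric",
  electrons = "numeric",
  logK = "numeric",
  logKTemperatureK = "numeric"
))

setValidity("Reaction", function(object) {
  msg <- character()
  if (is.null(names(object@stoich)) || any(!nzchar(names(object@stoich))))
    msg <- c(msg, "stoichiometry must be a named vector")
  if (any(object@stoich == 0))
    msg <- c(msg, "zero stoichiometric coefficients are not allowed")
  if (!(length(object@electrons) == 1 && object@electrons > 0))
    msg <- c(msg, "electrons transferred must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Reaction
#'
#' @param id short label.
#' @param stoich named numeric vector of signed coefficients (products
#'   positive, reactants negative), or an equation string such as
#'   \code{"S0 + 1.5 O2(aq) + H2O -> SO4-- + 2 H+"}.
#' @param electrons moles of electrons transferred (> 0).
#' @param name optional descriptive name.
#' @param logK optional tabulated log10 K.
#' @param logKTemperatureK temperature (K) of \code{logK}.
#' @param constants species registry used to balance-check the reaction;
#'   \code{NULL} skips the check.
#' @return a [Reaction-class] object.
#' @export
Reaction <- function(id, stoich, electrons, name = id,
                     logK = NA_real_, logKTemperatureK = NA_real_,
                     constants = NULL) {
  if (is.character(stoich) && length(stoich) == 1)
    stoich <- parseEquation(stoich)
  r <- new("Reaction", id = id, name = name, stoich = stoich,
           electrons = as.numeric(electrons), logK = logK,
           logKTemperatureK = logKTemperatureK)
  if (!is.null(constants)) validateReaction(r, constants)
  r
}

#' @describeIn Reaction reaction id accessor
#' @param object a \code{Reaction}.
#' @export
setGeneric("reactionId", function(object) standardGeneric("reactionId"))

#' @rdname Reaction
#' @export
setMethod("reactionId", "Reaction", function(object) object@id)

#' @describeIn Reaction signed stoichiometry accessor
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname Reaction
#' @export
setMethod("stoichiometry", "Reaction", function(object) object@stoich)

#' @describeIn Reaction electrons transferred accessor
#' @export
setGeneric("electronsTransferred",
           function(object) standardGeneric("electronsTransferred"))

#' @rdname Reaction
#' @export
setMethod("electronsTransferred", "Reaction", function(object) object@electrons)

setMethod("show", "Reaction", function(object) {
  s <- object@stoich
  side <- function(v) paste(sprintf("%s %s", ifelse(v == 1, "", format(v)),
                                    names(v)), collapse = " + ")
  cat(sprintf("Reaction %s (%s): %s -> %s [%g e-]\n", object@id, object@name,
              side(-s[s < 0]), side(s[s > 0]), object@electrons))
})

#' In-situ conditions for free-energy evaluation
#'
#' Temperature plus a set of species activity intervals (each a length-2
#' numeric \code{c(low, high)}) derived from a [ChemSample-class] and any
#' scenario overrides (for example a fixed dissolved-oxygen activity).
#'
#' @slot temperatureK absolute temperature (K).
#' @slot activities named list of length-2 activity intervals.
#' @slot sampleName label of the originating sample.
#' @export
setClass("EnergyContext", representation(
  temperatureK = "numeric",
  activities = "list",
  sampleName = "character"
))

setValidity("EnergyContext", function(object) {
  msg <- character()
  if (object@temperatureK <= 0) msg <- c(msg, "temperature must be > 0 K")
  ok <- vapply(object@activities, function(a)
    length(a) == 2 && all(is.finite(a)) && a[1] > 0 && a[1] <= a[2], logical(1))
  if (!all(ok))
    msg <- c(msg, sprintf("activity intervals must be positive ordered pairs (%s)",
                          paste(names(object@activities)[!ok], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnergyContext", function(object) {
  cat(sprintf("EnergyContext: %s at %.2f K, %d species activities\n",
              object@sampleName, object@temperatureK,
              length(object@activities)))
})

#' Reactant inventory for total-energy accounting
#'
#' Total moles available of each species, as intervals, on a declared basis
#' (for example 1 kg dry deposit plus 1 L porewater). Species drawn from an
#' effectively unlimited pool (atmospheric gases, water, the pH buffer) are
#' flagged replenished and never limit reaction extent.
#'
#' @slot basis human-readable description of the reference amount.
#' @slot moles named list of length-2 intervals (moles).
#' @slot replenished character vector of species names treated as unlimited.
#' @export
setClass("Inventory", representation(
  basis = "character",
  moles = "list",
  replenished = "character"
))

setValidity("Inventory", function(object) {
  ok <- vapply(object@moles, function(m)
    length(m) == 2 && all(is.finite(m)) && m[1] >= 0 && m[1] <= m[2],
    logical(1))
  if (!all(ok))
    sprintf("inventory intervals must be non-negative ordered pairs (%s)",
            paste(names(object@moles)[!ok], collapse = ", "))
  else TRUE
})

setMethod("show", "Inventory", function(object) {
  cat(sprintf("Inventory (basis: %s): %d species, %d replenished\n",
              object@basis, length(object@moles),
              length(object@replenished)))
})

#' Free-energy result for one reaction under one scenario
#'
#' All energetic quantities are intervals (\code{c(low, high)}) propagated
#' from the activity intervals: \code{deltaG} in kJ per mole of reaction,
#' \code{deltaGPerElectron} in kJ per mole of electrons, and (after
#' [totalEnergy()]) \code{totalKJ}, the energy available on the inventory
#' basis. Negative free energies are energy-yielding.
#'
#' @slot reactionId reaction label.
#' @slot lnQ natural-log reaction quotient interval.
#' @slot logK log10 equilibrium constant at the context temperature.
#' @slot deltaG interval, kJ/mol reaction.
#' @slot deltaGPerElectron interval, kJ/mol electrons.
#' @slot totalKJ available-energy interval, kJ per inventory basis (NA until
#'   computed).
#' @slot limitingReactant species limiting reaction extent (NA until
#'   computed).
#' @export
setClass("EnergyResult", representation(
  reactionId = "character",
  lnQ = "numeric",
  logK = "numeric",
  deltaG = "numeric",
  deltaGPerElectron = "numeric",
  totalKJ = "numeric",
  limitingReactant = "character"
))

setValidity("EnergyResult", function(object) {
  msg <- character()
  if (length(object@deltaG) == 2 && diff(object@deltaG) < -1e-9)
    msg <- c(msg, "deltaG interval must be ordered")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnergyResult", function(object) {
  cat(sprintf("EnergyResult %s: dGr [%.1f, %.1f] kJ/mol, per e- [%.1f, %.1f] kJ/mol\n",
              object@reactionId, object@deltaG[1], object@deltaG[2],
              object@deltaGPerElectron[1], object@deltaGPerElectron[2]))
  if (all(is.finite(object@totalKJ)))
    cat(sprintf("  total available [%.3g, %.3g] kJ (limiting: %s)\n",
                object@totalKJ[1], object@totalKJ[2],
                object@limitingReactant))
})
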
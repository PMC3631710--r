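# Activity / solubility layer: ionic strength, extended Debye-Hueckel and
# Setchenow activity coefficients, Henry's-law dissolved-gas maxima.

#' Map a chemistry table onto model-species concentration intervals
#'
#' Translates the analytical species of a [ChemSample-class] (totals, sulfide,
#' alkalinity, DOC) into the thermodynamic model species used by the reaction
#' set, all in mol/L:
#' \itemize{
#'   \item totals of Na, K, Mg, Ca, Mn map to the free ions; total As maps to
#'     arsenite and arsenate pools (each bounded by total As);
#'   \item total sulfide is split between H2S(aq) and HS- by the first
#'     dissociation constant of H2S at 0 degC evaluated at the sample pH;
#'   \item Fe2+ is capped at total Fe when the ferrous assay's detection
#'     limit exceeds the total-iron measurement;
#'   \item alkalinity is converted to bicarbonate molarity on its declared
#'     basis; DOC (mg C/L) is converted to acetate (2 carbons per molecule);
#'   \item below-detection species span \code{[floor, detection limit]}.
#' }
#'
#' @param sample a [ChemSample-class].
#' @param constants constants registry.
#' @return named list of length-2 concentration intervals (mol/L).
#' @export
modelConcentrations <- function(sample, constants = defaultConstants()) {
  sp <- speciesTable(sample)
  iv <- function(name) {
    i <- match(name, sp$species)
    if (is.na(i)) NULL else c(sp$low[i], sp$high[i])
  }
  out <- list()
  direct <- c("Total Na" = "Na+", "Total K" = "K+", "Total Mg" = "Mg++",
              "Total Ca" = "Ca++", "Total Mn" = "Mn++", "NH4+" = "NH4+",
              "SO4--" = "SO4--", "S2O3--" = "S2O3--", "Cl-" = "Cl-",
              "F-" = "F-", "Br-" = "Br-", "NO3-" = "NO3-", "NO2-" = "NO2-",
              "PO4---" = "PO4---", "Total Si" = "H4SiO4",
              "Total As" = "H3AsO3")
  for (tab in names(direct)) {
    v <- iv(tab)
    if (!is.null(v)) out[[direct[[tab]]]] <- v
  }
  # ferrous iron: below-detection interval cannot exceed measured total iron
  fe2 <- iv("Fe2+"); fet <- iv("Total Fe")
  if (!is.null(fe2)) {
    if (!is.null(fet)) fe2 <- pmin(fe2, fet[2])
    out[["Fe++"]] <- fe2
  } else if (!is.null(fet)) out[["Fe++"]] <- fet
  # sulfide speciation at sample pH
  sulf <- iv("Total sulfide")
  if (!is.null(sulf)) {
    pKa <- constants$pKa1_H2S_0C
    fHS <- 1 / (1 + 10^(pKa - sample@pH))
    out[["HS-"]] <- sulf * fHS
    out[["H2S(aq)"]] <- sulf * (1 - fHS)
  }
  # alkalinity -> bicarbonate
  if (sample@alkalinity > 0) {
    mm <- constants$molar_mass
    hco3 <- if (sample@alkalinityBasis == "CaCO3")
      2 * sample@alkalinity / mm$CaCO3 * 1e-3
    else sample@alkalinity / mm$HCO3 * 1e-3
    out[["HCO3-"]] <- c(hco3, hco3)
  }
  # DOC (mg C/L) treated as acetate: 2 carbons per acetate
  if (sample@DOC > 0) {
    ac <- sample@DOC / (2 * constants$molar_mass$C) * 1e-3
    out[["Acetate-"]] <- c(ac, ac)
  }
  out
}

#' Ionic strength of a sample
#'
#' Computes I = 1/2 * sum(c_i * z_i^2) over the charged model species of the
#' sample, with alkalinity contributing as bicarbonate. Uncharged species
#' contribute nothing.
#'
#' @param sample a [ChemSample-class].
#' @param endpoint \code{"high"} (default) or \code{"low"}: which end of each
#'   concentration interval to use.
#' @param constants constants registry (supplies charges).
#' @return ionic strength, mol/L.
#' @export
ionicStrength <- function(sample, endpoint = c("high", "low"),
                          constants = defaultConstants()) {
  endpoint <- match.arg(endpoint)
  conc <- modelConcentrations(sample, constants)
  if (!length(conc)) return(0)
  k <- if (endpoint == "high") 2L else 1L
  z <- vapply(names(conc), speciesCharge, integer(1), constants = constants)
  0.5 * sum(vapply(conc, `[`, numeric(1), k) * z^2)
}

#' Extended Debye-Hueckel activity coefficient
#'
#' log10(gamma) = -A z^2 sqrt(I) / (1 + B a0 sqrt(I)), with temperature-
#' appropriate A and B obtained by linear interpolation between the tabulated
#' values (0 and 25 degC in the shipped constants) and a per-species or
#' default ion-size parameter a0 (Angstrom). Uncharged species have gamma 1,
#' as does any species at infinite dilution.
#'
#' @param charge integer charge of the species.
#' @param I ionic strength, mol/L (>= 0).
#' @param temperatureC temperature, degrees C.
#' @param a0 ion-size parameter (Angstrom); default from the constants file.
#' @param constants constants registry.
#' @return activity coefficient in (0, 1].
#' @export
debyeHuckelGamma <- function(charge, I, temperatureC = 0, a0 = NULL,
                             constants = defaultConstants()) {
  if (any(I < 0)) stop("ionic strength must be non-negative")
  if (charge == 0) return(rep(1, length(I)))
  dh <- constants$debye_huckel
  A <- stats::approx(dh$temperatures_C, dh$A, xout = temperatureC,
                     rule = 2)$y
  B <- stats::approx(dh$temperatures_C, dh$B, xout = temperatureC,
                     rule = 2)$y
  if (is.null(a0)) a0 <- dh$default_a0
  sqI <- sqrt(I)
  10^(-A * charge^2 * sqI / (1 + B * a0 * sqI))
}

#' Setchenow (salting-out) activity coefficient for a dissolved gas
#'
#' gamma = 10^(ks * I); >= 1 for non-negative salting coefficients, so the
#' effective activity of a dissolved gas in saline water slightly exceeds its
#' molar concentration.
#'
#' @param I ionic strength, mol/L (>= 0).
#' @param ks Setchenow coefficient, L/mol.
#' @return activity coefficient.
#' @export
setchenowGamma <- function(I, ks = defaultConstants()$setchenow$default_ks) {
  if (any(I < 0)) stop("ionic strength must be non-negative")
  10^(ks * I)
}

#' Atmospheric gas context
#'
#' Bundles everything needed to compute a gas's equilibrium (maximum)
#' dissolved concentration: atmospheric mole fraction, total pressure, water
#' vapor pressure, the Henry's-law constant at the stated temperature and the
#' Setchenow salting coefficient.
#'
#' @slot gas gas name (e.g. \code{"O2"}).
#' @slot moleFraction atmospheric mole fraction in [0, 1].
#' @slot totalPressureBar total pressure, bar.
#' @slot waterVaporPressureBar water vapor pressure, bar.
#' @slot henryConstant Henry constant, mol/(L bar).
#' @slot temperatureC temperature at which the Henry constant applies.
#' @slot setchenowKs Setchenow coefficient, L/mol.
#' @export
setClass("GasContext", representation(
  gas = "character",
  moleFraction = "numeric",
  totalPressureBar = "numeric",
  waterVaporPressureBar = "numeric",
  henryConstant = "numeric",
  temperatureC = "numeric",
  setchenowKs = "numeric"
))

setValidity("GasContext", function(object) {
  msg <- character()
  if (object@moleFraction < 0 || object@moleFraction > 1)
    msg <- c(msg, "mole fraction must lie in [0, 1]")
  if (!(object@totalPressureBar > object@waterVaporPressureBar &&
        object@waterVaporPressureBar >= 0))
    msg <- c(msg, "must have total pressure > water vapor pressure >= 0")
  if (object@henryConstant <= 0)
    msg <- c(msg, "Henry constant must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GasContext
#'
#' Defaults describe a 0 degC atmosphere at 1 bar: shipped Henry constants are
#' for 0 degC only, so other temperatures require an explicit
#' \code{henryConstant}.
#'
#' @param gas gas name; must have a shipped Henry constant (O2, N2, CO2)
#'   unless \code{henryConstant} is supplied.
#' @param temperatureC temperature, degrees C.
#' @param moleFraction atmospheric mole fraction; default from the constants
#'   file.
#' @param totalPressureBar total pressure, bar.
#' @param waterVaporPressureBar water vapor pressure, bar.
#' @param henryConstant Henry constant, mol/(L bar), at \code{temperatureC}.
#' @param setchenowKs Setchenow coefficient, L/mol.
#' @param constants constants registry.
#' @return a [GasContext-class].
#' @export
gasContext <- function(gas, temperatureC = 0, moleFraction = NULL,
                       totalPressureBar = NULL, waterVaporPressureBar = NULL,
                       henryConstant = NULL, setchenowKs = NULL,
                       constants = defaultConstants()) {
  atm <- constants$atmosphere
  if (is.null(moleFraction)) {
    moleFraction <- atm$mole_fraction[[gas]]
    if (is.null(moleFraction))
      stop("no default mole fraction for gas '", gas, "'")
  }
  if (is.null(totalPressureBar)) totalPressureBar <- atm$total_pressure_bar
  if (is.null(waterVaporPressureBar))
    waterVaporPressureBar <- atm$water_vapor_pressure_bar
  if (is.null(henryConstant)) {
    if (abs(temperatureC) > 1e-9)
      stop("shipped Henry constants are for 0 degC; supply henryConstant for ",
           temperatureC, " degC")
    henryConstant <- constants$henry_0C[[gas]]
    if (is.null(henryConstant))
      stop("no Henry constant available for gas '", gas, "'")
  }
  if (is.null(setchenowKs)) setchenowKs <- constants$setchenow$default_ks
  new("GasContext", gas = gas, moleFraction = moleFraction,
      totalPressureBar = totalPressureBar,
      waterVaporPressureBar = waterVaporPressureBar,
      henryConstant = henryConstant, temperatureC = temperatureC,
      setchenowKs = setchenowKs)
}

#' Partial pressure of an atmospheric gas over water
#'
#' p = X * (P_total - pH2O): the dry-air mole fraction applied to the total
#' pressure corrected for water vapor.
#'
#' @param ctx a [GasContext-class].
#' @return partial pressure, bar.
#' @export
gasPartialPressure <- function(ctx) {
  ctx@moleFraction * (ctx@totalPressureBar - ctx@waterVaporPressureBar)
}

#' Maximum (equilibrium) dissolved-gas concentration
#'
#' Henry's law: c_max = K_H * p(gas), the concentration in equilibrium with
#' the atmosphere — the ceiling for the dissolved gas in surface-exposed
#' water.
#'
#' @param ctx a [GasContext-class].
#' @return concentration, mol/L, with attribute \code{"mg_per_L"} when the
#'   gas has a shipped molar mass.
#' @param constants constants registry (molar masses).
#' @export
maxDissolvedGas <- function(ctx, constants = defaultConstants()) {
  conc <- ctx@henryConstant * gasPartialPressure(ctx)
  mm <- constants$molar_mass[[ctx@gas]]
  if (!is.null(mm)) attr(conc, "mg_per_L") <- conc * mm * 1e3
  conc
}

#' Activity interval of one model species in a sample
#'
#' Applies the convention of low-temperature geochemical energetics:
#' \itemize{
#'   \item pure solids and water: unit activity;
#'   \item \code{H+}: activity 1e-pH directly (optionally an interval over
#'     the stated pH uncertainty);
#'   \item dissolved gases: concentration times the Setchenow coefficient;
#'   \item aqueous ions: concentration times the extended Debye-Hueckel
#'     coefficient; neutral aqueous species: coefficient 1.
#' }
#'
#' @param species model-species name.
#' @param sample a [ChemSample-class].
#' @param I ionic strength; computed from the sample (high endpoint) if NULL.
#' @param includePHUncertainty fold the stated pH uncertainty into the H+
#'   activity interval.
#' @param constants constants registry.
#' @return length-2 activity interval.
#' @export
speciesActivity <- function(species, sample, I = NULL,
                            includePHUncertainty = FALSE,
                            constants = defaultConstants()) {
  phase <- speciesPhase(species, constants)
  if (phase %in% c("solid", "water")) return(c(1, 1))
  if (species == "H+") {
    if (includePHUncertainty && sample@pHsd > 0)
      return(10^(-c(sample@pH + sample@pHsd, sample@pH - sample@pHsd)))
    return(rep(10^(-sample@pH), 2))
  }
  if (is.null(I)) I <- ionicStrength(sample, constants = constants)
  conc <- modelConcentrations(sample, constants)[[species]]
  if (is.null(conc))
    stop("species '", species, "' has no concentration in sample '",
         sampleName(sample), "'")
  gamma <- if (phase == "gas") {
    setchenowGamma(I, constants$setchenow$default_ks)
  } else {
    debyeHuckelGamma(speciesCharge(species, constants), I,
                     sample@temperatureC,
                     a0 = speciesInfo(species, constants)$a0,
                     constants = constants)
  }
  conc * gamma
}

#' Activity intervals for all model species of a sample
#'
#' @inheritParams speciesActivity
#' @return named list of length-2 activity intervals, including \code{H+}
#'   and unit-activity \code{H2O}.
#' @export
sampleActivities <- function(sample, includePHUncertainty = FALSE,
                             constants = defaultConstants()) {
  I <- ionicStrength(sample, constants = constants)
  conc <- modelConcentrations(sample, constants)
  out <- lapply(names(conc), speciesActivity, sample = sample, I = I,
                constants = constants)
  names(out) <- names(conc)
  out[["H+"]] <- speciesActivity("H+", sample,
                                 includePHUncertainty = includePHUncertainty,
                                 constants = constants)
  out[["H2O"]] <- c(1, 1)
  out
}
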
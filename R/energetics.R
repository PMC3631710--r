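# Catabolic free-energy engine: equilibrium constants at temperature,
# reaction quotients over activity intervals, dGr per reaction and per mole
# of electrons, and total energy available from reactant inventories.

#' Parse a reaction equation string
#'
#' Accepts equations such as \code{"S0 + 1.5 O2(aq) + H2O -> SO4-- + 2 H+"}.
#' Terms are separated by \code{" + "} (plus with surrounding spaces, so
#' trailing charge signs in species names are untouched); a leading number
#' on a term is its coefficient. Reactants receive negative signed
#' coefficients, products positive.
#'
#' @param equation equation string with a \code{"->"} separator.
#' @return named numeric vector of signed stoichiometric coefficients.
#' @export
parseEquation <- function(equation) {
  sides <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop("equation must contain exactly one '->': ", equation)
  parseSide <- function(side, sign) {
    terms <- strsplit(side, " + ", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (!length(terms)) stop("empty reaction side in: ", equation)
    coefs <- numeric(0)
    for (term in terms) {
      m <- regmatches(term, regexec("^([0-9]*\\.?[0-9]+)\\s+(.+)$", term))[[1]]
      if (length(m) == 3) {
        coef <- as.numeric(m[2]); sp <- m[3]
      } else {
        coef <- 1; sp <- term
      }
      coefs[sp] <- sign * coef + if (sp %in% names(coefs)) coefs[[sp]] else 0
    }
    coefs
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  both <- intersect(names(lhs), names(rhs))
  out <- c(lhs, rhs[setdiff(names(rhs), both)])
  for (sp in both) out[sp] <- lhs[sp] + rhs[sp]
  out[out != 0]
}

#' Validate charge and element balance of a reaction
#'
#' Checks that signed stoichiometry conserves charge and every element
#' recorded in the species registry. Called at load time for every shipped
#' reaction.
#'
#' @param reaction a [Reaction-class].
#' @param constants constants registry (charges and element compositions).
#' @param tol numeric tolerance for balance sums.
#' @return invisibly TRUE; errors with the offending quantity otherwise.
#' @export
validateReaction <- function(reaction, constants = defaultConstants(),
                             tol = 1e-9) {
  st <- stoichiometry(reaction)
  z <- vapply(names(st), speciesCharge, integer(1), constants = constants)
  if (abs(sum(st * z)) > tol)
    stop("reaction '", reactionId(reaction), "' is not charge balanced (net ",
         format(sum(st * z)), ")")
  elements <- unique(unlist(lapply(names(st), function(sp)
    names(speciesInfo(sp, constants)$elements))))
  for (el in elements) {
    n <- vapply(names(st), function(sp) {
      cnt <- speciesInfo(sp, constants)$elements[[el]]
      if (is.null(cnt)) 0 else cnt
    }, numeric(1))
    if (abs(sum(st * n)) > tol)
      stop("reaction '", reactionId(reaction),
           "' does not balance element ", el, " (net ", format(sum(st * n)), ")")
  }
  invisible(TRUE)
}

#' Read a reaction set from a YAML file
#'
#' Each entry must carry \code{id}, \code{equation} and \code{electrons};
#' optional \code{name}, \code{logK} and \code{logK_temperature_K} supply a
#' tabulated equilibrium constant. Every reaction is charge- and
#' element-balance checked against the species registry at load time.
#'
#' @param path YAML file path.
#' @param constants constants registry used for validation.
#' @return list of [Reaction-class] objects, named by id.
#' @export
readReactions <- function(path, constants = defaultConstants()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$reactions)) stop("no 'reactions' section in ", path)
  out <- lapply(raw$reactions, function(r) {
    for (f in c("id", "equation", "electrons"))
      if (is.null(r[[f]])) stop("reaction entry missing field '", f, "' in ", path)
    Reaction(id = r$id,
             stoich = parseEquation(r$equation),
             electrons = r$electrons,
             name = if (is.null(r$name)) r$id else r$name,
             logK = if (is.null(r$logK)) NA_real_ else r$logK,
             logKTemperatureK = if (is.null(r$logK_temperature_K)) NA_real_
                                else r$logK_temperature_K,
             constants = constants)
  })
  names(out) <- vapply(out, reactionId, character(1))
  out
}

#' The shipped default catabolic reaction set
#'
#' Fourteen reactions covering aerobic oxidation of the reduced sulfur
#' species (sulfide, elemental sulfur, thiosulfate, sulfite), aerobic acetate
#' oxidation, anammox, both nitrification steps, aerobic Fe(II)/Mn(II)/As(III)
#' oxidation, sulfur and thiosulfate disproportionation, and nitrate-coupled
#' sulfur oxidation.
#'
#' @param constants constants registry.
#' @return named list of [Reaction-class] objects.
#' @export
defaultReactions <- function(constants = defaultConstants()) {
  readReactions(system.file("extdata", "reactions.yaml", package = "LithoMet"),
                constants = constants)
}

#' log10 equilibrium constant of a reaction at temperature
#'
#' If the reaction carries a tabulated logK at (to within 0.01 K) the
#' requested temperature, it is returned unchanged. Otherwise logK is derived
#' from the standard formation values in the species registry by the
#' constant-enthalpy van't Hoff route: dG(T) = dH298 - T * dS298 with
#' dS298 = (dH298 - dG298) / 298.15, and logK = -dG(T) / (ln 10 * R * T).
#' The route taken is recorded in the \code{"route"} attribute.
#'
#' @param reaction a [Reaction-class].
#' @param temperatureK absolute temperature, K.
#' @param constants constants registry with formation values.
#' @return log10 K with attribute \code{"route"} of \code{"tabulated"} or
#'   \code{"vant_hoff"}.
#' @export
logKAtTemperature <- function(reaction, temperatureK = 273.15,
                              constants = defaultConstants()) {
  if (!is.na(reaction@logK)) {
    if (!is.na(reaction@logKTemperatureK) &&
        abs(reaction@logKTemperatureK - temperatureK) < 0.01)
      return(structure(reaction@logK, route = "tabulated"))
    if (is.na(reaction@logKTemperatureK))
      return(structure(reaction@logK, route = "tabulated"))
  }
  st <- stoichiometry(reaction)
  miss <- names(st)[vapply(names(st), function(sp) {
    info <- constants$species[[sp]]
    is.null(info) || is.null(info$dGf) || is.null(info$dHf)
  }, logical(1))]
  if (length(miss))
    stop("insufficient thermodynamic data for species: ",
         paste(miss, collapse = ", "))
  dG298 <- sum(st * vapply(names(st), function(sp)
    speciesInfo(sp, constants)$dGf, numeric(1)))
  dH298 <- sum(st * vapply(names(st), function(sp)
    speciesInfo(sp, constants)$dHf, numeric(1)))
  Tref <- constants$reference_temperature_K
  dS298 <- (dH298 - dG298) / Tref
  dGT <- dH298 - temperatureK * dS298
  R <- constants$gas_constant_kj
  structure(-dGT / (log(10) * R * temperatureK), route = "vant_hoff")
}

#' Build an in-situ energy context from a chemistry sample
#'
#' Assembles the activity intervals the reaction set needs:
#' \itemize{
#'   \item measured / below-detection species via [sampleActivities()];
#'   \item dissolved O2, N2 and CO2 at their Henry's-law atmospheric
#'     equilibrium maxima (O2 replaceable by a scan value via
#'     \code{overrides});
#'   \item the reduced-species convention for elements assayed only as
#'     totals: arsenite, arsenate and Mn2+ each span from the
#'     below-detection floor up to the total-element activity, so the
#'     interval covers "all oxidized" through "all reduced";
#'   \item sulfite, which the ion chromatography assay did not report, is
#'     assumed below a 2 uM detection limit (like thiosulfate);
#'   \item scenario \code{overrides} (named numbers or length-2 intervals)
#'     take precedence over everything.
#' }
#'
#' @param sample a [ChemSample-class].
#' @param overrides named list of activity values or intervals (e.g.
#'   \code{list("O2(aq)" = 1e-10)}).
#' @param temperatureK context temperature; defaults to the sample
#'   temperature.
#' @param sulfiteDetectionLimit assumed detection limit for unreported
#'   sulfite, mol/L.
#' @param floor below-detection floor activity, mol/L.
#' @param includePHUncertainty fold pH uncertainty into the H+ interval.
#' @param constants constants registry.
#' @return an [EnergyContext-class].
#' @export
buildEnergyContext <- function(sample, overrides = list(),
                               temperatureK = NULL,
                               sulfiteDetectionLimit = 2e-6,
                               floor = NULL,
                               includePHUncertainty = FALSE,
                               constants = defaultConstants()) {
  if (is.null(temperatureK)) temperatureK <- sample@temperatureC + 273.15
  if (is.null(floor)) floor <- constants$below_detection_floor
  act <- sampleActivities(sample, includePHUncertainty = includePHUncertainty,
                          constants = constants)
  I <- ionicStrength(sample, constants = constants)
  gammaGas <- setchenowGamma(I, constants$setchenow$default_ks)
  for (gas in names(constants$henry_0C)) {
    sp <- paste0(gas, "(aq)")
    cmax <- maxDissolvedGas(gasContext(gas, temperatureC = sample@temperatureC,
                                       constants = constants),
                            constants = constants)
    act[[sp]] <- c(as.numeric(cmax), as.numeric(cmax)) * gammaGas
  }
  # reduced/oxidized endpoints for elements assayed only as totals
  redox <- list("Mn++" = "Mn++", "H3AsO3" = "H3AsO3", "H2AsO4-" = "H3AsO3")
  totals <- list("Mn++" = act[["Mn++"]], "H3AsO3" = act[["H3AsO3"]])
  for (sp in names(redox)) {
    tot <- totals[[redox[[sp]]]]
    if (!is.null(tot)) act[[sp]] <- c(floor, tot[2])
  }
  if (is.null(act[["SO3--"]]))
    act[["SO3--"]] <- c(floor, sulfiteDetectionLimit) *
      debyeHuckelGamma(-2, I, sample@temperatureC,
                       a0 = speciesInfo("SO3--", constants)$a0,
                       constants = constants)
  for (sp in names(overrides)) {
    v <- overrides[[sp]]
    act[[sp]] <- if (length(v) == 1) c(v, v) else sort(as.numeric(v))
  }
  new("EnergyContext", temperatureK = temperatureK, activities = act,
      sampleName = sampleName(sample))
}

#' Natural-log reaction quotient over activity intervals
#'
#' lnQ = sum(coeff_i * ln a_i), with solids and water contributing ln 1 = 0.
#' Because lnQ is monotone in each activity, the interval endpoints follow by
#' giving every product its minimizing (maximizing) activity endpoint and
#' every reactant its maximizing (minimizing) one.
#'
#' @param reaction a [Reaction-class].
#' @param ctx an [EnergyContext-class].
#' @param constants constants registry (phases).
#' @return length-2 lnQ interval.
#' @export
reactionQuotient <- function(reaction, ctx, constants = defaultConstants()) {
  st <- stoichiometry(reaction)
  lo <- hi <- 0
  for (sp in names(st)) {
    if (speciesPhase(sp, constants) %in% c("solid", "water")) next
    a <- ctx@activities[[sp]]
    if (is.null(a))
      stop("no activity for species '", sp, "' in the context (reaction '",
           reactionId(reaction), "')")
    la <- log(a)
    if (st[[sp]] > 0) {
      lo <- lo + st[[sp]] * la[1]; hi <- hi + st[[sp]] * la[2]
    } else {
      lo <- lo + st[[sp]] * la[2]; hi <- hi + st[[sp]] * la[1]
    }
  }
  c(lo, hi)
}

#' In-situ Gibbs free energy of a reaction
#'
#' dGr = R * T * (lnQ - lnK), evaluated over the context's activity
#' intervals; the per-electron value divides by the moles of electrons
#' transferred. Negative values are energy-yielding.
#'
#' @param reaction a [Reaction-class].
#' @param ctx an [EnergyContext-class].
#' @param constants constants registry.
#' @return an [EnergyResult-class] (total-energy slots unset; see
#'   [totalEnergy()]).
#' @export
deltaG <- function(reaction, ctx, constants = defaultConstants()) {
  lnQ <- reactionQuotient(reaction, ctx, constants)
  logK <- logKAtTemperature(reaction, ctx@temperatureK, constants)
  R <- constants$gas_constant_kj
  lnK <- log(10) * as.numeric(logK)
  dG <- R * ctx@temperatureK * (lnQ - lnK)
  new("EnergyResult", reactionId = reactionId(reaction), lnQ = lnQ,
      logK = as.numeric(logK), deltaG = dG,
      deltaGPerElectron = dG / electronsTransferred(reaction),
      totalKJ = c(NA_real_, NA_real_), limitingReactant = NA_character_)
}

#' Default reactant inventory for a deposit sample
#'
#' Basis: \code{dryMassKg} of dry deposit plus \code{porewaterLPerKg} litres
#' of porewater per kg. Elemental sulfur contributes
#' \code{s0Fraction} (an interval of dry-weight fractions, default 10--100%)
#' of the dry mass as mol S; dissolved species contribute concentration
#' interval times porewater volume; atmospheric gases (O2, N2, CO2), water
#' and the pH-buffered proton pool are flagged replenished.
#'
#' @param sample a [ChemSample-class].
#' @param dryMassKg dry deposit mass, kg.
#' @param porewaterLPerKg porewater volume per kg dry deposit, L.
#' @param s0Fraction length-2 interval of S0 dry-weight fractions.
#' @param sulfiteDetectionLimit assumed detection limit for unreported
#'   sulfite, mol/L (same convention as [buildEnergyContext()]).
#' @param constants constants registry.
#' @return an [Inventory-class].
#' @export
defaultInventory <- function(sample, dryMassKg = 1, porewaterLPerKg = 1,
                             s0Fraction = c(0.10, 1.00),
                             sulfiteDetectionLimit = 2e-6,
                             constants = defaultConstants()) {
  vol <- dryMassKg * porewaterLPerKg
  conc <- modelConcentrations(sample, constants)
  moles <- lapply(conc, function(cc) cc * vol)
  if (is.null(moles[["SO3--"]]))
    moles[["SO3--"]] <- c(constants$below_detection_floor,
                          sulfiteDetectionLimit) * vol
  moles[["S0"]] <- s0Fraction * dryMassKg * 1000 / constants$molar_mass$S
  new("Inventory",
      basis = sprintf("%g kg dry deposit + %g L porewater", dryMassKg, vol),
      moles = moles,
      replenished = c("O2(aq)", "N2(aq)", "CO2(aq)", "H2O", "H+"))
}

#' Total energy available from a reaction given an inventory
#'
#' Reaction extent is limited by the scarcest non-replenished reactant
#' (moles available / |coefficient|). Available energy is |dGr| times extent
#' where dGr < 0 and zero otherwise; the returned interval combines the
#' reactant-amount and dGr intervals conservatively.
#'
#' @param result an [EnergyResult-class] from [deltaG()].
#' @param reaction the corresponding [Reaction-class].
#' @param inventory an [Inventory-class].
#' @return the [EnergyResult-class] with \code{totalKJ} and
#'   \code{limitingReactant} filled in.
#' @export
totalEnergy <- function(result, reaction, inventory) {
  st <- stoichiometry(reaction)
  reactants <- names(st)[st < 0]
  limited <- setdiff(reactants, inventory@replenished)
  if (!length(limited)) {
    stop("all reactants of '", reactionId(reaction),
         "' are replenished; total energy is unbounded")
  }
  ext <- vapply(limited, function(sp) {
    m <- inventory@moles[[sp]]
    if (is.null(m))
      stop("reactant '", sp, "' has no inventory entry and is not replenished")
    m / abs(st[[sp]])
  }, numeric(2))
  extentHi <- min(ext[2, ])
  extentLo <- min(ext[1, ])
  limiting <- limited[which.min(ext[2, ])]
  # energy per mole of reaction (non-negative; 0 where dGr >= 0)
  eLo <- max(0, -result@deltaG[2])
  eHi <- max(0, -result@deltaG[1])
  result@totalKJ <- c(eLo * extentLo, eHi * extentHi)
  result@limitingReactant <- limiting
  result
}

#' Free-energy landscape over a reaction set and oxygen scenarios
#'
#' Evaluates every reaction under every dissolved-oxygen scenario and
#' returns a ranked table. Scenario \code{"max"} uses the Henry's-law
#' atmospheric-equilibrium oxygen activity; numeric scenarios fix the O2
#' activity directly (the oxygen scan down to 1e-10 that models depletion
#' below the deposit surface).
#'
#' @param reactions list of [Reaction-class] objects.
#' @param sample a [ChemSample-class].
#' @param o2Scan scenarios: \code{"max"} and/or numbers (activities).
#' @param inventory an [Inventory-class]; default [defaultInventory()] of the
#'   sample.
#' @param constants constants registry.
#' @return data.frame with one row per reaction per scenario: lnQ, logK, dGr,
#'   per-electron dGr and total-energy intervals, the limiting reactant, and
#'   within-scenario ranks by per-electron dGr (most negative first) and by
#'   total energy (largest first); ties broken by reaction id.
#' @export
energyLandscape <- function(reactions, sample,
                            o2Scan = list("max", 1e-6, 1e-10),
                            inventory = NULL,
                            constants = defaultConstants()) {
  if (!length(reactions)) stop("empty reaction list")
  if (is.null(inventory))
    inventory <- defaultInventory(sample, constants = constants)
  rows <- list()
  for (scen in o2Scan) {
    if (identical(scen, "max")) {
      ctx <- buildEnergyContext(sample, constants = constants)
      label <- "max"
    } else {
      ctx <- buildEnergyContext(sample,
                                overrides = list("O2(aq)" = as.numeric(scen)),
                                constants = constants)
      label <- format(as.numeric(scen))
    }
    for (r in reactions) {
      res <- totalEnergy(deltaG(r, ctx, constants), r, inventory)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = reactionId(r), scenario_aO2 = label,
        lnQ_lo = res@lnQ[1], lnQ_hi = res@lnQ[2], logK = res@logK,
        dGr_lo = res@deltaG[1], dGr_hi = res@deltaG[2],
        dGr_per_e_lo = res@deltaGPerElectron[1],
        dGr_per_e_hi = res@deltaGPerElectron[2],
        total_kJ_lo = res@totalKJ[1], total_kJ_hi = res@totalKJ[2],
        limiting_reactant = res@limitingReactant,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$rank_per_e <- NA_integer_
  out$rank_total <- NA_integer_
  for (scen in unique(out$scenario_aO2)) {
    i <- which(out$scenario_aO2 == scen)
    out$rank_per_e[i] <- order(order(out$dGr_per_e_lo[i], out$reaction[i]))
    out$rank_total[i] <- order(order(-out$total_kJ_hi[i], out$reaction[i]))
  }
  out[order(match(out$scenario_aO2, sapply(o2Scan, function(s)
    if (identical(s, "max")) "max" else format(as.numeric(s)))),
    out$rank_per_e), ]
}
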
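test_that("ionic strength matches the closed form and the field sample", {
  empty <- ChemSample("empty",
                      data.frame(species = character(), status = character(),
                                 low = numeric(), high = numeric()),
                      pH = 7, temperatureC = 0)
  expect_identical(ionicStrength(empty), 0)

  nacl <- ChemSample("nacl",
                     data.frame(species = c("Total Na", "Cl-"),
                                status = "measured",
                                low = 1e-3, high = 1e-3),
                     pH = 7, temperatureC = 0)
  expect_equal(ionicStrength(nacl), 1e-3, tolerance = 1e-12)

  # deposit-extract sample, high endpoints: hand-summed 0.5 * sum(c z^2)
  # over the printed concentrations gives ~0.0455 mol/L
  s <- borup06b()
  I <- ionicStrength(s, endpoint = "high")
  expect_equal(I, 0.0455, tolerance = 0.02)

  # brute-force recomputation from the model concentrations
  conc <- modelConcentrations(s)
  z <- vapply(names(conc), speciesCharge, integer(1))
  oracle <- 0.5 * sum(vapply(conc, function(x) x[2], numeric(1)) * z^2)
  expect_equal(I, oracle, tolerance = 1e-12)

  # low endpoint can only be smaller (below-detection intervals collapse)
  expect_lt(ionicStrength(s, endpoint = "low"), I)
})

test_that("Debye-Hueckel coefficients obey limits, monotonicity and the frozen value", {
  expect_identical(debyeHuckelGamma(0, 0.5), 1)
  expect_equal(debyeHuckelGamma(-2, 0), 1)
  expect_error(debyeHuckelGamma(1, -0.1), "non-negative")

  # frozen regression: z = -2, I = 0.0455, 0 degC, a0 = 4.0 with the shipped
  # A = 0.4913, B = 0.3247 gives gamma = 0.46962 (hand evaluation)
  expect_equal(debyeHuckelGamma(-2, 0.0455, 0), 0.469622, tolerance = 1e-5)

  # gamma in (0, 1], decreasing with |charge| at fixed I
  I <- 0.0455
  g <- vapply(0:4, debyeHuckelGamma, numeric(1), I = I, temperatureC = 0)
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(diff(g) < 0))

  # all coefficients -> 1 as I -> 0
  for (z in c(-2, -1, 1, 2))
    expect_equal(debyeHuckelGamma(z, 1e-12, 0), 1, tolerance = 1e-5)
})

test_that("Setchenow salting-out coefficient follows 10^(ks I)", {
  expect_equal(setchenowGamma(0), 1)
  expect_equal(setchenowGamma(0.5, ks = 0), 1)
  expect_equal(setchenowGamma(0.0455, ks = 0.1), 1.010532, tolerance = 1e-5)
  expect_gte(setchenowGamma(1, ks = 0.1), 1)
})

test_that("gas partial pressure applies the water-vapor correction", {
  ctx0 <- gasContext("O2", moleFraction = 0)
  expect_equal(gasPartialPressure(ctx0), 0)
  ctx1 <- gasContext("O2", moleFraction = 1, totalPressureBar = 1,
                     waterVaporPressureBar = 0)
  expect_equal(gasPartialPressure(ctx1), 1)
  expect_equal(gasPartialPressure(gasContext("O2")), 0.21 * (1 - 0.00611),
               tolerance = 1e-12)
})

test_that("Henry's-law maxima reproduce cold-water oxygen solubility and are linear", {
  expect_equal(as.numeric(maxDissolvedGas(gasContext("O2",
                                                     moleFraction = 0))), 0)
  o2 <- maxDissolvedGas(gasContext("O2"))
  expect_equal(as.numeric(o2), 4.4e-4, tolerance = 0.05)
  expect_equal(attr(o2, "mg_per_L"), 14, tolerance = 0.05)

  # linear in mole fraction and in the Henry constant
  half <- maxDissolvedGas(gasContext("O2", moleFraction = 0.105))
  expect_equal(as.numeric(half) * 2, as.numeric(o2), tolerance = 1e-12)
  doubled <- maxDissolvedGas(gasContext("O2",
                                        henryConstant = 2 * 2.10e-3))
  expect_equal(as.numeric(doubled), 2 * as.numeric(o2), tolerance = 1e-9)

  # dissolved nitrogen at 0 degC from the shipped constant
  n2 <- maxDissolvedGas(gasContext("N2"))
  expect_equal(as.numeric(n2), 1.04e-3 * 0.78 * (1 - 0.00611),
               tolerance = 1e-12)

  expect_error(gasContext("Ar"), "Ar")
  expect_error(gasContext("O2", temperatureC = 25), "25")
})

test_that("species activities follow the phase conventions", {
  s <- borup06b()
  expect_identical(speciesActivity("S0", s), c(1, 1))
  expect_identical(speciesActivity("H2O", s), c(1, 1))
  expect_equal(speciesActivity("H+", s), rep(10^-6.5, 2))
  expect_equal(speciesActivity("H+", s, includePHUncertainty = TRUE),
               10^-c(7.0, 6.0))

  act <- sampleActivities(s)
  for (a in act) expect_true(a[1] <= a[2] + 1e-15)

  # an ion's activity is its concentration scaled by its gamma
  I <- ionicStrength(s)
  conc <- modelConcentrations(s)[["SO4--"]]
  g <- debyeHuckelGamma(-2, I, 0, a0 = 4.0)
  expect_equal(act[["SO4--"]], conc * g, tolerance = 1e-12)

  expect_error(speciesActivity("NO2-", ChemSample("x",
    data.frame(species = "Total Na", status = "measured",
               low = 1e-3, high = 1e-3), pH = 7, temperatureC = 0)),
    "NO2-")
})

test_that("chemistry model mapping honors speciation and unit rules", {
  s <- borup06b()
  conc <- modelConcentrations(s)
  # alkalinity 163 mg/L as bicarbonate -> 2.67e-3 M
  expect_equal(conc[["HCO3-"]][1], 163 / 61.016 * 1e-3, tolerance = 1e-9)
  # DOC 11.4 mg C/L as acetate (2 C per molecule) -> 4.75e-4 M
  expect_equal(conc[["Acetate-"]][1], 11.4 / (2 * 12.011) * 1e-3,
               tolerance = 1e-9)
  # ferrous iron interval capped at measured total iron (1 uM < 5 uM DL)
  expect_equal(conc[["Fe++"]][2], 1e-6, tolerance = 1e-12)
  # below-detection thiosulfate spans floor to detection limit
  expect_equal(conc[["S2O3--"]], c(1e-12, 2e-6), tolerance = 1e-12)
  # sulfide split: HS- and H2S shares sum to the total interval
  tot <- conc[["HS-"]] + conc[["H2S(aq)"]]
  expect_equal(tot[2], 5e-6, tolerance = 1e-9)

  # CaCO3 alkalinity basis doubles the equivalents per formula mass
  s2 <- borupChemistry(alkalinityBasis = "CaCO3")[["BF09-06b"]]
  expect_equal(modelConcentrations(s2)[["HCO3-"]][1],
               2 * 163 / 100.087 * 1e-3, tolerance = 1e-9)
})
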
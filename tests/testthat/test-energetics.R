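test_that("equation parsing and balance validation hold for the shipped set", {
  st <- parseEquation("S0 + 1.5 O2(aq) + H2O -> SO4-- + 2 H+")
  expect_equal(st[["S0"]], -1)
  expect_equal(st[["O2(aq)"]], -1.5)
  expect_equal(st[["SO4--"]], 1)
  expect_equal(st[["H+"]], 2)
  expect_error(parseEquation("A + B"), "->")

  rx <- defaultReactions()
  expect_length(rx, 14)
  cn <- defaultConstants()
  for (r in rx) {
    expect_true(validateReaction(r, cn))
    # independent balance sums straight from the registry
    s <- stoichiometry(r)
    z <- vapply(names(s), speciesCharge, integer(1))
    expect_equal(sum(s * z), 0, tolerance = 1e-9)
    sulfur <- vapply(names(s), function(sp) {
      el <- cn$species[[sp]]$elements$S
      if (is.null(el)) 0 else el
    }, numeric(1))
    expect_equal(sum(s * sulfur), 0, tolerance = 1e-9)
  }
  expect_error(
    Reaction("bad", "S0 + O2(aq) -> SO4--", electrons = 6, constants = cn),
    "balance")
})

test_that("logK derivation: tabulated identity and van't Hoff against hand arithmetic", {
  cn <- defaultConstants()
  tab <- Reaction("tab", c("HS-" = -1, "H+" = 1, "H2S(aq)" = -1,
                           "SO4--" = 1)[c(1, 2)], electrons = 1,
                  logK = 3.21, logKTemperatureK = 273.15)
  expect_equal(as.numeric(logKAtTemperature(tab, 273.15)), 3.21)
  expect_identical(attr(logKAtTemperature(tab, 273.15), "route"),
                   "tabulated")

  # independent oracle: formation values read from the YAML, constant-dH
  # van't Hoff evaluated inline for S0 + 1.5 O2(aq) + H2O -> SO4-- + 2 H+
  sp <- cn$species
  dG <- sp[["SO4--"]]$dGf - (1.5 * sp[["O2(aq)"]]$dGf + sp[["H2O"]]$dGf)
  dH <- sp[["SO4--"]]$dHf - (1.5 * sp[["O2(aq)"]]$dHf + sp[["H2O"]]$dHf)
  dS <- (dH - dG) / 298.15
  oracle <- -(dH - 273.15 * dS) / (log(10) * 8.3145e-3 * 273.15)
  got <- logKAtTemperature(defaultReactions()$s0_o2, 273.15)
  expect_equal(as.numeric(got), oracle, tolerance = 1e-9)
  expect_equal(as.numeric(got), 102.8575, tolerance = 1e-3)
  expect_identical(attr(got, "route"), "vant_hoff")

  # at the reference temperature the derivation reduces to -dG298/(ln10 R T)
  got298 <- logKAtTemperature(defaultReactions()$s0_o2, 298.15)
  expect_equal(as.numeric(got298), -dG / (log(10) * 8.3145e-3 * 298.15),
               tolerance = 1e-9)

  r <- Reaction("mystery", c("X" = -1, "H+" = 1), electrons = 1)
  expect_error(logKAtTemperature(r, 273.15), "X")
})

test_that("reaction quotients are additive and respect interval monotonicity", {
  cn <- defaultConstants()
  ctx <- new("EnergyContext", temperatureK = 273.15,
             activities = list("A" = c(1, 1), "B" = c(1, 1)),
             sampleName = "synthetic")
  cn$species$A <- list(charge = 0, phase = "aqueous")
  cn$species$B <- list(charge = 0, phase = "aqueous")
  r <- new("Reaction", id = "ab", name = "ab", stoich = c(A = -1, B = 1),
           electrons = 1, logK = 0, logKTemperatureK = NA_real_)
  expect_equal(reactionQuotient(r, ctx, cn), c(0, 0))

  ctx@activities$B <- c(2, 2)
  expect_equal(reactionQuotient(r, ctx, cn), rep(log(2), 2))

  # interval: product low with reactant high gives the lower endpoint
  ctx@activities$A <- c(0.5, 2); ctx@activities$B <- c(0.25, 4)
  q <- reactionQuotient(r, ctx, cn)
  expect_equal(q, c(log(0.25) - log(2), log(4) - log(0.5)))

  s <- borup06b()
  ctxS <- buildEnergyContext(s, overrides = list("O2(aq)" = 4.4e-4))
  qS <- reactionQuotient(defaultReactions()$s0_o2, ctxS, cn)
  # hand evaluation: ln a(SO4) + 2 ln a(H+) - 1.5 ln a(O2)
  a <- ctxS@activities
  expect_equal(qS[1],
               log(a[["SO4--"]][1]) + 2 * log(a[["H+"]][2]) -
                 1.5 * log(a[["O2(aq)"]][1]), tolerance = 1e-12)
})

test_that("deltaG vanishes at equilibrium, scales homogeneously, and obeys Hess", {
  cn <- defaultConstants()
  rx <- defaultReactions()
  s <- borup06b()
  ctx <- buildEnergyContext(s)

  # Q == K gives exactly zero for every shipped reaction
  for (r in rx) {
    q <- reactionQuotient(r, ctx, cn)
    rEq <- Reaction(reactionId(r), stoichiometry(r),
                    electronsTransferred(r),
                    logK = q[1] / log(10), logKTemperatureK = 273.15)
    res <- deltaG(rEq, ctx, cn)
    expect_equal(res@deltaG[1], 0, tolerance = 1e-9)
  }

  # doubling stoichiometry and electrons leaves the per-electron value alone
  r <- rx$s0_o2
  r2 <- Reaction("s0_o2_x2", 2 * stoichiometry(r),
                 2 * electronsTransferred(r))
  g1 <- deltaG(r, ctx, cn)
  g2 <- deltaG(r2, ctx, cn)
  expect_equal(g2@deltaGPerElectron, g1@deltaGPerElectron, tolerance = 1e-9)
  expect_equal(g2@deltaG, 2 * g1@deltaG, tolerance = 1e-9)

  # Hess: the stoichiometric sum of two reactions has the summed dGr at a
  # point (degenerate-interval) context
  ctxPt <- buildEnergyContext(s, overrides = list(
    "SO3--" = 1e-6, "Mn++" = 1e-6, "H3AsO3" = 1e-9, "H2AsO4-" = 1e-9,
    "HS-" = 1e-7, "S2O3--" = 1e-7, "NO2-" = 1e-7, "Fe++" = 1e-7,
    "N2(aq)" = 8e-4, "Br-" = 1e-7, "PO4---" = 1e-7, "H2S(aq)" = 1e-7))
  sum_st <- stoichiometry(rx$s0_o2)
  st2 <- stoichiometry(rx$so3_o2)
  for (sp in names(st2))
    sum_st[sp] <- st2[sp] + if (sp %in% names(sum_st)) sum_st[[sp]] else 0
  rSum <- Reaction("sum", sum_st[sum_st != 0], electrons = 8)
  gSum <- deltaG(rSum, ctxPt, cn)
  expect_equal(gSum@deltaG[1],
               deltaG(rx$s0_o2, ctxPt, cn)@deltaG[1] +
                 deltaG(rx$so3_o2, ctxPt, cn)@deltaG[1],
               tolerance = 1e-9)

  # dGr strictly increasing in lnQ at fixed K and T
  g_lo <- deltaG(r, buildEnergyContext(s, overrides = list("O2(aq)" = 1e-4)),
                 cn)
  g_hi <- deltaG(r, buildEnergyContext(s, overrides = list("O2(aq)" = 1e-8)),
                 cn)
  expect_lt(g_lo@deltaG[1], g_hi@deltaG[1])
})

test_that("interval results contain point evaluations at interior activities", {
  cn <- defaultConstants()
  rx <- defaultReactions()
  s <- borup06b()
  ctx <- buildEnergyContext(s)
  set.seed(42)
  for (rep in 1:20) {
    r <- rx[[sample(length(rx), 1)]]
    interval <- deltaG(r, ctx, cn)@deltaG
    ov <- lapply(ctx@activities, function(a)
      exp(runif(1, log(a[1]), log(a[2]))))
    ctxPt <- new("EnergyContext", temperatureK = ctx@temperatureK,
                 activities = lapply(ov, function(x) c(x, x)),
                 sampleName = "interior")
    pt <- deltaG(r, ctxPt, cn)@deltaG[1]
    expect_gte(pt, interval[1] - 1e-9)
    expect_lte(pt, interval[2] + 1e-9)
  }
})

test_that("total available energy follows the limiting reactant", {
  cn <- defaultConstants()
  rx <- defaultReactions()
  s <- borup06b()
  ctx <- buildEnergyContext(s)
  inv <- defaultInventory(s, constants = cn)

  res <- totalEnergy(deltaG(rx$s0_o2, ctx, cn), rx$s0_o2, inv)
  expect_identical(res@limitingReactant, "S0")
  # S0 spans 10-100% of 1 kg dry mass: the energy interval spans 10x the
  # inventory spread (dGr itself is degenerate for this reaction)
  expect_equal(res@totalKJ[2] / res@totalKJ[1], 10, tolerance = 1e-6)
  # and equals |dGr| times (mass fraction / molar mass) at both ends
  extent <- 0.10 * 1000 / 32.066
  expect_equal(res@totalKJ[1], -deltaG(rx$s0_o2, ctx, cn)@deltaG[2] * extent,
               tolerance = 1e-9)

  # zero inventory -> zero energy
  inv0 <- inv
  inv0@moles[["S0"]] <- c(0, 0)
  expect_equal(totalEnergy(deltaG(rx$s0_o2, ctx, cn), rx$s0_o2,
                           inv0)@totalKJ, c(0, 0))

  # an endergonic reaction yields nothing
  rBad <- Reaction("rev", -stoichiometry(rx$s0_o2), electrons = 6)
  resBad <- totalEnergy(deltaG(rBad, ctx, cn), rBad, inv)
  expect_equal(resBad@totalKJ[1], 0)

  # a reactant without inventory or replenished flag errors by name
  invMiss <- inv
  invMiss@moles[["NH4+"]] <- NULL
  expect_error(totalEnergy(deltaG(rx$anammox, ctx, cn), rx$anammox,
                           invMiss), "NH4\\+")
})

test_that("the energy landscape ranks reactions deterministically", {
  rx <- defaultReactions()
  s <- borup06b()
  land1 <- energyLandscape(rx["s0_o2"], s, o2Scan = list("max"))
  expect_equal(nrow(land1), 1)
  single <- deltaG(rx$s0_o2, buildEnergyContext(s))
  expect_equal(land1$dGr_per_e_lo, single@deltaGPerElectron[1])

  land <- energyLandscape(rx, s, o2Scan = list("max", 1e-10))
  expect_equal(nrow(land), 28)
  expect_setequal(unique(land$scenario_aO2), c("max", "1e-10"))
  for (scen in unique(land$scenario_aO2)) {
    sub <- land[land$scenario_aO2 == scen, ]
    expect_equal(sort(sub$rank_per_e), 1:14)
    expect_true(all(diff(sub$dGr_per_e_lo[order(sub$rank_per_e)]) >= 0))
  }
  # deterministic: a rerun gives an identical table
  expect_identical(land, energyLandscape(rx, s, o2Scan = list("max", 1e-10)))
})
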
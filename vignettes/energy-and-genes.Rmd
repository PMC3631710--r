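---
title: "From field chemistry to metabolism: the models behind LithoMet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From field chemistry to metabolism: the models behind LithoMet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LithoMet)
```

LithoMet asks a geomicrobiological question: given the water chemistry of an
environment, which redox reactions could feed microbial life, how much energy
does each offer, and do the functional genes found in a shotgun metagenome of
that environment line up with the energetic ranking? The package implements
the three quantitative layers of that comparison — catabolic free-energy
landscapes, normalized relative abundances (NRA) of functional genes, and
Poisson genome coverage — together with simulators that generate every input
with known ground truth. The worked examples throughout use the shipped
chemistry of a cold sulfide spring and its glacial elemental-sulfur deposit
(samples BF09-01 and BF09-06b).

## 1. The free-energy model

For each catabolic reaction the in-situ Gibbs free energy is

$$\Delta G_r = R\,T\,\ln(Q/K),$$

with $R = 8.3145\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$, $T$ in Kelvin, $Q$ the
reaction quotient over in-situ activities, and $K$ the equilibrium constant
at $T$. Negative values are energy-yielding; dividing by the moles of
electrons transferred puts reactions with different stoichiometries on a
common per-electron scale.

**Equilibrium constants.** Reactions may carry a tabulated $\log K$; the
shipped set instead derives $\log K(T)$ from standard formation values
($\Delta G^\circ_f$, $\Delta H^\circ_f$ at 25 °C, NBS/Wagman-style
compilations) by the constant-enthalpy van't Hoff route:
$\Delta G^\circ(T) = \Delta H^\circ_{298} - T\,\Delta S^\circ_{298}$. Over
the 25 °C → 0 °C span this approximation is conventional in low-temperature
geochemistry and changes $\log K$ by far less than the activity intervals
change $Q$. The derivation route is recorded on every result.

**Activities.** Concentrations become activities by the standard
low-temperature conventions: pure solids and water have unit activity,
$a_{H^+} = 10^{-\mathrm{pH}}$ directly, ions are corrected with the extended
Debye–Hückel expression

$$\log_{10}\gamma = \frac{-A z^2 \sqrt I}{1 + B\,a_0 \sqrt I},$$

with $A, B$ interpolated between their 0 °C and 25 °C values, Kielland
ion-size parameters $a_0$ (default 4.0 Å for species without one), and
$I = \tfrac12\sum c_i z_i^2$; dissolved gases are corrected with the
Setchenow salting-out factor $10^{k_s I}$ (default
$k_s = 0.1$ L mol$^{-1}$, configurable per gas — at
$I \approx 0.046$ mol L$^{-1}$ this is a ~1 % effect, so the generic default
is safe). The literature offers several "standard" Debye–Hückel variants;
at this ionic strength they differ by under 3 % in $\gamma$, which is why the
package documents its choice in the constants file rather than modeling the
alternatives.

```{r}
s <- borupChemistry()[["BF09-06b"]]
ionicStrength(s)
debyeHuckelGamma(-2, ionicStrength(s), temperatureC = 0)
```

**Dissolved gases.** Surface-exposed deposits exchange O₂, N₂ and CO₂ with
the atmosphere, so the dissolved maximum is the Henry's-law equilibrium
$c_\max = K_H\,X\,(P_{tot} - p_{H_2O})$, using the water-vapor-corrected
partial pressure (0.00611 bar at 0 °C and 1 bar total). Shipped Henry
constants are 0 °C values; the O₂ constant
($2.10\times10^{-3}$ mol L$^{-1}$ bar$^{-1}$, within the spread of published
0 °C constants) reproduces the familiar ~14 mg/L cold-water oxygen
saturation:

```{r}
maxDissolvedGas(gasContext("O2"))
```

**Intervals, not points.** Species below detection are carried as intervals
from a floor of $10^{-12}$ mol L$^{-1}$ (effectively zero, configurable) up
to the detection limit. Elements assayed only as totals (As, Mn) get the
reduced-species convention: the reduced form (arsenite; Mn²⁺) spans the
floor up to the full total, so the interval covers "all oxidized" through
"all reduced"; the default reduced species are those stable near pH 6.5
(H₃AsO₃, Mn²⁺). Because $\ln Q$ is monotone in each activity, interval
endpoints of $\Delta G_r$ follow by assigning every species its
quotient-extremizing endpoint, and every interior assignment provably falls
inside the interval (property-tested by randomized interior sampling).
Interval activity coefficients use the ionic strength at the
high-concentration endpoint; below-detection species contribute so little
that the low-endpoint $I$ differs by well under 1 %.

Three further conventions fill gaps a field dataset always has. Dissolved
organic carbon is modeled as acetate (mg C/L divided by 2 × 12.011 g C per
mole); alkalinity becomes bicarbonate on a declared basis (default
"as HCO₃⁻", switchable to "as CaCO₃" — the two differ by <5 % in ionic
strength here); total sulfide splits between H₂S and HS⁻ using
p$K_{a1}$(0 °C) = 7.33. Sulfite, which ion chromatography did not report, is
assumed below the same 2 µM detection limit as thiosulfate, since both
cycle rapidly wherever sulfide meets oxidants. Water activity is taken as
unity throughout — appropriate at $I < 0.05$.

**The reaction set.** There is no single canonical list of candidate
catabolic reactions for a site, so the package ships a documented,
user-replaceable default of 14: aerobic oxidation of sulfide, elemental sulfur, thiosulfate
and sulfite; aerobic acetate oxidation; anammox; both nitrification steps;
aerobic Fe(II), Mn(II) and As(III) oxidation; S⁰ and thiosulfate
disproportionation; and nitrate-coupled S⁰ oxidation. Every reaction is
charge- and element-balance checked at load time.

**Total energy.** Per-mole energies ignore how much reactant is actually
there. The inventory layer fixes a basis — default 1 kg dry deposit plus
1 L porewater per kg, always reported — and computes reaction extent from
the scarcest non-replenished reactant. Elemental sulfur contributes 10–100 %
of the dry mass (the deposit is nearly pure S⁰; the interval hedges against
admixed gypsum and ice), dissolved species contribute concentration × volume,
and atmospheric gases are replenished by diffusion. Only rankings are
claimed from these totals, and they are robust to the basis because S⁰
dominates the mass by orders of magnitude:

```{r}
land <- energyLandscape(defaultReactions(), s, o2Scan = list("max", 1e-10))
head(land[land$scenario_aO2 == "max",
          c("reaction", "dGr_per_e_lo", "dGr_per_e_hi",
            "total_kJ_lo", "total_kJ_hi")], 6)
```

The oxygen scan (default: atmospheric maximum, $10^{-6}$, $10^{-10}$)
models oxygen drawdown beneath the deposit surface; even at an O₂ activity
of $10^{-10}$, sulfur oxidation stays strongly exergonic (about
−90 kJ per mole of electrons here).

## 2. Functional-gene abundance (NRA)

The metagenome layer consumes an annotated hit table (BLAST outfmt-6 or a
pre-joined TSV), not raw reads: alignment and annotation are upstream tools'
jobs. Quantification follows four steps, each with the convention that
matters stated explicitly:

1. **Filter** at e-value ≤ 10⁻¹⁰ and identity ≥ 50 % (the usual
   functional-annotation cutoffs; both configurable).
2. **Deduplicate** per (read, gene family): annotation pipelines record a
   read once per equally good hit, so the best record (smallest e-value,
   ties by identity then first occurrence) is kept and a read can never
   count twice against one family. A read may still count once in each of
   several families, matching per-gene quantification; a strict mode that
   drops cross-family ties is a documented alternative, not the default.
3. **Normalize**: NRA = count / (gene length in kb) / (copies per genome).
   Longer and multi-copy genes accrue more hits from randomly sheared
   DNA; lengths and copy numbers are explicit inputs (taken from whichever
   organisms dominate the best hits), never database lookups.
4. **Attach 99 % confidence intervals**: with $p = k/n$ over the total
   retained hits $n$, $SE = \sqrt{p(1-p)/n}$, the count-scale interval
   $n(p \pm 2.58\,SE)$ is divided by the same length/copy factor as the
   point estimate (clamped at zero). Using the binomial on counts and
   transforming preserves "error bars on NRA" without inventing a variance
   model for the normalized scale. By default $n$ is the total retained
   hits across the quantified families — self-contained and reproducible —
   with an option to supply the library's total annotated protein-coding
   hits instead; the choice cancels in comparisons between families
   quantified in the same run.

Two families differ significantly at $p = 0.01$ exactly when their 99 %
intervals are disjoint (touching endpoints overlap); no multiple-comparison
correction is applied by default, with an optional conservative flag left to
the user. Monte-Carlo checks in the test suite confirm ~99 % coverage of
the interval and ≥95 % recovery of generating NRA ratios on simulated
tables.

## 3. Genome coverage

Given per-OTU SSU-rRNA read proportions $A_i$ and reference genome sizes
$G_i$, the expected share of the shotgun library from OTU $i$ is
$P_i = G_i A_i / \sum_j G_j A_j$; its mean coverage from a library of $T$
total base pairs is $m_i = P_i T / G_i$; and under the Poisson model of
shotgun sequencing the expected sequenced fraction of its genome is
$1 - e^{-m_i}$. OTUs without a known reference size default to 3 Mb. The
formatter reports $m$ and percentages to two decimals, as conventionally
printed, while full precision is kept internally.

```{r}
taxa <- readTaxa(system.file("extdata", "taxa_synthetic.tsv",
                             package = "LithoMet"))
coverageTable(taxa, totalBp = 514016777)[, c("otu", "P", "m",
                                             "pct_included_2dp")]
```

The shipped taxa table is synthetic — invented proportions shaped like a
sulfur-spring community — and exists to exercise the estimator, not to
reconstruct any published coverage table.

## 4. What the simulators emulate — and what they do not

`simulateHitTable()` draws reads multinomially across taxa in proportion to
cell abundance × genome size, drops each read into a gene family with
probability (length × copies)/genome, and gives on-gene hits log-uniform
e-values over $10^{-30}$–$10^{-5}$ and identities over 30–100 %, so both
annotation cutoffs are genuinely exercised and the analytic pass probability
is known. Duplicates (same read, same gene, strictly worse score) are
injected at a configurable rate; off-target spurious hits carry e-values
above the cutoff so the standard filter removes them. The closed-form truth
(library proportions, expected raw and retained counts, expected NRA)
accompanies every table. `simulateReadCoverage()` places uniform read starts
on a circular genome — circular to avoid edge effects irrelevant to the
Poisson model — and returns the realized covered fraction.
`makeChemistryFixture()` applies unit-mean log-normal noise of a given CV to
measured concentrations while preserving below-detection statuses.

These generators reproduce the *counting* structure of real data, not its
content: no sequence bases are simulated, e-values are not linked to
identity or read length, community composition has no phylogenetic
structure, and chemistry noise is independent across analytes. Passing tests
therefore demonstrate that the estimators are correct under their own
statistical assumptions — binomial sampling of reads, Poisson coverage,
multiplicative assay error — not that those assumptions hold in any
particular field dataset.

All generators run on a private seeded RNG stream: identical seeds give
byte-identical outputs, and the global random state is untouched.

## 5. Numerical and design notes

* Units: mol/L internally (readers convert mM/µM), °C at interfaces and
  Kelvin internally, pressures in bar, energies in kJ. The below-detection
  floor ($10^{-12}$ M), thresholds and the CI multiplier are `runConfig()`
  parameters with the conventional defaults stated above.
* pH uncertainty (±0.5 on paper-strip deposit measurements) is carried as
  metadata; the point value is used unless `includePHUncertainty = TRUE`
  folds it into the H⁺ activity interval.
* Landscape ordering is deterministic: within a scenario, rows rank by the
  most-negative per-electron endpoint and by largest total energy, ties
  broken alphabetically by reaction id.
* Degenerate inputs error early and by name: unknown species, missing
  Henry constants, unbalanced reactions, zero denominators, reactants with
  neither inventory nor a replenished flag.
* Problem sizes in the test suite — 2,000-replicate CI coverage, 200
  simulated libraries of 2×10⁴ reads, 100 random tables of up to 10⁴ hits,
  coverage simulations on 1 Mb genomes — were chosen so the whole suite
  runs in about a minute while keeping every stochastic assertion at least
  three standard errors wide.
* Known limitations: no aqueous speciation solving (dominant As/Mn species
  are inputs), no Pitzer/SIT activity models for brines, no kinetics or
  growth-yield modeling, and no temperature model for Henry constants
  beyond the shipped 0 °C values.
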
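# LithoMet

Does the energy available from redox chemistry predict which microbial
metabolisms an environment actually hosts? LithoMet implements the
quantitative toolkit for answering that question in chemolithotrophic
settings — worked out here for a cold sulfide spring and the elemental-sulfur
deposit it feeds on a High-Arctic glacier, but applicable to any site with a
water analysis and a shotgun metagenome. It is aimed at geomicrobiologists
and environmental bioinformaticians who want the energetic and genomic sides
of that comparison computed reproducibly from explicit inputs.

Three quantitative layers, plus simulators:

* **Catabolic free-energy landscapes.** For each reaction,
  ΔG_r = RT ln(Q/K) over in-situ activity *intervals*: extended
  Debye–Hückel corrections for ions (log₁₀γ = −Az²√I / (1 + B a₀√I)),
  Setchenow salting-out for dissolved gases (10^(k_s I)), Henry's-law
  atmospheric maxima for O₂/N₂/CO₂ with the water-vapor-corrected partial
  pressure X(P − p_H₂O), van't Hoff equilibrium constants from standard
  formation values, below-detection species carried as
  [10⁻¹² M, detection limit] intervals, and total available energy from
  reactant inventories with limiting-reactant accounting.
* **Functional-gene abundance.** From annotated hit tables
  (BLAST outfmt-6): filter (e ≤ 10⁻¹⁰, identity ≥ 50 %), deduplicate per
  (read, gene family), normalize to NRA = hits / kb / gene copy, and attach
  99 % binomial confidence intervals (±2.58·SE with SE = √(p(1−p)/n));
  families with disjoint intervals differ significantly at p = 0.01.
* **Poisson genome coverage.** P_i = G_iA_i / Σ G_jA_j,
  m_i = P_iT / G_i, expected sequenced genome fraction 1 − e^(−m).
* **Synthetic data.** Hit-table, read-placement and chemistry-perturbation
  generators with closed-form ground truth, so the whole chain is testable
  offline.

## Worked example

The shipped fixture carries the field chemistry of spring water (BF09-01)
and of water extracted from the sulfur deposit (BF09-06b), with detection
limits. Dissolved-oxygen ceiling at 0 °C, then the energy landscape:

```r
library(LithoMet)
s <- borupChemistry()[["BF09-06b"]]

maxDissolvedGas(gasContext("O2"))
#> [1] 0.0004383055
#> attr(,"mg_per_L")
#> [1] 14.0249
```

About 4.4×10⁻⁴ mol/L (14 mg/L): air-saturated near-freezing water, the
oxygen ceiling inside the surface-exposed deposit.

```r
land <- energyLandscape(defaultReactions(), s, o2Scan = list("max", 1e-10))
head(land[land$scenario_aO2 == "max",
          c("reaction", "dGr_per_e_lo", "dGr_per_e_hi", "total_kJ_hi",
            "rank_total")], 6)
#>    reaction dGr_per_e_lo dGr_per_e_hi total_kJ_hi rank_total
#>      so3_o2      -118.98      -102.51   4.759e-04         11
#>  acetate_o2      -106.18      -106.18   4.031e-01          3
#>     anammox      -102.88       -90.60   3.395e-03          6
#>     s2o3_o2       -99.44       -95.32   1.591e-03          7
#>       s0_o2       -98.65       -98.65   1.846e+04          1
#>       hs_o2       -96.79       -92.41   4.989e-04         10
```

Read this as: per mole of electrons, aerobic oxidation of the reduced
sulfur species (sulfite, thiosulfate, elemental sulfur, sulfide), of
organic carbon (as acetate) and anammox are the most exergonic reactions
(≈ −90 to −119 kJ/mol e⁻, with intervals spanning the below-detection
uncertainty), but on the total-energy basis (1 kg dry deposit + 1 L
porewater) aerobic S⁰ oxidation dwarfs everything else — up to ~1.8×10⁴ kJ,
four orders beyond the runner-up — because the deposit *is* elemental
sulfur. At an O₂ activity of 10⁻¹⁰ (the `1e-10` scenario rows) S⁰ oxidation
still yields about −90 kJ/mol e⁻.

Gene quantification from a simulated annotated hit table with known truth:

```r
spec <- communitySpec(
  data.frame(taxon = "cell", proportion = 1, genome_bp = 2e6),
  data.frame(taxon = "cell", family = c("soxB", "dsrA"),
             length_bp = c(2190, 1332), copy_number = 1))
sim <- simulateHitTable(spec, 2e5, seed = 11)
nraTable(sim$hits, data.frame(family = c("soxB", "dsrA"),
                              length_bp = c(2190, 1332), copy_number = 1))
#>  family   k n_total   nra ci_low ci_high    z
#>    soxB 125     188 57.08  49.45   64.70 2.58
#>    dsrA  63     188 47.30  34.76   59.83 2.58
```

Both families sit at the same per-genome density by construction, and their
99 % intervals overlap accordingly (`compareNRA()` returns
`not_significant`).

Coverage of a (synthetic) community by a 514-Mbp library:

```r
taxa <- readTaxa(system.file("extdata", "taxa_synthetic.tsv",
                             package = "LithoMet"))
coverageTable(taxa, totalBp = 514016777)[, c("otu", "P", "m",
                                             "pct_included_2dp")]
#>             otu       P     m pct_included_2dp
#>      Sulfurovum 0.50137 99.12           100.00
#>   Sulfuricurvum 0.26295 45.05           100.00
#>  Flavobacterium 0.13884 21.63           100.00
#>           other 0.07468 12.80           100.00
#>    Burkholderia 0.02019  1.44            76.35
#>       Ralstonia 0.00196  0.18            16.49
```

Dominant taxa are expected to be fully captured; rare ones only
fractionally.

The pipeline runners (`runEnergy()`, `runNRA()`, `runCoverage()`,
`runSimulate()`) wrap these functions with TSV outputs, `#`-comment config
headers and JSON run manifests; see the vignette
(`vignettes/energy-and-genes.Rmd`) for the models, conventions and
limitations.

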
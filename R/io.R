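# Readers and writers for the table dialects the pipeline speaks:
# chemistry CSV/TSV, BLAST tabular (outfmt 6) hit tables, gene-spec and
# taxon-abundance TSVs, and '#'-commented TSV outputs with JSON manifests.

readDelim <- function(path, header = TRUE, colClasses = NA) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = header, sep = sep, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE, fill = FALSE,
                    blank.lines.skip = TRUE, colClasses = colClasses,
                    check.names = FALSE, na.strings = c("NA", ""))
}

unitToMolar <- function(value, unit, path, row) {
  f <- c(M = 1, mM = 1e-3, uM = 1e-6)[[unit]]
  if (is.null(f) || is.na(f))
    stop(path, ":", row, ": unknown concentration unit '", unit, "'")
  value * f
}

#' Read a chemistry table into ChemSample objects
#'
#' Expects a delimited file with columns \code{sample}, \code{species},
#' \code{value}, \code{value_high} (optional second value where two methods
#' bracket a measurement), \code{unit} (\code{M}, \code{mM}, \code{uM};
#' \code{mg/L} for alkalinity/DOC), \code{detection_limit},
#' \code{uncertainty} and \code{status} (\code{measured} or
#' \code{below_detection}). Rows named \code{pH}, \code{temperature},
#' \code{alkalinity} and \code{DOC} populate the sample metadata; all other
#' rows become mol/L concentration intervals (below-detection rows span
#' \code{[floor, detection limit]}).
#'
#' @param path CSV/TSV file.
#' @param floor below-detection floor concentration, mol/L.
#' @param alkalinityBasis basis for alkalinity mg/L values: \code{"HCO3"}
#'   (default) or \code{"CaCO3"}.
#' @return named list of [ChemSample-class] objects.
#' @export
readChemistry <- function(path, floor = 1e-12, alkalinityBasis = "HCO3") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readDelim(path)
  need <- c("sample", "species", "value", "unit", "status")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  if (!"value_high" %in% names(tab)) tab$value_high <- NA_real_
  if (!"detection_limit" %in% names(tab)) tab$detection_limit <- NA_real_
  if (!"uncertainty" %in% names(tab)) tab$uncertainty <- NA_real_
  out <- list()
  for (s in unique(tab$sample)) {
    t1 <- tab[tab$sample == s, , drop = FALSE]
    meta <- list(pH = NA_real_, pHsd = 0, temperatureC = NA_real_,
                 alkalinity = 0, DOC = 0)
    rows <- list()
    for (i in seq_len(nrow(t1))) {
      r <- t1[i, ]
      rowNo <- as.integer(rownames(t1)[i])
      if (r$species == "pH") {
        meta$pH <- r$value
        if (!is.na(r$uncertainty)) meta$pHsd <- r$uncertainty
      } else if (r$species == "temperature") {
        meta$temperatureC <- r$value
      } else if (r$species == "alkalinity") {
        if (r$unit != "mg/L")
          stop(path, ":", rowNo, ": alkalinity must be in mg/L")
        meta$alkalinity <- r$value
      } else if (r$species == "DOC") {
        if (r$unit != "mg/L")
          stop(path, ":", rowNo, ": DOC must be in mg/L")
        meta$DOC <- r$value
      } else if (r$unit %in% c("%w")) {
        next  # solid-phase extras are not aqueous species
      } else if (r$status == "below_detection") {
        if (is.na(r$detection_limit))
          stop(path, ":", rowNo, ": below-detection row without a detection limit")
        dl <- unitToMolar(r$detection_limit, r$unit, path, rowNo)
        rows[[length(rows) + 1L]] <-
          data.frame(species = r$species, status = "below_detection",
                     low = floor, high = dl, stringsAsFactors = FALSE)
      } else {
        lo <- unitToMolar(r$value, r$unit, path, rowNo)
        hi <- if (is.na(r$value_high)) lo
              else unitToMolar(r$value_high, r$unit, path, rowNo)
        rows[[length(rows) + 1L]] <-
          data.frame(species = r$species, status = "measured",
                     low = lo, high = hi, stringsAsFactors = FALSE)
      }
    }
    out[[s]] <- ChemSample(name = s, species = do.call(rbind, rows),
                           pH = meta$pH, pHsd = meta$pHsd,
                           temperatureC = meta$temperatureC,
                           alkalinity = meta$alkalinity, DOC = meta$DOC,
                           alkalinityBasis = alkalinityBasis)
  }
  out
}

#' Write ChemSample objects back to a TSV chemistry table
#'
#' Emits the canonical dialect [readChemistry()] reads (concentrations in
#' mol/L), so read -> write -> read round-trips the sample objects.
#'
#' @param samples list of [ChemSample-class] objects.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeChemistry <- function(samples, path) {
  rows <- list()
  for (s in samples) {
    sp <- speciesTable(s)
    for (i in seq_len(nrow(sp))) {
      bdl <- sp$status[i] == "below_detection"
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sampleName(s), species = sp$species[i],
        value = if (bdl) NA_real_ else sp$low[i],
        value_high = if (!bdl && sp$high[i] > sp$low[i]) sp$high[i]
                     else NA_real_,
        unit = "M",
        detection_limit = if (bdl) sp$high[i] else NA_real_,
        uncertainty = NA_real_, status = sp$status[i],
        stringsAsFactors = FALSE)
    }
    extra <- function(species, value, unit, unc = NA_real_)
      data.frame(sample = sampleName(s), species = species, value = value,
                 value_high = NA_real_, unit = unit,
                 detection_limit = NA_real_, uncertainty = unc,
                 status = "measured", stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- extra("alkalinity", s@alkalinity, "mg/L")
    rows[[length(rows) + 1L]] <- extra("DOC", s@DOC, "mg/L")
    rows[[length(rows) + 1L]] <-
      extra("pH", s@pH, "su", if (s@pHsd > 0) s@pHsd else NA_real_)
    rows[[length(rows) + 1L]] <- extra("temperature", s@temperatureC, "C")
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Accepts either the 12-column headerless BLAST tabular dialect (query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score) plus a
#' gene-to-family mapping, or a pre-joined headered TSV that already carries
#' a \code{family} column.
#'
#' @param path hit-table file.
#' @param familyMap optional data.frame (\code{gene_id}, \code{family})
#'   mapping subject ids to gene families; required for the raw BLAST
#'   dialect. Subject ids without a mapping keep their own id as family.
#' @return data.frame with columns read_id, gene_id, family, evalue,
#'   pct_identity.
#' @export
readHits <- function(path, familyMap = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 50)
  first <- first[!startsWith(first, "#")][1]
  if (is.na(first)) stop(path, ": empty hit table")
  headered <- grepl("read_id", first, fixed = TRUE)
  if (headered) {
    tab <- readDelim(path)
    checkHitFrame(tab)
    return(tab[, c("read_id", "gene_id", "family", "evalue",
                   "pct_identity")])
  }
  raw <- readDelim(path, header = FALSE)
  if (ncol(raw) != 12)
    stop(path, ": expected 12 BLAST tabular columns, found ", ncol(raw))
  hits <- data.frame(read_id = as.character(raw[[1]]),
                     gene_id = as.character(raw[[2]]),
                     evalue = as.numeric(raw[[11]]),
                     pct_identity = as.numeric(raw[[3]]),
                     stringsAsFactors = FALSE)
  if (!is.null(familyMap)) {
    stopifnot(all(c("gene_id", "family") %in% names(familyMap)))
    fam <- familyMap$family[match(hits$gene_id, familyMap$gene_id)]
    hits$family <- ifelse(is.na(fam), hits$gene_id, fam)
  } else hits$family <- hits$gene_id
  hits[, c("read_id", "gene_id", "family", "evalue", "pct_identity")]
}

#' Read a gene-specification table
#'
#' @param path TSV/CSV with columns \code{family}, \code{length_bp},
#'   \code{copy_number}.
#' @return validated data.frame.
#' @export
readGeneSpecs <- function(path) {
  tab <- readDelim(path)
  need <- c("family", "length_bp", "copy_number")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  if (any(tab$length_bp < 1) || any(tab$copy_number <= 0))
    stop(path, ": gene specs need length_bp >= 1 and copy_number > 0")
  tab
}

#' Read a taxon-abundance table for coverage estimation
#'
#' @param path TSV/CSV with columns \code{otu}, \code{abundance_proportion}
#'   and optionally \code{genome_size_bp} (blank = use the default genome
#'   size downstream).
#' @return validated data.frame.
#' @export
readTaxa <- function(path) {
  tab <- readDelim(path)
  need <- c("otu", "abundance_proportion")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing columns ", paste(miss, collapse = ", "))
  if (any(tab$abundance_proportion < 0))
    stop(path, ": abundances must be non-negative")
  tab
}

#' Assemble and validate a run configuration
#'
#' Collects the pipeline's tunable thresholds with their conventional
#' defaults: annotation cutoffs 1e-10 / 50%, 0 degC, a 1e-12 M
#' below-detection floor, the 99% confidence multiplier 2.58, an oxygen scan
#' of the atmospheric maximum down to 1e-10, and a 3 Mb default genome.
#'
#' @param maxEvalue,minIdentity hit-filtering thresholds.
#' @param temperatureC analysis temperature, degC.
#' @param floor below-detection floor, mol/L.
#' @param z confidence multiplier.
#' @param o2Scan list of O2 scenarios (\code{"max"} or activities).
#' @param totalBp metagenome library size, bp (coverage runs).
#' @param defaultGenomeBp fallback genome size, bp.
#' @param seed integer seed for stochastic stages.
#' @param outDir output directory.
#' @return validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(maxEvalue = 1e-10, minIdentity = 50,
                      temperatureC = 0, floor = 1e-12, z = 2.58,
                      o2Scan = list("max", 1e-6, 1e-10),
                      totalBp = NULL, defaultGenomeBp = 3e6,
                      seed = 1L, outDir = ".") {
  stopifnot(maxEvalue > 0, minIdentity >= 0, minIdentity <= 100,
            floor > 0, z > 0, defaultGenomeBp > 0)
  structure(list(maxEvalue = maxEvalue, minIdentity = minIdentity,
                 temperatureC = temperatureC, floor = floor, z = z,
                 o2Scan = o2Scan, totalBp = totalBp,
                 defaultGenomeBp = defaultGenomeBp, seed = as.integer(seed),
                 outDir = outDir),
            class = "RunConfig")
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  cfg <- unclass(config)
  cfg$outDir <- NULL   # hash covers analysis parameters, not file locations
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                              digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

writeOutputTSV <- function(df, path, config, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", configHash(config)), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeManifest <- function(outDir, stage, inputs, config, outputs) {
  manifest <- list(stage = stage, inputs = inputs,
                   config = unclass(config), outputs = outputs,
                   package_version =
                     as.character(utils::packageVersion("LithoMet")),
                   r_version = R.version.string)
  path <- file.path(outDir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the free-energy landscape stage
#'
#' Reads a chemistry table, evaluates the reaction set over the configured
#' oxygen scan, and writes \code{energy_landscape.tsv} plus a JSON run
#' manifest to the output directory.
#'
#' @param chemistryPath chemistry CSV/TSV (see [readChemistry()]).
#' @param sample which sample in the file to analyse.
#' @param reactionsPath reaction YAML; NULL = the shipped default set.
#' @param config a [runConfig()].
#' @return the landscape data.frame, invisibly.
#' @export
runEnergy <- function(chemistryPath, sample, reactionsPath = NULL,
                      config = runConfig()) {
  constants <- defaultConstants()
  samples <- readChemistry(chemistryPath, floor = config$floor)
  if (!sample %in% names(samples))
    stop("sample '", sample, "' not present in ", chemistryPath)
  reactions <- if (is.null(reactionsPath)) defaultReactions(constants)
               else readReactions(reactionsPath, constants)
  land <- energyLandscape(reactions, samples[[sample]],
                          o2Scan = config$o2Scan, constants = constants)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$outDir, "energy_landscape.tsv")
  writeOutputTSV(land, out, config)
  writeManifest(config$outDir, "energy",
                list(chemistry = chemistryPath, sample = sample,
                     reactions = if (is.null(reactionsPath)) "default"
                                 else reactionsPath),
                config, list(landscape = out))
  invisible(land)
}

#' Run the NRA quantification stage
#'
#' Filters, deduplicates and normalizes a hit table, writes
#' \code{nra.tsv} (and \code{nra_significance.tsv} when requested) plus a
#' JSON manifest.
#'
#' @param hitsPath hit table (see [readHits()]).
#' @param geneSpecsPath gene-spec TSV.
#' @param familyMapPath optional gene-to-family mapping TSV.
#' @param significance also write the pairwise significance matrix.
#' @param config a [runConfig()].
#' @return the NRA data.frame, invisibly.
#' @export
runNRA <- function(hitsPath, geneSpecsPath, familyMapPath = NULL,
                   significance = FALSE, config = runConfig()) {
  fam <- if (is.null(familyMapPath)) NULL else readDelim(familyMapPath)
  hits <- readHits(hitsPath, familyMap = fam)
  specs <- readGeneSpecs(geneSpecsPath)
  tab <- nraTable(hits, specs, maxEvalue = config$maxEvalue,
                  minIdentity = config$minIdentity, z = config$z)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$outDir, "nra.tsv")
  writeOutputTSV(tab, out, config)
  outputs <- list(nra = out)
  if (significance) {
    sig <- significanceMatrix(tab)
    sigPath <- file.path(config$outDir, "nra_significance.tsv")
    writeOutputTSV(data.frame(family = rownames(sig), sig,
                              check.names = FALSE), sigPath, config)
    outputs$significance <- sigPath
  }
  writeManifest(config$outDir, "nra",
                list(hits = hitsPath, gene_specs = geneSpecsPath),
                config, outputs)
  invisible(tab)
}

#' Run the genome-coverage stage
#'
#' @param taxaPath taxon-abundance TSV (see [readTaxa()]).
#' @param totalBp total library base pairs; overrides the config value.
#' @param config a [runConfig()].
#' @return the coverage data.frame, invisibly.
#' @export
runCoverage <- function(taxaPath, totalBp = NULL, config = runConfig()) {
  if (is.null(totalBp)) totalBp <- config$totalBp
  if (is.null(totalBp)) stop("totalBp must be given (config or argument)")
  taxa <- readTaxa(taxaPath)
  tab <- coverageTable(taxa, totalBp,
                       defaultGenomeBp = config$defaultGenomeBp)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$outDir, "coverage.tsv")
  writeOutputTSV(tab, out, config)
  writeManifest(config$outDir, "coverage", list(taxa = taxaPath), config,
                list(coverage = out))
  invisible(tab)
}

#' Run the simulation stage
#'
#' Generates a synthetic annotated hit table from a community specification
#' and writes it in the same dialect the NRA stage reads, with the
#' ground-truth expectations as a JSON sidecar. Deterministic in the config
#' seed.
#'
#' @param spec a [communitySpec()].
#' @param nReads reads to simulate.
#' @param config a [runConfig()] (seed and output directory).
#' @param ... further arguments to [simulateHitTable()].
#' @return list(hits, truth), invisibly.
#' @export
runSimulate <- function(spec, nReads, config = runConfig(), ...) {
  sim <- simulateHitTable(spec, nReads, seed = config$seed, ...)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$outDir, "simulated_hits.tsv")
  writeOutputTSV(sim$hits, out, config, seed = config$seed)
  truthPath <- file.path(config$outDir, "simulated_truth.json")
  jsonlite::write_json(sim$truth, truthPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeManifest(config$outDir, "simulate",
                list(n_reads = nReads, seed = config$seed), config,
                list(hits = out, truth = truthPath))
  invisible(sim)
}

#' The packaged field-chemistry fixture
#'
#' Loads the shipped sulfide-spring / sulfur-deposit water chemistry table
#' (spring source BF09-01 and deposit extract BF09-06b with instrument
#' detection limits).
#'
#' @inheritParams readChemistry
#' @return named list of [ChemSample-class] objects.
#' @export
borupChemistry <- function(floor = 1e-12, alkalinityBasis = "HCO3") {
  readChemistry(system.file("extdata", "chemistry_borup.tsv",
                            package = "LithoMet"),
                floor = floor, alkalinityBasis = alkalinityBasis)
}
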
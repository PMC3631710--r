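# Synthetic-data generators: annotated hit tables from communities with
# known composition, read-placement coverage draws, and perturbed chemistry
# tables. Every generator runs on its own seeded RNG stream and leaves the
# global random state untouched, so identical seeds reproduce identical
# outputs.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Specify a synthetic community
#'
#' @param taxa data.frame with columns \code{taxon}, \code{proportion}
#'   (cell abundance, >= 0, sum > 0) and \code{genome_bp}.
#' @param genes data.frame with columns \code{taxon}, \code{family},
#'   \code{length_bp}, \code{copy_number}: the gene complement of each taxon.
#' @return a validated list of class \code{"CommunitySpec"}.
#' @export
communitySpec <- function(taxa, genes) {
  stopifnot(all(c("taxon", "proportion", "genome_bp") %in% names(taxa)),
            all(c("taxon", "family", "length_bp", "copy_number") %in%
                  names(genes)))
  if (any(taxa$proportion < 0) || sum(taxa$proportion) <= 0)
    stop("taxon proportions must be non-negative with positive sum")
  if (any(taxa$genome_bp <= 0)) stop("genome sizes must be positive")
  if (any(genes$length_bp <= 0) || any(genes$copy_number <= 0))
    stop("gene lengths and copy numbers must be positive")
  if (!all(genes$taxon %in% taxa$taxon))
    stop("gene complement refers to unknown taxa")
  structure(list(taxa = taxa, genes = genes), class = "CommunitySpec")
}

# Closed-form expectations implied by a community spec and library size.
simTruth <- function(spec, nReads, pPass) {
  taxa <- spec$taxa
  genes <- spec$genes
  P <- libraryProportions(taxa$proportion, taxa$genome_bp)
  names(P) <- taxa$taxon
  fams <- sort(unique(genes$family))
  expHits <- vapply(fams, function(f) {
    g <- genes[genes$family == f, , drop = FALSE]
    sum(vapply(seq_len(nrow(g)), function(i) {
      G <- taxa$genome_bp[match(g$taxon[i], taxa$taxon)]
      P[[g$taxon[i]]] * g$length_bp[i] * g$copy_number[i] / G
    }, numeric(1))) * nReads
  }, numeric(1))
  expRetained <- expHits * pPass
  # expected NRA: retained count over length/copy of each family's
  # (first) spec entry — generators use one spec per family per taxon
  expNRA <- vapply(fams, function(f) {
    g <- genes[genes$family == f, , drop = FALSE][1, ]
    expRetained[[f]] / (g$length_bp / 1000) / g$copy_number
  }, numeric(1))
  list(library_proportions = P, expected_hits = expHits,
       expected_retained = expRetained, expected_nra = expNRA,
       p_pass = pPass)
}

#' Simulate an annotated metagenome hit table with known truth
#'
#' Reads are assigned to taxa multinomially with probability proportional to
#' cell abundance times genome size; a read from a taxon lands in gene
#' family f with probability (length_f x copies_f) / genome size. On-gene
#' hits receive log-uniform e-values spanning both sides of the 1e-10
#' annotation cutoff and identities spanning the 50% cutoff, so filtering is
#' genuinely exercised. Duplicate hits (same read, same gene, strictly worse
#' score) are injected at \code{dupRate}; off-target spurious hits (random
#' family, e-value above the cutoff) at \code{offtargetRate}.
#'
#' @param spec a [communitySpec()].
#' @param nReads number of reads to draw (> 0).
#' @param dupRate probability an on-gene hit gains a duplicate entry.
#' @param offtargetRate expected spurious hits per read.
#' @param evalueRange log10 e-value range for on-gene hits.
#' @param identityRange percent-identity range for on-gene hits.
#' @param seed integer seed (required: generators are deterministic).
#' @return list with \code{hits} (data.frame: read_id, gene_id, family,
#'   evalue, pct_identity) and \code{truth} (library proportions, expected
#'   raw and post-filter counts, expected NRA, the analytic pass
#'   probability).
#' @export
simulateHitTable <- function(spec, nReads, dupRate = 0.05,
                             offtargetRate = 0.02,
                             evalueRange = c(-30, -5),
                             identityRange = c(30, 100), seed) {
  stopifnot(inherits(spec, "CommunitySpec"), nReads > 0)
  if (dupRate < 0 || dupRate > 1 || offtargetRate < 0)
    stop("invalid noise rates")
  if (missing(seed)) stop("a seed is required")
  # analytic probability that an on-gene hit survives both filters
  pE <- (log10(1e-10) - evalueRange[1]) / diff(evalueRange)
  pE <- min(max(pE, 0), 1)
  pI <- (identityRange[2] - 50) / diff(identityRange)
  pI <- min(max(pI, 0), 1)
  truth <- simTruth(spec, nReads, pE * pI)
  withSeed(seed, {
    taxa <- spec$taxa; genes <- spec$genes
    P <- truth$library_proportions
    taxonOf <- sample(taxa$taxon, nReads, replace = TRUE, prob = P)
    readIdx <- integer(0); famOf <- character(0); taxOf <- character(0)
    for (tx in taxa$taxon) {
      i <- which(taxonOf == tx)
      if (!length(i)) next
      g <- genes[genes$taxon == tx, , drop = FALSE]
      if (!nrow(g)) next
      G <- taxa$genome_bp[match(tx, taxa$taxon)]
      pFam <- g$length_bp * g$copy_number / G
      # a uniform position either falls inside one gene or misses them all
      j <- findInterval(stats::runif(length(i)), cumsum(pFam)) + 1L
      on <- j <= nrow(g)
      readIdx <- c(readIdx, i[on])
      famOf <- c(famOf, g$family[j[on]])
      taxOf <- c(taxOf, rep(tx, sum(on)))
    }
    o <- order(readIdx)
    readIdx <- readIdx[o]; famOf <- famOf[o]; taxOf <- taxOf[o]
    hits <- data.frame(
      read_id = sprintf("read_%06d", readIdx),
      gene_id = paste(taxOf, famOf, sep = "|"),
      family = famOf,
      evalue = 10^stats::runif(length(readIdx), evalueRange[1],
                               evalueRange[2]),
      pct_identity = stats::runif(length(readIdx), identityRange[1],
                                  identityRange[2]),
      stringsAsFactors = FALSE)
    # duplicate injection: same read vs same gene, strictly worse score
    if (dupRate > 0 && nrow(hits)) {
      dup <- hits[stats::runif(nrow(hits)) < dupRate, , drop = FALSE]
      if (nrow(dup)) {
        dup$evalue <- dup$evalue * 10^stats::runif(nrow(dup), 0.5, 3)
        dup$pct_identity <- pmax(0, dup$pct_identity -
                                   stats::runif(nrow(dup), 0.1, 10))
        hits <- rbind(hits, dup)
      }
    }
    # off-target spurious annotations; e-values sit above the cutoff so the
    # standard filter removes them
    nOff <- stats::rpois(1, offtargetRate * nReads)
    if (nOff > 0) {
      fams <- unique(genes$family)
      off <- data.frame(
        read_id = sprintf("offtarget_%06d", seq_len(nOff)),
        gene_id = "spurious",
        family = sample(fams, nOff, replace = TRUE),
        evalue = 10^stats::runif(nOff, -9, -5),
        pct_identity = stats::runif(nOff, 30, 100),
        stringsAsFactors = FALSE)
      hits <- rbind(hits, off)
    }
    list(hits = hits, truth = truth)
  })
}

#' Simulate shotgun read placement on a circular genome
#'
#' Places ceiling(m G / L) uniform read starts on a circular genome of size
#' G and returns the realized covered fraction — the empirical check of the
#' Poisson prediction 1 - e^-m. The circular convention avoids edge effects
#' irrelevant to the model.
#'
#' @param genomeBp genome size, bp.
#' @param m target mean fold coverage (>= 0).
#' @param readLen read length, bp (0 < readLen < genomeBp).
#' @param seed integer seed.
#' @return realized covered fraction in [0, 1].
#' @export
simulateReadCoverage <- function(genomeBp, m, readLen, seed) {
  stopifnot(genomeBp > readLen, readLen > 0, m >= 0)
  if (m == 0) return(0)
  withSeed(seed, {
    n <- ceiling(m * genomeBp / readLen)
    starts <- sort(sample.int(genomeBp, n, replace = TRUE) - 1L)
    gaps <- diff(c(starts, starts[1] + genomeBp))
    uncovered <- sum(pmax(0, gaps - readLen))
    1 - uncovered / genomeBp
  })
}

#' Perturb a chemistry sample with multiplicative noise
#'
#' Multiplies every measured concentration (and alkalinity and DOC) by
#' log-normal noise with unit mean and the given coefficient of variation.
#' Below-detection species keep their status and interval untouched, so the
#' perturbed sample remains a valid chemistry record.
#'
#' @param sample a [ChemSample-class].
#' @param cv coefficient of variation of the noise (>= 0; 0 returns the
#'   sample unchanged).
#' @param seed integer seed.
#' @return a perturbed [ChemSample-class].
#' @export
makeChemistryFixture <- function(sample, cv, seed) {
  if (cv < 0) stop("perturbation must be non-negative")
  if (cv == 0) return(sample)
  withSeed(seed, {
    sdlog <- sqrt(log1p(cv^2))
    sp <- speciesTable(sample)
    meas <- which(sp$status == "measured")
    f <- stats::rlnorm(length(meas), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    sp$low[meas] <- sp$low[meas] * f
    sp$high[meas] <- sp$high[meas] * f
    out <- sample
    out@species <- sp
    out@alkalinity <- sample@alkalinity *
      stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    out@DOC <- sample@DOC * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    methods::validObject(out)
    out
  })
}
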
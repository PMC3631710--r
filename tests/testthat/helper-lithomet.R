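# Shared fixtures and independent oracles used across the suite.

testConstants <- function() defaultConstants()

borup06b <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- borupChemistry()[["BF09-06b"]]
    cache
  }
})

# A random annotated hit table with duplicates and threshold-straddling
# scores, for oracle-equivalence checks.
randomHitTable <- function(n, nReads = max(1, n %/% 2), seed) {
  fams <- c("soxB", "dsrA", "sqr", "aclB")
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); force(expr)
  }
  withr_seed(data.frame(
    read_id = sprintf("r%05d", sample.int(nReads, n, replace = TRUE)),
    gene_id = sample(paste0("g", 1:8), n, replace = TRUE),
    family = sample(fams, n, replace = TRUE),
    evalue = 10^runif(n, -30, -5),
    pct_identity = runif(n, 30, 100),
    stringsAsFactors = FALSE))
}

# Brute-force oracle for the filter -> dedup -> count pipeline, written as a
# plain group-by so it shares no code with the production path.
bruteforceFamilyCounts <- function(hits, maxEvalue = 1e-10,
                                   minIdentity = 50) {
  kept <- hits[hits$evalue <= maxEvalue & hits$pct_identity >= minIdentity, ]
  if (!nrow(kept)) return(integer(0))
  groups <- split(kept, paste(kept$read_id, kept$family, sep = "\r"))
  best <- lapply(groups, function(g) {
    g <- g[g$evalue == min(g$evalue), , drop = FALSE]
    g <- g[g$pct_identity == max(g$pct_identity), , drop = FALSE]
    g[1, , drop = FALSE]
  })
  tab <- table(vapply(best, function(g) g$family, character(1)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Two-taxon community whose families have known per-genome gene densities.
makeTestCommunity <- function() {
  # small genomes keep per-family expected counts large enough for tight
  # stochastic assertions at modest read numbers
  taxa <- data.frame(taxon = c("epsilon", "flavo"),
                     proportion = c(0.7, 0.3),
                     genome_bp = c(2e5, 3e5),
                     stringsAsFactors = FALSE)
  genes <- data.frame(
    taxon = c("epsilon", "epsilon", "flavo"),
    family = c("soxB", "dsrA", "soxB"),
    length_bp = c(2000, 1500, 2000),
    copy_number = c(1, 1, 1),
    stringsAsFactors = FALSE)
  communitySpec(taxa, genes)
}
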
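# Poisson genome-coverage estimator: how much of each taxon's genome a
# shotgun library of known size is expected to capture, from SSU-rRNA read
# proportions and reference genome sizes.

#' Library proportions from taxon abundances and genome sizes
#'
#' P_i = G_i A_i / sum_j(G_j A_j): a taxon's share of the shotgun library is
#' its read abundance weighted by genome size (bigger genomes contribute
#' more DNA per cell), renormalized to sum to one.
#'
#' @param abundance numeric vector of SSU-rRNA read proportions (>= 0; need
#'   not sum to 1).
#' @param genomeBp genome sizes, bp (> 0).
#' @return numeric vector of library proportions summing to 1.
#' @export
libraryProportions <- function(abundance, genomeBp) {
  stopifnot(length(abundance) == length(genomeBp))
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (any(genomeBp <= 0)) stop("genome sizes must be positive")
  w <- abundance * genomeBp
  tot <- sum(w)
  if (tot <= 0) stop("all abundances are zero; proportions undefined")
  w / tot
}

#' Mean genome coverage of a taxon
#'
#' m = P * T / G: the taxon's share of the library's total base pairs spread
#' over its genome.
#'
#' @param P library proportion.
#' @param totalBp total post-quality-control base pairs in the library.
#' @param genomeBp genome size, bp.
#' @return fold coverage.
#' @export
meanCoverage <- function(P, totalBp, genomeBp) {
  stopifnot(totalBp > 0, all(genomeBp > 0))
  P * totalBp / genomeBp
}

#' Fraction of a genome included in the library
#'
#' Under the Poisson model of shotgun sequencing, a base is missed with
#' probability e^-m, so the expected sequenced fraction is 1 - e^-m.
#'
#' @param m mean fold coverage (>= 0).
#' @return fraction in [0, 1).
#' @export
fractionIncluded <- function(m) {
  if (any(m < 0)) stop("mean coverage must be non-negative")
  1 - exp(-m)
}

#' Per-taxon coverage table
#'
#' Applies [libraryProportions()], [meanCoverage()] and
#' [fractionIncluded()] across a taxon table. Taxa without a genome size
#' receive \code{defaultGenomeBp} (3 Mb, the usual assumption for
#' low-abundance phylotypes).
#'
#' @param taxa data.frame with columns \code{otu},
#'   \code{abundance_proportion} and optionally \code{genome_size_bp}
#'   (NA = use default).
#' @param totalBp total library base pairs.
#' @param defaultGenomeBp fallback genome size, bp.
#' @return data.frame (sorted by decreasing coverage): otu, genome_bp, P, m,
#'   pct_included (percent, full precision) and pct_included_2dp (formatted
#'   to two decimals as conventionally reported).
#' @export
coverageTable <- function(taxa, totalBp, defaultGenomeBp = 3e6) {
  stopifnot(all(c("otu", "abundance_proportion") %in% names(taxa)))
  G <- if ("genome_size_bp" %in% names(taxa)) taxa$genome_size_bp
       else rep(NA_real_, nrow(taxa))
  G[is.na(G)] <- defaultGenomeBp
  P <- libraryProportions(taxa$abundance_proportion, G)
  m <- meanCoverage(P, totalBp, G)
  out <- data.frame(otu = taxa$otu, genome_bp = G, P = P, m = m,
                    pct_included = 100 * fractionIncluded(m),
                    stringsAsFactors = FALSE)
  out$pct_included_2dp <- sprintf("%.2f", out$pct_included)
  out[order(-out$m, out$otu), ]
}
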
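# Functional-gene quantification from annotated shotgun-metagenome hit
# tables: filtering, per-family deduplication, normalized relative abundance
# (NRA) with binomial confidence intervals, and pairwise significance calls.

checkHitFrame <- function(hits) {
  need <- c("read_id", "gene_id", "family", "evalue", "pct_identity")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table missing columns: ", paste(miss, collapse = ", "))
  invisible(hits)
}

#' Filter metagenome hits on e-value and percent identity
#'
#' Keeps hits with \code{evalue <= maxEvalue} and
#' \code{pct_identity >= minIdentity} (defaults 1e-10 and 50, the usual
#' annotation cutoffs for functional-gene calling); input order is preserved.
#'
#' @param hits data.frame with columns \code{read_id}, \code{gene_id},
#'   \code{family}, \code{evalue}, \code{pct_identity}.
#' @param maxEvalue maximum e-value retained.
#' @param minIdentity minimum percent identity retained.
#' @return the filtered data.frame.
#' @export
filterHits <- function(hits, maxEvalue = 1e-10, minIdentity = 50) {
  checkHitFrame(hits)
  stopifnot(is.finite(maxEvalue), is.finite(minIdentity))
  keep <- hits$evalue <= maxEvalue & hits$pct_identity >= minIdentity
  keep[is.na(keep)] <- FALSE
  hits[keep, , drop = FALSE]
}

#' Remove duplicate hits of a read against the same gene family
#'
#' At most one record is retained per (read, family) pair — the hit with the
#' smallest e-value, ties broken by highest identity and then first
#' occurrence — so a read can never be counted twice against the same gene.
#' A read may still count once in each of several families (equally good top
#' hits against different genes).
#'
#' @param hits hit data.frame (see [filterHits()]).
#' @return deduplicated data.frame, best hits first within original order.
#' @export
dedupHits <- function(hits) {
  checkHitFrame(hits)
  if (!nrow(hits)) return(hits)
  ord <- order(hits$evalue, -hits$pct_identity, seq_len(nrow(hits)))
  key <- paste(hits$read_id, hits$family, sep = "\r")
  kept <- ord[!duplicated(key[ord])]
  hits[sort(kept), , drop = FALSE]
}

#' Normalized relative abundance of a gene family
#'
#' NRA = count / (gene length in kb) / (copies per genome): hit counts made
#' comparable across families by correcting for the extra hits that longer
#' or multi-copy genes accrue.
#'
#' @param k quality-controlled hit count (>= 0).
#' @param lengthBp gene length, bp (> 0).
#' @param copyNumber copies per genome (> 0; fractional values allowed for
#'   mixed references).
#' @return hits per kb per copy.
#' @export
nra <- function(k, lengthBp, copyNumber = 1) {
  if (any(lengthBp <= 0)) stop("gene length must be positive")
  if (any(copyNumber <= 0)) stop("copy number must be positive")
  if (any(k < 0)) stop("counts must be non-negative")
  k / (lengthBp / 1000) / copyNumber
}

#' NRA with a binomial confidence interval
#'
#' Treats the family's count k as a binomial draw out of \code{nTotal}
#' retained hits: p = k/n, SE = sqrt(p(1-p)/n). The count-scale interval
#' n(p +/- z SE) is divided by the same length/copy normalization as the
#' point estimate; the lower bound is clamped at 0. The default z = 2.58
#' gives 99% confidence.
#'
#' @param k family hit count (0 <= k <= nTotal).
#' @param nTotal total retained hits in the analysis (> 0).
#' @param lengthBp gene length, bp.
#' @param copyNumber copies per genome.
#' @param z confidence multiplier.
#' @param family optional family label carried through.
#' @return one-row data.frame: family, k, n_total, nra, ci_low, ci_high, z.
#' @export
nraCI <- function(k, nTotal, lengthBp, copyNumber = 1, z = 2.58,
                  family = NA_character_) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (k < 0 || k > nTotal) stop("k must lie in [0, nTotal]")
  p <- k / nTotal
  se <- sqrt(p * (1 - p) / nTotal)
  countLo <- max(0, nTotal * (p - z * se))
  countHi <- nTotal * (p + z * se)
  denom <- (lengthBp / 1000) * copyNumber
  data.frame(family = family, k = k, n_total = nTotal,
             nra = nra(k, lengthBp, copyNumber),
             ci_low = countLo / denom, ci_high = countHi / denom,
             z = z, stringsAsFactors = FALSE)
}

#' NRA table for all gene families in a hit table
#'
#' Runs the filter -> deduplicate -> count pipeline and attaches confidence
#' intervals. By default n is the total number of retained hits across the
#' quantified families; supply \code{nTotal} to use a different denominator
#' (for example the total annotated protein-coding hits of the library).
#'
#' @param hits raw hit data.frame.
#' @param geneSpecs data.frame with columns \code{family}, \code{length_bp},
#'   \code{copy_number}.
#' @param maxEvalue,minIdentity filtering thresholds (see [filterHits()]).
#' @param nTotal denominator for the binomial proportion; default the total
#'   retained count.
#' @param z confidence multiplier (2.58 = 99%).
#' @return data.frame with one row per family in \code{geneSpecs}.
#' @export
nraTable <- function(hits, geneSpecs, maxEvalue = 1e-10, minIdentity = 50,
                     nTotal = NULL, z = 2.58) {
  stopifnot(all(c("family", "length_bp", "copy_number") %in% names(geneSpecs)))
  if (any(geneSpecs$length_bp < 1) || any(geneSpecs$copy_number <= 0))
    stop("gene specs must have length_bp >= 1 and copy_number > 0")
  h <- dedupHits(filterHits(hits, maxEvalue, minIdentity))
  unknown <- setdiff(unique(h$family), geneSpecs$family)
  if (length(unknown))
    stop("hit families missing from the gene-spec table: ",
         paste(unknown, collapse = ", "))
  k <- vapply(geneSpecs$family, function(f) sum(h$family == f), numeric(1))
  if (is.null(nTotal)) nTotal <- sum(k)
  if (nTotal <= 0)
    stop("no hits retained; cannot form binomial proportions")
  out <- do.call(rbind, lapply(seq_along(k), function(i)
    nraCI(k[[i]], nTotal, geneSpecs$length_bp[i], geneSpecs$copy_number[i],
          z = z, family = geneSpecs$family[i])))
  rownames(out) <- NULL
  out
}

#' Compare two NRA results for significance
#'
#' Two families differ significantly (at the confidence level of their
#' intervals; p = 0.01 for z = 2.58) exactly when their confidence intervals
#' do not overlap. Intervals sharing only an endpoint count as overlapping.
#'
#' @param a,b one-row data.frames as returned by [nraCI()] (or any objects
#'   with \code{ci_low}/\code{ci_high}).
#' @return \code{"significant"} or \code{"not_significant"}.
#' @export
compareNRA <- function(a, b) {
  disjoint <- a$ci_high < b$ci_low || b$ci_high < a$ci_low
  if (isTRUE(disjoint)) "significant" else "not_significant"
}

#' Pairwise significance matrix for an NRA table
#'
#' @param tab data.frame from [nraTable()].
#' @return logical matrix; TRUE where the two families' intervals are
#'   disjoint (significantly different).
#' @export
significanceMatrix <- function(tab) {
  n <- nrow(tab)
  m <- matrix(FALSE, n, n, dimnames = list(tab$family, tab$family))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j)
      m[i, j] <- compareNRA(tab[i, ], tab[j, ]) == "significant"
  m
}
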
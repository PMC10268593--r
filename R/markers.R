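# Unique best-hit assignment of conserved X-linked marker genes to scaffolds
# and an exact binomial test against the length-proportional null.

#' Best hit per query
#'
#' Keeps, per query, the hit with the smallest e-value; ties are broken by
#' larger bitscore, then longer alignment, then lexicographically smallest
#' subject, so the result is identical under any permutation of input rows.
#'
#' @param hits data frame from [read_hits_tsv()].
#' @return A data frame with one row per query: `query`, `subject`,
#'   `evalue`, `bitscore`, `aln_length`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) stopf("empty hit table")
  o <- order(hits$query, hits$evalue, -hits$bitscore, -hits$aln_length,
             hits$subject, method = "radix")
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query)
  out <- h[first, c("query", "subject", "evalue", "bitscore", "aln_length"),
           drop = FALSE]
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count best hits per scaffold
#'
#' Scaffolds with no hits are reported with an explicit zero.
#'
#' @param best best-hit table from [best_hits()].
#' @param scaffolds character vector of all scaffold names.
#' @return A named integer vector of counts, one entry per scaffold.
#' @export
scaffold_hit_counts <- function(best, scaffolds) {
  unknown <- setdiff(unique(best$subject), scaffolds)
  if (length(unknown) > 0L) {
    stopf("best hit on unknown scaffold '%s'", unknown[1])
  }
  counts <- stats::setNames(integer(length(scaffolds)), scaffolds)
  if (nrow(best) > 0L) {
    tab <- table(best$subject)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Exact binomial test of hit counts against length proportionality
#'
#' Under the null that markers land on scaffolds in proportion to scaffold
#' length, the count on scaffold i is Binomial(n, w_i) with w_i its length
#' share. The two-sided p-value sums the probabilities of all outcomes no
#' more likely than the observed one; q-values are Benjamini-Hochberg
#' adjusted across scaffolds.
#'
#' @param counts named vector of observed best-hit counts per scaffold.
#' @param lengths named vector of scaffold lengths (positive), covering
#'   every scaffold in `counts`.
#' @return A data frame: `scaffold`, `length`, `observed`, `expected`,
#'   `fold`, `p_value`, `q_value`.
#' @export
proportionality_test <- function(counts, lengths) {
  miss <- setdiff(names(counts), names(lengths))
  if (length(miss) > 0L) stopf("no length for scaffold '%s'", miss[1])
  lengths <- lengths[names(counts)]
  if (any(lengths <= 0)) stopf("scaffold lengths must be positive")
  n <- sum(counts)
  if (n < 1) stopf("no hits to test")
  w <- as.numeric(lengths) / sum(lengths)
  p <- vapply(seq_along(counts), function(i) {
    stats::binom.test(as.integer(counts[i]), n, w[i],
                      alternative = "two.sided")$p.value
  }, numeric(1))
  expected <- n * w
  data.frame(scaffold = names(counts), length = as.numeric(lengths),
             observed = as.integer(counts), expected = expected,
             fold = as.numeric(counts) / expected,
             p_value = pmin(p, 1), q_value = stats::p.adjust(pmin(p, 1), "BH"),
             stringsAsFactors = FALSE)
}

#' Combined depth + marker evidence report for the X scaffold
#'
#' Joins the copy-ratio calls with the marker-enrichment statistics. The
#' headline call names the single scaffold that is both hemizygous and
#' significantly hit-enriched (q below `alpha`, fold above 1); if no
#' scaffold, or more than one, satisfies both lines of evidence, the
#' headline is "no call".
#'
#' @param calls data frame from [classify_ploidy()].
#' @param stats data frame from [proportionality_test()].
#' @param alpha significance level on the BH-adjusted q-value (default 0.05).
#' @return A list: `table` (merged per-scaffold evidence), `headline`
#'   (scaffold name or `NA`), `reason`.
#' @export
x_evidence_report <- function(calls, stats, alpha = 0.05) {
  tab <- merge(calls, stats, by = "scaffold", all = TRUE, sort = TRUE)
  cand <- tab$scaffold[!is.na(tab$label) & tab$label == "hemizygous" &
                         !is.na(tab$q_value) & tab$q_value < alpha &
                         !is.na(tab$fold) & tab$fold > 1]
  if (length(cand) == 1L) {
    list(table = tab, headline = cand,
         reason = "unique scaffold with concordant depth and marker evidence")
  } else if (length(cand) == 0L) {
    list(table = tab, headline = NA_character_,
         reason = "no scaffold satisfies both evidence lines")
  } else {
    list(table = tab, headline = NA_character_,
         reason = sprintf("ambiguous: %d scaffolds satisfy both evidence lines (%s)",
                          length(cand), paste(cand, collapse = ", ")))
  }
}
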
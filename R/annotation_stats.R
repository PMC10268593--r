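# Intron statistics from a GFF3 annotation.

#' Infer intron lengths per transcript from exon features
#'
#' Exon features are grouped by their `Parent` attribute and sorted by
#' start; the intron between consecutive exons (s1,e1), (s2,e2) has length
#' s2 - e1 - 1 (1-based inclusive exon coordinates). Single-exon
#' transcripts map to an empty vector. Strand never enters: intron lengths
#' are coordinate differences.
#'
#' @param features data frame from [read_gff3()].
#' @return A named list mapping transcript id to an integer vector of
#'   intron lengths.
#' @export
infer_introns <- function(features) {
  ex <- features[features$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stopf("no exon features in input")
  if (anyNA(ex$Parent)) stopf("exon feature without a Parent attribute")
  # an exon may serve several transcripts (comma-separated parents)
  parents <- strsplit(ex$Parent, ",", fixed = TRUE)
  reps <- lengths(parents)
  ex <- ex[rep(seq_len(nrow(ex)), reps), , drop = FALSE]
  ex$Parent <- unlist(parents)
  out <- lapply(split(ex, ex$Parent), function(g) {
    if (length(unique(g$scaffold)) > 1L) {
      stopf("transcript '%s' has exons on several scaffolds", g$Parent[1])
    }
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1L && any(g$start[-1] <= g$end[-nrow(g)])) {
      stopf("transcript '%s' has overlapping exons", g$Parent[1])
    }
    if (nrow(g) == 1L) integer(0)
    else as.integer(g$start[-1] - g$end[-nrow(g)] - 1L)
  })
  out[order(names(out))]
}

#' Summary statistics of per-transcript intron lengths
#'
#' The headline statistic is the unweighted mean of per-transcript mean
#' intron lengths, over transcripts with at least one intron; the pooled
#' mean over all introns is reported alongside so either reading of a
#' "mean intron length per transcript" figure can be checked.
#'
#' @param per_transcript named list from [infer_introns()].
#' @return A list: `headline_mean` (mean of per-transcript means, `NA` if
#'   no transcript has introns), `pooled_mean`, `n_transcripts`,
#'   `n_transcripts_with_introns`, `n_introns`.
#' @export
intron_summary <- function(per_transcript) {
  if (length(per_transcript) == 0L) stopf("empty transcript mapping")
  n_introns <- sum(lengths(per_transcript))
  with_introns <- per_transcript[lengths(per_transcript) > 0L]
  if (length(with_introns) == 0L) {
    warnf("no transcript has introns; headline mean undefined")
    return(list(headline_mean = NA_real_, pooled_mean = NA_real_,
                n_transcripts = length(per_transcript),
                n_transcripts_with_introns = 0L, n_introns = 0L))
  }
  list(headline_mean = mean(vapply(with_introns, mean, numeric(1))),
       pooled_mean = mean(unlist(with_introns)),
       n_transcripts = length(per_transcript),
       n_transcripts_with_introns = length(with_introns),
       n_introns = n_introns)
}
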
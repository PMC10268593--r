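# Contiguity and composition statistics of a scaffold set.

#' Contiguity statistics (N50/L50) of a length multiset
#'
#' N50 is the length of the scaffold at which the descending cumulative sum
#' first reaches at least half of the total assembly length; L50 is the rank
#' of that scaffold. N50 is always an element of the input multiset.
#'
#' @param lengths positive integer scaffold lengths.
#' @return A list with `n_seqs`, `total_len`, `max_len`, `n50`, `l50`.
#' @export
contiguity_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stopf("empty length set")
  if (anyNA(lengths) || any(lengths < 1)) stopf("all lengths must be >= 1")
  sl <- sort(lengths, decreasing = TRUE)
  total <- sum(sl)
  l50 <- which(cumsum(sl) >= total / 2)[1]
  list(n_seqs = length(sl), total_len = total, max_len = sl[1],
       n50 = sl[l50], l50 = l50)
}

#' GC content of a set of nucleotide sequences
#'
#' (G+C) / (A+C+G+T), pooled over all sequences; N positions are excluded
#' from the denominator (assembly gap runs carry no composition signal).
#'
#' @param seqs named character vector over A/C/G/T/N (see [read_fasta()]).
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  set <- Biostrings::BStringSet(seqs)
  counts <- Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T"))
  acgt <- sum(counts)
  if (acgt == 0) stopf("no non-N bases in input")
  sum(counts[, c("G", "C")]) / acgt
}

#' Count and length share of scaffolds above a size threshold
#'
#' @param lengths positive scaffold lengths.
#' @param min_len threshold; scaffolds strictly longer are counted.
#' @return A list with `count` and `fraction_of_total_length`.
#' @export
length_fraction_above <- function(lengths, min_len) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stopf("empty length set")
  big <- lengths > min_len
  list(count = sum(big),
       fraction_of_total_length = if (sum(lengths) > 0) {
         sum(lengths[big]) / sum(lengths)
       } else 0)
}

#' Full assembly report
#'
#' Contiguity, GC content and the large-scaffold length share, mirroring
#' the summary table of a genome report.
#'
#' @param seqs named character vector of scaffold sequences.
#' @param min_large threshold defining "large" scaffolds (default 60 Mb).
#' @return A list combining [contiguity_stats()], `gc_fraction`,
#'   `n_large`, and `large_fraction`.
#' @export
assembly_report <- function(seqs, min_large = 6e7) {
  lens <- nchar(seqs)
  ct <- contiguity_stats(lens)
  lf <- length_fraction_above(lens, min_large)
  c(ct, list(gc_fraction = gc_content(seqs), min_large = min_large,
             n_large = lf$count, large_fraction = lf$fraction_of_total_length))
}
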
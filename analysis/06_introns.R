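#!/usr/bin/env Rscript
# Intron statistics: exon features grouped per transcript, intron lengths
# from the gaps between consecutive exons, and both readings of a "mean
# intron length per transcript" figure (mean of per-transcript means, and
# the pooled mean over all introns).

suppressPackageStartupMessages(library(hemiscan))

gff <- "scratch/sim/annotation.gff3"
if (!file.exists(gff)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

features <- read_gff3(gff)
per <- infer_introns(features)
s <- intron_summary(per)

tab <- data.frame(transcript = names(per),
                  n_introns = lengths(per),
                  mean_intron = vapply(per, function(x) {
                    if (length(x)) mean(x) else NA_real_
                  }, numeric(1)))
write.table(tab, "results/06_introns_per_transcript.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(s, "results/06_intron_summary.json", auto_unbox = TRUE,
                     digits = NA)

message(sprintf(
  "%d transcripts (%d with introns, %d introns total)",
  s$n_transcripts, s$n_transcripts_with_introns, s$n_introns))
message(sprintf(
  "mean intron length per transcript %.0f (pooled mean %.0f)",
  s$headline_mean, s$pooled_mean))
message("wrote results/06_introns_per_transcript.tsv and 06_intron_summary.json")
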
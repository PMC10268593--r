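#!/usr/bin/env Rscript
# Marker placement: unique best hit per conserved X-linked marker, counts
# per scaffold, and an exact binomial test of each scaffold's count
# against the length-proportional expectation. The combined report joins
# this with the depth calls into one headline X call.

suppressPackageStartupMessages(library(hemiscan))

if (!file.exists("scratch/sim/hits.tsv")) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

seqs <- read_fasta("scratch/sim/genome.fasta")
hits <- read_hits_tsv("scratch/sim/hits.tsv")
truth <- jsonlite::read_json("scratch/sim/truth.json")

b <- best_hits(hits)
lens <- setNames(nchar(seqs), names(seqs))
counts <- scaffold_hit_counts(b, names(lens))
stats <- proportionality_test(counts, lens)
write.table(stats[order(stats$q_value), ], "results/04_marker_stats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# join with the depth calls from the previous stage
calls <- jsonlite::read_json("results/03_xscan.json", simplifyVector = TRUE)$calls
report <- x_evidence_report(calls, stats)
jsonlite::write_json(list(headline = report$headline, reason = report$reason,
                          table = report$table),
                     "results/04_x_evidence.json", auto_unbox = TRUE,
                     digits = NA)

top <- stats[which.min(stats$q_value), ]
message(sprintf(
  "%d/%d markers best-hit the true X (%s); top enrichment: %s (%d observed vs %.1f expected, fold %.1f, q = %.3g)",
  counts[[truth$x_scaffold]], sum(counts), truth$x_scaffold,
  top$scaffold, top$observed, top$expected, top$fold, top$q_value))
message(sprintf("headline X call: %s (%s)", report$headline, report$reason))
message("wrote results/04_marker_stats.tsv and results/04_x_evidence.json")
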
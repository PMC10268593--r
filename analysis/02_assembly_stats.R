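#!/usr/bin/env Rscript
# Contiguity and composition of the simulated assembly: N50/L50, GC
# content, and the share of length held by chromosome-scale scaffolds.

suppressPackageStartupMessages(library(hemiscan))

fasta <- "scratch/sim/genome.fasta"
if (!file.exists(fasta)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

seqs <- read_fasta(fasta)
rep <- assembly_report(seqs, min_large = 1e6)

tab <- data.frame(statistic = c("n_scaffolds", "total_bp", "max_bp",
                                "n50_bp", "l50", "gc_pct",
                                "n_large_scaffolds", "large_length_pct"),
                  value = c(rep$n_seqs, rep$total_len, rep$max_len, rep$n50,
                            rep$l50, round(100 * rep$gc_fraction, 2),
                            rep$n_large, round(100 * rep$large_fraction, 2)))
write.table(tab, "results/02_assembly_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(rep, "results/02_assembly_stats.json",
                     auto_unbox = TRUE, digits = NA)

message(sprintf(
  "N50 %.2f Mb (L50 %d) over %d scaffolds; GC %.1f%%; scaffolds > 1 Mb hold %.1f%% of the length",
  rep$n50 / 1e6, rep$l50, rep$n_seqs, 100 * rep$gc_fraction,
  100 * rep$large_fraction))
message("wrote results/02_assembly_stats.{tsv,json}")
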
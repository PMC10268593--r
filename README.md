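# hemiscan

Identify the X chromosome of a male genome assembly from depth of
coverage, and compute the companion statistics of a genome report.

In a male with an XY or X0 sex-determination system the X is present in
one copy, so long reads cover X scaffolds at roughly half the autosomal
depth. `hemiscan` turns that observation into a tested analysis:

- **Depth scan** — per-base depth is averaged in 10 kb bins, GC-corrected
  by stratified median-ratio normalization
  (`norm = depth × median(all) / median(GC stratum)`), summarized per
  scaffold (median and central-95% interval of bin values), and classified
  by copy ratio *r* = median / reference (reference = length-weighted
  median across scaffolds): hemizygous for *r* ∈ [0.35, 0.65], diploid for
  *r* ∈ [0.80, 1.20], ambiguous otherwise.
- **Marker enrichment** — conserved X-linked proteins searched against the
  assembly (12-column tabular hits) are reduced to one best hit per query
  (minimal e-value, deterministic tie-breaks); per-scaffold counts are
  tested against the length-proportional null, count ~ Binomial(n, w_i)
  with w_i the scaffold's length share, using the exact two-sided binomial
  test with Benjamini–Hochberg correction. The headline X call requires a
  single scaffold with concordant depth *and* marker evidence.
- **Assembly statistics** — N50/L50 (descending cumulative sum reaching
  half the total), GC content (N excluded), large-scaffold length share.
- **Supermatrix curation** — per-locus missingness filter (taxa with >50%
  missing vs. the per-locus maximum), occupancy filter (>80% of the taxon
  list, focal taxon required), neighbor-joining screens on p-distance
  trees for terminal-branch outliers and paralog-contaminated loci (a
  reference clade split by an internal edge carrying ≥20% of tree length),
  and partitioned concatenation written as NEXUS/PHYLIP with charsets.
- **Intron statistics** — intron lengths from consecutive exons per
  transcript; both the mean of per-transcript means and the pooled mean.
- **Synthetic data** — seeded generators for every input (genome, binned
  depth with GC bias and negative-binomial noise, marker hits, amino-acid
  loci with injected paralogs, GFF3 annotation), each emitting ground
  truth, so the full workflow is testable without sequencing data.

The package is intended for genome-assembly teams who have a
chromosome-scale male assembly, a long-read depth track, and a set of
known sex-linked markers from a related taxon, and who want the
coverage/homology evidence for a sex scaffold made explicit and testable.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (seed 42). `analysis/01_simulate.R` writes the inputs to
`scratch/sim/`; the later stages consume those files through the package's
readers and write tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_xscan.R
Rscript analysis/04_markers.R
```

prints

```
simulated 12 scaffolds (21.4 Mb total); the true X is scaffold_07 (1.0 Mb)
...
classified 11 scaffolds against reference depth 28.48
hemizygous call: scaffold_07 (ratio 0.509); simulated truth: scaffold_07
...
62/100 markers best-hit the true X (scaffold_07); top enrichment:
scaffold_07 (62 observed vs 4.7 expected, fold 13.3, q = 3.51e-55)
headline X call: scaffold_07 (unique scaffold with concordant depth and marker evidence)
```

Reading the numbers: the simulated X was sequenced at copy ratio 0.5, and
the scan recovers a median normalized depth of 0.509× the genome-wide
reference — inside the hemizygous band — while no autosome leaves the
diploid band. Independently, 62 of 100 markers place on that scaffold
against a length-proportional expectation of 4.7, a 13-fold enrichment
with q ≈ 10⁻⁵⁵; the two evidence lines agree, so the headline call names
scaffold_07. The same functions (`xscan()`, `best_hits()`,
`proportionality_test()`, `x_evidence_report()`) take any FASTA + depth
BED + hit table.

The remaining stages compute assembly contiguity
(`analysis/02_assembly_stats.R`), curate 200 simulated loci into a
partitioned supermatrix while flagging injected paralogs
(`analysis/05_supermatrix.R`), and summarize intron lengths from the
simulated annotation (`analysis/06_introns.R`).

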
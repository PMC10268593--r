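---
title: "Coverage-based X identification and genome-report statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based X identification and genome-report statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hemiscan implements the bespoke computations behind a male insect genome
report: identifying the X chromosome from depth of coverage, corroborating
it with conserved X-linked marker genes, and the companion statistics
(assembly contiguity, phylogenomic supermatrix curation, intron lengths).
This vignette explains the models and the choices behind them; the worked
numbers it refers to are produced by the package's own tests and by
`scripts/acceptance.R`, not asserted here.

## The coverage model

In a male with an XY or X0 system, the X is present in one copy while
autosomes are present in two. Long reads from such an individual cover the
X at roughly half the autosomal depth, so the X can be identified from
binned depth alone. The scan proceeds in four steps.

**Binning.** Per-base depth (0-based, half-open intervals; positions absent
from the input count as depth 0) is averaged in fixed windows of
`bin_size` (default 10 kb): the bin mean is the overlap-weighted average of
interval depths. The trailing partial bin of each scaffold is kept but
flagged and excluded from everything downstream — its mean is an average
over fewer positions and correspondingly noisier.

**GC normalization.** Library preparation and sequencing chemistry make
depth depend on local GC content, typically unimodally. The bin GC is
(G+C)/(non-N bases) over the window, undefined when more than half the
window is N (assembly gap). Bins are stratified by GC in windows of width
0.01; each bin's depth is rescaled by (global median depth)/(stratum median
depth). This stratified median-ratio correction is the standard CNV-style
approach: it is robust to outliers, makes no assumption about the shape of
the bias, and is exactly testable (after normalization the Spearman
correlation between depth and GC should vanish, and the global median is
conserved by construction). Strata with fewer than `min_bins` (30) bins are
merged with the nearest populated stratum so that no bin is rescaled by a
noisy median; when no stratum reaches the minimum, all bins form one
stratum and the correction degrades gracefully to the identity.

**Summaries.** Per scaffold we report the median normalized depth and the
central 95% interval, i.e. the 2.5th and 97.5th percentiles of bin values
with linear interpolation (R's type-7 quantile). A "95% percentile range"
can also be read as the 5th–95th interval; the central reading matches the
convention of depicting 95% error bars and is what the package uses.
Scaffolds with fewer than 50 usable bins (0.5 Mb at the default bin size)
are excluded: a median over fewer bins is too unstable to classify.

**Classification.** The reference depth is the length-weighted median of
all scaffolds' medians (weights = bin counts), computed over *all*
classified scaffolds rather than "all but the candidate": the X is a small
minority of total length, so including it cannot move a weighted median,
and excluding candidates would make the reference depend on the answer.
Each scaffold's ratio (median/reference) is called hemizygous in
[0.35, 0.65], diploid in [0.80, 1.20], ambiguous otherwise. The bands are
deliberately wide: a true X sits near 0.5 and true autosomes near 1.0, and
anything between is evidence of collapsed repeats, mosaicism, or
mis-scaffolding rather than of a sex chromosome. Only scaffolds of at
least `min_scaffold_len` (1 Mb) enter classification, standing in for the
chromosome-scale "major scaffolds" a karyotype-level analysis considers.
Classification is invariant to rescaling all depths by a constant.

## Marker enrichment

Conserved X-linked proteins searched against the assembly (tblastn-style,
12-column tabular hits) give a second, independent line of evidence. Per
query we keep the hit with the smallest e-value; ties are broken by larger
bitscore, then longer alignment, then lexicographically smallest subject.
The tie chain beyond e-values is our own convention — its only purpose is
that the result is identical under any permutation of input rows. Queries
hitting nothing are reported separately and do not enter the denominator.

Under the null of no linkage, best hits fall on scaffold *i* with
probability equal to its length share $w_i$, so the count on scaffold *i*
is Binomial($n$, $w_i$). We test each scaffold with the exact two-sided
binomial test (summing the probabilities of all outcomes no more likely
than the observed one) and adjust across scaffolds with
Benjamini–Hochberg. The headline X call requires *concordant* evidence:
exactly one scaffold that is both hemizygous by depth and significantly
hit-enriched (q < 0.05, fold > 1). Zero or several such scaffolds yield
"no call" with both evidence lines reported.

No e-value or alignment-length floor is applied before best-hit selection
by default; both are configurable, since search sensitivity settings are a
property of the upstream search, not of this analysis.

## Assembly statistics

N50 is the length at which the descending cumulative sum of scaffold
lengths first reaches *at least* half the total (the standard convention);
L50 is that scaffold's rank. "Large scaffold" thresholds are strict
(length > threshold). GC content is (G+C)/(A+C+G+T) with N excluded from
the denominator — assemblies carry long gap runs whose inclusion would
dilute composition; whether a published GC figure includes Ns is often
unstated, so the choice is documented here rather than hidden.

## Supermatrix curation

Per-locus amino-acid alignments are curated in the order missingness →
occupancy → tree screens → missingness again → concatenation.

*Missingness.* Characters `-`, `?`, `X` (case-insensitive) count as
missing, following common aligner/trimmer output. A taxon is removed when
its missing fraction, measured against the largest per-taxon non-missing
count in the locus, strictly exceeds 0.5. The denominator could also be
read as the alignment length; we use the maximum non-missing count because
alignment length includes columns missing in every retained taxon, which
would understate everyone's completeness.

*Occupancy.* A locus is kept when it covers strictly more than 80% of the
full taxon list and always contains the focal taxon.

*Tree screens.* A neighbor-joining tree is built from uncorrected
p-distances over jointly non-missing sites (at least 20 shared sites per
pair, else an error naming the pair); negative NJ branch lengths are
clamped to zero. p-distances are deliberate: the screen is a curation
heuristic, not inference, and a model correction would add a choice to
defend without changing what the screen detects. Two screens follow, both
automations of what is usually done by eye, with explicit thresholds so
the decisions are reproducible and reportable:

- **Branch outliers**: a leaf is flagged when its terminal branch exceeds
  5× the median terminal branch *and* an absolute floor of 0.05
  substitutions/site. The floor prevents flagging in nearly identical
  alignments where the median is ~0 and any variation looks extreme.
- **Paralogs**: a locus is flagged when some reference clade (from the
  published phylogeny, supplied by the user) is non-monophyletic *and* an
  internal edge carrying at least 20% of the total tree length separates
  members of that clade. This is the signature of a deep duplication:
  sequences sampled from different gene copies join across the duplication
  edge, splitting a clade that the species phylogeny says is intact. Both
  conditions are required — non-monophyly alone is common estimation
  noise, and long internal edges alone are legitimate rate variation.

*Concatenation.* Survivors are concatenated in input order; absent taxa
are padded with `-`; partitions are recorded 1-based inclusive; per-taxon
missingness is recomputed over the full matrix. The matrix is written as
NEXUS with a charset block, relaxed PHYLIP, and a RAxML-style partition
file. Alignment, trimming, and ML inference are consumed and produced as
files; the package never reimplements them.

## Intron statistics

Introns are defined from exon features only (grouped by `Parent`, sorted
by start): the intron between consecutive exons $(s_1,e_1),(s_2,e_2)$ has
length $s_2-e_1-1$. "Mean intron length per transcript" is read as the
unweighted mean of per-transcript mean intron lengths over transcripts
with at least one intron; because published figures rarely state which
averaging they use, the pooled mean over all introns is always reported
alongside, so either reading can be checked. Strand never enters; intron
lengths are coordinate differences.

## The synthetic-data generators

Every pipeline input can be generated with ground truth, so the whole
workflow is testable without sequencing data. All generators are pure
functions of (config, seed): the RNG kind is pinned (Mersenne–Twister,
inversion, rejection sampling) and the caller's RNG state is restored.

**Genome.** 11 autosomes of 0.5–3 Mb and one 1 Mb X, i.i.d. bases in
10 kb blocks. Each block's GC target is drawn uniformly on [0.30, 0.55],
so every scaffold spans the genome-wide GC range, as real chromosome-scale
scaffolds do. This matters: if instead each scaffold occupied a narrow GC
band, GC strata around the X's band would be dominated by hemizygous bins,
the stratum medians would absorb the copy-number signal, and stratified
normalization would be ill-posed — an instructive failure mode, but not a
realistic one for chromosome-scale assemblies.

**Depth.** One negative-binomial draw per 10 kb bin with mean
$\mu = D \cdot c \cdot g(\mathrm{gc})$, where $D = 30$ is base depth, $c$
the copy ratio (1 autosomal, 0.5 for the X) and
$g(\mathrm{gc}) = \max(\epsilon,\, 1-\beta(\mathrm{gc}-\mathrm{gc}_0)^2)$
a unimodal bias ($\mathrm{gc}_0 = 0.42$, $\beta = 4$, $\epsilon = 0.1$) —
a simple shape that genuinely stresses stratified normalization because it
is not monotone. Dispersion $\theta = 10$ (variance $\mu + \mu^2/\theta$)
reflects the strong overdispersion of long-read depth; the Poisson case is
recovered as $\theta \to \infty$. Depth is simulated at bin resolution and
emitted as per-bin-constant BED — the analysis consumes depth, not reads,
and read-level simulation would add hours without changing what is tested.

**Markers.** Each of 100 markers originates on the X with probability 0.6
(matching the observed concentration of conserved X genes), otherwise on
an autosome proportionally to length. The true-origin hit receives e-value
$10^{-U}$, $U \sim \mathrm{Uniform}(20,120)$; up to 3 decoy hits are at
least $10^3$-fold weaker, so best-hit filtering provably recovers the
origin and the enrichment test is exercised on a known signal.

**Loci.** Amino-acid sequences evolve along a fixed base tree (12 taxa,
edges uniform on [0.01, 0.05] substitutions/site — a scale typical of
conserved single-copy protein alignments) under the equal-rates 20-state
model, in which the expected proportion of differing sites at distance $d$
is $\frac{19}{20}(1-e^{-20d/19})$. Taxa drop out independently with
probability 0.1 per locus. Paralogous loci are emulated as a deep
duplication: a taxon subset that straddles a reference clade (at least two
members regrafted, two left behind, plus at least one outside taxon) is
regrafted as a clade on an internal edge of 5× the tree height. The
straddle-plus-outsider condition guarantees the reference clade is
genuinely split in the gene tree, which is exactly what the screen is
meant to detect; elongating an intact clade's stem would lengthen an edge
without breaking any clade, and no paralog screen keyed to clade integrity
could (or should) fire on it.

**Annotation.** Transcripts carry $1+\mathrm{Geometric}(0.25)$ exons with
log-normal exon and intron lengths. The intron median is 1075 with
sdlog 0.75, giving a log-normal mean of $1075\,e^{0.75^2/2} \approx 1424$,
a realistic scale for a large insect genome. Ground truth records every
intron length, so inference from the emitted GFF3 can be checked exactly.

What the generators do *not* emulate: read-level error and mappability,
repeat-driven coverage artifacts, within-locus alignment error and indels,
rate heterogeneity across sites, and real GC landscapes. Passing tests on
synthetic data therefore demonstrate that the computations are correct and
that the recovery logic works under realistic noise — not that any real
assembly's X has been found.

## Validation sizes and known limitations

The test suite and `scripts/acceptance.R` validate at these problem sizes,
chosen to exercise the asymptotics the methods rely on while staying
comfortably reproducible on a laptop: 100 replicate genomes (~20 Mb each)
for X recovery; 10,000 bins for GC flattening; all $n \le 12$ for the
exact binomial test against an enumeration oracle; 1,000 random length
multisets for N50/L50 against brute force; 200 random additive distance
matrices (4–8 taxa) for NJ, with an exhaustive least-squares topology
search as oracle up to 6 taxa; 200 loci for the paralog screen; 2,000
transcripts for intron statistics.

One sampling-theory point deserves emphasis. With a 1 Mb X in 10 kb bins,
the scaffold median is estimated from only 100 overdispersed bins; its
sampling sd is ≈ 0.8 depth units at $\theta = 10$, i.e. ≈ 0.027 on the
copy-ratio scale once the reference's own noise is included. The
hemizygous *label* (band [0.35, 0.65]) is therefore essentially always
correct, but the ratio itself falls outside a tight [0.45, 0.55] window in
roughly 6–10% of replicates — with this design's defaults we observe
94/100 inside that window. This is irreducible sampling noise in the
median of 100 bins, not a normalization defect; on real chromosome-scale
data (a 100+ Mb X gives 10,000+ bins) the ratio concentrates far more
tightly. Other known limitations: the GC correction assumes the bias is a
function of GC alone (not, e.g., of repeat context); the paralog screen
requires a trusted reference phylogeny and cannot see duplications that do
not split any supplied clade; and the binomial null treats markers as
independent, which real tandem arrays of X genes would violate.
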
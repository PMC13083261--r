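---
title: "Methods: genome quality, species clustering and biosynthetic potential of reef microbiomes"
author: "reefMAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome quality, species clustering and biosynthetic potential of reef microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefMAGs)
```

# Scope

reefMAGs implements the downstream, table-level analysis of a reef-microbiome
genome collection: everything from quality-assessed metagenomic bins to
candidate natural-product super-producer species. Upstream sequence work —
read QC, assembly, binning, CheckM/Anvi'o quality estimation, GTDB taxonomy
inference, antiSMASH BGC prediction, gene-catalogue construction — is out of
scope; its outputs (quality statistics, pairwise ANI, BGC predictions and
distances, taxonomic profiles, read-to-gene alignments) are the package's
input contracts, exchanged as TSV tables. Because those inputs are large and
external, the package ships a seeded generator (`simulateReefData()`) that
plants the statistical structure every stage assumes, so the whole pipeline
is exercised end-to-end without downloads.

# Genome quality

Two independent assessors report completeness (cpl, %) and contamination
(ctn, %). A genome is retained if **either** assessor reports cpl ≥ 50 and
ctn ≤ 10; the retention check runs on per-assessor values, and merged values
are the unweighted mean of the available assessors. We check retention before
averaging because the admission rule is phrased per tool; averaging first
would silently tighten it. The quality score on merged values is

$$Q = \mathrm{cpl} - 5\,\mathrm{ctn},$$

and tiers are assigned by first match in the order high (cpl ≥ 90, ctn ≤ 5),
good (cpl ≥ 70, ctn ≤ 10), medium (cpl ≥ 50, ctn ≤ 10), fair (otherwise).
The tier boundaries overlap at cpl = 50 (medium says ≥ 50, fair says ≤ 50);
ordered matching resolves the tie in favour of medium, consistent with the
retention rule already admitting cpl = 50. Averaging two assessors can also
drop a retained genome's merged cpl below 50; such genomes are retained but
tiered fair. Percentages are carried at full precision and rounded (half-up,
2 decimals) only in reports.

Species-level genome sizes correct observed assembly sizes for
incompleteness: members with cpl ≥ 70 qualify, each contributes
`size_bp × 100 / cpl`, and the species estimate is the mean over qualifying
members. Species with no member at 70% completeness are flagged rather than
estimated.

# Species clustering

Genomes are clustered into species by single-linkage connected components of
the ANI graph: edges with alignment coverage < 0.2 are discarded, remaining
edges with ANI ≥ 95% connect genomes, and a missing pair counts as below
threshold. The 95%/0.2 thresholds are the method's contract; the two-stage
sketch-plus-alignment machinery of dereplication tools is not reproduced
because the package starts from a supplied ANI table. Asymmetric ANI entries
are symmetrized by the arithmetic mean before thresholding. Species ids are
deterministic (ordered by each component's smallest member id).

Each species' representative maximizes

$$Q' = \mathrm{cpl} - 5\,\mathrm{ctn} +
      \mathrm{ctn}\times\mathrm{SH}/100 + 0.5\log_{10}(\mathrm{N50}),$$

with SH the strain heterogeneity (%). The logarithm base is not fixed by the
formula's source; we fix log10 (a 100 kbp N50 contributes 2.5 points) and
expose it as an argument. Ties break to the lexicographically smallest
genome id.

Alternative clusterings are compared by conditional-entropy statistics:
homogeneity (each evaluated cluster holds one reference class), completeness
(each reference class sits in one cluster) and their harmonic mean, the
V-measure. Taxonomic novelty of a species follows the deepest assigned rank
of its representative's taxonomy string: a full seven-rank assignment is a
known species; otherwise the species is new at the child of the deepest
assigned rank, with everything above family collapsed to "new order or
higher" for reporting (the full rank is available internally).

# Community analysis

Profiles (samples × species scaled counts) are filtered in one pass, in this
order: species detected in fewer than 10 samples are removed, then samples
with total abundance ≤ 3 are removed. The pass is not iterated: removing
samples can, in principle, expose species newly below the detection
threshold, but an iterated filter would make results depend on loop order
and, on real data, rarely changes anything. Idempotence therefore holds
exactly unless the sample filter exposes such species, which is documented
behaviour.

Between-sample distances are presence/absence Jaccard
(`d = 1 − |A∩B|/|A∪B|`, detection = strictly positive abundance; two
all-absent samples are at distance 0 by convention). Ordination is classical
scaling: double-centre `−½ D²`, eigendecompose, scale eigenvectors by the
square roots of positive eigenvalues. Negative eigenvalues — expected for
Jaccard — are counted and reported; no Lingoes/Cailliez correction is
applied, so coordinates exactly reproduce distances only for
Euclidean-embeddable inputs (verified to 1e−9 on planted configurations).

Group effects are tested by PERMANOVA in Anderson's distance-based
formulation: `SS_total = Σ_{i<j} d²_ij / N`, within-group sums analogously
per group, pseudo-F from among/within mean squares, and
`p = (1 + #{F* ≥ F}) / (n_perm + 1)` with the observed statistic included in
both counts (the standard exact-test correction, which guarantees
`p ≥ 1/(n_perm+1)`). For non-Euclidean matrices the among-group sum can be
marginally negative under the null, so R² is reported unclamped (bounded
above by 1 only); clamping would bias the type-I behaviour that the test
suite verifies (rejection rate at α = 0.05 within the 99% binomial interval
over 1,000 null simulations). Unbalanced designs use the balanced-subsampling
protocol: every group larger than the subsample size (default 50) is
subsampled without replacement in each of 100 repetitions, smaller groups
enter whole, and results aggregate as the median p and mean R² — the
aggregation rule is ours, as the protocol's source states only that
statistics derive from the repetitions.

Seawater distance decay is summarized per water category (C
coral-surrounding, R reef, O open ocean): the fraction of host-associated
species detected in at least one sample of the category, and the mean
per-sample summed relative abundance of those species.

# Gene abundance

Alignments are retained at identity ≥ 95%, alignment length ≥ 80% of the
query and ≥ 45 bases. Counting is unique-then-fractional: per insert,
candidate genes reduce to those at maximal identity; a single survivor makes
the insert unique (count 1); ambiguous inserts distribute one count across
their candidates in proportion to the candidates' unique counts, with an
equal split when all candidates have zero unique count (the source is silent
on this case). The distribution is a single pass — no EM iteration — so the
total equals the number of retained inserts exactly, a conservation law the
tests assert to 1e−9. Abundances are normalized by gene length and then by
the sample's total mOTU count (a sequencing-depth proxy); we use unfiltered
totals, since whether depth normalization preceded or followed profile
filtering is not specified. ELP (eukaryotic-like protein) content per genome
is the fraction of predicted proteins carrying at least one ELP-associated
family, each protein counted once.

# Biosynthetic potential

BGCs on contigs shorter than 5 kbp are rejected at ingest, mirroring the
prediction settings. Families (GCFs) come from average-linkage agglomerative
clustering of the pairwise BGC distance table, cut strictly below 0.5;
missing pairs default to distance 1, and rows are sorted by BGC id so the
merge order is deterministic. The clustering tool referenced by the protocol
is not published in detail; average linkage at the stated threshold is our
choice, verified against a brute-force Lance–Williams oracle on small
instances. Each GCF receives the majority natural-product class of its
members after mapping antiSMASH labels through a BiG-SCAPE-style class map
(ties and unknown labels go to "others"). Novelty against reference BGC
collections (predicted and experimentally validated) reuses the 0.5
threshold with strict inequality, since no separate novelty threshold is
stated.

Richness is normalized by sampling effort three ways: GCFs per species and
per genome within a grouping (reported at 2 and 1 decimals, half-up);
per-sample GCF counts divided by the sample's total mOTU count; and
rarefaction curves — for k = 1..n units (host genera or islands), the mean
cumulative number of distinct GCFs over random unit orderings (100
iterations for host genera, 500 for islands in the original protocol;
configurable here). Curves are monotone per iteration and the endpoint is
deterministic.

Candidate BGC-rich ("super-producer") species are scored per genome by a
composite of three indices in [0, 100]: complete-BGC count and N50, each
normalized as `log(x)/max(log x) × 100`, and Q clamped to [0, 100] (so the
"0 to 100" range holds even for contaminated genomes with negative Q). The
log ratio is base-invariant, which the tests assert numerically for bases e,
2 and 10; `x = 0` maps to 0 and `x = max` (including the degenerate
`max ≤ 1`) to 100. Whether the normalizing maximum is within-species or
global is ambiguous in the source phrase "normalized per species"; both are
implemented and within-species is the default, since the selection is among
a species' member genomes. A species is a candidate if its highest-composite
genome encodes at least 15 complete BGCs. Contig-edge BGCs participate in
GCF clustering but never count toward the 15-BGC rule.

# The synthetic-data generator

`simConfig()` fixes the study conditions; one global seed feeds per-table
substreams, so adding a table leaves the others byte-identical. Defaults and
their rationale:

* **ANI structure** — within-species ANI uniform on [95.5, 100], between
  on [80, 92], coverage on [0.3, 1]. The gap around the 95% threshold makes
  the planted partition exactly recoverable (V-measure 1), which is the
  point: the clustering contract, not the ANI estimator, is under test.
* **Quality** — latent completeness uniform on [50, 100]; contamination
  exponential with mean 2%, capped at 10; assessors report truth ± 3
  percentage points of uniform jitter (clipped to valid ranges), enough to
  exercise the averaging and either-tool rules without pathological
  disagreement. Observed assembly size is exactly
  `true size × completeness/100`, so the size-correction recovery check can
  demand 1e−9 relative error when the jitter is set to 0.
* **Community** — four host genera (two stony, one fire, one sponge) with
  10 samples each; exactly `floor(0.95 × n)` species confined to their home
  genus (detection probability 0.9 per home sample, and every species is
  forced into at least one home sample so none is orphaned); non-confined
  species may appear in one secondary genus at probability 0.3. Water
  samples retain each host-associated species with probability 0.2 (C), 0.1
  (R) and 0.02 (O), producing the distance-decay ordering in expectation.
  Detected abundances are log-normal (meanlog 1, sdlog 1).
* **BGCs** — complete BGCs per genome Poisson with mean 2; contig-edge BGCs
  at rate 0.3; exactly `floor(0.1 × n)` species (the first ids) are planted
  BGC-rich by topping their best genome up to ≥ 15 complete BGCs. That
  genome is also given its species' best contamination and N50, so the
  planted genome wins the composite score and recovery is exact by
  construction (sensitivity = specificity = 1). Within-family BGC distances
  are uniform on [0, 0.3] and between-family on [0.6, 1], straddling the
  0.5 threshold.
* **Alignments** — every insert has one filter-passing primary alignment;
  exactly `floor(0.1 × n)` inserts (the first ids) get a second equal-identity
  alignment, making ambiguity counts exact rather than Bernoulli; decoy
  alignments straddle each filter threshold and always fail at least one,
  so the filters are exercised while noise-free counting recovers the
  planted abundances exactly.

What the generator does **not** emulate: sequence-level error, compositional
correlations between species, geographic autocorrelation beyond the island
labels, real MAG quality distributions (unpublished), seawater-specific
background taxa, or BGC fragmentation biology. Passing tests therefore show
that the algorithms implement their contracts on data satisfying the planted
assumptions — not that real reef data satisfy those assumptions.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at 50
species, roughly 200 genomes, about 800 BGCs and 42 samples — a size at
which every stage's behaviour is identifiable while the whole run takes
seconds. PERMANOVA null calibration uses 1,000 simulated datasets at 16
samples with 199 permutations each. Tolerances: exact identities are
asserted to 1e−9 or tighter; entropy statistics to 1e−12 against an
independent implementation; PCoA self-consistency to 1e−9. Tie-breaks are
deterministic throughout (lexicographic genome ids for representatives and
scoring genomes, input order for clustering).

# Known limitations

* The published dataset-level quantities (4,224 species, 6,612 GCFs,
  PERMANOVA R² of 0.31/0.18) depend on the real 2,074-sample data and are
  not recomputable here; the package recomputes the printed ratios from the
  printed totals and validates the algorithms on planted structure.
* Single-linkage species clustering is sensitive to chained edges; this is
  inherent to the method's contract, not corrected.
* The GCF clustering reproduces a distance-threshold contract, not the
  internals of any specific BGC-comparison tool.
* PCoA reports, but does not correct, negative eigenvalues.
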
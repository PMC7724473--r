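---
title: "Stratifying Polycomb targets from multi-condition ChIP-seq: methods and design"
author: "prc2strat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying Polycomb targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analytical problem

PRC2 reaches its target chromatin through at least three routes: direct,
DNA-mediated binding of MTF2 at unmethylated CpG-rich sequence (PRC2.1);
JARID2-mediated recruitment, itself responsive to PRC1-deposited
H2AK119ub (PRC2.2); and the allosteric EED–H3K27me3 feedback loop. To ask
how much each route contributes *per class of target*, one profiles
several subunits (EZH2, MTF2, JARID2) and the catalytic product
(H3K27me3) across a grid of genotypes (wild type, *Mtf2* mutant,
*Jarid2* knockout, *Eed* knockout) and treatments (the EED inhibitor
EED226), quantifies every track on one common set of target regions, and
stratifies the regions by how their multi-condition signal pattern
responds to the perturbations.

`prc2strat` implements that workflow: signal-matrix extraction,
normalization, correlation-distance k-means stratification, cluster-level
bootstrap quantification, DNA-shape-conditioned GCG motif counting, and
hypergeometric term enrichment, plus a synthetic-study generator that
makes every stage testable against known ground truth.

# Coordinate and signal conventions

All user-facing coordinates are BED convention: 0-based, half-open.
Internally peaks live in a `GRanges`; the conversion happens in exactly
one place. The center of a peak `[start, end)` is
`floor((start + end) / 2)`. Coverage is a per-base-pair step function
(run-length encoded); its unit is *reads per bin* at the track's bin
size (50 bp by default), so window means read off mean reads-per-bin
directly and the per-peak read count used for RPKM is
`mean binned depth × number of bins` — the coverage track is the single
source of truth, with no read-level recounting.

Windows that run past a chromosome end are zero-padded; a peak on a
chromosome absent from a track is a hard error rather than a silent
zero, because silent zeros would corrupt WT-normalized percentages
downstream.

The enrichment criterion used for co-occupancy and for solo-peak
exclusion calls a peak bound when its window mean exceeds a fold
threshold (default 2) times the track's *background* depth. Background
is estimated as the weighted median bin depth, not the mean: in the
synthetic genomes peaks cover a quarter or more of the sequence, so a
plain mean is inflated by the peaks themselves and would silently drop
true targets. On sparse real genomes median and mean background nearly
coincide.

# Normalizations

RPKM is `count / ((length/1000) × (library/10^6))`. Input subtraction is
performed on RPKM values and *retains negative values*: clamping at zero
before taking cluster medians would bias the quantification upward at
weakly bound regions. (Whether input is subtracted per bin before
averaging or after is immaterial without clamping — subtraction and
averaging are both linear — which is why the package subtracts at the
aggregated level.) Wild-type-relative percentages
(`100 × condition / WT`) are applied to cluster-level statistics, not per
peak, matching figure-level quantification practice; a zero WT statistic
is an explicit error.

Spike-in scaling multiplies depths by
`reference spike-in reads / sample spike-in reads`. The package also
ships a simulation (`spikein_experiment`) of the regime where spike-in
normalization matters: libraries sequenced to a fixed total while true
genome-wide occupancy shifts. There, per-million scaling suffers a
composition effect (lost signal reads are redistributed over the rest of
the library) while the constant exogenous chromatin claims a read share
inversely proportional to occupancy, so spike-in scaling recovers the
true between-sample ratio. The concordance diagnostic
(`normalization_concordance`, a Pearson correlation across samples) is
high in this regime even though the per-million *scale* is distorted —
concordance and unbiasedness are different claims.

# Stratification by signal shape

## Features

Clustering uses the signal within ±1 kb of each peak center at 50-bp
bins, per condition. Each condition block is z-scored row-wise
independently, and blocks are concatenated in sample-sheet order. Row
z-scoring means only the *shape* of the signal in the window enters the
distance — a row's amplitude, and any affine transform of it, is
invisible. Two consequences worth knowing:

* a condition in which a peak has no signal contributes a pure-noise
  block, which is informative (its z-profile is flat on average) exactly
  in contrast to conditions with a shaped profile;
* a *broad plateau* much wider than the window is flat within ±1 kb and
  therefore shapeless after z-scoring — wide domains are distinguishable
  from bound narrow peaks, but two flat-in-window classes are
  distinguishable from each other only through conditions where their
  presence/absence patterns differ.

## Distance and algorithm

The distance is `1 − r` (Pearson). For rows scaled to mean 0 and unit
sample standard deviation, `||z(x) − z(y)||² = 2(p − 1)(1 − r(x, y))`:
squared Euclidean distance on z-scores is a strictly increasing affine
transform of the Pearson distance, so Lloyd iterations under the two
objectives rank partitions identically. The package therefore runs
ordinary Euclidean Lloyd steps on the z-scored rows; the test suite
checks the resulting partitions against a direct Pearson-distance Lloyd
implementation and against exhaustive bipartition search on small
instances.

Numerical policy:

* best of `n_init = 10` random restarts by within-cluster inertia;
  `max_iter = 300`, with a warning and a `converged = FALSE` flag if no
  restart converges;
* an empty cluster during iteration is re-seeded at the point currently
  farthest from its assigned centroid;
* rows with zero variance across all features (Pearson distance
  undefined) are excluded from fitting, then assigned to the cluster
  whose raw-space centroid is nearest in Euclidean distance, and flagged
  in the returned object;
* the seed is a mandatory argument — there is no hidden RNG state.

## Choosing k, and renumbering clusters

`select_k_elbow` scans a k range (default 2–10) and places the elbow at
the maximum discrete second difference of the inertia curve,
`I(k−1) − 2I(k) + I(k+1)`. When the maximum curvature falls below a
tolerance (5% of the initial inertia drop) the result is flagged as
having no pronounced knee. A known limitation of this statistic: on pure
noise the second differences fluctuate at 20–40% of the first drop, so
genuinely structureless data is *not* reliably flagged at the default
tolerance — and any tolerance large enough to flag it would also flag
real but modest knees. The flag is best treated as a guard against
near-degenerate curves, not as a test for cluster structure.

Because k-means numbering is arbitrary, `relabel_clusters` renumbers
clusters by a per-cluster statistic — by default wild-type signal
sharpness, the ratio of center-bin signal to window-mean signal — in
descending order, with ties broken by cluster size and then original id.
Cluster 1 is then always the sharpest class, making runs comparable.

Peaks bound by a single subunit only (the JARID2-only phenomenon) are
removed before clustering: `exclude_solo_peaks` keeps peaks enriched in
at least `min_marks` (pipeline default 2) of the untreated wild-type
EZH2, H3K27me3 and MTF2 tracks.

# Bootstrap quantification

The exchangeable unit is the peak. For each (condition × cluster) cell,
`n_boot = 1000` resamples of the member peaks' input-subtracted RPKM
values are drawn with replacement; each round's *median* is recorded
(these are the plotted dots), and the confidence interval is the central
percentile interval — linear interpolation between order statistics,
`quantile` type 7 — of the bootstrapped *means*, at level 99.9% by
default. Medians-as-dots with a CI-of-means is deliberately implemented
as stated in the figure convention it mirrors; since the intent is
ambiguous, `ci_of = "median"` switches the interval to the bootstrapped
medians. The percentile method was chosen over BCa as the minimal
assumption-free construction.

Resampling uses integer indices only, each cell draws from its own
deterministic sub-seed, and peaks are sorted by id before resampling, so
results are identical across platforms and invariant to input order.
Cells with fewer than two peaks are flagged and get an undefined
interval. Calibration is checked empirically (`boot_ci_coverage`): the
99% interval for the mean over 500 Gaussian replications at n = 200 must
cover the truth in at least 97% of replications.

# DNA shape and GCG counting

MTF2's DNA-binding preference is for unmethylated GCG trinucleotides in
a locally unwound helix (reduced twist). The package represents the
shape model as a pentamer table: the base-pair step between positions
`i` and `i+1` takes the twist of the pentamer covering `i−2 … i+2` —
two bases of context on each side of the step. A GCG at position `p`
spans two internal steps, `(p, p+1)` and `(p+1, p+2)`; it is
shape-matching when its mean twist over those two steps is strictly
below the threshold. Both the threshold (default: table median) and the
averaging window are explicit parameters and the defaults are marked as
placeholders — the calibrated values belong to the upstream shape
model, not to this package. Minus-strand hits (CGC on the forward
strand) are scored on the reverse-complement sequence's own pentamers,
which makes counts exactly strand-symmetric. Hits whose context runs
past the sequence edge are excluded and tallied separately
(`flank_mode = "strict"`).

A deterministic synthetic pentamer table ships with the package
(`synthetic_shape_table`, an integer-hash construction mapped to a
realistic 28–40° twist range), so no external shape database is needed
for testing; it is labelled synthetic and is not a measured model.

# Gene assignment and enrichment

Each peak maps to the gene with the nearest TSS within 10 kb of the peak
center (Polycomb targets are predominantly promoter-proximal bivalent
elements, hence the promoter-scale cap); exact ties go to the
lexicographically smaller gene id, and unassigned peaks are reported.
Gene sets are deduplicated (a gene may own several peaks). Term
enrichment is the upper-tail hypergeometric probability with
Benjamini–Hochberg correction across the whole result table; terms with
fewer than 3 genes in the background are skipped and reported.

Two backgrounds are supported, and the difference is the point: against
*all* genes, anything Polycomb-bound is enriched for the globally
Polycomb-like program; against the *target* genes only, the global
program vanishes and cluster-specific programs remain. The test suite
pins both directions on planted terms.

# The synthetic study

`default_study` writes a complete desk-scale study: a 2 × 5 Mb
two-chromosome genome, 1,610 peaks in seven planted classes, 15 ChIP
conditions (EZH2, H3K27me3, MTF2, JARID2 across wild type, *Mtf2*
mutant, *Jarid2* knockout, *Eed* knockout and EED226 treatment) with
matched inputs, FASTA sequence with class-specific planted motif
densities, a TSS annotation, a term map, and a JSON manifest. One base
seed governs every draw through a documented stream-splitting scheme
(`sub_seed`): universe = stream 1, condition *i* = stream 10 + *i*,
annotation = stream 100. The same seed reproduces every file
byte-identically.

## What is planted, and why

* **Noise model.** Per-bin ChIP depth is Poisson at
  `background + fraction × amplitude × profile(bin)`; inputs are Poisson
  at background (1 read/bin). Poisson-only noise (no biological
  replicate variance, no overdispersion) is the simplest model
  sufficient for parameter recovery.
* **Shapes.** Narrow classes are Gaussian bumps (σ = width/4); broad
  classes are flat plateaus with a linear taper over the outer 10% of
  the width per side.
* **Six condition-profile classes.** Four narrow classes share one width
  range (0.8–1.6 kb) and are distinguished by balanced, near-binary
  residual-fraction codes (0.90 vs 0.00) in the perturbation conditions
  whose values the emulated study does not pin down numerically — i.e.
  archetypal recruitment modes: fully JARID2-dependent at one extreme,
  fully DNA/MTF2-autonomous at the other. The two broad classes differ
  in width: one (1.8–2.1 kb) shows its plateau taper inside the ±1 kb
  window, the other (4–6 kb) is flat there — under row z-scoring this
  within-window shape difference is what separates them. Conditions with
  printed per-class residual ranges use those printed values (H3K27me3
  in the *Mtf2* mutant: 6/13/20/27% narrow vs 48/56% broad; EZH2:
  9–12% vs 23–26%; JARID2: 11–19% vs 30–34%), and the EED226-treated
  rows are weighted so the peak-average residuals sit at the printed
  overall levels (≈77% EZH2, 85% MTF2, 41% JARID2, interpreted as
  residual levels; `default_design(eed226_as_reduction = TRUE)` flips
  the interpretation to amounts of reduction).
* **Class sizes** are near-equal (300/300/300/250 narrow, 270/90
  broad). Balanced sizes and balanced pairwise class separations are
  what let the maximum-second-difference elbow land at the planted
  k = 6: with a strongly hierarchical geometry (one dominant split) the
  curvature maximum sits at the top-level split instead.
* **A JARID2-only decoy class** (100 narrow peaks visible to the JARID2
  antibody only) exercises the solo-peak exclusion filter end to end.
* **Sequence.** Chromosomes are random ACGT purged of all GCG/CGC;
  shape-matching GCG motifs (plus half as many non-matching decoy GCGs)
  are planted per peak at class-specific densities (8–12/kb narrow vs
  1.5–2/kb broad) inside junction-proof 8-mers, so the counted density
  equals the planted density by construction.
* **Spike-in counts** are inversely proportional to the condition's
  global efficiency parameter, and library sizes are equal within an
  antibody: simulated depths deliberately do not depend on the
  library-size metadata, so within-antibody WT-normalization stays
  parameter-consistent while between-antibody differences still exercise
  the RPKM library term.

## What the generator does not emulate

Read-level artifacts (fragment-length effects, mappability, duplicate
reads, diploidy), biological replicate variability and overdispersion,
background GCG content outside peaks, a real ontology graph, and
realistic genome scale. The planted class contrasts are sharper than a
real study's: presence/absence codes and fully balanced separations make
the class-recovery checks close to noiseless. Passing those checks
demonstrates the machinery is correct and calibrated at the planted
effect sizes — not that six classes would be recovered this cleanly from
real chromatin.

# Problem sizes used by the checks

The shipped checks run the full default study (1,510 clustered peaks ×
15 conditions × 40 bins, elbow scan over k = 2–10 with 10 restarts
each), a residual-fraction recovery experiment at 300 peaks per class
for fractions 0.10/0.25/0.50/0.85, bootstrap calibration over 500
Gaussian replications (n = 200, 500 resamples each), and exhaustive
oracles (all 31 bipartitions at n = 6; all 27 resamples at n = 3; all
792 draws at a background of 12; full rescans of 2-kb sequences). These
sizes were chosen so the whole suite runs on a laptop in a couple of
minutes while keeping every estimate's Monte-Carlo error well inside the
tolerances being checked.
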
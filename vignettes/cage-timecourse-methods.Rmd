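---
title: "Methods: dissecting a CAGE differentiation time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting a CAGE differentiation time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cagecascade` implements the analysis cascade used to dissect dense CAGE
(Cap Analysis of Gene Expression) time courses of cellular state
transitions — the archetypal case being growth arrest and
monocyte-to-macrophage differentiation of a myeloid cell line after phorbol
ester stimulation. The pipeline starts from per-base CTSS (CAGE
transcription start site) tag counts, one track per sample, and ends with
co-expression clusters, gene-set enrichment statistics, candidate
enhancers, and inferred transcription-factor motif activities. A synthetic
data generator with complete ground truth accompanies every stage, so the
whole cascade is testable without any external sequencing data.

# The processing model, stage by stage

## Tag clustering and power-law normalization

CTSS on the same chromosome and strand are chained into tag clusters by
single-linkage whenever consecutive positions are at most `max_gap` apart
(default 20 bp, the conventional distance-clustering scale for CAGE
promoters). A cluster's per-sample value is the sum over member CTSS and
its representative position is the dominant (highest pooled count) CTSS.

CAGE tag-count marginals are heavy tailed and approximately power-law over
several decades. Library depth and tail shape differ between samples, so
raw counts are not comparable. Each sample's tail exponent `alpha` is
estimated by least squares on the log10 reverse-cumulative count
distribution restricted to counts in `fit_range` (default `[10, 1000]`),
and counts are mapped onto a common reference law with exponent
`alpha_ref` (default 1.25, the canonical human CAGE value) by the monotone
transform

    x  ->  b * x^(alpha / alpha_ref),

with `b` set so every normalized sample totals `total_ref` (default 1e6).
The transform preserves within-sample rank order exactly and maps zero to
zero. Values are then expressed as tags per million (TPM; every column
sums to 1e6 before any filtering), filtered to rows with at least 10 TPM
in at least one sample (thresholds inclusive, "at least"), annotated
against the nearest same-strand annotated TSS within 500 bp (ties: smaller
distance, then lexicographically smallest symbol), and averaged over
replicates per time point.

Two numerical points deserve emphasis:

* **Pooled exponent for matrices.** At desk scale (roughly 1,500 CTSS per
  sample in the synthetic study) the per-sample exponent estimate has a
  standard deviation near 0.09. Applying each sample's own noisy exponent
  distorts large counts differently in every sample — enough to break
  correlations between genes whose expression sits at high counts. Since
  all samples of one experiment share a tail exponent, the matrix method
  of `normalize_power_law()` therefore pools (median) the per-sample
  estimates by default (`pool_alpha = TRUE`); the vector method keeps the
  sample's own fit, which is the form under which the refit property holds
  exactly: re-fitting the normalized output over the image of the fit
  window returns `alpha_ref` to numerical precision.
* **Where the power law lives after normalization.** Normalization
  rescales the data, so the power-law window moves to the image of
  `fit_range` under the transform. With realistic library sizes the image
  is close to `fit_range` in TPM units; with a small synthetic genome the
  totals are small and the image sits higher. Diagnostics in this package
  therefore refit over `range(y[x >= 10 & x <= 1000])` rather than blindly
  over `[10, 1000]`.

## Co-expression networks and Markov Clustering

Pairwise Pearson correlations are computed between replicate-averaged,
untransformed TPM profiles (a log option exists but the default follows
the common practice for CAGE network analysis). An edge is kept when
`r >= r_min`; the study thresholds are 0.95 for sample-to-sample graphs,
0.85 (or 0.75 / 0.95 at other stringencies) for gene-to-gene graphs, and
0.60 for motif-activity profiles. Zero-variance profiles have no defined
correlation; they are excluded and reported rather than silently dropped.

The graph is partitioned with a from-scratch Markov Clustering (MCL)
implementation at inflation 1.7: the weighted adjacency gets self-loops
equal to each node's maximum incident weight (1 for isolated nodes), is
column-normalized, and is then iterated through expansion (matrix square),
inflation (elementwise power, column renormalization) and pruning of
entries below 1e-5, until the largest column change falls below 1e-8 or
200 iterations. Clusters are read off attractor rows (nonzero diagonal); a
node claimed by several attractors goes to the lowest-indexed one, which
makes the partition deterministic and invariant (up to label names) to the
input order of nodes. Labels are assigned by size, `Cluster001` being the
largest. Edge weights are the correlations themselves; an unweighted mode
is available since the original tooling leaves this choice open.

`subcluster()` reruns the graph + MCL combination on the members of one
cluster at higher stringency, reporting nodes that fail the threshold
against all others as excluded — the pattern used to split a
proliferation-associated cluster into decay-phase subclusters.

## Gene-set enrichment

Cluster enrichment uses the exact hypergeometric tail, not a normal or
chi-square approximation: the interesting departures from expectation sit
at P ~ 1e-6 where approximations are unreliable. For a universe of `N`
genes of which `K` belong to the set, a cluster of `n` with `k` members
scores `P(X >= k)` (over) and `P(X <= k)` (under); the smaller tail is
reported with its direction and Bonferroni-corrected by the number of
clusters tested. The universe is the clustered, gene-annotated node set —
not the genome — matching how cluster composition percentages are quoted
in practice. A gene with several promoters counts once by default
(`dedupe_genes`); promoter-level counting is available because
node-versus-gene bookkeeping is genuinely ambiguous in published cluster
sizes. Phase composition (e.g. S versus G2/M labels) reports per-phase
counts, expectations `n*K/N`, both tails, and a two-sided value
`min(1, 2*min(tails))`.

## Enhancer calling from bidirectional transcription

Active enhancers produce short, unstable, *balanced bidirectional* eRNA.
Candidates are found by pairing every divergent arrangement — a
reverse-strand tag cluster upstream of a forward-strand cluster — whose
gap is at most `pairing_max_gap` (default 400 bp), placing a locus at the
gap midpoint, and tallying per-sample forward tags in
`[mid, mid + window_half)` and reverse tags in `[mid - window_half, mid)`
(default half-window 200 bp, the scale of the established bidirectional
eRNA method). Overlapping loci are merged keeping the higher-expressed
one. The directionality score `D = (F - R)/(F + R)` measures strand
balance on pooled raw tags.

Two stringency tiers gate the candidates, with strict/inclusive
comparisons taken literally from their definitions: the stringent tier
requires more than one raw tag per flank in at least two samples, pooled
`|D| < 0.8` (strict), and bidirectional tags in *more than two* samples;
the lenient tier requires more than one tag per flank in at least one
sample and bidirectionality in at least one sample. The stringent set is a
subset of the lenient set by construction. Tag thresholds apply to raw
tags, not normalized values, since eRNA counts sit near the detection
floor where normalization is least meaningful.

Loci closer than 500 bp to an annotated TSS *or* closer than 100 bp to an
exon are then removed (distance 0 inside an interval; strict
inequalities, so exactly 500 bp survives). The removal rule is a
disjunction because its purpose is to avoid calling promoters: a locus
hugging a TSS must go regardless of its exon distance. A conjunction mode
is provided for completeness. Finally `overlap_reference()` reports how
many surviving loci intersect a reference enhancer BED by at least 1 bp
(half-open intervals; adjacency is not overlap).

## Motif activities (MARA-style ridge regression)

Promoter windows spanning −300..+100 bp of each cluster's dominant CTSS
(strand-aware, reverse-complemented on the minus strand, truncated and
flagged at chromosome edges) are scanned with JASPAR-style PFMs: log-odds
scores with uniform background and pseudocount 0.5, on both strands; a hit
is any position scoring at least `score_frac` (default 0.85) of the
motif's maximum achievable score. Cross-species conservation filtering of
sites is *not* implemented; a site whitelist can be supplied where
externally computed conserved sites exist.

The activity model explains log-expression (`log2(TPM + 1)`; the offset is
a choice, the model needs only some variance-stabilizing log) as

    E[p, s] = c_p + c_s + sum_m N[p, m] * A[m, s].

`E` is double-centered (promoter then sample means), `N` column-centered,
and `A` solved in closed form through the SVD of the centered `N`:
ridge shrinkage `d/(d^2 + lambda)` on the singular values, which at
`lambda = 0` is the pseudoinverse. Column-centering always costs (at most)
the constant direction — absorbed by re-centering each motif's activities
to sum to zero — so rank deficiency is only an error, at `lambda = 0`,
when the centered rank falls below `min(n_motifs, n_promoters - 1)`.
`lambda` defaults to the minimizer of generalized cross-validation on a
log-spaced grid; recovery experiments use `lambda = 1`, which is
negligible against the design's singular values and serves only as
numerical regularization. Z-scores are `A / SE(A)` with standard errors
from the ridge covariance diagonal — the error model of the original MARA
service is not public, so this definition is stated rather than claimed as
a reproduction. Activity profiles are then clustered with the same
correlation + MCL machinery at `r >= 0.60`.

# The synthetic study and its ground truth

`sim_config()` fixes the study conditions; `simulate_timecourse()` writes
a toy genome (FASTA), annotation (GTF), one CTSS BED6 track per sample and
the truth tables. Defaults emulate the dense differentiation design:
samples hourly from 0–12 h, two-hourly to 18 h, then 24/36/48/96 h
(20 points; the schedule is explicit configuration), three replicates per
point, 500 promoters and 20 enhancers on a 3 Mb genome.

* **Baseline expression** is Pareto with tail exponent `pareto_alpha`
  (default 1.25) and scale 20 tags, truncated at 300× scale so that no
  single locus dominates library composition while the `[10, 1000]` fit
  window stays clear of the truncation. Each promoter spreads its
  expression over three CTSS (70/20/10%), giving realistic within-cluster
  structure for the aggregation step.
* **Temporal archetypes** follow the transition patterns such experiments
  report: an early transient pulse (peak 2 h), a mid pulse (peak 6 h), a
  progressive decline (exponential to 5% by 96 h), a mirrored progressive
  rise, and a flat background class, mixed 15/15/25/25/20%. Decline and
  rise are mass-symmetric so that library composition stays roughly
  constant — without this, compositional coupling through the fixed TPM
  total would give "flat" genes a spurious coherent trend.
* **Replicate noise** is negative binomial with size 20 (overdispersion
  0.05), the scale of well-controlled clonal cell-culture replicates.
  Downstream analyses work on replicate means, so this is the noise the
  correlation thresholds see after averaging over three.
* **Enhancers** are two single-base CTSS 180 bp apart on divergent
  strands, with per-strand means drawn within ±10% of each other (so
  |D| < 0.3 in expectation, comfortably inside the < 0.8 gate), pulsing
  `erna_lead_h` (default 2 h) *before* their linked promoter's peak —
  the transient eRNA-leads-promoter phenomenon. Enhancers are unannotated
  and placed ≥ 1 kb from promoters, making the TSS/exon masks
  exercisable.
* **Motif design.** `simulate_motif_design()` draws a full-column-rank
  promoter × motif count matrix (binomial(3, 0.3) per cell) and smooth
  ground-truth activities (rising, falling, early- and late-pulsed
  shapes, amplitude ~1 log2 unit, rows centered). Promoter means are
  multiplied by `2^(N A)`, so the MARA stage can be scored against truth.

The generator's parameters were chosen once to make its stated
calibration contract hold — marginal tail exponent recoverable within
±0.15, per-motif activity recovery r ≥ 0.9 at 500 promoters, archetype
recovery Rand ≥ 0.9 at r ≥ 0.85 / inflation 1.7 — and then frozen.

Two deliberate experiment-design points: the *archetype recovery*
experiment runs with `motif_amplitude = 0`, because when motif activities
also drive expression the archetype labels are only a partial truth and a
Rand index against them would conflate genuine signal with "error"; the
*motif recovery* experiment uses the full design. And recovery of planted
enhancers is scored before the reference-overlap step against the truth
table itself, which doubles as a self-consistency check of
`overlap_reference()`.

What the generator does **not** emulate: real human sequence composition
(the genome is i.i.d. uniform), mapping artifacts and multimapping, G-bias
of CAGE 5′ additions, unannotated transcripts other than enhancers,
miRNA-mediated regulation, and cross-sample batch structure. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration under the stated generative model — not robustness to every
pathology of real CAGE libraries.

# Numerical and degenerate-input conventions

* Coordinates: CTSS and BED are 0-based half-open; GTF is 1-based
  inclusive; conversions happen at the readers.
* Threshold grammar: "at least" is inclusive, "more than"/"less than"
  strict — applied consistently in filtering, stringency tiers and masks.
* Ties: dominant CTSS, smallest position; annotation, smallest distance
  then lexicographic symbol; MCL attractors, lowest index; cluster labels,
  size then smallest member index.
* Zero-variance profiles, empty CTSS files, all-zero samples, chromosome
  -edge windows, motifs longer than windows, and zero-transcription loci
  are all either reported or rejected with named errors, never silently
  altered.
* Determinism: a fixed seed makes the generator byte-identical and the
  whole pipeline manifest-identical across runs; all randomness flows
  from the single configured seed.

# Problem sizes

The bundled experiments run the full default study (60 samples, ~1,540
CTSS, 540 tag clusters, 8 motifs), exhaustive hypergeometric enumeration
to population size 12 (~6,400 tails), 50 random MCL comparison graphs of
up to 30 nodes, and 2,000 null draws for the type-I error check. These
sizes were chosen so the entire battery completes in well under a minute
on one core while every stage still operates in its intended regime.

# Known limitations

* The exact normalization variant used by any given published analysis
  may differ in detail (fit windows, exponent pooling); both pooled and
  per-sample modes are exposed, but no claim is made of bit-for-bit
  equivalence with external tools.
* MARA z-scores follow the ridge-covariance definition documented above;
  absolute z magnitudes are not comparable with the original service.
* Enhancer-target assignment is limited to the simulated truth links;
  no chromatin-contact integration is attempted.
* At desk scale the power-law fit is noisy (sd ≈ 0.1 on the exponent);
  quantities derived from a single sample's fit should be read with that
  uncertainty in mind.
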
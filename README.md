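# cagecascade

Network-based dissection of dense CAGE time courses — from per-base
transcription start site (CTSS) tag counts to co-expression clusters,
candidate enhancers and transcription-factor motif activities.

## The problem

Cap Analysis of Gene Expression (CAGE) sequences capped 5′ RNA ends,
quantifying transcription initiation at single-base resolution. Sampled
densely across a cellular state transition — the motivating case is
growth arrest and monocyte-to-macrophage differentiation of a myeloid
leukemia line over 96 h — CAGE resolves a *cascade* of transient
transcriptional waves that sparse designs blur into monotone trends, and
with sufficient depth it also detects the short, balanced, bidirectional
eRNAs that mark active enhancers before their target promoters fire.
`cagecascade` packages the analysis chain such a study needs, for R users
working with CTSS-level data:

1. **CTSS core** — read BED6 CTSS tracks, chain them into tag clusters
   (single-linkage, gap ≤ 20 bp), normalize each sample's heavy-tailed
   count distribution onto a common reference power law
   (`x → b·x^(α/α_ref)`, default `α_ref = 1.25`, totals 10⁶), express as
   tags per million (TPM), filter (≥ 10 TPM in ≥ 1 sample), annotate
   against the nearest same-strand TSS, and average replicates.
2. **Co-expression networks** — thresholded Pearson graphs
   (genes or samples; `r ≥ 0.85` and `r ≥ 0.95` are the usual working
   points) partitioned by a from-scratch Markov Clustering (MCL)
   implementation at inflation 1.7, with cluster mean profiles and
   higher-stringency subclustering.
3. **Gene-set enrichment** — exact hypergeometric over/under tails per
   cluster (the relevant departures sit near P ~ 10⁻⁶, beyond the reach
   of approximations), Bonferroni-corrected; phase-composition tests for
   labelled sets (e.g. S vs G2/M cell-cycle genes).
4. **Enhancer calling** — balanced bidirectional loci
   (`D = (F−R)/(F+R)`, gate `|D| < 0.8`), two published stringency tiers,
   masks removing loci < 500 bp from annotated TSS or < 100 bp from
   exons, and overlap reporting against reference enhancer sets.
5. **Motif activities (MARA-style)** — log-odds PFM scanning of
   −300..+100 bp promoter windows, then ridge regression of
   `E_ps = c_p + c_s + Σ_m N_pm A_ms` for motif activities `A`, with
   z-scores and activity-profile clustering (`r ≥ 0.60`).
6. **Synthetic truth** — a generator that emulates the study design
   (20 time points over 0–96 h, ≥ 3 replicates, Pareto-tailed baselines,
   five temporal archetypes, eRNA pulses leading their linked promoters,
   a planted promoter×motif design) so every stage is testable end to
   end. `run_pipeline()` drives the whole cascade from one config and
   writes a reproducible run manifest.

## Worked example

```r
library(cagecascade)

cfg <- sim_config(seed = 1)              # the default synthetic study
sim <- simulate_timecourse(cfg, "sim")   # genome, GTF, 60 CTSS tracks, truth
meta <- sim$metadata; meta$path <- sim$paths$ctss

ctss <- read_ctss(meta$path, meta)
ctss
#> CTSS table: 1540 sites x 60 samples (20 time points)

fit_power_law(ctss$counts[, "t000_r1"])
#> Power-law fit: alpha = 1.168 (r2 = 0.994, 83 distinct counts in [10, 1000])

cn <- ctss
cn$counts <- normalize_power_law(ctss$counts)   # pooled-exponent transform
tc <- aggregate_ctss(cn)
tc
#> Tag clusters: 540 clusters x 60 samples (median width 13 bp)

expr <- filter_expressed(to_tpm(tc$counts))     # >= 10 TPM in >= 1 sample
avg  <- average_replicates(expr, meta)

g <- build_correlation_graph(avg, r_min = 0.85)
g
#> Co-expression graph (genes): 540 nodes, 7523 edges at r >= 0.85 (0 excluded)

mcl_cluster(g, inflation = 1.7)
#> MCL result: 540 nodes in 92 clusters (inflation 1.7, 23 iterations)
#>   6 cluster(s) with >= 10 nodes; largest: Cluster001 (89 nodes)

loci <- find_bidirectional_loci(ctss)
mask_annotated(apply_stringency(loci, "lenient"),
               read_annotation(sim$paths$gtf))
#> Bidirectional loci: 20 candidates across 60 samples
```

Reading the output: the t = 0 sample's count tail has fitted exponent
≈ 1.17 (the generator plants 1.25; a single desk-scale sample carries
± ~0.1 of fit noise). After normalization and filtering, the 540 tag
clusters correlate into a graph whose MCL partition recovers the planted
temporal archetypes as its large clusters — rising, declining, early- and
mid-pulsed expression — and all 20 planted enhancers survive the
stringency and annotation-mask gates as balanced bidirectional loci.
From here, `test_cluster_enrichment()` scores any gene list against the
clustering, and `fit_mara(log2(E + 1), N, lambda = 1)` recovers the
planted motif activities with per-motif correlation ≥ 0.9
(`summary(fit)` ranks motifs by |z|).

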
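# mirseedscape

Expression-based discovery of microRNA targets, and what those targets are
worth prognostically.

When a miRNA is overexpressed in a cell line, many of its direct targets are
destabilised at the mRNA level. `mirseedscape` implements the computational
side of that experimental design for R users in transcriptomics:

- **Seed-site scanning.** From a mature miRNA sequence it derives the two
  canonical 7-nt target-site patterns — the *7mer-m8* (perfect match to seed
  positions 2–8) and the *7mer-1A* (match to positions 2–7 followed by an
  adenosine) — and scans promoter, 5′ UTR, ORF and 3′ UTR sequences for them,
  merging overlapping typed hits (an 8mer site contains both) into single
  counted sites and assigning each gene a UTR occupancy category.
- **Regional enrichment.** Given a differential-expression table, it asks
  whether down- (or up-) regulated transcripts are enriched for seed sites in
  each region, comparing log₂ fold-change distributions of seeded vs unseeded
  genes with the Wilcoxon rank-sum test (exact enumeration for small samples,
  tie-corrected normal approximation otherwise), relates site *count* to
  repression magnitude, contrasts 3′UTR-only against 5′UTR-only genes, and
  calls **direct targets**: significantly repressed genes carrying a 3′ UTR
  seed site.
- **Compartment miRNA profiling.** Replicate-group fold changes with BH-adjusted
  t-tests, fold-change ranking with deterministic tie-breaks, correlation-distance
  hierarchical clustering, and qPCR `2^-ΔCt` relative quantification.
- **Signature scoring and survival.** A repressed-target gene signature is
  selected by fold-change/Q thresholds; samples are scored by the weighted
  average of standardised expression, `score_s = Σ_g w_g z_gs / Σ_g |w_g|`;
  score quantiles (default top 25% vs bottom 75%) stratify Kaplan–Meier
  curves compared by the log-rank test.
- **Synthetic data with ground truth.** Generators emit transcriptomes with
  planted seed sites (the scanner provably recovers exactly what was
  planted), expression responses with per-gene or per-site repression
  effects, compartment profiles with planted enrichment ratios, and survival
  cohorts with hazard `h₀·exp(β·score)` — so every stage of the pipeline is
  testable end to end without any external download.

The package also ships two small worked-example tables transcribed from a
published mammary-gland study of miR-184: ten compartment-enriched miRNA
candidates (terminal end bud vs duct) and the thirty most repressed genes
from a miRNA-mimic array experiment.

## Worked example

```r
library(mirseedscape)

## seed patterns from a mature miRNA
mir <- load_example_mirnas()[["hsa-let-7a-5p"]]
patterns <- seed_sequences(mir)
patterns
#> Seed-site patterns for hsa-let-7a-5p
#>   7mer-m8: CTACCTC
#>   7mer-1A: TACCTCA

## a synthetic 300-gene transcriptome with planted 3'UTR sites,
## then scan it and test regional enrichment among repressed genes
cfg <- generator_config(seed = 42, n_genes = 300)
tx <- generate_transcriptome(cfg, patterns)
profiles <- profile_genes(tx$regions, patterns)
table(profiles$occupancy)
#>    3utr_only    5utr_only    both_utrs non_utr_only         none
#>           63           23            4           41          169

de <- generate_expression_response(tx$truth, cfg)
regional_enrichment(de, profiles, direction = "down")
#>     region site_class n_with n_without statistic            p degenerate
#> 1 promoter        any     17       164      1757 3.082939e-01      FALSE
#> 2     utr5        any     16       165      1751 1.410845e-01      FALSE
#> 3      orf        any     13       168      1233 7.856389e-01      FALSE
#> 4     utr3        any     65       116      2632 2.821825e-22      FALSE
```

Only the 3′ UTR — the region where the generator planted a −1 log₂
repression effect on seeded genes — is enriched; the other regions carry
sites but no effect, and their p-values are null.

```r
## signature selection on the packaged repressed-gene table,
## then survival stratification of a synthetic cohort
fx <- load_fixture_tables()
sig <- select_signature(fx$repressed_genes, fc_threshold = 2, q_threshold = 0.05)
sig
#> Gene signature: 18 genes (repression ratio > 2, q < 0.05)
#>   PRAS40, SLC7A5, CSF1, RRP1B, SEMA7A, ADAM19, TNFSF18, CARM1, ...

co <- generate_survival_cohort(generator_config(seed = 42, beta = 1, n_samples = 500))
scores <- signature_score(co$expression, co$signature_genes)
groups <- stratify_quantile(scores, upper_fraction = 0.25)
rec <- cbind(co$survival, group = as.character(groups))
kaplan_meier(rec)
#> Group high: 125 times, 115 events, final S = 0.000
#> Group low: 375 times, 276 events, final S = 0.090
logrank_test(rec)$p.value
#> 1.69e-28
```

The top-quartile score group (125 of 500 samples) has median survival 2.5
versus 10.7 time units in the bottom three quartiles — the planted
score-dependent hazard, recovered through scoring and stratification.

`run_pipeline(pipeline_config(seed = 1, beta = 1), "out/")` chains all
stages (simulate → scan → enrich → targets → signature → survive) and writes
per-stage TSVs plus a JSON run manifest.

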
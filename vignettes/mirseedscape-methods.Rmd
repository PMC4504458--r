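---
title: "Methods: seed-match target discovery, enrichment statistics and signature survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-match target discovery, enrichment statistics and signature survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseedscape)
```

## The analysis this package implements

A miRNA overexpression experiment destabilises the mRNAs of many direct
targets. `mirseedscape` turns that observation into a target-discovery
pipeline with four statistical stages, plus a synthetic-data module that
makes every stage testable against known ground truth.

### Seed-site model

The seed of a mature miRNA is positions 2–8 of its 5′→3′ sequence. Two
site classes are scanned, both 7 nt on the mRNA sense strand:

* **7mer-m8** — the reverse complement of seed positions 2–8;
* **7mer-1A** — the reverse complement of positions 2–7 followed by an `A`
  in the mRNA (the adenosine opposite miRNA position 1 is a property of the
  target, not a complementarity requirement).

No other site classes (6mer, 8mer as a separate class), conservation
filters, context scores or free-energy terms are modelled. Coordinates are
0-based, half-open; this makes interval merging unambiguous. `N` bases
never match (exact string equality), and scanning is invariant to case and
to U/T spelling.

Because an 8mer site contains one hit of each type offset by one base, a
gene's *typed* hit count can exceed its biologically meaningful site count.
Counting therefore runs on **merged sites**: overlapping 7-nt hit intervals
within a region collapse to one site (intervals starting ≥ 7 apart are
distinct). Typed hits are retained in scan output for inspection; all
presence/absence logic uses merged counts.

Each gene's four regions (promoter, 5′ UTR, ORF, 3′ UTR — any may be empty)
yield an occupancy category: `3utr_only`, `5utr_only`, `both_utrs`,
`non_utr_only`, `none`. The UTR categories ignore promoter/ORF sites: a
gene with 3′ UTR and ORF sites is `3utr_only`. The five categories
partition any gene set.

### Enrichment statistics

The enrichment question is: are repressed transcripts more likely to carry
a seed site in region *r* than expected? For each region we compare the
log₂ fold-change distributions of seeded vs unseeded genes with the
**Wilcoxon rank-sum test**:

* combined sample size ≤ 12: the two-sided p-value is exact — all
  $\binom{m+n}{m}$ assignments of the observed midranks are enumerated and
  the smaller tail probability is doubled (capped at 1). Enumeration with
  midranks is used for tied data too, so the exact regime never silently
  degrades;
* larger samples: tie-corrected normal approximation with continuity
  correction. Against exhaustive enumeration at 8-vs-8 the absolute error
  is typically below 0.01 with occasional excursions to ~0.011; tests
  bound it at 0.02.

The contrast population is a genuinely open design choice: an enrichment
figure of this kind can compare seeded vs unseeded genes *within* the
regulated set, or regulated seeded genes vs *all* unseeded genes. The
default is the within-direction contrast (`background = "direction"`),
which asks whether seed carriage deepens repression among already-repressed
genes and keeps the two groups matched on direction; the alternative is one
flag away. Direction membership is by fold-change sign; raw p-values are
reported per region (BH adjustment is available but regional p-values are
conventionally shown raw in this analysis).

Degenerate contrasts — a region where every gene or no gene carries a site —
report `p = NA` with a `degenerate` flag rather than a misleading 1.

**Seed-count response** bins genes by merged site count (default 0 / 1 / 2 /
≥3; the granularity is configurable because no standard exists) and
compares adjacent bins by rank-sum. A flat response across the seeded bins
is the signature of a per-gene (saturating) repression mechanism; strictly
decreasing medians indicate per-site additivity.

**Direct targets** are genes with adjusted p below threshold, repression
ratio above threshold and at least one merged 3′ UTR site. The repression
ratio is `2^-log2fc` (control/treatment; > 1 means repressed) — printed
fold-change tables in this field use that orientation, and `read_de_table()`
converts on read. With the fold-change threshold at its default of 1, the
called set is exactly the union of the `3utr_only` and `both_utrs`
occupancy classes among significantly repressed genes.

### Compartment profiling

Fold changes between compartments are ratios of group means of normalised
intensities (not means of per-sample ratios; robust to per-sample scaling).
With ≥ 2 samples per group a pooled two-sample t-test on log₂ intensities
supplies p-values, BH-adjusted across miRNAs. The original array pipeline
behind published compartment tables is vendor-specific and not
reconstructible, so the packaged candidate table is treated as a worked
example for ranking, never as a recomputation target. Ranking is by fold
change (descending for numerator-enriched candidates, ascending for
denominator-enriched), ties broken by q then identifier — fully
deterministic. Clustering uses `1 − Pearson correlation` across samples
with average linkage, the common expression-profiling default (both
configurable); rows are pre-sorted by identifier so input order cannot
change the dendrogram. qPCR relative quantification is the standard
`2^-ΔCt` against a reference gene.

### Signature scoring and survival

The signature is selected from a differential-expression table by
repression ratio > 2 and Q < 0.05 (defaults). The published description of
weighted-average scoring does not reproduce its weights; since every
signature gene is repressed by the same miRNA, the default weight is +1 per
gene, with `weights = "log2_ratio"` or a user-supplied named vector as
alternatives. The score is

$$\mathrm{score}_s = \frac{\sum_g w_g z_{gs}}{\sum_g |w_g|},$$

with $z_{gs}$ the per-gene standardisation across the scored samples (mean
0, sample SD with the $n-1$ denominator). Standardising within the scored
cohort — rather than against an external reference — is the choice made
here; it makes scores invariant to per-gene affine rescaling but means a
sample's score depends on its cohort.

Stratification takes the `1 − upper_fraction` type-7 quantile of the scores
as threshold; samples at or above it are `high`, so threshold ties all go
high and `|high| ≥ ⌈fraction · n⌉`. The quantile type and tie rule are
fixed because published high/low splits imply some tie convention without
stating one; determinism matters more than which convention. Constant
scores are an error — stratification would be meaningless.

Kaplan–Meier curves and the two-group log-rank test are delegated to the
`survival` package behind this package's interfaces (`kaplan_meier()`
returns per-group step functions with at-risk counts; censored observations
reduce risk sets without a step). With no censoring the estimate equals the
empirical survival function exactly. Only the univariate stratified
comparison is implemented; multivariate Cox adjustment is out of scope.

## The synthetic-data model

Generators are pure functions of a `generator_config()` (seed mandatory):
re-running one reproduces identical bytes.

**Transcriptome.** Background sequence is uniform over A/C/G/T with every
window matching either site pattern resampled until clean; sites are then
planted at recorded positions with ≥ 2 spare bases between sites, and
flanking bases are adjusted so a planted site of one type cannot create an
accidental hit of the other (an `A` after a 7mer-m8 site would contain a
7mer-1A; the m8's first base before a 7mer-1A would contain an m8). The
construction is verified by re-scanning and retried on the rare failure, so
**the scanner's output equals the planted truth exactly**, making
enrichment tests sharp rather than probabilistic. Per region, a gene is
seeded with probability `site_prob[region]` and then carries
`1 + Binomial(max_sites − 1, extra_site_prob)` sites, so `site_prob` is
exactly the seeded-gene fraction.

**Expression response.** Replicate intensities are normal on the log₂ scale
(lognormal intensities — the standard array noise model) around a per-gene
baseline; the treatment arm is shifted by the planted effect: `per_gene`
applies `delta[region]` once per seeded region, `per_site` multiplies by
the merged count. Defaults are the conditions the enrichment suites
assume: 500 genes, 20% 3′UTR-seeded, δ = −1 log₂ unit, σ = 0.5, 3
replicates per arm. Per-gene p-values come from the pooled t-test on log₂
intensities, q from BH.

**Compartment profiles.** A 3/2/3-replicate three-compartment design with
planted first/second-compartment ratios (default 10) on a log-normal noise
floor (σ = 0.2 log₂ units).

**Survival cohort.** Latent score ~ N(0, 1); event times exponential with
hazard $h_0 e^{\beta \cdot \mathrm{score}}$; censoring times uniform on
$(0, c_{\max})$ with $c_{\max}$ solved by root-finding so the expected
censored fraction matches the configuration (default 20%). Signature genes
track the score with unit slope plus noise, so weighted-average scoring
recovers it (correlation > 0.95 at the default noise); background genes
are inert.

**What the generators do not emulate:** probe-level array artifacts, batch
effects, gene–gene correlation, heavy-tailed noise, informative censoring,
or sequence composition bias (real UTRs are not uniform-random). Passing
tests therefore demonstrate correctness of the computations under the
stated model, not robustness of the science to real-data pathologies.

## Numerical conventions and edge cases

* Exact/approximate rank-sum cutoff at m + n = 12 (≤ 924 enumerations);
  continuity correction of 0.5 toward the null mean; all-tied data return
  p = 1.
* BH adjustment never lowers a p-value and is order-equivariant. (It is
  *not* idempotent in general: re-adjusting an adjusted vector multiplies
  by `m/i` again and collapses toward the largest value — a property worth
  knowing before feeding q-values back in.)
* Merged-site counting: intervals starting exactly 7 apart are adjacent,
  not overlapping — two sites.
* Zero group means in compartment fold changes flag the row rather than
  producing `Inf`; constant rows are dropped before clustering with a
  warning; empty count bins are omitted with a warning.
* Degenerate thresholds degrade gracefully: a q-threshold of 0 calls no
  targets and the pipeline completes with a warning rather than failing.

## Problem sizes used by the test and acceptance suites

Scanner-vs-oracle equivalence runs on 1,000 random sequences of 30–800 nt;
planted-truth round-trips on 100 random configurations of 8 genes; the
type-I suite on 1,000 replicates of 500-gene null cohorts (observed
rejection rate ~0.05); power and count-bin suites on 100 replicates each;
survival ordering on 100 cohorts of 500 samples. These sizes give stable
rates from pure-R simulation at interactive speed; all are set in the test
code, not in the package.

## Known limitations

* The scanner expects pre-extracted region sequences (FASTA with
  `gene|region` headers); it does not extract regions from genome
  annotation.
* Enrichment treats genes as exchangeable — no length or composition
  covariates, although longer UTRs carry more sites by chance in real
  data; the synthetic backgrounds are length-matched by construction, so
  this bias does not affect the validation suites.
* The compartment t-test/BH combination is a reasonable stand-in for
  whatever vendor pipeline produced any particular published table; exact
  Q-value reproduction is out of reach without the raw arrays.
* Survival analysis is univariate; no proportional-hazards diagnostics are
  provided.
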
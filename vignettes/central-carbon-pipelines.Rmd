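---
title: "Models and methods behind the central-carbon metabolomics pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the central-carbon metabolomics pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacarb)
```

This vignette is the package's own account of what it computes and why: the
statistical models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where the design was genuinely open.

## The data model

Targeted SRM metabolomics yields one protein-normalized peak area per
(metabolite, sample). `intensity_matrix` stores these as a tibble with one
row per metabolite and one numeric column per sample, plus three attributes:
a `scale` state, a sample→condition map, and a provenance log. Missing cells
are `NA`, deliberately distinct from 0 — a zero peak area is a measurement,
an `NA` is a value below the limit of detection (LOD). The scale state makes
the pipeline one-way: raw → log/log10 → median_centered, and an operation
demanding one scale rejects the others, so it is impossible to, say,
log-transform twice or median-center before imputing.

## Steady-state preprocessing

The chain is `filter_missingness` → `map_kegg` → `deduplicate` →
`log_transform` → `impute_qrilc` → `median_normalize`.

**Missingness filter.** A metabolite is retained iff its missing fraction is
*strictly* below τ (default 0.2) in at least one condition. The strict
inequality matters at the boundary: a metabolite missing in exactly 20% of
both groups is removed at τ = 0.2. The per-condition disjunction keeps
metabolites that are cleanly measured in one group but censored in the other
— exactly the ones that carry strong directional signal.

**KEGG mapping and deduplication.** Metabolites without a KEGG compound id
are dropped (pathway definitions are KEGG-keyed). When several chromatographic
entries map to one compound, one row must win: `higher_mean` keeps the entry
with the greater mean over all non-missing values (the convention for fly
SRM panels, favouring the better-detected transition);
`lowest_variance_in_normal` keeps the entry with the smallest variance across
normal-tissue samples (the convention for human cancer panels, favouring
stability in the reference tissue). Ties keep the first entry in input
order, making the result deterministic.

**Log transform and zeros.** Raw areas must be positive to log-transform. A
recorded 0 is ambiguous — a true zero is indistinguishable from below-LOD —
so the default is to *error* on zeros and make the caller decide;
`zeros = "missing"` applies the common alternative of treating zeros as
censored. The error-by-default choice avoids silently reclassifying data.

**QRILC imputation.** Missingness here is left-censored: each run has an
LOD, and everything below it is absent. Quantile-regression imputation of
left-censored data estimates, per sample, the full (uncensored) normal
distribution from the observed upper tail. If a fraction `p_obs` of a
sample's values is observed, the sorted observations are the empirical
quantiles of the full distribution at probabilities in (1 − p_obs, 1). We
place one grid point per observation, equally spaced from (1 − p_obs) + ε to
1 − ε with ε = 0.001 (a plotting-position convention that keeps `qnorm`
finite at both ends), and fit the straight line y = μ + σ·Φ⁻¹(p) by least
squares. Missing values are then drawn from Normal(μ, tune_sigma·σ)
truncated above at the estimated censoring point μ + σ·Φ⁻¹(1 − p_obs), via
inverse-CDF sampling so every draw respects the truncation exactly. Fitting
is per sample (column) because the censoring mechanism — the LOD — is a
per-run property.

Parameters: `tune_sigma` (default 1.0) shrinks or widens the imputation
spread without moving the censoring point; `min_observed_frac` (default
0.3) refuses samples with under 30% observed values, where the Q-Q line is
extrapolated too far — the fix is stronger filtering upstream, and the error
says so. On simulated standard-normal data censored at the 30th percentile
with 5,000 values per sample, the estimates land within ±0.05 of the true
μ = 0 and σ = 1 (this is asserted in the test suite).

**Median centering.** After imputation each sample's median is subtracted:
metabolites at the sample median map to 0, below-median to negative values.
The pipeline returns *both* the imputed matrix and the median-centered
matrix: enrichment statistics consume the imputed matrix (centering is a
monotone per-sample shift that would not change Welch tests anyway, but the
imputed matrix is the canonical analysis object), while the centered matrix
is the display/relative-abundance object. Exposing both avoids guessing a
single canonical output.

## Differential statistics

`welch_test` is the unequal-variance two-sided t test, sample sd on n − 1,
Welch–Satterthwaite df. P values are reported unadjusted; a
Benjamini–Hochberg column is included for users but never drives the
significance flag, keeping per-metabolite significance calls comparable with
the common practice for targeted panels (a few hundred partially dependent
tests). Degenerate inputs follow explicit conventions rather than producing
NaN: both groups constant and equal → p = 1, flagged; both constant but
different → p = 0, flagged; fewer than 2 values in either group → p = NA,
flagged and excluded downstream. `row_zscore` is the heatmap display
transform ((x − row mean)/row sd; constant rows emitted as zero and
flagged); it produces a terminal `zscore` scale that no pipeline operation
accepts as input.

## Pathway scores

**ORA.** The enrichment statistic is the hypergeometric upper tail
P[X ≥ k], with the background N defined as all tested, KEGG-mapped
metabolites — not the pathway universe — so the test conditions on what the
panel could actually see. Pathways with fewer than `min_members = 2`
measured members are dropped: singletons reduce to the metabolite's own test
and would dominate rankings. Sorting is by ascending p, ties broken by
descending enrichment ratio (k/m)/(K/N), then name, so rankings are total
and reproducible. Web-platform enrichment tools layer further modelling on
top of set statistics; absolute p values from this implementation will
differ from theirs, while rankings on strong effects agree — which is what
the cross-study comparison consumes.

**DA score.** S = (U − D)/T summarizes the net direction of metabolite
change per pathway on a [−1, 1] scale: +1 means every measured member is
significantly up. U and D count unadjusted-significant members at α; T is
members measured. S is exactly antisymmetric under negating all effects, a
property the tests assert.

## Cross-study concordance

Two studies are compared on their top-k enriched pathways (k default 16).
`shared_enriched` reports the overlap per study and, because "shared with
multiple datasets" is ambiguous when there are several comparison studies,
counts reference-top pathways appearing in at least t studies for *every*
t = 1..n_studies, defaulting displays to t = 1. Direction comes from
sign(S): a shared pathway is concordant when the signs agree and neither is
zero; zero-sign pathways presume no direction and are excluded from the
denominator but listed. The concordant fraction is reported per study and
pooled (summed counts), since "two-thirds concordance" can legitimately mean
either. `concordance_permutation_null` permutes the comparison study's
directions across its pathways and reports
p = (1 + #{c_perm ≥ c_obs})/(1 + n_perm), the standard add-one permutation
estimator whose floor is 1/(n_perm + 1).

## Isotopologue tracing

Inputs are long tables of protein-normalized areas per (metabolite, M+i,
sample). `fractional_labeling` normalizes each (metabolite, sample) pool to
fractions f_i, the labeled fraction L = 1 − f₀, and the mean enrichment
E = Σ i·f_i / n_max. Dividing by the carbon capacity n_max makes E
comparable across metabolites of different carbon number — necessary for
chain scoring — at the cost of treating E as a fraction of *possible*
labeling rather than an absolute count. Conventions: unmonitored mass-shift
channels are filled with area 0 (an unmonitored SRM transition contributes
nothing to the pool; the filled count is recorded so users can audit);
zero pools are flagged undefined and excluded from tests; fractions are
computed per replicate and then tested, matching per-replicate plotting of
biological points, rather than pooling areas first. No natural-abundance
correction is applied: the data model is raw SRM isotopologue areas, and a
correction-matrix step can be added upstream without changing any interface.

`pool_partition` compares M+0, ΣM+n (n ≥ 1) and each individual isotopologue
pool between conditions, each with its own unadjusted Welch test — tests are
applied independently per isotopologue. `fraction_test` does the same on the
fractions and on L, and flags the *reciprocal* pattern (f₀ significantly
down with some f_{i≥1} up) that signals increased tracer incorporation.
Because fractions sum to 1, the fraction deltas sum to 0 for every
metabolite — asserted, not assumed, in the tests.

**Chain discontinuity.** For an ordered metabolite chain (upstream →
downstream), d_j = E(m_j) − E(m_{j+1}) scores each edge; a large positive
score — a precursor markedly more enriched than its product — marks a
candidate point where labeled carbon leaves the chain (a drain node). E is
chosen over L for the score because it weights higher-order isotopologues,
which are precisely what fails to propagate through a drain; L is available
in the same table for comparison. The candidate edge is the argmax over
positive scores (no candidate if none is positive), with a percentile
bootstrap CI over replicates. With a planted drain (E 0.8 → 0.3, cv = 0.1,
n = 6) the argmax localizes the edge in ≥95 of 100 seeds.

## The synthetic-data generator

The generator provides planted-truth data matching the structure of the real
pipelines' inputs: 310 metabolites by default (the scale of a polar SRM
panel), 6 replicates per condition (typical for these designs), log-normal
intensities with per-metabolite baselines N(18, 1.5²) on the natural-log
scale (peak areas around 10⁷–10⁸) and replicate sds uniform on 0.2–0.6,
multiplicative log-normal noise for tracing areas (cv default 0.1; peak
areas are positive and heteroscedastic, so noise is multiplicative, not
additive), per-replicate pool sizes log-normal with cv 0.2, and left
censoring at a per-sample quantile q_c (default 0.15) — the LOD-varies-by-run
mechanism QRILC assumes. Effects are planted as per-pathway log-scale mean
shifts; multi-study panels plant exactly round(cf·n_shared) concordant
pathway directions per study (seeded random subset), recording the realized
fraction when cf is not exactly representable. Duplicate-KEGG rows (lower,
noisier copies) exercise both dedup rules; comparison studies carry a
"normal" condition so the human-panel rule is testable.

What it does *not* emulate: chromatographic drift and batch effects,
correlated metabolite panels (covariance is diagonal given the planted
shifts), natural-abundance isotope patterns, and non-normal heavy-tailed
noise. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated censoring and noise model, not robustness to
every artefact of real LC-MS data.

## Numerical and reproducibility conventions

Every stochastic operation takes an explicit integer seed; fixed seed means
identical output, and the CLI writes numeric report values at 12 significant
digits so determinism is byte-testable. Matrix files round-trip bit-exactly
(shortest round-trip double representation). Problem sizes used by the test
suite and the acceptance script — 5,000 values per sample for imputation
recovery, 2,000 null metabolites for type-I calibration, exhaustive
enumeration up to N = 12 for ORA, 100 seeds for discontinuity detection,
5 studies × 12 shared pathways for the end-to-end concordance — were chosen
to make Monte-Carlo error small relative to the assertions while keeping the
default run a desk-scale computation.

## Known limitations

Imputation assumes a normal uncensored log-intensity distribution per
sample; heavy-tailed or multimodal samples will bias μ̂ and σ̂. The ORA
background is the measured panel, so conclusions are conditional on panel
design. DA scores treat all pathway members equally regardless of topology.
The discontinuity score compares adjacent chain members only and does not
model branch points feeding into the chain; it localizes, but does not
quantify, a flux bottleneck — formal flux analysis is out of scope.
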
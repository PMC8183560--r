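# fmtengraft

Coverage-aware engraftment analysis for placebo-controlled fecal
microbiota transplantation (FMT) trials.

Longitudinal 16S amplicon studies of FMT ask which donor microbes
establish durably in recipients (*gains*) and which resident microbes
are displaced (*losses*), at the resolution of amplicon sequence
variants (ASVs).  Naive presence/absence bookkeeping fails on real
data for two reasons: sequencing depth varies more than an order of
magnitude between samples, so detection limits masquerade as biology;
and communities fluctuate, so a treatment-attributed gain must be
*consistently* present across follow-ups.  `fmtengraft` is for
microbiome analysts working with such trials: it implements a
Poisson detection-limit scoring scheme for per-patient per-ASV gain
and loss calls, plus the surrounding trial analyses — donor-anchored
alpha-diversity classification, generalized UniFrac dynamics toward
the donors, placebo-floored post-processing of microbial
source-attribution output, clinical response/severity classification
from IBS-SSS, and differential-abundance and correlation screens with
Benjamini–Hochberg control.  A synthetic-cohort simulator with planted
ground truth makes every stage testable end to end without external
data.

## The core model

If an ASV with true relative abundance *p* is sequenced to depth *C*,
its read count is ~ Poisson(λ) with λ = *Cp*, so the probability a
truly present ASV yields at least one read is

    score(λ) = P(X ≥ 1) = 1 − exp(−λ)

For an ASV absent at baseline, the **gain score** multiplies (a) the
confidence that the baseline absence is real, 1 − exp(−λ₀) with
λ₀ = baseline coverage × mean follow-up proportion, by (b) a
consistency term over chronologically adjacent follow-up pairs — 1
when both present, 0 when both absent, exp(−λ) when exactly one is
absent (the probability that absence is a depth artifact) — with the
pair scores multiplied pairwise along the series and the products
averaged.  For an ASV present at baseline, the **loss score** averages
pairwise products of per-follow-up terms: 0 where observed, else
1 − exp(−C·p_T0).  Scores ≥ 0.85 are called; ternary profiles (0 lost,
1 unchanged, 2 gained) feed Euclidean distances, PCoA, and a
permutation test for arm-level differences.  Engraftment proportions
from source tracking are background-corrected against the placebo arm:
score = (P_FMT − P_placebo)/(1 − P_placebo), floored at zero.

## Worked example

Simulate a small trial with planted truth, score it, and summarize:

```r
library(fmtengraft)

# a transient colonizer: present in the first two follow-ups only;
# a naive comparison of baseline vs early follow-ups would call a gain
gain_score(c(0, 20, 20, 0, 0), c(1e4, 1e4, 1e4, 1e3, 1e3))
#> [1] 0.06766457     # far below the 0.85 cutoff: correctly not gained

cfg <- simulation_config(n_fmt_patients = 6, n_placebo_patients = 6,
                         n_asvs = 300, n_planted_gains = 12,
                         n_planted_losses = 8, n_planted_transients = 10,
                         dropout_rate = 0, rng_seed = 42)
sim <- simulate_cohort(cfg)
scores <- score_cohort_gain_loss(sim$table, sim$meta)
calls  <- call_gains_losses(scores, cutoff = 0.85)
summarize_gains_losses(calls, sim$meta, sim$taxonomy)$group_summary
#> # A tibble: 2 × 4
#>   arm     n_patients median_gains median_losses
#> 1 FMT              6         95.5             8
#> 2 placebo          6          0               0
```

The FMT arm's median of 95.5 called gains combines the 12 planted
gains with donor taxa genuinely introduced by the simulated donor
mixing; the placebo arm's spontaneous fluctuations are transient and
essentially never called.  The Mann–Whitney comparison of per-patient
counts gives p = 0.0037 (gains) and p = 0.0013 (losses).  The
donor-anchored baseline classification recovers the planted
low-diversity patients exactly (2 low / 4 normal per arm).

## The analysis workflow

Numbered drivers under `analysis/` run the full analysis on a
full-scale synthetic cohort (52 patients, 2,000 ASVs, ~20% missing
visits), each printing what it found and writing tables under
`results/`:

1. `01_simulate_cohort.R` — cohort, tree, truth ledger
2. `02_alpha_diversity.R` — Chao1/Shannon/Simpson, low/normal classes,
   change-from-baseline tests
3. `03_beta_diversity.R` — generalized UniFrac distance-to-donors
   course and PCoA
4. `04_gain_loss.R` — scores, ternary calls, recovery vs truth,
   summaries, trend test
5. `05_engraftment.R` — source attribution, placebo-floored genus
   scores
6. `06_clinical_stats.R` — response/severity, differential abundance,
   diversity–symptom screen

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

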
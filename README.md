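# lectinLFQ

Identification and quantification of **core-glycosylated surface proteins**
from differential lectin-affinity label-free quantitative (LFQ) mass
spectrometry, for proteomics groups analysing lectin pull-downs with a
glycosidase-defined background.

The experimental design the package models: surface proteins are purified
with the mannose-binding lectin concanavalin A (ConA) either directly
(condition **A**, target — mannose-rich *core* N-glycans intact) or after
EndoH digestion, which removes core glycans and abolishes specific binding
(condition **B**, background). EndoH is efficient but not absolute, so B is
a mixture of missing values and low-intensity carry-over — which breaks the
usual protein-level LFQ averaging. The package implements a peptide-based
strategy instead, plus the downstream quantification steps used alongside
it.

## The statistics at the core

Each peptide is placed in a two-dimensional score plane:

* **Repeatability** `r = ICC_bio x ICC_tech`, the product of two one-way
  random-effects intraclass correlations over the condition-A intensities:
  grouped by biological replicate, and grouped by preparation
  (biological x experimental replicate). For class mean squares MSB, MSW
  and effective class size k0,

  `ICC(1) = (MSB - MSW) / (MSB + (k0 - 1) MSW)`, clamped to [0, 1].

* **Enrichment** `e = (mean_A - mean_B) / max(mean_A, mean_B)` on
  zero-imputed intensities, bounded in [-1, 1]: `e = 1` for peptides found
  only in A, `e = 0` for equal abundance.

Peptides are separated by hierarchical clustering (Euclidean distance, cut
at 0.2) in the `(r, e)` plane; the *natural cluster* — the one with the
jointly highest repeatability and enrichment centroid — defines the
high-confidence core-glycosylated protein calls. The calls are
cross-validated three ways: a retrospective two-sample Kolmogorov–Smirnov
comparison of member vs non-member peptides, a conventional LFQ selection
(detection in >= 10 of the 13–14 A runs, >= 1.3-fold A/B ratio,
Kruskal–Wallis p < 0.05) with a set-concordance summary, and exact
hypergeometric annotation enrichment against a reference proteome.

Companion modules quantify relative surface expression from two-fraction
blots, `S / (S + bI/a)` with `1/a`, `1/b` the loading dilutions;
glycoform-resolved half-lives from pulse-chase decays (log-linear fits,
`t_half = ln 2 / lambda`); and stimulus-response kinetics (time-to-peak,
mono-exponential plateau decay).

Because the study's raw runs are not deposited, a synthetic-data module
generates peptide tables with the study's full replicate structure
(2 biological x 2 experimental x 3–4 technical replicates = 14 runs per
condition) and planted targets, so the whole pipeline is exercised and
tested end to end against known ground truth.

## Worked example

```r
library(lectinLFQ)

sim <- simulate_peptide_table(sim_config(seed = 7))
sim$table
#> peptide_table: 1231 peptides, 300 protein groups, 28 runs (14 A, 14 B)
#>   missing cells: 913 (2.6%)

res <- run_peptide_pipeline(sim$table)   # score -> cluster -> select -> call
res
#> peptide-based LFQ pipeline: 1231 peptides, 2 clusters, 30/300 protein groups called core-glycosylated
#>   retrospective KS: D(e) = 1.000, D(r) = 0.379

evaluate_calls(res$calls, sim$truth)[c("sensitivity", "fdp")]
#> $sensitivity
#> [1] 1
#>
#> $fdp
#> [1] 0

std <- standard_lfq_select(sim$table)
concordance(res$core_proteins, std$proteins)
#> [1] 100
```

All 30 planted target proteins are recovered with no false calls; every
call is confirmed by the conventional selection (100% concordance), and the
KS statistic `D(e) = 1` says the called proteins' peptides are perfectly
separated from the background in enrichment.

Glycoform turnover from a simulated pulse-chase (generating half-lives
3.4 h core / 21.1 h mature, 10% noise, 4 replicates):

```r
s <- simulate_decay_series(c(core = 3.4, mature = 21.1),
                           times = c(0, 2, 4, 8, 16, 24),
                           noise_cv = 0.1, n_rep = 4, seed = 7)
round(compare_glycoform_turnover(s)$half_lives, 2)
#>   core mature
#>   3.30  23.29

fit_half_life(s, form = "core")
#> half-life: 3.3 h (lambda = 0.2099 /h, 4 replicates, SEM 0.0313 h)
```

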
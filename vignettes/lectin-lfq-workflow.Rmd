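---
title: "Peptide-based scoring of differential lectin-affinity LFQ: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-based scoring of differential lectin-affinity LFQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinLFQ)
```

## The problem

Mannose-rich ("core") N-glycans are normally an endoplasmic-reticulum
intermediate, yet a sizeable population of neuronal surface proteins
carries them. Operationally they are defined by two reagents: they bind
the lectin ConA, and that binding is destroyed by EndoH, which cleaves
core but not mature complex glycans. A differential purification therefore
yields a target condition **A** (ConA-bound, no EndoH) and a background
condition **B** (ConA-bound after EndoH). If deglycosylation were perfect,
B would be empty; in practice it is a mixture of missing values and
low-intensity non-specific carry-over. That asymmetry — absence in B is
*informative*, not missing-at-random — is what breaks standard
protein-level LFQ averaging and motivates a peptide-level strategy.

## Peptide scoring model

Every peptide is summarized by two statistics.

**Repeatability.** Detection reproducibility across the nested replicate
structure (biological preparations, affinity-purification preparations,
repeated LC-MS injections) is measured with the one-way random-effects
intraclass correlation, the only ICC computable from a plain grouping with
no rater structure. For $a$ classes of sizes $n_i$ ($N = \sum n_i$),

$$\widehat{ICC} = \frac{MS_B - MS_W}{MS_B + (k_0 - 1)\,MS_W},\qquad
k_0 = \frac{N - \sum n_i^2/N}{a - 1},$$

clamped to $[0,1]$ (the estimator can go negative when between-class
spread falls below the within-class expectation; a negative variance
component carries no extra information here). An all-identical input is
defined as ICC $= 1$, the continuity limit of perfect repeatability.
The peptide's repeatability index is the product
$r = ICC_{bio} \times ICC_{tech}$: the ICC of its condition-A intensities
grouped by biological replicate, times the ICC of the same intensities
grouped by preparation. Condition A is used because that is where the
target signal lives; a config switch includes B.

**Enrichment.** $e = (\bar{x}_A - \bar{x}_B) / \max(\bar{x}_A, \bar{x}_B)$
on zero-imputed raw intensities (never log-transformed — the statistic is
defined on intensities). The max-of-means denominator bounds $e$ to
$[-1, 1]$, with $e = 1$ exactly for A-only peptides and $e = 0$ for equal
means; $0/0$ is defined as $0$. An alternative reading of the denominator
(maximum over single runs) is available via the scoring internals but is
not the default, because it does not give the clean $[-1,1]$ bounds that
the score plane relies on.

## Cluster selection

Peptides are clustered in the $(r, e)$ plane with hierarchical
agglomeration on Euclidean distance and the dendrogram cut at 0.2 — i.e.
two tenths of the unit-bounded score axes. The default linkage is
**single**, so the cut is exactly a 0.2 threshold on the pairwise distance
matrix: clusters are the connected components of the "closer than 0.2"
graph. This choice is deliberate and load-bearing. With only two
biological replicates — the design this assay actually uses — a one-way
ICC estimate from two classes is intrinsically high-variance, so genuinely
enriched peptides form a dense *band* spanning the full repeatability axis
at high enrichment rather than a tight blob. Average or complete linkage
at cut 0.2 fragments that band into several clusters and the subsequent
selection keeps only a fragment; single linkage keeps the band whole while
the wide enrichment gap to the background keeps the two components apart.
Average, complete and Ward linkage remain available through the `linkage`
argument for data where the blob geometry is different.

The *natural cluster* is the one maximizing the centroid mean
$(\bar r + \bar e)/2$, ties broken by higher $\bar e$, then larger size.
A protein group is called core-glycosylated when at least `min_peptides`
(default 1) of its peptides fall in that cluster. Two retrospective
checks follow: a two-sample Kolmogorov–Smirnov comparison of the called
proteins' peptides against the rest (on $e$ and on $r$), and a
conventional LFQ selection — detection in at least 10 of the 13–14 A
runs, condition-mean ratio at least 1.3 (inclusive), Kruskal–Wallis
p below 0.05 per peptide, uncorrected (the test is used as a filter, so
no multiplicity adjustment is applied by default) — summarized as the
percentage of peptide-based calls the conventional selection confirms.
"Detected" always means observed before zero-imputation; the fold change
is computed after it.

## Annotation enrichment

Category over-representation of the calls uses the exact hypergeometric
upper tail ($p = P(X \ge k)$, no normal approximation) and fold enrichment
$(k/n)/(K/N)$ against a reference proteome, with selected proteins absent
from the reference appended to it (a double-purification can legitimately
recover proteins the reference list lacks). The baseline for fold
enrichment is the full universe; raw p-values are reported by default with
Benjamini–Hochberg available via `adjust = TRUE`. Topology/glycosite
classes arrive as flat annotation tables; the package does not run
predictors or traverse ontologies.

## Surface expression and kinetics

With band intensities $S$ (surface fraction, loaded at dilution $1/a$) and
$I$ (intracellular, $1/b$), relative surface expression is
$S/(S + bI/a)$; treatment effects are expressed as $\log_2$
treated/control ratios. Pulse-chase turnover is fit per replicate by
ordinary least squares of $\ln(\text{intensity})$ on time — matching how
such decays are plotted and summarized on a log scale — with
$t_{1/2} = \ln 2 / \lambda$ and replicates aggregated as mean ± SEM
(pooling before fitting is the main alternative; per-replicate fits match
the error reporting convention of the blots). Zero or negative
intensities are excluded from the log fit with a recorded count; a
non-decaying series is flagged with an infinite half-life rather than an
error. A nonlinear least-squares alternative with a background offset is
available (`method = "nls"`). For a summed two-form pool the log-linear
fit of a sum of exponentials is an effective single-rate approximation;
its half-life falls between the two component half-lives.

Stimulus-response traces (baseline-normalized fluorescence, explicit
stimulus onset — onset is an input, never inferred) yield the post-onset
peak, time-to-peak, and a mono-exponential plateau decay
$f(t) = p + (1-p)e^{-t/\tau}$ of the peak-normalized tail. Numerically
the decay amplitude is a free parameter ($p_0 + A e^{-t/\tau}$, plateau
$= p_0/(p_0+A)$): pinning the amplitude to the observed maximum
propagates the noise of that single sample into $\tau$ (an upward bias of
order 10% at 5% measurement noise), while the free-amplitude fit is
unbiased and reduces to the same model when noise-free. A trace whose
fitted decay amplitude is below `flat_tol` ($10^{-3}$ of the peak) leaves
$\tau$ unidentifiable and is flagged rather than fit.

## The synthetic-data generator

No raw runs are publicly deposited for this assay, so the generator is a
first-class module that reproduces the statistical structure the scoring
assumes; its defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_bio`, `n_exp`, `n_tech` | 2, 2, (3,4,3,4) | 14 runs per condition: 2 biological preps x 2 purifications, injected 3–4x |
| `n_proteins`, `frac_target` | 300, 0.10 | proteome size and planted core-glycosylated fraction |
| `peptides_per_protein` | 4 | mean of a zero-truncated Poisson |
| `base_log_intensity`, `sigma_peptide` | 14, 1.5 | natural-log intensity scale of LC-MS peptide signals |
| `sigma_bio`, `sigma_exp`, `sigma_tech` | 0.5, 0.3, 0.2 | nested log-scale variance components; biology varies most, injections least |
| `target_B_attenuation` | 10 | EndoH removes most, not all, specific binding |
| `dropout_B` | 0.5 | Bernoulli missingness of target peptides in B |
| `background_noise_inflation` | 2 | run-level noise multiplier for non-target peptides |
| `dropout_floor` | 0 (off) | optional raw-intensity censoring across all runs |

Intensities are log-normal with additive nested random effects on the log
scale — the standard multiplicative-error model for LFQ. The biological
effect of a peptide is shared between the A and B runs of the same
biological preparation (both conditions derive from one surface proteome);
preparation and run effects are independent per condition. Background
peptides get inflated *run-level* noise only: non-specific carry-over
repeats poorly from injection to injection, which places background
peptides in the low-repeatability region of the score plane as in the
real assay, while run-level noise averages out of the 14-run condition
means and therefore leaves the enrichment separation intact. (Inflating
preparation-level noise instead widens the background enrichment tails
until chaining merges the clusters — a useful stress case, reachable by
configuration, but not the default study condition.)

What the generator does **not** emulate: retention-time structure and
match-between-runs, shared-peptide protein inference (one peptide, one
protein by default; a `shared_peptides` toggle exists), interference/
co-elution, intensity-dependent missingness in the default setting
(available via `dropout_floor`), and any search-engine identification
error. Passing tests therefore demonstrate the correctness and internal
consistency of the statistical procedure under its own assumptions — not
robustness to those real-data phenomena.

## Numerical choices and degenerate inputs

* Normalization: total-sum scaling of each run to the across-run median
  of observed sums (the simplest LFQ-consistent choice; switchable off).
  An all-missing run is left unscaled with a warning. Normalization is
  idempotent and order-preserving within runs.
* Missing data: `NA` at ingest, collapsed to 0 before scoring (absence in
  B is evidence); the pre-imputation detection mask is retained for the
  conventional selection's detection filter.
* ICC: undefined for fewer than two classes or no replication — such
  peptides score $r = 0$ with a `degenerate` flag rather than aborting a
  whole-table scan.
* Clustering determinism: points are canonically ordered before
  agglomeration and cluster labels renumbered by centroid quality, so the
  partition is invariant to input order; cutting lower refines the
  partition (a property of any dendrogram cut).
* Inclusive thresholds (`>=`) at the detection-count and fold-change
  boundaries of the conventional selection.
* Exact hypergeometric tails everywhere; $k = 0$ gives fold 0 and $p = 1$.

## Problem sizes

The test suite and `scripts/acceptance.R` run the full pipeline on the
default 300-protein / ~1200-peptide / 28-run experiment (seconds), verify
the ICC estimator against an ANOVA-from-definitions oracle on 200 random
tables, the hypergeometric tail against explicit enumeration over the
complete $N \le 60$ grid, and half-life recovery over 100 simulated
chases at the generating half-lives 3.4 h and 21.1 h with 10%
multiplicative noise — sizes at which every check is exact or tightly
bounded while the whole suite stays fast.

## Known limitations

The natural-cluster criterion assumes the target band and background are
separated in enrichment by more than the cut height; with much weaker
attenuation or heavier background tails the components can touch, at
which point single linkage merges them (the failure is conservative in
neither direction — it simply calls everything, and the retrospective KS
statistic collapses, which is the diagnostic to watch). Protein calls
default to single-peptide evidence, inheriting peptide-level error;
raise `min_peptides` for stricter calls. The concordance statistic is
directional (fraction of peptide-based calls confirmed) and says nothing
about proteins only the conventional selection finds.
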
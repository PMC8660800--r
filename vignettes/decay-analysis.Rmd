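---
title: "Methods: mRNA half-life estimation, deadenylation kinetics and interactome filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mRNA half-life estimation, deadenylation kinetics and interactome filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decaykit)
```

# Scope

`decaykit` quantifies mRNA turnover controlled by the CCR4-NOT deadenylase
from four kinds of measurements: actinomycin-D (actD) transcription shut-off
RNA-seq time courses, targeted qPCR/northern/western chase series, gel line
scans of in vitro deadenylation reactions, and AP-MS bait-versus-control
proteomics. A synthetic-data module generates each input type with known
ground truth, so every stage of the analysis is testable end to end without
raw sequencing or MS data. This vignette documents the models, the tunable
parameters, and the design decisions where the methodology was genuinely
open.

# First-order decay model

All half-life estimation assumes first-order kinetics: abundance
$y(t) = a\,e^{bt}$ with $b < 0$ for a decaying transcript, so that
$t_{1/2} = \ln 2 / (-b)$. Fits are performed by ordinary least squares of
$\ln y$ on time ("log-linear"), pooling all replicate points of a condition
into one regression. This reading of "fitting an exponential by linear
regression" is used consistently for the RNA-seq, qPCR and protein cases, so
the targeted and transcriptome-wide code paths share one OLS core and agree
exactly on identical inputs. A nonlinear least-squares alternative
(`fit_first_order(..., method = "nls")`) exists for sensitivity analysis but
is off by default: on log-normal multiplicative noise (the realistic case
for counts and densitometry) the log-linear fit is the maximum-likelihood
estimator, and it cannot chase negative predictions.

Assumptions worth keeping in mind:

* **Single phase.** Biphasic decay, delays after actD addition, or residual
  transcription all violate the model; the $R^2$ filter (below) removes the
  worst offenders but does not test for them explicitly.
* **Positive signals.** Logarithms require positive values. Zero counts are
  **dropped** from the regression, and a fit is attempted only when at least
  3 positive points remain (`status = "too_few_points"` otherwise, recorded
  in the exclusion log rather than raised as an error). A pseudocount was
  rejected deliberately: it biases the slopes of exactly the fast-decaying
  genes the analysis cares most about, whereas the positive-half-life and
  $R^2$ filters already remove genes too sparse to fit.
* **Censoring.** For targeted series, a fitted half-life longer than the
  observation window is reported as a bound (`"> 6 h"`) and flagged
  `censored`, never as a point estimate; a chase that shows no decay cannot
  distinguish 12 h from 120 h.

# Spike-in normalization

ActD shuts off transcription globally, so total mRNA shrinks over the chase
and within-sample normalizations (CPM, TPM) would erase the very signal
being measured. Each sample therefore receives a fixed mass of external
spike-in RNA (ERCC mix), and every gene's counts are divided by the sample's
total spike-in reads. Expected spike-in abundance is constant over time, so
the normalized series is proportional to absolute abundance.

A cosmetic rescale keeps normalized values in a count-like range. It is
implemented as the **power of two nearest the median spike-in total** rather
than the median itself: multiplying by a power of two is exact in binary
floating point, which makes every downstream slope, $R^2$ and half-life
bit-for-bit invariant when a sample's library size changes (a property the
test suite asserts with `identical()`). Any common scale factor is
mathematically irrelevant to the fits; this choice makes it numerically
irrelevant too.

Samples with zero spike-in reads are a hard error naming the sample:
normalization is undefined there and silently dropping the sample would
change the design.

# Reliability filtering

A gene enters the half-life table only if, **in every condition**, its fit
succeeded, its slope is negative (finite positive half-life), and its
$R^2$ exceeds 0.5 **strictly**. Spike-ins are always excluded. Genes that
never produced a fittable series are reported as `not_quantified`, distinct
from `filtered`, so losses to sparsity and losses to poor fits can be
audited separately.

Two consequences of this filter matter for interpretation:

* **Survivorship bias.** Long-lived transcripts barely decay over a 6-h
  chase, so their $R^2$ is low and they are removed preferentially. The
  retained median half-life therefore sits a few percent below the true
  population median. This is a property of the filtering strategy itself,
  not of this implementation, and it affects real data identically.
* **Regression to the mean in binned analyses.** Binning genes on the
  *estimated* reference-condition half-life preferentially places
  upward-noise estimates in the top bin; the second condition's independent
  estimate of the same genes is unbiased, so the top bin's median ratio
  drifts below 1 even between biologically identical conditions. Per-bin
  conclusions are therefore safest for the lower bins, and the rescue
  analysis asserts its "no effect" claims only there.

## Replicate handling

Whether replicates should be pooled into one regression or fit separately
and averaged is not dictated by the model. The default **pools** all
replicate points of a condition: it gains degrees of freedom at these small
designs (8 points instead of 4) and yields the single $R^2$ that the filter
thresholds. Per-replicate fits (`per_replicate = TRUE`) are provided for
sensitivity analysis; at low noise the two agree closely.

# The chase simulator

`simulate_chase()` draws true half-lives from a log-normal (default median
4.9 h, log-SD 0.5 — a typical spread for mammalian mRNA stability, giving
roughly a 2.7-fold interquartile range), assigns each condition a global
decay multiplier, and samples gene-level counts as negative binomial with a
shared size parameter around expectations
$a_{0,g}\,e^{-k_g m_c t}$, scaled so that spike-ins take a fixed fraction
(default 5%) of the library at $t = 0$. Defaults emulate a two-condition
HeLa experiment: 2000 genes, $t = 0/2/4/6$ h, two replicates, depth
$5\times10^6$, NB size 50 (14% biological CV), 92 spike-in species. The
three-point design ($0/3/6$ h) is supported by changing `timepoints_h`.

Gene-set effects (an IEG-like labile subset with extra per-condition decay
multipliers) are assigned as consecutive index blocks recorded in the truth
table, so subgroup analyses are exactly reproducible. Stability-conditional
effects (`stability_effects`) apply an extra multiplier only to genes whose
baseline half-life exceeds a threshold; this encodes a rescue construct that
restores short-lived but not long-lived transcripts. For the four-condition
rescue analysis the simulator is run with log-SD 0.6 and NB size 200: the
long-lived bins drive that contrast, and they are informative only in an
experiment clean enough that genes beyond 9 h pass the reliability filter.

What the generator deliberately does **not** emulate: read-level artifacts
(mapping, positional/length bias), fragment-level sampling, transcriptional
leakage after actD, delayed shut-off, batch effects between replicates, or
correlated gene-gene noise. Passing recovery tests on this generator
demonstrates that the estimation pipeline is correct and well-calibrated for
first-order decay with NB counting noise — not that any real chase satisfies
those assumptions.

# Deadenylation kinetics from line scans

In vitro deadenylation assays resolve a short fluorescent RNA (7-nt body +
20 As) on a denaturing gel; the poly(A) ladder collapses toward the body
band as CCR4-NOT removes adenosines. The quantification chain is:

1. **Calibration** (`calibrate()`): strictly monotone piecewise-linear
   interpolation of fragment length against migration position from the
   marker lane. PAGE mobility is only locally linear in length, so the
   calibration never assumes a global linear model, and extrapolation
   outside the marker range is clamped.
2. **Modal intermediate** (`most_abundant_tail()`): rolling-minimum
   background subtraction (window 21 grid points, clamped at zero), then
   the global intensity argmax within the calibrated region, mapped to
   length, minus the body (7 nt), rounded to a whole adenosine (the
   intermediates form a single-nucleotide ladder). Ties are broken toward
   the **longer** tail: deterministic, and conservative in that it can only
   underestimate the rate.
3. **Rate** (`estimate_rate()`): OLS of tail length on time over the
   pre-plateau window; the apparent rate in As/min is the negative slope.
   Points after the series first reaches ≤ 1 A are excluded (the first such
   point is kept as the end of the linear phase) — a fully deadenylated
   substrate carries no kinetic information and including it flattens the
   slope. The threshold is configurable. A positive slope is physically
   impossible and is clamped to rate 0 with a warning.
4. **Fold inhibition** (`fold_inhibition()`): ratio of reference to test
   rate with the standard error propagated from both regressions; a zero
   test rate yields the lower bound `reference/SE` instead of infinity.

# Comparative statistics

Half-life tables are compared with the two-sided **Wilcoxon signed-rank**
test on per-gene pairs. The terminology "paired rank sum" is internally
inconsistent (the rank-sum test is unpaired); since the pairing of the same
genes across conditions is the scientifically meaningful structure, the
signed-rank test is implemented, with an unpaired Mann–Whitney option for
sensitivity analysis. Zero differences are dropped before ranking
(Wilcoxon's original treatment). The exact null is used for n ≤ 25 untied
pairs (with tied magnitudes and n ≤ 14, by full sign enumeration with
average ranks) and the normal approximation with continuity correction
above. No multiple-testing correction is applied across bins or subgroups
by default — raw p values are reported, and `stats::p.adjust` is one call
away for users who need it.

Binning uses half-open intervals $(lo, hi]$ with default edges 3/6/9/12 h
(a gene at exactly 6 h falls in $(3,6]$), assigned on the reference
condition's estimates; edges are fully configurable. The sample median uses
the midpoint rule for even n.

# AP-MS filtering and SILAC testing

The interactome module follows presence/absence logic throughout: flagged
rows (contaminant, decoy, identified-by-site) are removed; a protein must
have LFQ intensity in at least 3 of the 4 bait replicates (counting in bait
samples only by default — counting across all samples is a flag away, since
the convention is ambiguous); and a candidate interactor is called by
**exclusive identification**: present in bait pull-downs, absent from every
control run. Missing intensities are never imputed — imputation would
fabricate exactly the control signal whose absence defines an exclusive hit.

SILAC regulation is tested with a two-sided one-sample t test of
per-replicate **log2** ratios against 0, the log-scale reading of "control
set to 1": ratio noise is multiplicative and symmetric on the log scale.
Degenerate inputs degrade softly: one replicate yields a mean without a p
value; zero replicate variance yields a floored p value with a warning
rather than an error. Gradient co-sedimentation profiles are normalized to
relative distributions (fractions summing to 1) so proteins detected with
different antibodies or exposures can be overlaid.

# Numerical choices and test scale

* All regressions go through one closed-form OLS helper (normal equations);
  the test suite verifies it against `stats::lm` to $10^{-10}$ and the
  signed-rank implementation against full $2^n$ sign enumeration.
* $R^2$ is undefined for a constant response and reported as `NA`, which
  the reliability filter treats as failing.
* Simulation sizes in the test suite are chosen to finish in seconds on one
  CPU while keeping every assertion comfortably powered: the study-scale
  chase uses 2000 genes × 2–4 conditions at depth $5\times10^6$; property
  checks use 60–400 genes; the SILAC null calibration uses $10^4$ proteins.
* Fixed seeds make every simulated dataset reproducible; generators consume
  their seed via `set.seed` at entry and are byte-stable across calls.

# Known limitations

* First-order decay only; no biphasic or delay models.
* Isoform-level half-lives are out of scope (gene-level counts in).
* The gel model quantifies the modal intermediate only; it does not
  deconvolve the full intermediate distribution, and raw gel images (lane
  segmentation) are upstream of this package.
* Wilcoxon p values at very large n are driven by tiny systematic shifts;
  effect sizes (median ratios) should always be read alongside them.
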
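---
title: "Kinome chip analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinome chip analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomechip)
```

# Overview

`kinomechip` models a dual-chip peptide-microarray kinase assay end to end.
A tissue lysate is applied to two arrays — 196 phosphotyrosine (PTK) and 144
serine/threonine (STK) peptide substrates — and the instrument images each
spot repeatedly while the kinase reaction proceeds (94 PTK / 124 STK
reaction cycles), at several camera exposures per cycle. Inhibitors can be
added directly to the reagent mix, so the same lysate is profiled with and
without each candidate drug. The package provides a generative model of this
acquisition with known ground truth, and the analysis chain from raw
intensities to per-patient drug-response reports.

This vignette records the science behind each stage: the model, its
assumptions, the parameters that matter, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

# The generative model

## Effective velocity

The phosphorylation velocity of substrate $s$ in sample $u$ under treatment
$d$ is a weighted sum over the annotated upstream kinases:

$$V_{s,u,d} \;=\; \sum_{K \in \mathrm{ann}(s)} w_{K,s} \; b_K \;
  m_{K,\mathrm{tissue}(u),\mathrm{sex}(u)} \; \frac{1}{1 + [D]_d / \mathrm{IC50}_{K,d}}$$

with catalytic weights $w_{K,s} \in (0,1]$, baseline activities $b_K$
(AU/ms per cycle unit), multiplicative condition effects $m$ (default 1),
and single-site competitive occupancy for the drug term. Assumptions:
kinase contributions are additive (no substrate competition between
kinases), condition effects are multiplicative on activity, and ATP
competition is folded into the effective IC50 rather than modeled
explicitly — the simplest mechanism that produces graded on- and off-target
inhibition from a drug/IC50 table.

Drug action on a *non*-interacting kinase is the identity (no IC50 entry);
at $[D] = \mathrm{IC50}$ activity is exactly halved. The optional
non-responder override replaces the occupancy factor $f$ by $2 - f$ for a
listed (patient, drug, kinase) triple, so a drug that would halve the
target's activity instead increases it by half — emulating patients whose
target activity paradoxically rises under an inhibitor.

## Kinetics and acquisition

The cycle-resolved signal follows a saturating exponential,
$A_{s}(c) = V_s (1 - e^{-r_s c})$, the minimal monotone real-time curve;
per-substrate rate constants $r_s$ (default Uniform(0.02, 0.10) per cycle)
make end-levels differ from initial velocities. The recorded intensity at
exposure $e$ (ms) is

$$I = \mathrm{clip}\!\left(B + e \, A_s(c)\, \eta_{\mathrm{spot}}\,
  \eta_{\mathrm{rep}} + \varepsilon,\; 0,\; S\right)$$

with background $B$ (default 150 AU), 16-bit saturation $S = 65535$,
multiplicative lognormal spot and replicate-chip effects with unit mean
(defaults: 10% and 5% CV — typical spot-to-spot and chip-to-chip
variability for this array class), and additive Gaussian background noise
(SD 5 AU). The exposure ladder defaults to 10/20/50/100/200 ms —
conventional values for this instrument class, configurable because the
true ladder is an acquisition setting, not a constant of the chemistry.

Pooled mode averages the noiseless per-patient velocities within each sex
(equal allocation) before noise is applied, matching how pooled lysates
physically combine material before measurement.

## The annotation fixture

`build_default_annotation()` generates a structurally realistic
substrate-to-kinase map: PTK substrates annotate to TK/TKL kinases, STK
substrates to the serine/threonine branches; each substrate's kinase degree
is drawn as $1 + \mathrm{Binomial}(14, 0.36)$ (support 1..15, mean ~6);
weights are Uniform(0.3, 1); the kinase roster spans the eight kinome
branches in roughly human-kinome proportions and retains 500+ kinases with
at least one annotated substrate. Canonical kinases (ABL1, ABL2, INSR, SYK,
DDR1, FRK, SRC, AKT1, AKT2, ERK1, GSK3, AMPKA1, AURA) are guaranteed
present with realistic substrate sets (ABL1: at least 10 PTK substrates).
The commercial annotation behind such arrays is proprietary; this fixture
reproduces its *structure* (bipartite, weighted, many-to-many, branch-
segregated), not its content, and is clearly synthetic.

The default ground truth scripts the study biology used throughout the
tests: ABL1/ABL2 elevated 2.5-fold in tumor tissue in both sexes, AKT1/AKT2
up 1.8-fold in male tumors but down (0.6) in female tumors, INSR strongly
up in female tumors, SYK moderately up in both; the drug-IC50 table gives
the three ABL antagonists their target affinities plus plausible off-target
interactions (imatinib/DDR1, rebastinib/DDR1+FRK, olverembatinib/SRC+FRK).

# Quantification

Each spot at each cycle is quantified as the background-corrected
least-squares slope through the origin of intensity versus exposure,
after discarding saturated points ($I \ge S$); at least two points must
survive, otherwise the cycle is undefined and, if the whole end window is
undefined, the cell is flagged `saturated`. This multi-exposure slope is
the standard saturation-robust signal for cameras with a hard ceiling: a
spot too bright at 200 ms is still quantified from its 10–100 ms images.

The per-spot statistic is the **end-level**: the mean slope over the last
10 cycles (configurable). End-level was chosen over initial velocity
because final-cycle images and end-state heat maps are the natural readout
of the saturating kinetic; on the generative model the end-level equals
$V_s \cdot \overline{(1 - e^{-r_s c})}_{\mathrm{window}}$, so treatment
ratios are exactly ratios of velocities (the kinetic factor cancels).
Replicates are collapsed by arithmetic mean *after* quantification,
matching technical-triplicate group assessment; the replicate CV is kept
and cells with CV > 0.5 are flagged `high_cv`; cells below 0.01 AU/ms are
`low_signal`. Flags are exclusive (priority: saturated, high_cv,
low_signal) and exhaustive, and `qc_filter()` applies a policy —
`mask_cell` (default), `drop_substrate`, or `keep` — while reporting counts.

Log2 transformation floors linear values at $10^{-3}$ AU/ms so fold
changes stay finite; the floor is recorded in the matrix metadata.

# Substrate statistics

Log fold changes are computed on the log2 scale, per pairing unit: per
patient for tumor-vs-adjacent, per sample for drug-vs-vehicle, then
averaged. Swapping contrast labels negates every LFC exactly. Substrates
with $|\mathrm{mean\ LFC}| \ge 0.2$ are flagged for the waterfall display;
the boundary is treated as *inclusive* ("passing a threshold of 0.2" read
as $\ge$) — the convention is configurable and recorded in the output.
No per-substrate hypothesis test is run by default: significance is
assessed at the kinase level, where mapped substrates are combined.

Heat-map export z-scores rows (constant rows become zeros with a warning)
and orders them by average-linkage hierarchical clustering on correlation
distance $1 - r$; correlations undefined because of constant rows are
treated as 0 (maximal distance).

# Upstream kinase inference

The observed statistic of kinase $K$ is the arithmetic mean LFC of its
mapped, measured substrates (mean rather than median: with $m \ge 3$ and
heavy-tailed outliers already damped by replicate averaging, the mean keeps
the statistic linear and the nulls analytic; both the statistic floor
`min_substrates = 3` and the choice are configurable). Sampling is always
within chip type — PTK and STK are physically separate chips with separate
runs, so a PTK kinase is only compared against the measured PTK panel.

**Sampling null (`sampling_z`)**: draw `n_iter` (default 2000) random
subsets of size $m$ without replacement from the measured panel, compute
the mean-LFC statistic on each, and standardize the observed statistic
against the draws (sample SD). **Exact oracle (`exhaustive_z`)**: enumerate
all $\binom{n}{m}$ subsets (bounded at 200,000) and use the population SD
over the complete enumeration — on the worked 4-choose-2 example this gives
null mean 0.25, SD 0.25 exactly. The sampling estimate converges to the
exact value; the test suite verifies agreement within 0.05 at 50,000
iterations, and calibration: under i.i.d. Gaussian noise with random maps
about 5% of kinases exceed $|z| > 1.96$.

**Two-component ranking (`uka_rank`)**: hierarchical upstream-kinase rating
tools combine how *specific* a signal is to a kinase's substrate set with
how *significant* it is against noise. The package's documented
construction is:

- `specificity_z` — the observed statistic against the random-substrate-set
  null above (would any substrate set of this size look like this?);
- `significance_z` — the observed statistic against a sign-flip null that
  negates each pair's LFCs (consistently across substrates, respecting the
  paired design and its inter-substrate correlation);
- `final_score` = sign(stat) x mean(|specificity_z|, |significance_z|),
  ranked by magnitude; ties break by larger $m$, then kinase id.

This follows the published spirit of two-component hierarchical ratings but
is this package's own scheme; it is fully documented and reproducible and
is *not* expected to match any proprietary tool numerically. A sign-flip
null is the right significance null for paired contrasts; a label-
permutation variant would be the unpaired analogue. Degenerate nulls (zero
SD, e.g. all LFCs identical) yield a component z of 0 inside the ranking —
so an all-zero dataset ranks purely by tie-breaks — while the standalone
`sampling_z` raises a classified error, since there a zero-variance null
means the question is ill-posed.

Kinome-tree export writes one row per kinase — branch (color), signed
activity (node color), score magnitude (node size) — as plain TSV for
external tree renderers.

# PerMed scoring and the trial report

The PerMed score of kinase $K$ under contrast (treat, ctrl) is

$$\mathrm{PerMed}(K) = \frac{1}{|S_K|} \sum_{s \in S_K}
  100 \cdot \frac{\mathrm{treat}_s - \mathrm{ctrl}_s}{\mathrm{ctrl}_s}$$

computed on the **linear background-subtracted** scale. The scale matters:
ratios of non-negative raw signals cannot fall below -100%, but
background-subtracted treated signals can go negative, and scores below
-100% are meaningful ("the signal fell below background by three times the
control's height"). Substrates whose control magnitude is below
$\varepsilon$ (default $10^{-3}$ AU/ms) are *excluded and reported* rather
than clipped — a transparent near-zero-denominator policy. The score is
invariant under uniform gain, and on noiseless simulations it equals the
analytic oracle `truth_permed()` (velocity ratios) to floating-point
precision, because the kinetic factor cancels per substrate.

`run_trial()` scores every (unit, drug, kinase) triple versus vehicle and
derives:

- **off-target calls**: kinases other than the nominal target with
  $|\mathrm{PerMed}| \ge 20\%$, direction retained so compensatory
  *increases* are visible. The 20% default is a reporting threshold, not an
  inference; it is configurable and always recorded in the report.
- **non-responder**: strictly positive target PerMed under an inhibitor —
  the drug's target moved the wrong way for that patient.
- **drug ranking**: most negative target PerMed first; ties by fewer
  off-target calls, then smaller summed off-target magnitude; non-responder
  drugs last regardless of target score (a drug that moves its target the
  wrong way is not rescued by effect size).

# Numerical choices and degenerate inputs

- Through-origin slope: closed form $\sum e_i y_i / \sum e_i^2$; exact on
  proportional data.
- log2 floor $10^{-3}$ AU/ms; PerMed denominator guard $\varepsilon =
  10^{-3}$ AU/ms; both recorded in metadata.
- Exhaustive null uses the population SD over the full enumeration;
  the sampling null the sample SD of its draws (consistent estimators).
- Replicate CV with zero or undefined spread is treated as 0.
- Clipping bounds every simulated intensity to $[0, S]$; tests confirm no
  excursions.
- All stochastic stages take an explicit seed; the ranking derives a
  per-kinase sub-seed from it so results are invariant to row order.
- Intermediate artifacts are plain TSV/JSON; floats are written with
  readr's shortest-round-trip representation, so write-read cycles are
  lossless; every pipeline artifact carries the resolved-config hash, and
  the run log records stages and seeds but no wall-clock times, keeping
  identical runs byte-identical.

# What the generator does and does not emulate

Emulated: dual-chip geometry and cycle structure, exposure ladders with
detector saturation, many-to-many weighted annotation, condition and sex
effects, dose-dependent on/off-target inhibition, technical replicates,
pooled and per-patient modes, non-responder patients.

Not emulated: spot images and segmentation (the simulator emits per-spot
intensities, not pixels), spatial/plate artifacts, wash-step effects,
ATP-depletion kinetics, batch effects across runs, and — importantly —
*pathway crosstalk*: compensatory activation of other kinases under
inhibition arises in cells, and the occupancy model cannot generate it
(off-target effects enter only through additional IC50 entries, i.e. as
decreases). Off-target *increase* reporting is therefore exercised with
constructed fixtures, not simulated biology. Passing tests show the
analysis chain is correct and calibrated on the stated generative model;
they do not show the model captures everything real lysates do.

# Problem sizes

The shipped demo configuration and the test suite run scaled-down layouts
(for example 18 PTK + 12 STK substrates over 20/24 cycles, three patients,
duplicates) so a full pipeline run takes seconds; the statistical checks
use the full-size panels where the property demands it (196-substrate
panels for null calibration and spiked-kinase recovery; 50 seeded
repetitions for the recovery rates; 50,000 draws against the exact
enumeration oracle). The full default geometry (340 substrates, 9 patients,
triplicates, four treatments, all cycles and exposures) generates about
37 million intensity rows; it simulates and quantifies in minutes and is
intended for batch use rather than interactive iteration.

# Known limitations

- The quantification statistic of commercial pipelines is proprietary;
  the end-level exposure slope here is validated against the package's own
  generative model only, and an initial-rate mode is offered but secondary.
- The two-component ranking is a documented approximation of hierarchical
  upstream-kinase ratings, not a reimplementation; absolute scores are not
  comparable across tools, ranks are the stable output.
- PerMed values depend on the background-subtraction convention; published
  per-patient percentages from other pipelines are not directly
  reproducible without their quantification internals.
- Kinase deconvolution dilutes per-kinase inhibition across co-annotated
  kinases; target PerMed scores shrink toward 0 as substrate sets overlap
  more (visible in the README example), which is a property of the assay,
  not a bug of the scoring.
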
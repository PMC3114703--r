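---
title: "Methods: kinetics, viral production and fingerprints in fractionation microcosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetics, viral production and fingerprints in fractionation microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microloop)
```

## The experimental system

Size-fractionation microcosms separate the mortality agents of lake
bacterioplankton. Whole water is filtered to build three treatments:

* **V** (< 1.6 µm): viruses + bacteria only — flagellate grazers and
  autotrophs excluded (a 1–5% residual of the picocyanobacterial
  community passes the filter);
* **VF** (< 5 µm, dark): viruses + bacteria + nanoflagellate grazers,
  with autotrophic activity suppressed by darkness;
* **VFA** (< 5 µm, light): as VF plus active small autotrophs.

Each treatment is incubated in triplicate for four days and sampled at
0, 48 and 96 h for counts (flow cytometry: bacteria, viruses,
picocyanobacteria; microscopy: heterotrophic and pigmented
nanoflagellates, HNF/PNF), bacterial production (³H-leucine), viral
production (0–24 h dilution assays) and community structure (DGGE of
16S rRNA gene amplicons). This package implements the complete
computational chain from those raw outputs to the derived rates,
stimulation statistics and fingerprint analytics, together with a
synthetic generator that emulates the whole design with known ground
truth.

## Rate estimators

**Net growth and loss.** Between two sampling times, bacterial net
growth is taken as exponential, `r = (ln N_t − ln N_0)/t` with `t` in
days (`growth_rate()`). With predators the same estimator gives `rb`;
the predator-attributable loss rate is the difference `g = r − rb`
(`loss_rate()`). Negative `g` means bacteria grew *faster* with
predators — the signature of predator-mediated nutrient release.
Because the V and VF/VFA bottles are physically distinct, there is no
natural replicate pairing: `rate_table()` forms `g` per replicate as
the V-treatment replicate mean minus that replicate's `rb`, and
combines the two treatments' standard deviations in quadrature. Rates
are reported in d⁻¹ and rounded to two decimals in report tables.

**Viral production.** In a dilution assay the hosts are diluted (the
50:150 ml design gives a factor 1/3) into virus-free water and viral
abundance is tracked over 24 h. `fit_viral_production()` takes the
ordinary least-squares slope `m` of counts against time and corrects it
for the host dilution: `VP = m × (b/B)` with `b`/`B` the bacterial
concentration after/before dilution. All assay points are used, with no
outlier handling; a negative slope is floored to zero production with a
warning (production is physically non-negative). The `b/B` correction
*shrinks* VP when hosts are diluted; the intuitive scale-up `B/b` is
available as `correction = "B_over_b"` for sensitivity analysis, and the
default follows the convention as printed in the source protocol.

**Lysis mortality.** Lysed cells per day are `VP × 24 / burst size`
(`lysed_cells()`, default burst size 27 — the average estimated for
these lakes), and the per-capita mortality is lysed cells divided by
standing bacterial abundance (`lysis_mortality()`). The ×24 lives in
`lysed_cells()` so VP stays in virus ml⁻¹ h⁻¹ and lysis rates in
cell ml⁻¹ d⁻¹, the customary units of each.

**Bacterial production.** Net leucine incorporation is the mean of the
live tubes minus the mean of the two killed controls
(`blank_correct()`, floored at zero), converted to carbon with
`BP = Leu × 131.2 / 0.073 × 0.86 × 1` through an explicit
pmol → mol → g → µg unit chain (`leucine_to_carbon()`); with the
default constants, 647 pmol l⁻¹ h⁻¹ ≡ 1.000 µg C l⁻¹ h⁻¹, which the
test suite pins as an oracle.

## The stimulation statistic

The stimulation of a quantity X in a predator treatment T over a window
is the difference of relative variations, in percentage points:

$$ S = 100\left[\frac{X_T(t_1)-X_T(t_0)}{X_T(t_0)} -
\frac{X_V(t_1)-X_V(t_0)}{X_V(t_0)}\right] $$

The algebraic body of the original equation is available only as a
figure in the source material; the implementation follows its verbal
definition (difference in variation between the flagellate treatments
and the flagellate-free treatment), which forces the convenient anchor
cases: identical series give 0, and V doubling while T triples gives
+100. The statistic is antisymmetric under swapping the two series and
invariant to rescaling either by a positive constant. An
absolute-difference variant (`mode = "absolute"`) is provided for
sensitivity analysis. Windows follow the design: 0–48 h and 48–96 h,
with 0–96 h as a convenience. Whether headline values should average
the two windows or use the endpoint is not specified in the source;
`stimulation_table()` emits every window so either summary can be
formed.

Group comparisons use one-way ANOVA with Fisher's protected LSD
(pairwise comparisons only when the omnibus F is significant at
α = 0.05) and two-sided paired t tests, via `stats::aov` and the
classical difference formula. Two degenerate cases are handled
explicitly because the stock routines misbehave there: exactly
identical groups return F = 0, p = 1, and a constant non-zero paired
difference is flagged degenerate rather than reported as infinitely
significant. No multiple-testing correction is applied beyond the LSD
protection, matching the original analysis.

## Fingerprint analytics

DGGE lanes arrive as (position, peak surface) lists — one pooled lane
per treatment × time, since replicate DNA extracts are pooled before
electrophoresis. `match_bands()` aligns bands across lanes by greedy
nearest-position clustering within a tolerance (default 5 px — no value
is published, so it is configurable); the canonical position is the
running mean of members, ties break toward the lower position, and two
same-lane bands mapping to one canonical band raise a conflict error.
Relative intensities are `P_i = n_i / N` per lane. A band is "in" a
treatment if present in any of its lanes, above an optional detection
floor (default 0; 0.004 emulates the commonly quoted DGGE sensitivity
of populations above ~0.3–0.4% of cells). `commonality_table()`
partitions bands into common-to-all, single-treatment-specific and
exactly-two-treatment classes; the partition identity (classes sum to
the total) holds on every input and is property-tested. Lane similarity
is Bray–Curtis, `1 − Σ|p_i − q_i| / Σ(p_i + q_i)`, reported as
similarity to match the customary scale bars, and dendrograms use UPGMA
(average linkage on `1 − similarity` via `stats::hclust`, lanes
pre-sorted by label so ties resolve deterministically), serialized to
newick with ape.

## The synthetic generator

`simulate_experiment()` emulates one experiment end to end. Mean
dynamics are deterministic ODEs integrated with a fixed-step RK4 scheme
(step ≤ 0.1 h):

* bacteria: `dB/dt = (µ_b(1 + boosts) − δ_v − g·[flagellates]) B`,
  where the `enrich` boost applies when flagellates are present (VF,
  VFA) and `autotroph_boost` only in VFA;
* viruses: `dV/dt = β δ_v B − d_v V` with burst size β (default 27);
* flagellates: logistic growth when present; picocyanobacteria grow
  logistically in the light (VFA) and decay otherwise.

Bacteria are therefore exactly exponential, so the two-point estimators
recover the composite net rate to solver precision — by design: the
estimators assume smooth exponential dynamics, and demographic
stochasticity is deliberately out of scope. Stochasticity enters only
as mean-one multiplicative lognormal observation noise (CV default 5%,
a typical flow-cytometry counting error), which keeps counts positive.
With no viral decay the integrated trajectories conserve
"viruses gained = β × cells lysed", checked against a closed-form
oracle at 0.1% tolerance. Dilution assays reproduce their own
closed-form mean slope `β δ_v b / 24`; leucine assays are generated
from the gross production `µ_b(1+boosts) · B(t) ·` 20 fg C cell⁻¹
pushed backwards through the leucine conversion; gels are generated
from per-lane phylotype profiles with a detection floor and positional
jitter, retaining the truth matrix for partition-recovery tests.

The four presets `microcosm_preset("LA1"|"LA2"|"LB1"|"LB2")` seed
initial abundances from the published in situ values of the two lakes
(oligotrophic LA, mesotrophic LB) in early spring (1) and summer (2),
with rates chosen once so each scenario's noise-free V-treatment net
growth and lysis mortality fall in the observed ranges (spring low,
summer high, mesotrophic highest). `params_for_stimulation()` inverts
the exponential map to plant an exact deterministic stimulation, which
the recovery suite uses: over 50 seeded bundles (CV 5%, triplicates)
the grand-mean recovered stimulation must sit within 2 Monte-Carlo
standard errors of the planted +25 points, and per-bundle composite net
rates within 15% of truth. The functional forms themselves are an
artifact choice — the source material specifies no within-bottle
dynamics — so parameter-recovery results validate the estimators, not
any mechanistic claim about the lakes.

What the generator does *not* emulate: demographic (birth–death)
noise, spatial structure, substrate depletion or any real
light/photochemistry beyond the VFA/VF boost switch, virivory, or
lysogeny. Passing tests on synthetic bundles therefore demonstrate
estimator correctness under the stated model, not robustness to every
feature of real microcosm data. One visible consequence: because
simulated production tracks abundance proportionally, the stimulation
of bacterial *production* in strongly growing scenarios (e.g. the LB2
preset) is far larger than the published ~30–50% values; the
acceptance checks on those scenarios are accordingly qualitative
(positive stimulation), as only sign and ordering are identified.

## Numerical and degenerate-input choices

* RK4 step 0.1 h (the estimators' quantities are exact for exponential
  dynamics well above this resolution); states clipped at 0.
* Two-point log-ratio rates error on missing time points or
  non-positive counts rather than imputing.
* Regression slopes require ≥ 3 points and non-degenerate time
  variance; dilution factors must lie strictly in (0, 1).
* `read_counts()` rejects non-positive counts and duplicate
  (series, time) rows, naming the offending lines; absent populations
  are represented by absent rows, not zeros.
* Percentages in commonality tables are rounded to integers, matching
  the published precision; report-table rates round to two decimals.
* Problem sizes in the shipped tests and scripts (triplicates, 50
  recovery seeds, ≤ 6-lane oracle fixtures, 20-phylotype gels) were
  chosen to mirror the source design where stated and to keep each
  suite's Monte-Carlo error well inside its assertion margins.

## Known limitations

* Published loss-rate and percentage cells that are internally
  inconsistent with their own printed means/counts (they exist) are
  not asserted; only internally consistent cells are reproduced.
* The `b/B` correction convention is implemented as printed even
  though its direction is debatable; the switch documents the
  alternative rather than silently choosing it.
* The split of two-treatment bands *including V* into V+VF vs V+VFA is
  unconstrained by the published tallies; the shipped fixture uses an
  arbitrary documented split that does not affect any asserted cell.
* `summarize_stimulation()` assumes the `LA1`-style labelling
  convention to derive lake and season; other designs can use
  `stimulation_table()` directly.
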
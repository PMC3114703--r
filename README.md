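# microloop

Analysis chain for **predator-manipulation (size-fractionation)
microcosm experiments** on lake bacterioplankton: what do flagellate
grazers and viruses each do to bacterial abundance, production and
community structure?

The experimental design behind the package incubates three treatments
in triplicate for four days — **V** (< 1.6 µm: viruses + bacteria),
**VF** (< 5 µm, dark: + flagellate grazers) and **VFA** (< 5 µm, light:
+ small autotrophs) — and samples counts, ³H-leucine incorporation,
0–24 h viral-production dilution assays and DGGE fingerprints. The
package turns those outputs into the derived quantities of interest,
and ships a synthetic microcosm generator with known ground truth so
every estimator has a parameter-recovery test.

## What it computes

| Stage | Functions | Core relation |
|---|---|---|
| Growth/loss kinetics | `growth_rate`, `loss_rate`, `rate_table` | `r = (ln N_t − ln N_0)/t`, `g = r − rb` (d⁻¹) |
| Viral activity | `fit_viral_production`, `lysed_cells`, `lysis_mortality` | `VP = m(b/B)`; lysed = `VP·24/β`, burst size β = 27 |
| Bacterial production | `blank_correct`, `leucine_to_carbon` | `BP = Leu × 131.2/0.073 × 0.86 × 1` (647 pmol ≡ 1 µg C l⁻¹ h⁻¹) |
| Stimulation | `stimulation`, `stimulation_table`, `summarize_stimulation`, `one_way_anova`, `paired_t` | `100[(ΔX_T/X_T0) − (ΔX_V/X_V0)]` (percentage points) |
| Fingerprints | `match_bands`, `relative_intensity`, `commonality_table`, `bray_curtis_similarity`, `cluster_lanes` | `P_i = n_i/N`; Bray–Curtis `1 − Σ\|p−q\|/Σ(p+q)`; UPGMA |
| Synthetic data | `sim_params`, `microcosm_preset`, `simulate_experiment`, `simulate_dilution_assay`, `simulate_gel` | exponential-core ODEs + lognormal observation noise |
| I/O & pipeline | `read_counts`, `read_bundle`, `write_bundle`, `run_pipeline` | CSV bundles → rates/lysis/bp/stimulation/fingerprint tables |

## Worked example

```r
library(microloop)

# a mesotrophic-summer-like scenario with known truth
p <- microcosm_preset("LB2")
b <- simulate_experiment(p, label = "LB2", seed = 12)

rate_table(b)[1:3, ]
#>   experiment treatment horizon_h growth_rate  growth_sd   loss_rate    loss_sd
#> 1        LB2         V        48   0.5650282 0.06571645          NA         NA
#> 2        LB2        VF        48   0.6562079 0.04810051 -0.09117965 0.08143901
#> 3        LB2       VFA        48   0.7263574 0.05246096 -0.16132922 0.08408808
```

The V bottles grew at ~0.57 d⁻¹; with grazers present bacteria grew
*faster* (negative loss rates ≈ −0.09 to −0.16 d⁻¹): predation losses
were outweighed by predator-mediated nutrient release — the package's
central "stimulation" phenomenon. Viral production from the same
bundle's dilution assays:

```r
va <- viral_activity_table(b$dilution_assays)  # slope, VP, lysed, mortality
aggregate(vp ~ treatment, va, mean)
#>   treatment      vp
#> 1         V 1325831
#> 2        VF 1853103
#> 3       VFA 2288468
```

Viral production is ~40–73% higher with grazers — the synergy between
grazing and viral lysis. `stimulation_table(b)` quantifies the same
effect for any counted variable, and `run_pipeline()` executes every
stage over an on-disk bundle, writing `rates.csv`, `lysis.csv`,
`bp.csv`, `stimulation.csv` and the fingerprint outputs.

The numbered scripts under `analysis/` run the full workflow over the
four lake-scenario presets (`Rscript analysis/01_simulate.R`, then
`02`–`06`); each prints what it found and writes its tables under
`results/`.

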
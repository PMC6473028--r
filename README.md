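# metabnet

Group-level **metabolic covariance network analysis** for FDG-PET cohorts.

Regional glucose uptake covaries across subjects: brain regions that work
together metabolically rise and fall together across a cohort. Building a
network from that covariation — one node per atlas region, edges from the
strongest between-subject associations — and summarizing it with graph
theory can separate dementia syndromes (Alzheimer's disease, Parkinson's
disease dementia, dementia with Lewy bodies) whose raw uptake maps look
alike. metabnet is for neuroimaging analysts who have subject × ROI mean
uptake tables (or NIfTI volumes plus an AAL-style label image) and want the
full group-network workflow as tested, scriptable R functions.

## What it computes

For each group of subjects over a 90-region AAL-style parcellation
(cerebellum excluded; bundled as `aal90_atlas()`):

* **Network construction** — partial correlation between every ROI pair
  controlling age and sex (`partial_correlation()`), binarized by a sparsity
  threshold: at sparsity *s*, the top `round(s · P)` of the `P = R(R−1)/2`
  strongest pairs become edges (`binarize_at_sparsity()`,
  `sparsity_sweep()` over 6–40%).
* **Graph metrics** — clustering coefficient C, characteristic path length L,
  global/local efficiency, and the small-world indices γ = C/C_null,
  λ = L/L_null, σ = γ/λ against degree-preserving rewired surrogates
  (`metric_curve()`, `small_world_indices()`). Hubs are nodes whose
  normalized betweenness bᵢ = BC/mean(BC) exceeds 1.5 (`hub_table()`,
  default sparsity 28%).
* **Group comparison** — non-parametric permutation test on any metric at
  every sparsity, with significant sparsity ranges
  (`permutation_test()`, `significant_ranges()`).
* **Seed-based correlation** — per-group seed maps (default seed: right
  middle temporal gyrus, MTG.R), Fisher r-to-z transform
  z = ½·ln((1+r)/(1−r)), the two-group statistic
  Z = (z₁ − z₂)/√(1/(n₁−3) + 1/(n₂−3)), and Benjamini–Hochberg FDR
  (`seed_comparison()`).
* **Hemispheric asymmetry** — independent 45-region networks per hemisphere,
  efficiencies M_L and M_R, the asymmetry index
  AI = 200·|M_R − M_L|/(M_R + M_L), a calibrated subject-level sign-flip
  test of M_R = M_L, bootstrap AI distributions, and a Welch t-test between
  groups (`within_group_test()`, `compare_ai_between_groups()`).
* **Synthetic cohorts** — a generator with planted covariance communities,
  homotopic coupling, hub nodes, and controllable hemispheric imbalance
  (`generate_cohort()`, `planted_structure()`, `plant_asymmetry()`), so the
  entire pipeline is testable without patient data.

`run_pipeline()` orchestrates everything from a YAML/JSON config and writes
plain-text tables plus a JSON manifest; `inst/cli/metabnet.R` is a thin
command-line shim (`run-all`, `simulate`, `seed-map`, `asymmetry`,
`validate`).

## Worked example

```r
library(metabnet)

cohort <- generate_cohort(cohort_config(seed = 42))   # HC/AD/PDD/DLB, 22/22/18/22
pc <- partial_correlation(cohort$tables$HC)
pc
#> Partial-correlation network: 90 ROIs, group 'HC', n = 22, covariates: age, sex

hubs <- hub_table(pc, sparsity = 0.28)                # 1121 of 4005 pairs kept
dplyr::arrange(hubs, dplyr::desc(bi))[1:5, ]
#> # A tibble: 5 × 5
#>   roi        degree    BC    bi hub
#>   <chr>       <int> <dbl> <dbl> <lgl>
#> 1 SFGdor.R       45 115.   3.42 TRUE
#> 2 IFGoperc.L     30  78.9  2.35 TRUE
#> 3 INS.R          34  72.1  2.14 TRUE
#> 4 OLF.R          40  66.9  1.99 TRUE
#> 5 CAL.L          40  63.3  1.88 TRUE

sw <- small_world_indices(binarize_at_sparsity(pc, 0.28), n_null = 20, seed = 1)
#> gamma = 1.253, lambda = 1.014, sigma = 1.236

asym <- within_group_test(cohort$tables$DLB, n_rep = 200, seed = 7)
asym
#> Hemispheric asymmetry, group 'DLB' (sparsity 28%, 200 signflip replicates)
#> # A tibble: 2 × 6
#>   metric   M_L   M_R    AI     p direction
#>   <chr>  <dbl> <dbl> <dbl> <dbl> <chr>
#> 1 global 0.616 0.605  1.70 0.507 none
#> 2 local  0.708 0.693  2.18 0.706 none
```

Reading the output: the hub table says node `SFGdor.R` carries 3.4× the mean
betweenness, so it is flagged as a hub (bᵢ > 1.5). The small-world indices
say the control network clusters more than its degree-matched surrogates
(γ > 1) at essentially unchanged path length (λ ≈ 1), hence σ > 1 — a
small-world topology. The asymmetry table reports each hemisphere's global
and local efficiency, the percent-scaled asymmetry index, and a sign-flip
p-value: at n = 22 with the default mild planted gain, no significant
lateralization is detected (direction `none`).

Fitted-object verbs follow broom conventions: `tidy()`, `glance()`,
`autoplot()` work on partial-correlation matrices, permutation results, and
asymmetry results; `plot_metric_curves()` and `plot_hubs()` draw the
standard displays.

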
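# phycoflux

Constraint-based analysis of compartmentalized genome-scale metabolic
models (GSMMs) of oleaginous microalgae — organisms like *Nannochloropsis*
that pack triacylglycerol (TAG) into lipid bodies when nitrogen runs out.
The package covers the full workflow such a reconstruction supports:

* **Model core** — SBML Level 3 + fbc v2 read/write (`read_sbml`,
  `write_sbml`), gene–protein–reaction boolean rules (`gpr_parse`,
  `gpr_eval`, `knockout_genes`), elemental/charge balance checking
  (`check_balances`), reaction-kind statistics (`model_stats`).
* **LP engine** — flux balance analysis `max c'v` s.t. `S v = 0`,
  `lb ≤ v ≤ ub` (`fba`), flux variability (`fva`), blocked-reaction
  detection (`blocked_reactions`), flux-coupling classification
  (`flux_coupling`), metabolite connectivity (`connectivity`). LPs are
  solved with HiGHS via scipy/reticulate.
* **Validation** — growth/no-growth batteries with the strict
  `mu > mu_ref / 3` call, confusion-matrix accuracies (simple and
  geometric mean), growth-rate prediction from measured uptakes, CO2
  biofixation `C · P · MW_CO2 / MW_C` and its specific-uptake conversion.
* **Dynamic FBA** — staged batch cultures with biomass-equation switching
  (nitrogen-replete / depleted), nutrient pools, and storage-lipid
  bookkeeping (`simulate_stages`, `stage_spec`, `switch_biomass`).
* **Strain design** — a randomized four-step pruning search
  (`run_search`) for reaction-knockout sets that make storage-lipid
  production *growth-coupled*: the FVA minimum of an added target demand
  at optimal growth must clear a threshold (`add_target_demand`,
  `verify_coupled`), candidates ranked by `m = mu · r_t / |k|`.
* **Synthetic ground truth** — a deterministic four-compartment toy model
  with closed-form optima, a planted 32-condition battery (24 TP / 5 TN /
  3 FP / 0 FN by construction) and a planted growth-coupling knockout
  pair, so every stage is testable without any external model file
  (`make_toy_model`, `make_condition_battery`).

## Worked example

```r
library(phycoflux)

tm <- make_toy_model()          # model + planted truth
model <- tm$model
fba(model)$objective_value
#> [1] 5.490196                  # = 280/51, the planted rich-medium mu*

batt <- make_condition_battery(model, tm$truth)
res <- run_battery(model, batt)
res$summary
#>   TP TN FP FN  n sensitivity specificity accuracy_simple accuracy_geometric
#> 1 24  5  3  0 32           1       0.625         0.90625          0.7905694
```

The three false positives are the planted extreme-light conditions: a
stoichiometric model cannot represent growth inhibition, so it predicts
growth where the culture died — the characteristic failure mode of
qualitative GSMM validation. Strain design on the same model:

```r
tgt <- target_spec("addTAG", c(mag_lb = 1))
md <- add_target_demand(model, tgt)
sr <- run_search(md, tgt, iterations = 200, seed = 1)
head(sr$candidates, 3)
#>   rank   knockouts size       mu      r_t        m
#> 1    1 RESP;T_urea    2 2.628205 8.108891 10.65591
#> 2    2   RESP;URC1    2 2.628205 8.108891 10.65591
#> 3    3   RESP;URC2    2 2.628205 8.108891 10.65591
```

Every returned set re-verifies from the untouched model: the mutant still
grows (always slower than wild type) and the target demand's FVA minimum
at optimal growth stays above `epsilon_t` — production is guaranteed, not
merely possible. The top designs remove respiration together with a cheap
nitrogen route, forcing reductant regeneration through fatty-acid
synthesis and hence lipid overflow; the planted pair `{R_A, T_glyc}`
(glycolytic bypass + glycerol export) is recovered as well.

The numbered scripts under `analysis/` run the full narrative — model
overview, validation, the three-stage nitrogen-starvation dFBA
(growth caps 0.0045 / 0.0036 h⁻¹; storage lipid accumulates only in the
depleted stage, at four times the replete specific lipid rate), and the
knockout search — writing tables under `results/`.

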
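---
title: "Constraint-based modeling of microalgal growth and storage-lipid production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of microalgal growth and storage-lipid production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoflux)
```

## The modeling problem

Oleaginous microalgae such as *Nannochloropsis* accumulate triacylglycerols
(TAG) in lipid bodies when nitrogen becomes scarce, which makes them
attractive biodiesel feedstocks. Genome-scale metabolic models (GSMMs)
describe such an organism as a stoichiometric matrix $S$ over compartmented
metabolites, with flux bounds, gene–protein–reaction (GPR) rules, and one or
more biomass pseudo-reactions whose flux is the specific growth rate $\mu$
(h$^{-1}$). This package provides the full constraint-based workflow such a
model supports:

* structural characterization — reaction-kind statistics, elemental and
  charge balance checking, blocked reactions, flux variability, flux
  coupling, metabolite connectivity;
* growth validation — qualitative growth/no-growth batteries against
  in vivo observations, and quantitative growth-rate prediction from
  measured uptake rates;
* dynamic FBA of staged batch cultures with biomass-equation switching
  under nitrogen starvation; and
* a randomized strain-design search for reaction knockouts that *force*
  storage-lipid production at optimal growth.

All fluxes are in mmol gDW$^{-1}$ h$^{-1}$; uptake is negative flux through
an exchange reaction.

## Flux balance analysis and its relatives

`fba()` solves $\max c^\top v$ subject to $S v = 0$, $lb \le v \le ub$ with
HiGHS (through scipy's `linprog`; no LP solver is re-implemented here). The
objective value of an optimal solution is unique and is the package's
contract; the flux *vector* is one of possibly many alternate optima and is
only ever asserted through variability envelopes.

`fva(model, fraction_of_optimum)` minimizes and maximizes each reaction's
flux subject to the objective staying at or above the given fraction of its
optimum (with an absolute slack of $10^{-6}$ so the floor is never
infeasible by round-off). Fraction 0 explores the unconstrained network and
defines **blocked** reactions: those whose fraction-0 range is $(0, 0)$
with every exchange opened to default capacities ($\pm 1000$). Blockedness
is treated as a property of the topology, not of a medium, which is why
`blocked_reactions()` opens the exchanges first.

`flux_coupling()` classifies unordered pairs of unblocked reactions as
fully, partially, or directionally coupled, or uncoupled. "$i$ forces $j$"
is decided by the feasibility test *can $v_i \neq 0$ while $v_j = 0$?* (two
LPs, short-circuited); ratio fixedness for mutually coupled pairs by
pinning $v_j$ at a feasible nonzero value and minimizing/maximizing $v_i$.
The test suite checks the classification against an independent LP-ratio
oracle on every generated net of at most 20 reactions. The zero-flux
threshold is $\varepsilon = 10^{-6}$ throughout; the solver runs at
$10^{-9}$ primal/dual feasibility tolerance.

## Growth validation

**Qualitative rule.** A condition is called "growth" when its FBA optimum
strictly exceeds one third of a reference rate obtained in an in silico
rich medium. `reference_growth()` by default takes the model's own exchange
capacities as that rich medium — the generator parameterizes its default
state as nutrient-replete, and for user models the transporter capacities
are exactly what "free uptake" means; an explicit common uptake bound can
be passed instead. Calls are tallied into a confusion matrix;
`confusion_summary()` reports both the simple accuracy $(TP+TN)/n$ and the
geometric mean $\sqrt{\text{sensitivity} \times \text{specificity}}$. The
two differ whenever errors are asymmetric, so both are always exposed and
neither is silently preferred.

**Templates.** Media conditions are declarative overlays
(`media_condition()` + `apply_condition()`): autotrophic closes
organic-carbon uptakes (species with $\ge 2$ carbon atoms, which keeps urea
— a nitrogen source — open), caps oxygen uptake at 10 mmol gDW$^{-1}$
h$^{-1}$, disables enzymes tagged `light-inhibited`, and restricts
chloroplast water transport to the export direction; heterotrophic and dark
conditions shut photon uptakes and light-driven reactions. An infeasible
condition is counted as no-growth rather than aborting a battery.

**Quantitative rule.** `predict_growth_rate()` fixes the measured uptake
capacities (lower bound $-$rate), closes every other uptake except an
explicit keep-open list (water, protons), and maximizes growth.
`error_report()` uses the experimental rate as the denominator of the
relative error. `co2_specific_uptake()` converts biofixation
$C \cdot P \cdot MW_{CO_2}/MW_C$ (g CO$_2$ L$^{-1}$ d$^{-1}$) to a specific
uptake by dividing by culture density and the molar mass and applying the
day-to-hour factor 24 exactly once.

## Staged dynamic FBA

`simulate_stages()` uses the static-optimization scheme: per step of `dt`
(default 0.1 h) the stage's biomass variant becomes the objective with its
flux capped at the stage's $\mu_{max}$, each tracked nutrient's uptake is
bounded by pool availability ($lb \ge -\text{pool}/(X\,dt)$), the LP is
solved, then $X \leftarrow X e^{\mu dt}$ (exact for constant $\mu$) and
pools update by Euler. Each step is solved *lexicographically*: maximize
$\mu$; at fixed $\mu$, minimize the summed uptake of the tracked nutrients;
then minimize the demand (storage) fluxes. The second and third stages
resolve alternate optima that would otherwise waste pool nutrients in
futile uptake–secretion cycles or dump surplus carbon into storage — the
stored amount is exactly what the active biomass equation forces, which is
the intended meaning of "lipid produced and not consumed by biomass". This
is a determinism device for the time-stepping loop, not a parsimonious-FBA
analysis of the flux distribution.

The three-stage nitrogen-shift scenario uses the literature growth caps
0.0045 h$^{-1}$ (replete) and 0.0036 h$^{-1}$ (depleted). Initial
conditions are not dictated by any published axis values, so the analysis
scripts choose a realistic batch: $X_0 = 0.05$ gDW/L, 0.4 mmol/L nitrate,
stages of 160/240/160 h (tests use shortened stages of tens of hours; the
acceptance script 30/40/30 h at `dt` 0.5 h). Halving `dt` moves the final
state by well under 1%.

## Strain design for a biomass constituent

TAG is a biomass constituent, not a secreted product, so maximizing it
directly is meaningless. `add_target_demand()` therefore creates an
artificial route: a synthesis reaction consuming the target species (in
given proportions for composite targets) into an `additional_*`
pseudo-species drained by an irreversible demand. Any pre-existing demand
on a target species is closed at the same time — otherwise the
"guaranteed" production could leak through a free sink and the guarantee
would be vacuous.

A knockout set $k$ is **sound** when, after removing $k$, the mutant still
grows ($\mu > \varepsilon_g = 10^{-6}$) and the *FVA minimum* of the target
demand, subject to growth within a fractional slack $\delta = 10^{-6}$ of
its optimum, is at least $\varepsilon_t = 10^{-3}$ mmol gDW$^{-1}$
h$^{-1}$. The FVA minimum — not a single FBA flux — is what makes the
claim a guarantee under alternate optima. The slack has a visible
first-order cost: lowering growth by $\delta\mu$ frees the carbon the
forced route would otherwise claim, so the guaranteed rate sits below its
closed-form value by $O(\delta\mu)$ scaled by the pathway's carbon
stoichiometry (about $7\delta\mu$ in the toy network); tests compare at
$10^{-4}$ relative tolerance accordingly.

`prune_search_iteration()` implements the four-step randomized pruning:
(1) random-order removal of reactions not needed for target production;
(2) restart from the full model, random-order removal of reactions not
needed for biomass, protecting the step-1 conserved set; (3) accept only
if the pruned model's optimal growth still guarantees target production,
else restart; (4) re-add removed reactions one at a time in random order —
a reaction whose return breaks the guarantee joins $k$. Because step 4
never revisits earlier decisions, supersets of minimal sets can and do
appear; they are genuine, independently verified designs and are kept as
distinct candidates, exactly as a single forward pass produces them.
`run_search()` runs seeded iterations (iteration index folded into the
seed stream, 50 restarts per iteration at most), deduplicates by set
equality, and ranks by $m = \mu \cdot r_t / |k|$, ties broken by smaller
$|k|$ then lexicographically. Exchanges, demands, biomass equations and
the target construction itself are exempt from removal.

## The synthetic toy model

`make_toy_model()` builds a deterministic four-compartment network
(extracellular, cytosol, chloroplast, lipid bodies) that emulates the
structural features the analyses assume, at hand-checkable size:
photon-driven CO$_2$ fixation with a finite carboxylation capacity (without
that cap, CO$_2$ released by fatty-acid synthesis could be re-fixed without
limit under saturating light, and the optimum would no longer be
hand-derivable); a disaccharide with an efficient route R\_A and a
glycerol-yielding route R\_B; acetate assimilation; nitrate → nitrite →
ammonia reduction, plus a two-step urea route (carboxylase + allophanate
hydrolase; a single urease when `include_urea_cycle = FALSE`); a
monoacylglycerol TAG-analog built from fatty acid and glycerol, transported
into lipid bodies with a storage demand; and two biomass equations — the
depleted variant needs no nitrogen, doubles the bound-lipid coefficient
(`depleted_fold = 2`, following the roughly one-fold lipid increase
reported for *Nannochloropsis* under starvation) and deposits
`storage_coeff = 1.5` mmol of lipid per unit flux into lipid bodies. A
generic redox-carrier pair (pseudo-element `R`) closes electron
bookkeeping, so every non-boundary, non-light reaction is mass and charge
balanced.

Because every internal conversion has unit marginal carbon cost, the LP
optima are closed-form rationals recorded as *planted truth*: rich-medium
$\mu^\ast = 280/51 \approx 5.49$, autotrophic $40/17$, and so on; the
planted growth-coupling pair $\{R\_A, T\_{glyc}\}$ has mutant
$\mu = 95/21$ and guaranteed production $r_t = 115/42$. The 32-row planted
battery mirrors a literature battery's structure (light levels, carbon
sources, nitrogen sources, reductase knockouts) and plants exactly three
false positives — extreme-light conditions where a purely stoichiometric
model must over-predict growth because it cannot represent inhibition —
giving 24 TP / 5 TN / 3 FP / 0 FN by construction. The generator is pure
and seed-independent; `seed` is kept in `toy_spec()` for interface
symmetry.

What passing on this toy does and does not show: it validates the
*machinery* — LP correctness against hand optima and oracles, balance
accounting, battery plumbing, coupling logic, search soundness — on a
network whose truth is known exactly. It does not certify predictions on a
real reconstruction, whose accuracy depends on curation quality, biomass
composition and measured uptakes.

## Numerical choices, in one place

| quantity | value | where |
|---|---|---|
| LP feasibility tolerances | $10^{-9}$ | solver options |
| zero-flux threshold $\varepsilon$ | $10^{-6}$ | blocked/coupling |
| FVA objective floor slack | $10^{-6}$ absolute | `fva()` |
| growth call | $\mu > \mu_{ref}/3$, strict | `growth_call()` |
| $\varepsilon_t$, $\varepsilon_g$, $\delta$ | $10^{-3}$, $10^{-6}$, $10^{-6}$ | strain design |
| dFBA step | 0.1 h default, exponential-$X$ / Euler-pool | `simulate_stages()` |
| default bounds when SBML lacks them | $(\mp 1000, 1000)$ by reversibility | `read_sbml()` |

Degenerate inputs: reversible reactions are never split; ties in the
search ranking fall back to set size then lexicographic order; an
infeasible FBA is a status, never a silent zero — except where a battery
or dFBA step explicitly maps it to no-growth by design.

## Known limitations

Light is a scalar photon exchange, not a spectrum; no Michaelis–Menten
uptake kinetics, light attenuation, or pH/gas transfer in dFBA; no
thermodynamic constraints or flux sampling; the coupling implementation
favors clarity over the specialized preprocessing of dedicated FCA tools
and scales as $O(n^2)$ LPs, adequate for the problem sizes here (tests run
nets of $\le 47$ reactions; the full pairwise scan of the toy takes about
15 s). Regulatory effects — the reason knockout predictions on real algae
need experimental follow-up — are outside the stoichiometric formalism.
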
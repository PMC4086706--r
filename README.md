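# fluxbal

Flux-balance modeling from curated reaction databases, at desk scale.

`fluxbal` is for systems biologists who want the computational machinery of
database-derived genome-scale metabolic modeling — network construction from
reaction tables, flux balance analysis, gene-knockout essentiality
screening, and phenotype-microarray growth prediction — in a form small
enough to inspect, test, and reason about. Everything runs on bundled,
fully mass- and charge-balanced fixture networks of *E. coli* core energy
metabolism; nothing is downloaded.

## What it computes

**Network construction.** A model is a set of tibbles: metabolites (with
Hill-notation formula, charge, compartment), reactions (signed
stoichiometry, direction, type flags), and gene–product associations
(catalyst units: a complex is a multi-gene unit, isozymes are alternative
units; plus substrate-supplier genes). `build_network()` applies the filter
cascade used when deriving a solvable network from a curated database:
compound-class instantiation (Cartesian binding of class slots, keeping
mass-balanced instances, with a permutation cap), then removal of
unbalanced/undetermined, physiologically irrelevant, polymerization-type,
one-sided, string-only, variable-stoichiometry, and disconnected reactions,
each logged with its category.

**Two-stage FBA.** With steady state *S·v = 0* and per-reaction bounds
(mmol/gCDW/hr), stage 1 maximizes the objective flux; stage 2 pins the
objective at its optimum and minimizes the taxicab norm Σ|v| (parsimonious
FBA), which selects a unique, shortest-route flux vector among alternate
optima:

```
max  c'v            subject to  S v = 0,  lb ≤ v ≤ ub
min  Σ|v|           subject to  the same, plus  c'v = optimum
```

A biomass objective drains precursors at measured coefficients
(mmol/gCDW) plus a growth-associated maintenance (GAM, default 53.95 mmol
ATP/gCDW) ATP turnover, with non-growth-associated maintenance (NGAM,
default 3.15 mmol ATP/gCDW/hr) as a flux floor on standing ATP hydrolysis;
biomass flux equals specific growth rate µ (hr⁻¹).

**Screens.** `simulate_knockout()` removes the reactions a knockout
gene-disables (no surviving isozyme unit, or a sole substrate supplier) and
re-solves; `ko_screen()` scores predictions against OD600 growth criteria
(narrow: ≤ 0.005 at 24 and 48 hr; broad: ≤ 0.091 at 24 hr) and tabulates a
growth-positive confusion matrix with accuracy, sensitivity, and
specificity. `pm_screen()` builds phenotype-microarray well media by
element-role replacement (C/N/P/S), applies aerobic/anaerobic adjustments,
forms cross-dataset consensus respiration calls (normal/low → positive,
unanimity required), and benchmarks growth predictions per well.

## Worked example

ATP maximization on the aerobic core energy network, glucose uptake fixed
at 10 mmol/gCDW/hr:

```r
library(fluxbal)

net <- fixture_core_energy_network("ecocyc", glucose = 10)
sol <- solve_fba(net)          # two-stage: maximize, then minimize Σ|v|
sol
#> <fba_solution> status: optimal, objective(ATPM) = 216, Sum|v| = 1072, growth: TRUE

dplyr::arrange(tidy(sol, nonzero = TRUE), dplyr::desc(abs(flux)))
#> # A tibble: 27 × 2
#>   reaction_id             flux
#> 1 ATPM                   216.
#> 2 ATP-SYNTHASE           176.
#> 3 NADH-DEHYDROG-A-RXN    100.
#> 4 SECRETION[co2[c]]       60.0
#> 5 CYTOCHROME-BO-OXIDASE   60.0
#> 6 UPTAKE[o2[c]]           60.0
#> ...
```

216 mmol ATP/gCDW/hr is the maximal aerobic ATP yield of this network under
the 4 H⁺/2e⁻ NADH-dehydrogenase convention; under the alternative
3 H⁺/2e⁻ convention (`fixture_core_energy_network("ijo")`) the same LP
gives 235, the entire difference coming from electron-transport proton
accounting. Anaerobically the fermentation network secretes the
stoichiometrically optimal 1:2:1 acetate:formate:ethanol mix:

```r
an <- solve_fba(fixture_fermentation_network(o2 = 0))
flux_of(an, "SECRETION[ac[c]]"); flux_of(an, "SECRETION[for[c]]"); flux_of(an, "SECRETION[etoh[c]]")
#> [1] 10    [1] 20    [1] 10
```

A knockout screen over every gene of the growth-configured fixture, scored
against a (here, self-consistent) experimental table:

```r
net <- fixture_growth_network()
# experimental_table: tibble(gene, od600_24h, od600_48h); here generated so
# that the experimental calls equal the simulated ones (self-consistency)
res <- ko_screen(net, fixture_fermentation(), experimental_table,
                 essentiality_criteria("broad"))
res
#> <screen_result> n = 58 (58 correct): accuracy 100.0%, sensitivity 100.0%, specificity 100.0%
glance(res)
#> # A tibble: 1 × 9
#>      tp    fp    fn    tn total correct accuracy sensitivity specificity
#> 1    44     0     0    14    58      58      100         100         100
```

The published screen-summary arithmetic is one call:

```r
confusion_stats(1175, 58, 12, 200)
#> accuracy 95.2, sensitivity 99.0, specificity 77.5  (n = 1445)
```

A thin command-line interface ships in `exec/fluxbal`
(`fixtures`, `build`, `fba`, `sweep`, `ko-screen`, `pm-screen`, `report`).

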
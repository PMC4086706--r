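---
title: "Flux-balance modeling from curated reaction tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-balance modeling from curated reaction tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxbal)
```

# The model

`fluxbal` treats a metabolic model the way a curated database does: as
tables of metabolites, reactions, and gene–product associations, from which
a solvable stoichiometric network is *derived*, not hand-assembled. The
derivation and the simulation layers are deliberately separated, because
most of the scientific content lives in the derivation rules:

1. **Balance checking.** A reaction is balanced when its signed per-element
   sums and net charge are zero; protons count like any other element. Any
   participant without a chemical structure (absent formula, or absent
   charge when charge checking is on) makes the balance *undetermined* —
   such reactions are unusable because an unbalanced reaction inside a
   steady-state model can create or destroy matter. Charge balance is
   checked alongside element balance by default (`check_charge = TRUE`,
   exposed as a switch): proton bookkeeping drives the entire
   electron-transport economy below, and a charge-only imbalance is a real
   imbalance.

2. **Class instantiation.** Reactions written against compound classes
   ("an alcohol") are expanded over the Cartesian product of their class
   slots; only mass-balanced bindings survive, an identical class on both
   sides binds to one instance, a slot with no balanced binding rejects the
   reaction as ambiguous, and reactions with more than `cap = 10000`
   candidate bindings are rejected outright rather than enumerated.

3. **The filter cascade.** In a fixed order — unbalanced/undetermined,
   physiologically irrelevant, polymerization-type flags, one-sided,
   string-only participants, variable stoichiometry, and finally
   disconnectedness run to a fixed point (a removal can disconnect further
   reactions) — with every exclusion logged under its category. The order
   is our choice (it is not forced by the semantics); fixing it, and
   re-running only the disconnected filter to convergence, makes
   construction deterministic and the logs reproducible. Two wrinkles are
   worth noting: instantiation runs *before* the filters, because a class
   reaction has no balance status of its own; and structurally one-sided
   reactions — which are trivially unbalanced — are left to the one-sided
   filter so the log carries the informative category.

Stoichiometric coefficients are kept exact: `normalize_stoichiometry()`
rescales every reaction to minimal whole-integer form (least common
multiple of rationalized denominators, divided by the overall GCD).
Scaling never changes balance status, but it *does* matter downstream: when
the taxicab stage (below) weighs Σ|v|, a reaction written per half-molecule
of O2 is half as "expensive" per unit of chemistry as the whole-molecule
form, so a canonical scaling is part of the model definition, not
cosmetics. This sensitivity is asserted in the test suite.

# Two-stage flux balance analysis

Fluxes are in mmol/gCDW/hr throughout; biomass coefficients in mmol/gCDW;
a biomass flux of 1.0 is a specific growth rate µ of 1.0 hr⁻¹. Stage 1
maximizes the objective reaction's flux subject to `S v = 0` over every
metabolite and the per-reaction bounds. Stage 2, on by default
(`minimize_fluxes`), pins the objective at its stage-1 optimum and
minimizes Σ|v| via the standard flux splitting (each reaction is one or two
non-negative variables, so Σ|v| is a linear objective). The reported
objective is always the stage-1 optimum; the growth call is
`objective > eps` with `eps = 1e-6` — our operationalization of "any
growth at all", configurable, and well above solver tolerance (1e-9).
Infeasible and unbounded statuses are reported as such and never coerced
into a no-growth call; an unbounded status is diagnostic of a
thermodynamically broken cycle touching the objective.

## The solver

The LP layer is an internal dense two-phase bounded-variable simplex with
Bland's anti-cycling rule (`R/simplex.R`). Writing it into the package was
a deliberate numerical choice: FBA screens generate thousands of small,
highly degenerate LPs (knockouts with zero optimum, redundant conserved-
moiety rows, exactly-balanced proton economies), and the solver is the one
component that must never fail silently on them. Determinism comes free:
entering variable is the smallest eligible index, leaving variable the
smallest basis index among ratio-test ties, so identical inputs give
identical vertices. Conserved moieties (NAD(H), CoA, quinone pools) make
`S` rank-deficient; the equality block is reduced to an independent row set
by QR factorization before solving, which is exact for zero right-hand
sides. The stage-2 objective pin is an exact equality row; if the pinned
system were ever numerically intractable the stage-1 vertex is returned
unchanged, so taxicab minimization degrades gracefully. During development
the solver was cross-checked against an independent LP implementation on
randomized bounded problems; the shipped tests check it against closed-form
and hand-enumerated optima instead, keeping the test oracles independent of
any solver.

## Maintenance energy

The biomass objective carries growth-associated maintenance (GAM) of
53.95 mmol ATP/gCDW inside the biomass reaction (ATP + H2O consumed, ADP +
Pi + H+ returned, scaled by biomass flux) and non-growth-associated
maintenance (NGAM) of 3.15 mmol ATP/gCDW/hr as a lower bound on the
standing ATP-hydrolysis reaction. Because NGAM is a constant flux floor,
growth is *affine*, not linear, in substrate supply: doubling the glucose
feed more than doubles µ. The chemostat-protocol tests therefore assert
exact homogeneity with NGAM = 0 and the maintenance offset with NGAM > 0.

# The fixture networks and the proton economy

The aerobic core-energy fixture (`fixture_core_energy()`) is a 23-reaction,
fully element- and charge-balanced model: PTS glucose uptake, glycolysis
through the fructose-6-phosphate aldolase / dihydroxyacetone-PTS branch,
pyruvate dehydrogenase, the complete TCA cycle, soluble transhydrogenase,
NADH dehydrogenase and succinate dehydrogenase feeding a cytochrome *bo*
oxidase, ATP synthase, and ATP hydrolysis as the standing objective.

Two electron-transport conventions are built in. Under the first, NADH
dehydrogenase translocates 4 H⁺ per 2 e⁻ and the oxidase is written per
whole O2; under the second, 3 H⁺ per 2 e⁻ with a half-O2 oxidase. The
remaining two coefficients — oxidase proton pumping and synthase H⁺/ATP —
are not free parameters: at the ATP-maximization reference state (glucose
10, NADH-dehydrogenase flux 100, oxidase flux 60 or 120, synthase flux 176
or 195), total proton conservation across the membrane reduces to a single
linear Diophantine relation per convention,

```
176·h_syn − 60·h_ox = 400        (whole-O2, 4 H+/2e−)
195·h_syn − 120·h_ox = 300       (half-O2, 3 H+/2e−)
```

whose smallest positive-integer solutions are (h_ox = 8, h_syn = 5) and
(h_ox = 4, h_syn = 4). `derive_proton_coefficients()` performs this
derivation; the fixture generators use its frozen output. The half-O2
solution reproduces the textbook 4 H⁺-per-half-O2 oxidase and 4 H⁺/ATP
synthase stoichiometries, which is a satisfying consistency check. With
these coefficients the maximal aerobic ATP yield on glucose 10 is exactly
216 (whole-O2 convention) or 235 (half-O2 convention) mmol/gCDW/hr, the
whole difference being proton bookkeeping.

The fermentation fixture extends the core with pyruvate-formate lyase,
acetate kinase/phosphotransacetylase, the two-step ethanol branch, lactate
dehydrogenase, PEP carboxylase with fumarate reductase, and
formate-hydrogen lyase (present but closed by default). It also restores
classical lower glycolysis (phosphofructokinase with the pfkA/pfkB isozyme
pair, aldolase, pyruvate kinase): the aldol-cleavage branch spends its
second PEP on the dihydroxyacetone PTS, which is precisely why the
parsimonious ATP-max optimum uses it (same ATP yield, fewer reactions) and
also why it cannot supply biomass precursors on its own — losing both
phosphofructokinase isozymes is lethal in this network while losing either
alone is not, the canonical isozyme-pair pattern.

Three media facts are load-bearing and easy to miss. Cytosolic protons
must be secretable (mixed-acid fermentation exports ~3 H⁺ per glucose);
water must be a free nutrient as well as a secretion (anaerobic fermentation
is a net water consumer); and growth media must supply phosphate, because
phosphorylated biomass precursors export phosphorus. In this desk-scale
network O2 and phosphate are supplied directly in the cytosol (there are no
transporters for them), as is ammonium in full-scale practice; glucose
enters through the periplasm via the PTS.

At zero oxygen the ATP-maximal solution secretes acetate, formate, and
ethanol at exactly 1:2:1 — the stoichiometric optimum of mixed-acid
fermentation — and an oxygen sweep from 0 to 20 mmol/gCDW/hr at glucose 10
eliminates ethanol first (at O2 = 10), then formate (at 20), with acetate
persisting until respiration fully covers the glucose supply at O2 = 60.

The miniature biomass (`fixture_biomass()`) drains eight glycolytic and
TCA precursors at coefficients of realistic magnitude. It is deliberately
not a measured cell composition: its purpose is to give the fixture a rich
essentiality structure (unique routes, isozyme pairs, shared complex
subunits, anaplerosis) at desk scale. Consequences to keep in mind: µ
values are not calibrated growth rates, and genes whose products act beyond
these eight precursors cannot be scored at all.

# Knockout and nutrient-utilization screening

A knockout disables a reaction when every catalyst unit intersects the
knockout set (complexes lose any subunit; isozyme units rescue each other)
or when a substrate-supplier gene with no declared alternative is lost.
Spontaneous/orphan reactions are never gene-disabled. Knockout solves skip
the taxicab stage: the growth call depends only on the stage-1 optimum, and
screens are the hot path. Multi-gene knockouts are supported as set-valued
input. A knockout that leaves the NGAM floor unsatisfiable comes back
infeasible and is scored as no growth.

Experimental classification uses the two standard OD600 readings of
high-throughput deletion data: narrow essentiality (≤ 0.005 at both 24 and
48 hr) and broad essentiality (≤ 0.091 at 24 hr). Boundary equality counts
as essential, consistent with the "≤" phrasing of both definitions. Narrow
classification refuses tables missing the 48-hour point rather than
guessing. The confusion matrix uses the growth-positive orientation
(true positive = growth in both simulation and experiment); percent
statistics are rounded half-up to one decimal, which reproduces the
published screen summaries from their count matrices exactly.

Phenotype-microarray screening builds each well's nutrient set from a base
minimal-media composition by element-role replacement (a carbon-plate well
removes the base carbon source and adds the test compound in the
periplasm), replaces ferric with ferrous iron, supplies ammonium in the
cytosol, and flags MOPS buffer, when present, as a usable sulfur source.
The base composition is a plain-text fixture file, not hard-coded.
Anaerobic adjustment changes exactly three things — O2 bound to zero,
formate-hydrogen lyase enabled, and the protoheme and pyridoxal
5′-phosphate requirements dropped from the biomass — and is idempotent.
Respiration scores are compared directly against simulated growth
(checkpoint linkage of elemental starvation to respiratory arrest); per
dataset, normal/low respiration maps to positive, and the cross-dataset
consensus requires unanimity, with a majority policy available as a
documented alternative reading. No-consensus wells are excluded from
accuracy, never imputed. In this fixture PDH is not anaerobically
repressed (gene regulation is out of scope), so the anaerobic network
grows even without formate-hydrogen lyase; enabling it strictly increases
anaerobic biomass, and the tests assert that monotone property.

# Synthetic experimental data

`generate_essentiality_table()` draws a two-mode OD600 distribution: a
non-growing mode near 0.002, a severe-growth-defect tail between the narrow
and broad thresholds (so the two criteria disagree on a known subset), and
a growing mode around 0.4 — the qualitative shape of genome-wide deletion
OD data. Defaults (11% non-growing, 7% defect) match the approximate
narrow- and broad-essential fractions of such screens. With noise 0 the
modes collapse to central values and classification recovers the ground
truth exactly — the property the acceptance checks lean on.
`generate_pm_dataset()` emits per-well, per-dataset respiration scores with
a configurable conflict rate (default 70/383, the observed fraction of
conflicted wells); a conflicted well receives one flipped dataset, which is
exactly what the unanimity consensus rejects. All generators are pure
functions of configuration and seed.

What passing these tests shows — and does not. The generators reproduce
the *decision structure* of the experimental data (bimodality, threshold
placement, conflict rate), not its biology: there are no batch effects, no
media carryover, no partial-growth ambiguity beyond the defect tail. A
perfect score on synthetic recovery validates the classification and
consensus machinery, not the model's biological accuracy.

# Numerical choices, sizes, limitations

* Growth threshold `eps = 1e-6`; solver pivot tolerance 1e-9; steady-state
  residual asserted ≤ 1e-6 on every optimum the tests produce.
* Fixture problem sizes: 23 internal reactions (core), 37 (fermentation;
  50 with exchanges, 60 LP variables after flux splitting); the full-gene
  knockout screen is 58 genes. These sizes were chosen so that any result in the test suite
  can be re-derived by hand from the stoichiometry tables.
* Exchange bounds default to 3000 mmol/gCDW/hr for "unconstrained" — an
  order of magnitude above any flux these networks can carry, small enough
  to keep the tableau well-scaled.
* The chemostat protocol (substrate supply as the only fixed constraint,
  equality-pinned, biomass maximized) is implemented and property-tested;
  reproducing published chemostat flux tables requires the full
  genome-scale database model, which is out of scope here by design.
* No flux-variability analysis, no MOMA/ROOM, no quadratic objectives, no
  regulation or expression modeling; gap-filling is limited to reporting
  blocked biomass members via `reachability_scan()`.
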
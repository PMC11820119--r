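---
title: "Building GWP* food composition databases: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building GWP* food composition databases: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwpstar)
```

## The problem and the model

GWP\* expresses the warming impact of a food in kg CO₂e per kg, accounting
for the distinct atmospheric dynamics of short-lived gases such as methane.
Because methane's contribution depends on the *trend* in emissions, GWP\*
values can legitimately be zero (water) or negative (commodities from herds
with declining methane output); the package treats sign as unconstrained
everywhere.

Published GWP\* values exist for a few hundred mostly single-ingredient
commodities, while survey food composition databases contain thousands of
foods, most of them composite. The package assigns a value to *every* food
by a staged procedure in which each food's assignment method and target are
recorded in a curated **match specification** — one row per food. This
externalizes the expert matching judgment (which is consensus-driven, not
algorithmic) as data: the pipeline validates and executes it, and the whole
build is replayable and auditable. The package deliberately does **not**
attempt automated semantic matching of food names.

### Composite foods

A composite food's value is the weight-proportional sum of its ingredient
values:

$$\mathrm{GWP}^*(\mathrm{food}) \;=\; \sum_i \frac{w_i}{W}\,
  \mathrm{GWP}^*(\mathrm{ingredient}_i),$$

with $w_i$ the ingredient weight in the recipe and $W$ the total recipe
weight. Recipes nest: a casserole's sauce is itself a composite, so
evaluation proceeds in topological order over the recipe graph, each
composite ingredient contributing its fully resolved value. The graph is
validated to be acyclic before any evaluation starts; a cycle raises an
error carrying the offending path, never an infinite loop.

**Unmatched ingredients.** When an ingredient has no obtainable value, it
and its weight are removed from both numerator and denominator — the
remaining ingredients are renormalized over the matched weight. The
alternative reading (unmatched ingredients contribute zero but keep their
weight in the denominator) is available as
`gwp_config(excluded_ingredient_policy = "zero")`; the renormalization is
the default because the exclusion is of the ingredient *and its weight*.
Either way the per-food `coverage` — matched weight over total weight —
is reported, so partially valued foods remain visible. If *no* ingredient
matches, the composite itself propagates as unmatched and is excluded.

**Coverage does not inherit.** Once a composite is resolved, parents that
use it treat it as fully specified: the parent's coverage reflects only its
own direct ingredients. Cascading coverage multiplicatively through deep
recipes would conflate "this sub-recipe was partially valued" with "this
ingredient is unvalued", and the diagnostic value of coverage as a local
property would be lost; the build report lists every coverage < 1 food
instead.

**No yield factors.** Recipe weights are used exactly as given; no
cooking-yield or moisture-change adjustment is applied. Volumes in
description-derived recipes are converted at water density (1 g/mL), which
is appropriate for the dilute aqueous preparations (tea, broths, diluted
beverages) these descriptions concern.

### Stage-3 approximations

*Group averages* take the unweighted arithmetic mean of the **distinct**
reference items mapped to the food's classification group. The mapping is
derived from the stage-1 entries of the match specification: the reference
items "belonging" to a group are the ones its own foods were directly or
approximately matched to. Averaging distinct reference items — rather than
database foods — keeps a many-foods-to-one-item group from double-weighting
a single commodity. When a minor group has no mapped items the search falls
back to the sub-major and then the major level (logged in the build report);
the fallback can be disabled, in which case the food is excluded.

*Processing factors* approximate processed produce from fresh counterparts:
for commodity pairs where both forms are published, the ratio
processed/fresh is computed, and the factor is the **mean of ratios** (not
the ratio of sums), computed separately for fruit and vegetables. The
word order of the procedure — divide each pair, then average — dictates
this choice, and the test suite pins it with a pair set,
$\{(2,1),(9,3)\}$, on which the two estimators disagree (2.5 vs 2.75).
Pairs with a zero fresh value are rejected with a warning.

### Rounding and export

Internal computation keeps full double precision; rounding would otherwise
compound through recursive recipes. Only `write_gwp_database()` rounds, to
two decimals, **half-up** (half away from zero): `0.185 → 0.19`. Published
tables in this field use half-up presentation; base R's round-half-to-even
would disagree on exact half-way values. A guard of `sqrt(.Machine$double.eps)`
absorbs binary representation error so that decimal literals like 2.675
round as a human would expect. Tabulated percentages are rounded the same
way, which is why printed percentages may not sum to exactly 100.

Sign convention for half-up at negative values: away from zero
(`-0.185 → -0.19`), matching the symmetric treatment of negative GWP\*
values.

### Group statistics

`summarize_by_group()` reports unweighted per-food mean and SD per
classification group, excluded foods omitted; groups with no matched foods
are kept with `n = 0` and empty statistics. The default SD is the sample
SD (n − 1) — the descriptive convention for food-group tables — so a
single-food group has an undefined (NA) SD; `sd_mode = "population"` is
available. Each food counts once: the statistics describe the database, not
consumption-weighted diets.

## Dietary footprints

`compute_footprint()` scores intake records as
$\mathrm{kg\ CO_2e} = (\mathrm{amount_g}/1000)\times \mathrm{GWP}^*$ and
aggregates per food, per major group, and per subject/day. Intakes of
excluded foods contribute zero but are counted and their grams totalled in
a separate report, because silently dropping them would hide the systematic
underestimation that exclusions cause. The computation is linear and
additive by construction, and the test suite asserts both properties on
generated diets.

## The synthetic-data generator

`generate_bundle()` produces a complete input bundle with known ground
truth. Its defaults are the study conditions the package is tested under:

* **Step mix** (`default_step_mix()`): the observed proportions of a
  full-scale national database build — roughly 35 % stage 1, 55 % stage 2
  (dominated by recipe-file calculations), 6 % stage 3, 4 % excluded.
* **Reference values**: log-normal, `meanlog = 0`, `sdlog = 1` — median
  1 kg CO₂e/kg with a long right tail, the shape of published commodity
  footprint tables, which span roughly 0.05 (vegetables, water-like
  beverages) to above 16 (beef) — with 2 % of values negated to emulate
  declining-methane commodities. Salt (0.06) and water (0) are always
  present as ordinary reference rows.
* **Recipes**: nested up to depth 3 by default (5 maximum), 2–6 ingredients
  per recipe, weights uniform on 5–200 g.
* **Intakes** (`generate_intakes()`): gamma-distributed serving sizes
  (shape 2, scale 75: mean 150 g, right-skewed like real serving-size
  distributions).

Ground-truth values are computed by a **flat leaf-expansion oracle**
(`flat_leaf_expansion()`): an explicit-worklist traversal that accumulates
`fraction × leaf value` contributions without recursion or memoized
intermediate results, i.e. a structurally different algorithm from the
pipeline's topological evaluator. A shared bug would have to be implemented
twice differently to go unnoticed. Composites containing an unmatched
ingredient are planted only as terminal foods (never reused as ingredients);
this keeps every reused sub-recipe at coverage 1, the regime in which the
two evaluation orders are provably identical, and mirrors real recipe files,
where partially valued foods are overwhelmingly end products. The
coverage < 1 *nesting* semantics is separately unit-tested against
hand-computed fixtures.

**What the generator does not emulate:** real ingredient-proportion error
(label-derived proportions estimated from ingredient order), the semantic
difficulty of matching itself (the generator's match spec is correct by
construction), consumption-weighted food frequencies, and cooking yield
changes. Passing the recovery tests therefore demonstrates that the
*pipeline arithmetic and bookkeeping* are correct, not that any particular
real-world matching is.

## Numerical choices and degenerate inputs

* Tolerances: oracle-equivalence and recovery tests assert agreement within
  1e-9; direct arithmetic identities within 1e-12.
* Empty recipes, zero total weight, non-positive weights, malformed or
  duplicate food codes, duplicate reference items, and missing match-spec
  entries are classed validation errors naming the offending rows.
* Cycle errors (`gwpstar_cycle_error`) carry the cycle path in a `cycle`
  field, for recipe graphs and similar-food chains alike.
* Similar-food chains resolve by the same dependency ordering as recipes;
  a chain ending in an excluded food propagates the exclusion.
* Fraction-based recipe descriptions must sum to ≤ 1 (tolerance 1e-6).
* The relative deviation in the nutrient consistency report floors its
  denominator at 1e-9 to tolerate zero-valued target nutrients; nutrients
  missing from any ingredient profile are reported as "not comparable"
  rather than failing.

## Problem sizes used by the test and acceptance suites

The oracle-equivalence suite evaluates 500 random DAGs (3–8 leaves, 3–8
composites, depth ≤ 5). End-to-end recovery builds 20 seeded bundles of
200–2000 foods and checks values to 1e-9 and stage counts exactly. These
sizes exercise every pathway — including multi-level nesting, negative
values, partial coverage, and group-average fallback — while keeping a full
test run in the low minutes on a single core.

## Known limitations

* The package executes a curated match specification; it does not propose
  matches. Garbage judgments in, garbage database out — the validation
  catches structural errors, not semantic ones.
* Group averaging assumes the classification hierarchy is encoded in food
  code prefixes (configurable lengths). Databases with non-positional
  classifications would need a shim.
* The nutrient consistency check is linear mixing per 100 g; it does not
  model nutrient losses in preparation, so it is a screening report, not a
  validation of recipe realism.
* Excluded foods bias footprints downward by construction; the footprint
  report quantifies the exposure (records and grams affected) but cannot
  correct it.
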
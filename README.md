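# gwpstar

Build climate-footprint-annotated food composition databases and apply them
to dietary intake data.

## The problem

Quantifying the climate impact of whole diets requires a footprint value for
*every* food in the food composition database that underlies the dietary
survey — not just the few hundred commodities for which life-cycle analysis
results exist. GWP\* (Global Warming Potential Star) values, expressed in
kg CO₂e per kg of food, capture the warming impact of foods including the
distinct dynamics of short-lived gases such as methane; they can be negative
for commodities with declining methane emissions (e.g. Australian lamb).
Published GWP\* values cover only a couple of hundred mostly single-ingredient
commodities, while a national survey database contains thousands of foods,
most of them composite.

`gwpstar` implements the systematic, staged procedure for bridging that gap:

* **Stage 1 — direct / approximate matching**: a database food is matched to a
  single published reference value (e.g. raw beef mince → "Beef meat").
* **Stage 2 — composite-food calculation**: a multi-ingredient food's value is
  the weight-proportional sum of its ingredient values,

  `GWP*(food) = Σᵢ (wᵢ / W) · GWP*(ingredientᵢ)`

  with `wᵢ` the ingredient weight and `W` the total recipe weight, applied
  recursively through nested recipes. Ingredients with no obtainable value
  are excluded from numerator *and* denominator (renormalization), and the
  fraction of recipe weight still covered is reported per food. Ingredient
  lists can come from a recipe table, from quantity descriptions ("15 g of
  tea leaves to one litre of water"), from product labels, from nut-content
  data, from a conceptually similar food's calculated value, or from online
  recipes — all expressed as rows of a curated *match specification* file
  that externalizes the expert matching judgment as data.
* **Stage 3 — approximation**: remaining foods take the unweighted mean of
  the reference items associated with their classification group (minor →
  sub-major → major fallback), or, for processed produce, the fresh
  counterpart's value times a *processing conversion factor* (the mean of
  processed/fresh value ratios, computed separately for fruit and
  vegetables).
* Foods with no defensible match are **excluded**, and stay visible: they are
  exported with empty values, tabulated, and counted separately when diets
  are scored (their intake contributes 0, flagging underestimation).

Every assigned value carries stage/step provenance, and the package produces
the two standard summary reports: the stage/step accounting table (counts and
half-up-rounded percentages) and per-food-group mean ± SD values.

A seeded synthetic-data generator (`generate_bundle()`) emits complete,
internally consistent input bundles — hierarchical 8-digit food codes,
acyclic multi-level recipes, a reference table with negative values, a match
specification covering every pathway — together with ground-truth values
computed by an independent flat leaf-expansion oracle, so the entire pipeline
is testable without access to restricted survey data.

## Worked example

The package ships a miniature eleven-food database under `inst/extdata`
exercising every assignment pathway:

```r
library(gwpstar)

ext <- function(f) system.file("extdata", f, package = "gwpstar")
foods      <- read_food_details(ext("food_details.csv"))
reference  <- read_gwp_reference(ext("gwp_reference.csv"))
recipes    <- read_recipes(ext("recipes.csv"))
match_spec <- read_match_spec(ext("match_spec.csv"))
pairs      <- readr::read_csv(ext("processing_pairs.csv"), show_col_types = FALSE)

build <- build_gwp_database(foods, recipes, reference, match_spec, pairs)
build
#> <gwp_build> 11 foods: 10 matched (90.91%), 1 excluded
#>   stage 1            4 (36.36%)
#>   stage 2            4 (36.36%)
#>   stage 3            2 (18.18%)
#>   stage excluded     1 (9.09%)
#>   processing factors: fruit=2, vegetable=3
#>   warning: 1 food(s) valued with recipe coverage < 1: 13104001
```

`write_gwp_database(build, foods, "db.csv")` exports the database rounded
half-up to two decimals (full precision is kept internally):

```
food_code,name,gwp_star_kg_co2e_per_kg,stage,step,coverage,provenance
13101234,"Beef, mince, <5% fat, raw",16.68,1,direct,1.000000,Beef meat (16.68)
13102001,"Beef casserole, homemade",8.34,2,recipe-file,1.000000,13101234 (8.34); 11101001 (0)
10201001,"Tea, black, brewed, plain",0.11,2,description,1.000000,Tea leaves (0.1079); Water (0)
19101001,"Echidna, wild caught, flesh, raw",,excluded,excluded,,NA
13104001,Beef dish with wild-caught meat,16.68,2,recipe-file,0.900000,13101234 (16.68)
16101001,"Apple, canned",1.00,3,processing-factor,1.000000,Apple fresh (0.5)
...
```

Reading the rows: the homemade casserole is 500 g beef + 500 g water, so its
value is `0.5 × 16.68 = 8.34`; brewed tea is 15 g leaves per litre of water,
`15/1015 × 7.3 ≈ 0.11`; the dish containing 10 g of an excluded wild-caught
meat is renormalized over the 90 % of its weight that matched; canned apple
is fresh apple (0.5) times the fruit processing factor (0.8/0.4 = 2).

Scoring a diet against the built database:

```r
intakes <- read_intakes(ext("intakes.csv"))
fp <- compute_footprint(intakes, build)
fp
#> <gwp_footprint> total 7.5384 kg CO2e over 3 record(s)
glance(fp)   # totals, excluded-intake count and grams
tidy(fp)     # per-record contributions
```

A 250 g serve of the beef mince contributes `0.250 × 16.68 = 4.17` kg CO₂e.
`tidy()`, `glance()` and `autoplot()` methods are provided for built
databases and footprints, and a thin command-line front end
(`inst/cli/gwpstar.R`) exposes `validate`, `build`, `summarize`, `footprint`
and `simulate` subcommands.

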
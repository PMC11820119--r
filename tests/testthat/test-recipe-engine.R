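resolver_from <- function(values) function(id) values[[id]] %||% NA_real_

test_that("composite value is the weight-proportional mean of ingredient values", {
  recipe <- tibble::tibble(ingredient_id = c("A", "B"), weight_g = c(50, 50))
  res <- compute_composite_gwp(recipe, resolver_from(list(A = 2, B = 4)))
  expect_equal(res$value, 3)
  expect_equal(res$coverage, 1)
  expect_equal(res$total_weight_g, 100)

  uneven <- tibble::tibble(ingredient_id = c("A", "B"), weight_g = c(15, 1000))
  res2 <- compute_composite_gwp(uneven, resolver_from(list(A = 7.3, B = 0)))
  expect_equal(res2$value, 15 / 1015 * 7.3)
})

test_that("unmatched ingredients follow the configured exclusion policy", {
  recipe <- tibble::tibble(ingredient_id = c("A", "C"), weight_g = c(90, 10))
  vals <- resolver_from(list(A = 1))

  renorm <- compute_composite_gwp(recipe, vals, policy = "renormalize")
  expect_equal(renorm$value, 1)       # weight removed from both sides
  expect_equal(renorm$coverage, 0.9)
  expect_equal(nrow(renorm$excluded), 1)

  zero <- compute_composite_gwp(recipe, vals, policy = "zero")
  expect_equal(zero$value, 0.9)       # weight stays in the denominator
  expect_equal(zero$coverage, 0.9)

  nothing <- compute_composite_gwp(recipe, resolver_from(list()))
  expect_true(nothing$unmatched)
  expect_true(is.na(nothing$value))
  expect_equal(nothing$coverage, 0)
})

test_that("degenerate recipes are rejected", {
  expect_error(compute_composite_gwp(
    tibble::tibble(ingredient_id = character(), weight_g = numeric()),
    resolver_from(list())), "Empty recipe")
  expect_error(compute_composite_gwp(
    tibble::tibble(ingredient_id = "A", weight_g = 0),
    resolver_from(list(A = 1))), "non-positive")
})

test_that("composite values are convex, homogeneous in weights, and monotone", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(2:8, 1)
    ids <- paste0("I", seq_len(k))
    vals <- stats::rnorm(k, 1, 4) # negative values allowed
    w <- stats::runif(k, 0.5, 50)
    recipe <- tibble::tibble(ingredient_id = ids, weight_g = w)
    res <- compute_composite_gwp(recipe, resolver_from(as.list(stats::setNames(vals, ids))))
    expect_gte(res$value, min(vals) - 1e-12)
    expect_lte(res$value, max(vals) + 1e-12)

    scaled <- compute_composite_gwp(
      dplyr::mutate(recipe, weight_g = weight_g * 7.5),
      resolver_from(as.list(stats::setNames(vals, ids))))
    expect_equal(scaled$value, res$value, tolerance = 1e-12)

    bumped <- vals
    bumped[1] <- bumped[1] + 1
    res_b <- compute_composite_gwp(recipe,
      resolver_from(as.list(stats::setNames(bumped, ids))))
    expect_gt(res_b$value, res$value)
  }
})

test_that("recursive evaluation matches flat leaf expansion on random DAGs", {
  for (seed in 1:60) {
    dag <- random_dag(seed)
    rec <- recursive_dag_values(dag)
    flat <- vapply(dag$comp_codes, function(code) {
      flat_leaf_expansion(code, dag$recipes, dag$leaf_values)
    }, numeric(1))
    expect_equal(rec, flat, tolerance = 1e-9)
  }
})

test_that("a three-level nested fixture equals its single-pass expansion", {
  recipes <- tibble::tibble(
    parent_food_code = c("P", "P", "M", "M", "M2", "M2"),
    ingredient_food_code = c("M", "L1", "L2", "M2", "L3", "L4"),
    ingredient_weight_g = c(60, 40, 30, 70, 10, 90)
  )
  leaves <- c(L1 = 2, L2 = -1, L3 = 10, L4 = 0.5)
  vm2 <- (10 * 10 + 90 * 0.5) / 100
  vm <- (30 * -1 + 70 * vm2) / 100
  vp <- (60 * vm + 40 * 2) / 100
  expect_equal(flat_leaf_expansion("P", recipes, leaves), vp, tolerance = 1e-12)
  dag <- list(recipes = recipes, leaf_values = leaves,
              comp_codes = c("M2", "M", "P"))
  expect_equal(unname(recursive_dag_values(dag)[["P"]]), vp, tolerance = 1e-12)
})

test_that("description-derived recipes convert amounts to grams at water density", {
  tea <- tibble::tibble(ingredient_id = c("Tea leaves", "Water"),
                        amount = c(15, 1), unit = c("g", "L"))
  rows <- recipe_from_description(tea)
  expect_equal(rows$weight_g, c(15, 1000))
  res <- compute_composite_gwp(rows, resolver_from(list("Tea leaves" = 7.3, Water = 0)))
  expect_equal(res$value, 15 / 1015 * 7.3)

  single <- recipe_from_description(tibble::tibble(
    ingredient_id = "Oats", amount = 1, unit = "fraction"))
  res1 <- compute_composite_gwp(single, resolver_from(list(Oats = 0.62)))
  expect_equal(res1$value, 0.62)

  expect_error(recipe_from_description(tibble::tibble(
    ingredient_id = c("A", "B"), amount = c(0.6, 0.5), unit = "fraction")),
    "sum to")
  expect_error(recipe_from_description(tibble::tibble(
    ingredient_id = "A", amount = 1, unit = "cup")), "Unknown unit")
})

test_that("nutrient consistency report measures linear mixing deviations", {
  profiles <- tibble::tibble(
    id = rep(c("A", "B"), each = 2),
    nutrient = rep(c("protein", "fat"), 2),
    per_100g = c(10, 0, 0, 10))
  recipe <- tibble::tibble(ingredient_id = c("A", "B"), weight_g = c(50, 50))
  target <- tibble::tibble(nutrient = c("protein", "fat"), per_100g = c(5, 5))
  rep1 <- nutrient_consistency_report(recipe, profiles, target)
  expect_equal(rep1$deviation, c(0, 0))
  expect_false(any(rep1$flagged))

  # identity: recipe = 100% of an ingredient whose profile equals the target
  solo <- nutrient_consistency_report(
    tibble::tibble(ingredient_id = "A", weight_g = 100),
    profiles, tibble::tibble(nutrient = c("protein", "fat"), per_100g = c(10, 0)))
  expect_equal(solo$deviation, c(0, 0))

  # hand-computed three-ingredient deviation
  profiles3 <- tibble::tibble(
    id = rep(c("A", "B", "C"), each = 1),
    nutrient = "protein", per_100g = c(10, 20, 40))
  recipe3 <- tibble::tibble(ingredient_id = c("A", "B", "C"),
                            weight_g = c(20, 30, 50))
  composite <- (20 * 10 + 30 * 20 + 50 * 40) / 100
  rep3 <- nutrient_consistency_report(recipe3, profiles3,
    tibble::tibble(nutrient = "protein", per_100g = 25), tolerance = 0.1)
  expect_equal(rep3$composite, composite)
  expect_equal(rep3$deviation, abs(composite - 25) / 25)
  expect_true(rep3$flagged)

  # missing nutrient key is reported, not an error
  missing <- nutrient_consistency_report(recipe, profiles,
    tibble::tibble(nutrient = "fibre", per_100g = 3))
  expect_false(missing$comparable)
  expect_false(missing$flagged)
})
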
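# Hand-built miniature database: a dozen foods covering every assignment
# pathway, with values small enough to verify by hand.
mini_inputs <- function() {
  reference <- tibble::tibble(
    item_name = c("Beef meat", "Salt", "Water", "Tea leaves", "Apple fresh",
                  "Pear processed", "Pear fresh", "Bean processed", "Bean fresh"),
    gwp_value = c(16.68, 0.06, 0, 7.3, 0.5, 0.8, 0.4, 0.9, 0.3),
    source_tag = "fixture"
  )
  foods <- tibble::tibble(
    food_code = c("13101234", "13101235", "11101001", "14101001", "13102001",
                  "10201001", "13103001", "19101001", "13104001", "13101236",
                  "16101001"),
    name = c("Beef, mince, <5% fat, raw",
             "Beef, mince, cooked, no added fat",
             "Water, tap",
             "Salt, table",
             "Beef casserole, homemade",
             "Tea, black, brewed, plain",
             "Beef casserole, takeaway",
             "Echidna, wild caught, flesh, raw",
             "Beef dish with wild-caught meat",
             "Beef, other cut",
             "Apple, canned"),
    description = "fixture food"
  )
  match_spec <- tibble::tibble(
    food_code = foods$food_code,
    method = c("direct", "approximate", "direct", "direct", "recipe_file",
               "description_recipe", "similar_food", "excluded", "recipe_file",
               "group_average", "processing_factor"),
    target = c("Beef meat", "Beef meat", "Water", "Salt", NA,
               "Tea leaves=15; Water=1000", "13102001", NA, NA,
               NA, "Apple fresh | fruit"),
    note = NA_character_
  )
  recipes <- tibble::tibble(
    parent_food_code = c("13102001", "13102001", "13104001", "13104001"),
    ingredient_food_code = c("13101234", "11101001", "13101234", "19101001"),
    ingredient_weight_g = c(500, 500, 90, 10)
  )
  processing_pairs <- tibble::tibble(
    category = c("fruit", "vegetable"),
    processed_item = c("Pear processed", "Bean processed"),
    fresh_item = c("Pear fresh", "Bean fresh")
  )
  list(foods = foods, reference = reference, match_spec = match_spec,
       recipes = recipes, processing_pairs = processing_pairs)
}

mini_build <- function(config = gwp_config()) {
  m <- mini_inputs()
  build_gwp_database(m$foods, m$recipes, m$reference, m$match_spec,
                     m$processing_pairs, config = config)
}

# Random acyclic recipe DAG over abstract nodes: leaves carry values (possibly
# negative), composites reference strictly earlier nodes, so depth is bounded.
# Returns the pieces needed to evaluate both recursively (per-node engine
# calls) and flat (leaf expansion).
random_dag <- function(seed, max_depth = 5) {
  set.seed(seed)
  n_leaf <- sample(3:8, 1)
  leaf_codes <- sprintf("9%02d00000", seq_len(n_leaf))
  leaf_values <- stats::setNames(stats::rnorm(n_leaf, 2, 3), leaf_codes)
  n_comp <- sample(3:8, 1)
  comp_codes <- sprintf("8%02d00000", seq_len(n_comp))
  depth <- stats::setNames(rep(0L, n_leaf), leaf_codes)
  rows <- list()
  for (i in seq_len(n_comp)) {
    pool <- names(depth)[depth < max_depth]
    k <- sample(2:min(5, length(pool)), 1)
    ing <- pool[sample.int(length(pool), k)]
    rows[[i]] <- tibble::tibble(parent_food_code = comp_codes[i],
                                ingredient_food_code = ing,
                                ingredient_weight_g = stats::runif(k, 1, 100))
    depth[comp_codes[i]] <- 1L + max(depth[ing])
  }
  list(recipes = dplyr::bind_rows(rows), leaf_values = leaf_values,
       comp_codes = comp_codes)
}

# Recursive route: resolve composites in dependency order with the package's
# per-node engine, each composite ingredient using its resolved value.
recursive_dag_values <- function(dag) {
  resolved <- as.list(dag$leaf_values)
  for (code in dag$comp_codes) {
    rows <- dag$recipes[dag$recipes$parent_food_code == code, ]
    res <- compute_composite_gwp(
      tibble::tibble(ingredient_id = rows$ingredient_food_code,
                     weight_g = rows$ingredient_weight_g),
      function(id) resolved[[id]] %||% NA_real_,
      parent = code)
    resolved[[code]] <- res$value
  }
  unlist(resolved[dag$comp_codes])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
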
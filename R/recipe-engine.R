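#' Compute a composite food's GWP* value from its recipe
#'
#' Implements the weight-proportional summation by which a composite food's
#' climate footprint is assembled from its ingredients: each ingredient's
#' value (kg CO2e/kg) is weighted by its share of the recipe weight and the
#' shares are summed. Ingredients for which the resolver reports no value
#' ("unmatched") are handled according to `policy`:
#'
#' * `"renormalize"` (default): the unmatched ingredient and its weight are
#'   removed from both numerator and denominator, i.e. the value is the
#'   weighted mean over matched ingredients only.
#' * `"zero"`: the unmatched ingredient contributes 0 but its weight stays in
#'   the denominator.
#'
#' Under either policy `coverage` — the fraction of total recipe weight
#' carried by matched ingredients — is reported so partial valuation remains
#' visible. If no ingredient matches, the composite itself is unmatched and
#' the exclusion propagates upward.
#'
#' @param recipe data frame with columns `ingredient_id` and `weight_g`
#'   (positive).
#' @param resolver function taking an ingredient id and returning its GWP*
#'   value in kg CO2e/kg, or `NA` to signal "unmatched".
#' @param parent identifier of the composite food (used in messages and in
#'   the returned resolution).
#' @param policy unmatched-ingredient policy, `"renormalize"` or `"zero"`.
#' @return an object of class `recipe_resolution`: a list with elements
#'   `parent`, `value` (NA when unmatched), `coverage`, `total_weight_g`,
#'   `matched_weight_g`, `included` (tibble of ingredient, weight, value,
#'   contribution), `excluded` (tibble of ingredient, weight) and
#'   `unmatched` (logical).
#' @examples
#' recipe <- tibble::tibble(ingredient_id = c("A", "B"), weight_g = c(50, 50))
#' res <- compute_composite_gwp(recipe, function(id) c(A = 2, B = 4)[[id]])
#' res$value    # 3
#' res$coverage # 1
#' @export
compute_composite_gwp <- function(recipe, resolver, parent = NA_character_,
                                  policy = c("renormalize", "zero")) {
  policy <- match.arg(policy)
  recipe <- tibble::as_tibble(recipe)
  if (!nrow(recipe)) {
    abort_validation(sprintf("Empty recipe for food %s", parent))
  }
  if (any(!is.finite(recipe$weight_g) | recipe$weight_g <= 0)) {
    abort_validation(sprintf("Recipe for food %s has non-positive weights", parent))
  }
  total <- sum(recipe$weight_g)
  if (total <= 0) {
    abort_validation(sprintf("Recipe for food %s has zero total weight", parent))
  }

  values <- vapply(recipe$ingredient_id, function(id) {
    v <- resolver(id)
    if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)

  matched <- !is.na(values)
  matched_weight <- sum(recipe$weight_g[matched])
  coverage <- matched_weight / total

  if (matched_weight == 0) {
    return(structure(list(
      parent = parent, value = NA_real_, coverage = 0,
      total_weight_g = total, matched_weight_g = 0,
      included = tibble::tibble(ingredient_id = character(), weight_g = numeric(),
                                gwp_value = numeric(), contribution = numeric()),
      excluded = tibble::tibble(ingredient_id = recipe$ingredient_id,
                                weight_g = recipe$weight_g),
      unmatched = TRUE, policy = policy
    ), class = "recipe_resolution"))
  }

  denom <- if (policy == "renormalize") matched_weight else total
  contrib <- recipe$weight_g[matched] / denom * values[matched]

  structure(list(
    parent = parent,
    value = sum(contrib),
    coverage = coverage,
    total_weight_g = total,
    matched_weight_g = matched_weight,
    included = tibble::tibble(ingredient_id = recipe$ingredient_id[matched],
                              weight_g = recipe$weight_g[matched],
                              gwp_value = values[matched],
                              contribution = contrib),
    excluded = tibble::tibble(ingredient_id = recipe$ingredient_id[!matched],
                              weight_g = recipe$weight_g[!matched]),
    unmatched = FALSE, policy = policy
  ), class = "recipe_resolution")
}

#' @export
print.recipe_resolution <- function(x, ...) {
  cat(sprintf("<recipe_resolution> %s\n", x$parent))
  if (x$unmatched) {
    cat("  unmatched: no ingredient carries a GWP* value\n")
  } else {
    cat(sprintf("  value: %.4f kg CO2e/kg  coverage: %.3f  (policy: %s)\n",
                x$value, x$coverage, x$policy))
  }
  cat(sprintf("  ingredients: %d matched (%.1f g), %d excluded (%.1f g)\n",
              nrow(x$included), x$matched_weight_g,
              nrow(x$excluded), x$total_weight_g - x$matched_weight_g))
  invisible(x)
}

#' @export
tidy.recipe_resolution <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$included, status = "included"),
    dplyr::mutate(x$excluded, gwp_value = NA_real_, contribution = NA_real_,
                  status = "excluded")
  )
}

#' Build recipe rows from a description of ingredient quantities
#'
#' Converts human-readable ingredient quantities — as found in food database
#' description fields such as "15 g of tea leaves to one litre of water" —
#' into normalized recipe rows in grams. Volumes are converted at water
#' density (1 g/mL), the convention for the dilute aqueous preparations these
#' descriptions concern. Unitless fractions are interpreted as proportions of
#' a 100 g batch and must not sum above 1.
#'
#' @param ingredients data frame with columns `ingredient_id`, `amount` and
#'   `unit`, where `unit` is one of `"g"`, `"kg"`, `"mL"`, `"L"`,
#'   `"fraction"`.
#' @param tolerance slack allowed on the fraction sum (default 1e-6).
#' @return a tibble with columns `ingredient_id` and `weight_g`, suitable for
#'   [compute_composite_gwp()].
#' @examples
#' tea <- tibble::tibble(
#'   ingredient_id = c("Tea leaves", "Water"),
#'   amount = c(15, 1), unit = c("g", "L")
#' )
#' recipe_from_description(tea) # 15 g + 1000 g
#' @export
recipe_from_description <- function(ingredients, tolerance = 1e-6) {
  ingredients <- tibble::as_tibble(ingredients)
  units <- c(g = 1, kg = 1000, mL = 1, L = 1000)
  bad <- setdiff(unique(ingredients$unit), c(names(units), "fraction"))
  if (length(bad)) {
    abort_validation(sprintf("Unknown unit(s): %s", paste(sQuote(bad), collapse = ", ")))
  }
  if (any(!is.finite(ingredients$amount) | ingredients$amount <= 0)) {
    abort_validation("Ingredient amounts must be positive")
  }
  frac <- ingredients$unit == "fraction"
  if (any(frac)) {
    fsum <- sum(ingredients$amount[frac])
    if (fsum > 1 + tolerance) {
      abort_validation(sprintf("Ingredient fractions sum to %.4f > 1", fsum))
    }
  }
  weight_g <- ifelse(frac, ingredients$amount * 100,
                     ingredients$amount * unname(units[ingredients$unit]))
  tibble::tibble(ingredient_id = ingredients$ingredient_id, weight_g = weight_g)
}

#' Check a recipe's nutrient profile against its target food
#'
#' Computes the weight-proportional nutrient profile implied by a recipe's
#' ingredients (per 100 g) and reports the relative deviation from the target
#' food's published profile, nutrient by nutrient. This is the in-code
#' counterpart of checking an estimated recipe in dietary analysis software:
#' large deviations indicate that estimated ingredient proportions need
#' adjusting.
#'
#' @param recipe data frame with columns `ingredient_id`, `weight_g`.
#' @param profiles long-format tibble of ingredient profiles with columns
#'   `id`, `nutrient`, `per_100g` (see [read_nutrient_profiles()]).
#' @param target_profile tibble with columns `nutrient`, `per_100g` for the
#'   composite food itself.
#' @param tolerance relative deviation above which a nutrient is flagged
#'   (default 0.2, i.e. 20%).
#' @param eps floor applied to the target value in the relative-deviation
#'   denominator, guarding near-zero targets (default 1e-9).
#' @return a tibble with one row per target nutrient: `nutrient`, `composite`
#'   (recipe-implied value), `target`, `deviation` (relative), `flagged`, and
#'   `comparable` (FALSE when an ingredient profile lacks the nutrient).
#' @export
nutrient_consistency_report <- function(recipe, profiles, target_profile,
                                        tolerance = 0.2, eps = 1e-9) {
  recipe <- tibble::as_tibble(recipe)
  total <- sum(recipe$weight_g)
  share <- stats::setNames(recipe$weight_g / total, recipe$ingredient_id)

  purrr::map_dfr(seq_len(nrow(target_profile)), function(i) {
    nut <- target_profile$nutrient[[i]]
    tgt <- target_profile$per_100g[[i]]
    ing <- profiles[profiles$nutrient == nut, ]
    have <- recipe$ingredient_id %in% ing$id
    if (!all(have)) {
      return(tibble::tibble(nutrient = nut, composite = NA_real_, target = tgt,
                            deviation = NA_real_, flagged = FALSE, comparable = FALSE))
    }
    vals <- stats::setNames(ing$per_100g, ing$id)[recipe$ingredient_id]
    composite <- sum(share[recipe$ingredient_id] * vals)
    dev <- abs(composite - tgt) / max(abs(tgt), eps)
    tibble::tibble(nutrient = nut, composite = composite, target = tgt,
                   deviation = dev, flagged = dev > tolerance, comparable = TRUE)
  })
}
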
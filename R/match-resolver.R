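# Fixed, total mapping from match method to matching stage and step label.
STAGE_STEP <- tibble::tibble(
  method = c("direct", "approximate", "recipe_file", "description_recipe",
             "label_recipe", "nut_recipe", "similar_food", "online_recipe",
             "group_average", "processing_factor", "excluded"),
  stage  = c("1", "1", "2", "2", "2", "2", "2", "2", "3", "3", "excluded"),
  step   = c("direct", "approximate", "recipe-file", "description", "label",
             "nut-database", "similar-food", "online-recipe", "group-average",
             "processing-factor", "excluded")
)

#' The stage/step taxonomy of the matching process
#'
#' Returns the fixed mapping from assignment method to matching stage
#' (1 = direct or approximate match to a single reference value, 2 = value
#' calculated from multiple ingredients, 3 = approximation, or excluded) and
#' step label, as used in stage tabulations and provenance.
#'
#' @return a tibble with columns `method`, `stage`, `step`.
#' @export
stage_step_table <- function() STAGE_STEP

#' Resolve a single food to its GWP* value
#'
#' Executes one match-specification entry: copies a reference value (direct or
#' approximate match), evaluates a recipe (from the recipe table or an inline
#' ingredient list), copies a similar food's already-resolved value, delegates
#' to the stage-3 approximators, or marks the food excluded. Normally called
#' via [build_gwp_database()], which supplies dependencies in topological
#' order; exposed for testing and for interactive inspection of a single food.
#'
#' @param food_code the food to resolve.
#' @param match_spec validated match specification tibble.
#' @param context a list with elements `reference` (reference tibble),
#'   `recipes` (recipe tibble), `resolved` (named list of already-resolved
#'   values, NA = excluded), `foods` (food details), `group_items` (tibble
#'   `group_code`, `item_name` from [derive_group_item_map()]),
#'   `factors` (named numeric: processing factor per category), and `config`.
#' @return a one-row tibble: `food_code`, `value`, `stage`, `step`,
#'   `coverage`, `provenance` (list column), `note`.
#' @export
resolve_food <- function(food_code, match_spec, context) {
  entry <- match_spec[match_spec$food_code == food_code, ]
  if (!nrow(entry)) {
    abort_validation(sprintf("Unspecified food: no match spec entry for %s", food_code),
                     class = "gwpstar_unspecified_food")
  }
  method <- entry$method[[1]]
  target <- entry$target[[1]]
  ref <- context$reference
  policy <- context$config$excluded_ingredient_policy %||% "renormalize"

  row <- function(value, coverage = 1, provenance = NULL, note = NA_character_) {
    ss <- STAGE_STEP[STAGE_STEP$method == method, ]
    tibble::tibble(food_code = food_code, value = value, stage = ss$stage,
                   step = ss$step, coverage = coverage,
                   provenance = list(provenance %||%
                     tibble::tibble(id = character(), contribution = numeric())),
                   note = note)
  }
  lookup_ref <- function(item) {
    hit <- ref$gwp_value[ref$item_name == item]
    if (!length(hit)) {
      abort_validation(sprintf("Reference item not found: %s (food %s)",
                               sQuote(item), food_code),
                       class = "gwpstar_unknown_reference_item")
    }
    hit[[1]]
  }
  # ingredient resolver shared by recipe-based methods: digit strings are food
  # codes (must already be resolved; NA value = excluded), anything else is a
  # reference item name
  ingredient_resolver <- function(id) {
    if (grepl("^[0-9]+$", id)) {
      if (!id %in% names(context$resolved)) {
        abort_validation(sprintf(
          "Ingredient %s of food %s is not resolved yet (dependency order broken)",
          id, food_code))
      }
      context$resolved[[id]]
    } else {
      lookup_ref(id)
    }
  }

  switch(method,
    direct = ,
    approximate = {
      v <- lookup_ref(target)
      row(v, provenance = tibble::tibble(id = target, contribution = v))
    },
    recipe_file = {
      rows <- if (!is.null(context$recipes_by_parent)) {
        context$recipes_by_parent[[food_code]]
      } else {
        context$recipes[context$recipes$parent_food_code == food_code, ]
      }
      if (is.null(rows) || !nrow(rows)) {
        abort_validation(sprintf("No recipe rows for food %s (method recipe_file)",
                                 food_code))
      }
      recipe <- tibble::tibble(ingredient_id = rows$ingredient_food_code,
                               weight_g = rows$ingredient_weight_g)
      res <- compute_composite_gwp(recipe, ingredient_resolver,
                                   parent = food_code, policy = policy)
      if (res$unmatched) {
        excluded_row(food_code, note = "all ingredients unmatched")
      } else {
        row(res$value, coverage = res$coverage,
            provenance = tibble::tibble(id = res$included$ingredient_id,
                                        contribution = res$included$contribution))
      }
    },
    description_recipe = ,
    label_recipe = ,
    nut_recipe = ,
    online_recipe = {
      recipe <- parse_inline_ingredients(target, food_code)
      res <- compute_composite_gwp(recipe, ingredient_resolver,
                                   parent = food_code, policy = policy)
      if (res$unmatched) {
        excluded_row(food_code, note = "all ingredients unmatched")
      } else {
        row(res$value, coverage = res$coverage,
            provenance = tibble::tibble(id = res$included$ingredient_id,
                                        contribution = res$included$contribution))
      }
    },
    similar_food = {
      if (!target %in% names(context$resolved)) {
        abort_validation(sprintf(
          "similar_food target %s of food %s is not resolved (missing or cyclic)",
          target, food_code))
      }
      v <- context$resolved[[target]]
      if (is.na(v)) {
        excluded_row(food_code, note = sprintf("similar food %s is excluded", target))
      } else {
        row(v, provenance = tibble::tibble(id = target, contribution = v))
      }
    },
    group_average = {
      food <- context$foods[context$foods$food_code == food_code, ]
      v <- group_average_for_food(food, context$group_items, ref,
                                  explicit_group = if (!is.na(target) && nzchar(target %||% "")) target else NULL,
                                  fallback = context$config$group_fallback %||% TRUE)
      if (is.null(v)) {
        excluded_row(food_code, note = "no reference items in any classification level")
      } else {
        row(v$value, provenance = tibble::tibble(id = v$items, contribution = rep(v$value, length(v$items))),
            note = sprintf("group %s (%d items)", v$group, length(v$items)))
      }
    },
    processing_factor = {
      tg <- parse_processing_target(target, food_code)
      factor <- context$factors[[tg$category]]
      if (is.null(factor) || is.na(factor)) {
        excluded_row(food_code,
                     note = sprintf("no processing factor for category %s", tg$category))
      } else {
        fresh <- lookup_ref(tg$fresh_item)
        row(apply_processing_factor(fresh, factor),
            provenance = tibble::tibble(id = tg$fresh_item, contribution = fresh),
            note = sprintf("factor %.6g (%s)", factor, tg$category))
      }
    },
    excluded = excluded_row(food_code, note = entry$note[[1]] %||% NA_character_),
    abort_validation(sprintf("Unknown match method %s for food %s",
                             sQuote(method), food_code))
  )
}

excluded_row <- function(food_code, note = NA_character_) {
  tibble::tibble(food_code = food_code, value = NA_real_, stage = "excluded",
                 step = "excluded", coverage = NA_real_,
                 provenance = list(tibble::tibble(id = character(),
                                                  contribution = numeric())),
                 note = note)
}

#' Tabulate matching stages and steps
#'
#' Counts resolved foods per matching step and reports percentages of the
#' total, rounded half-up to two decimals (so printed percentages may not sum
#' exactly to 100). The result has the shape of the standard stage/step
#' accounting table: one row per step, one subtotal row per stage, plus
#' `matched` (everything not excluded) and `total` rows.
#'
#' @param resolved a `gwp_build` object or a tibble with `stage` and `step`
#'   columns, one row per food.
#' @return a tibble with columns `row_type` (`"step"`, `"stage"`,
#'   `"matched"`, `"total"`), `stage`, `step`, `n`, `pct`.
#' @examples
#' resolved <- tibble::tibble(
#'   stage = c("1", "1", "2", "excluded"),
#'   step = c("direct", "approximate", "recipe-file", "excluded")
#' )
#' tabulate_stages(resolved)
#' @export
tabulate_stages <- function(resolved) {
  if (inherits(resolved, "gwp_build")) resolved <- resolved$resolved
  total <- nrow(resolved)
  pct <- function(n) round_half_up(100 * n / total, 2)

  steps <- dplyr::count(
    dplyr::mutate(resolved,
                  step = factor(.data$step, levels = STAGE_STEP$step)),
    .data$step, .drop = FALSE, name = "n")
  steps <- dplyr::left_join(steps,
                            dplyr::distinct(STAGE_STEP[c("step", "stage")]),
                            by = "step")
  step_rows <- tibble::tibble(row_type = "step", stage = steps$stage,
                              step = as.character(steps$step), n = steps$n,
                              pct = pct(steps$n))

  stage_rows <- steps |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(factor(.data$stage, levels = c("1", "2", "3", "excluded")))
  stage_rows <- tibble::tibble(row_type = "stage", stage = stage_rows$stage,
                               step = NA_character_, n = stage_rows$n,
                               pct = pct(stage_rows$n))

  n_matched <- sum(resolved$stage != "excluded")
  dplyr::bind_rows(
    step_rows,
    stage_rows,
    tibble::tibble(row_type = "matched", stage = NA_character_,
                   step = NA_character_, n = n_matched, pct = pct(n_matched)),
    tibble::tibble(row_type = "total", stage = NA_character_,
                   step = NA_character_, n = total, pct = pct(total))
  )
}
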
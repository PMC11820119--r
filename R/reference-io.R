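#' Read a food details file
#'
#' Parses a delimited food details table (one row per database food) and
#' derives the hierarchical classification codes from the food code prefixes.
#' Food codes follow the survey convention of fixed-length digit strings in
#' which the leading 2, 3 and 5 digits identify the major, sub-major and minor
#' food groups respectively; both the code length and the prefix lengths are
#' configurable.
#'
#' @param path path to a UTF-8 CSV file with header columns `food_code`,
#'   `name` and `description` (extra columns are kept).
#' @param prefix_lengths named integer vector giving the number of leading
#'   digits for each classification level; names become `<name>_code` columns.
#' @param code_length required length of `food_code` (digits only).
#' @return a tibble of food records with one row per food and derived
#'   `major_code`, `sub_major_code` and `minor_code` columns.
#' @seealso [read_gwp_reference()], [read_recipes()], [read_match_spec()]
#' @export
read_food_details <- function(path,
                              prefix_lengths = c(major = 2L, sub_major = 3L, minor = 5L),
                              code_length = 8L) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("food_code", "name", "description")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_validation(sprintf("Food details file is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  validate_food_details(df, prefix_lengths = prefix_lengths, code_length = code_length)
}

#' Validate a food details table and derive classification codes
#'
#' @param foods data frame with at least `food_code`, `name`, `description`.
#' @inheritParams read_food_details
#' @return validated tibble with classification code columns.
#' @export
validate_food_details <- function(foods,
                                  prefix_lengths = c(major = 2L, sub_major = 3L, minor = 5L),
                                  code_length = 8L) {
  foods <- tibble::as_tibble(foods)
  foods$food_code <- as.character(foods$food_code)
  bad <- which(!grepl(sprintf("^[0-9]{%d}$", code_length), foods$food_code))
  if (length(bad)) {
    abort_validation(sprintf(
      "Malformed food_code at row(s) %s: expected %d digits, got %s",
      paste(utils::head(bad, 5), collapse = ", "), code_length,
      paste(sQuote(utils::head(foods$food_code[bad], 5)), collapse = ", ")))
  }
  dup <- unique(foods$food_code[duplicated(foods$food_code)])
  if (length(dup)) {
    abort_validation(sprintf("Duplicate food_code(s): %s",
                             paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (any(prefix_lengths >= code_length) || any(prefix_lengths < 1)) {
    abort_validation("prefix_lengths must be between 1 and code_length - 1")
  }
  for (lvl in names(prefix_lengths)) {
    foods[[paste0(lvl, "_code")]] <- substr(foods$food_code, 1L, prefix_lengths[[lvl]])
  }
  foods
}

#' Read a GWP* reference table
#'
#' Reads the table of published climate-footprint values, one per reference
#' item, in kg CO2e per kg of food. Negative values are legitimate (methane
#' dynamics can give declining-emission commodities such as Australian lamb a
#' negative GWP* value) and zero is legitimate (water). Pantry staples such as
#' salt are ordinary rows, not special cases.
#'
#' @param path path to a CSV file with columns `item_name`, `gwp_value` and
#'   optionally `source_tag`.
#' @return a tibble keyed by `item_name` with numeric `gwp_value`.
#' @export
read_gwp_reference <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(c("item_name", "gwp_value"), names(df))
  if (length(missing)) {
    abort_validation(sprintf("GWP* reference file is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  if (!"source_tag" %in% names(df)) df$source_tag <- NA_character_
  validate_gwp_reference(df)
}

#' @rdname read_gwp_reference
#' @param reference data frame with `item_name` and `gwp_value` columns.
#' @export
validate_gwp_reference <- function(reference) {
  reference <- tibble::as_tibble(reference)
  val <- suppressWarnings(as.numeric(reference$gwp_value))
  bad <- which(is.na(val) | !is.finite(val))
  if (length(bad)) {
    abort_validation(sprintf("Non-numeric or non-finite gwp_value for item(s): %s",
                             paste(sQuote(utils::head(reference$item_name[bad], 5)),
                                   collapse = ", ")))
  }
  dup <- unique(reference$item_name[duplicated(reference$item_name)])
  if (length(dup)) {
    abort_validation(sprintf("Duplicate reference item_name(s): %s",
                             paste(sQuote(utils::head(dup, 5)), collapse = ", ")))
  }
  reference$gwp_value <- val
  if (!"source_tag" %in% names(reference)) reference$source_tag <- NA_character_
  reference[c("item_name", "gwp_value", "source_tag")]
}

#' Read a food recipe table
#'
#' Reads the recipe file of weighted parent-to-ingredient edges that defines
#' composite foods, and validates that weights are positive, no food is its
#' own ingredient, and the overall parent/ingredient relation is acyclic.
#'
#' @param path path to a CSV file with columns `parent_food_code`,
#'   `ingredient_food_code`, `ingredient_weight_g`.
#' @return a tibble of validated recipe rows.
#' @export
read_recipes <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    parent_food_code = readr::col_character(),
    ingredient_food_code = readr::col_character(),
    ingredient_weight_g = readr::col_double()
  ), progress = FALSE)
  validate_recipes(df)
}

#' @rdname read_recipes
#' @param recipes data frame of recipe rows.
#' @export
validate_recipes <- function(recipes) {
  recipes <- tibble::as_tibble(recipes)
  recipes$parent_food_code <- as.character(recipes$parent_food_code)
  recipes$ingredient_food_code <- as.character(recipes$ingredient_food_code)
  recipes$ingredient_weight_g <- as.numeric(recipes$ingredient_weight_g)
  bad <- which(!is.finite(recipes$ingredient_weight_g) | recipes$ingredient_weight_g <= 0)
  if (length(bad)) {
    abort_validation(sprintf("Non-positive ingredient_weight_g at recipe row(s): %s",
                             paste(utils::head(bad, 5), collapse = ", ")))
  }
  self <- which(recipes$parent_food_code == recipes$ingredient_food_code)
  if (length(self)) {
    abort_validation(sprintf("Food listed as its own ingredient at row(s): %s",
                             paste(utils::head(self, 5), collapse = ", ")))
  }
  # raises gwpstar_cycle_error with the cycle path if the relation is cyclic
  topo_order(data.frame(from = recipes$parent_food_code,
                        to = recipes$ingredient_food_code),
             what = "recipe")
  recipes
}

# -- match specification ------------------------------------------------------

MATCH_METHODS <- c("direct", "approximate", "recipe_file", "description_recipe",
                   "label_recipe", "nut_recipe", "similar_food", "online_recipe",
                   "group_average", "processing_factor", "excluded")

#' Read a match specification file
#'
#' The match specification externalizes the curated, expert matching judgment:
#' one row per food, naming the assignment method and its target. It is data,
#' not an algorithm — the pipeline validates and executes it. The `target`
#' column is method-dependent:
#'
#' * `direct` / `approximate`: a reference `item_name`.
#' * `recipe_file`: empty (ingredients come from the recipe table).
#' * `description_recipe`, `label_recipe`, `nut_recipe`, `online_recipe`: an
#'   inline ingredient list `"name=grams; name=grams; ..."`, where a name that
#'   is an all-digit food code refers to another database food and anything
#'   else refers to a reference item.
#' * `similar_food`: another food code whose resolved value is copied.
#' * `group_average`: empty (the food's own classification codes are used) or
#'   an explicit group code.
#' * `processing_factor`: `"fresh item name | category"` with category
#'   `fruit` or `vegetable`.
#' * `excluded`: empty.
#'
#' @param path path to a CSV file with columns `food_code`, `method`,
#'   `target`, and optionally `note`.
#' @return a tibble with one validated row per food.
#' @export
read_match_spec <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(c("food_code", "method"), names(df))
  if (length(missing)) {
    abort_validation(sprintf("Match spec file is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  if (!"target" %in% names(df)) df$target <- NA_character_
  if (!"note" %in% names(df)) df$note <- NA_character_
  validate_match_spec(df)
}

#' @rdname read_match_spec
#' @param match_spec data frame of match specification rows.
#' @export
validate_match_spec <- function(match_spec) {
  match_spec <- tibble::as_tibble(match_spec)
  match_spec$food_code <- as.character(match_spec$food_code)
  bad <- setdiff(unique(match_spec$method), MATCH_METHODS)
  if (length(bad)) {
    abort_validation(sprintf("Unknown match method(s): %s",
                             paste(sQuote(bad), collapse = ", ")))
  }
  dup <- unique(match_spec$food_code[duplicated(match_spec$food_code)])
  if (length(dup)) {
    abort_validation(sprintf("More than one match spec entry for food_code(s): %s",
                             paste(utils::head(dup, 5), collapse = ", ")))
  }
  needs_target <- c("direct", "approximate", "description_recipe", "label_recipe",
                    "nut_recipe", "similar_food", "online_recipe", "processing_factor")
  blank <- is.na(match_spec$target) | !nzchar(trimws(match_spec$target))
  bad <- which(match_spec$method %in% needs_target & blank)
  if (length(bad)) {
    abort_validation(sprintf("Missing target for method %s (food_code %s)",
                             sQuote(match_spec$method[bad[1]]),
                             match_spec$food_code[bad[1]]))
  }
  inline <- match_spec$method %in% INLINE_RECIPE_METHODS & !blank
  for (i in which(inline)) {
    parse_inline_ingredients(match_spec$target[[i]], match_spec$food_code[[i]])
  }
  if (!"note" %in% names(match_spec)) match_spec$note <- NA_character_
  match_spec[c("food_code", "method", "target", "note")]
}

INLINE_RECIPE_METHODS <- c("description_recipe", "label_recipe", "nut_recipe",
                           "online_recipe")

# "Peanuts=88; Vegetable oil=6; Sugar=4; Salt=2" -> tibble(ingredient_id, weight_g)
parse_inline_ingredients <- function(target, food_code = "?") {
  parts <- strsplit(target, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts) || !all(grepl("=", parts, fixed = TRUE))) {
    abort_validation(sprintf(
      "Invalid inline ingredient list for food %s: expected 'name=grams; ...', got %s",
      food_code, sQuote(target)))
  }
  nm <- trimws(sub("=[^=]*$", "", parts))
  wt <- suppressWarnings(as.numeric(sub("^.*=", "", parts)))
  if (any(is.na(wt)) || any(wt <= 0) || any(!nzchar(nm))) {
    abort_validation(sprintf(
      "Inline ingredient weights must be positive numbers (food %s): %s",
      food_code, sQuote(target)))
  }
  tibble::tibble(ingredient_id = nm, weight_g = wt)
}

# "Pear fresh | fruit" -> list(fresh_item, category)
parse_processing_target <- function(target, food_code = "?") {
  parts <- trimws(strsplit(target, "|", fixed = TRUE)[[1]])
  if (length(parts) != 2L || !parts[2] %in% c("fruit", "vegetable")) {
    abort_validation(sprintf(
      "Invalid processing_factor target for food %s: expected 'fresh item | fruit-or-vegetable', got %s",
      food_code, sQuote(target)))
  }
  list(fresh_item = parts[1], category = parts[2])
}

#' Read intake records
#'
#' @param path path to a CSV file with columns `food_code`, `amount_g`, and
#'   optional identifier columns (e.g. `subject`, `day`).
#' @return a tibble of intake records with non-negative amounts.
#' @export
read_intakes <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    food_code = readr::col_character(),
    amount_g = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_intakes(df)
}

#' @rdname read_intakes
#' @param intakes data frame of intake records.
#' @export
validate_intakes <- function(intakes) {
  intakes <- tibble::as_tibble(intakes)
  intakes$food_code <- as.character(intakes$food_code)
  intakes$amount_g <- as.numeric(intakes$amount_g)
  bad <- which(is.na(intakes$amount_g) | intakes$amount_g < 0)
  if (length(bad)) {
    abort_validation(sprintf("Negative or missing amount_g at intake row(s): %s",
                             paste(utils::head(bad, 5), collapse = ", ")))
  }
  intakes
}

#' Read ingredient nutrient profiles
#'
#' Long-format per-100 g nutrient profiles used by the recipe consistency
#' check: one row per (id, nutrient) pair, where `id` is a reference item
#' name or a food code.
#'
#' @param path path to a CSV file with columns `id`, `nutrient`,
#'   `per_100g`.
#' @return a tibble of nutrient profile rows.
#' @export
read_nutrient_profiles <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    nutrient = readr::col_character(),
    per_100g = readr::col_double()
  ), progress = FALSE)
}

# -- output database ----------------------------------------------------------

#' Write a built GWP* database to CSV
#'
#' Exports one row per food with the assigned value rounded half-up to
#' `digits` decimals (full precision is kept internally; rounding happens only
#' at export, so recursive recipe arithmetic never compounds rounding error).
#' Excluded foods are emitted with an empty value field and stage
#' `"excluded"`, so the output always covers the complete food list.
#'
#' @param resolved a `gwp_build` object from [build_gwp_database()], or its
#'   [tidy()] tibble of resolved foods.
#' @param foods the food details table the database was built from.
#' @param path output CSV path.
#' @param digits export decimal places (default 2).
#' @return the exported tibble, invisibly.
#' @export
write_gwp_database <- function(resolved, foods, path, digits = 2) {
  if (inherits(resolved, "gwp_build")) resolved <- resolved$resolved
  missing_foods <- setdiff(foods$food_code, resolved$food_code)
  if (length(missing_foods)) {
    abort_validation(sprintf(
      "Pipeline incomplete: food(s) neither resolved nor excluded: %s",
      paste(utils::head(missing_foods, 5), collapse = ", ")))
  }
  unresolved <- resolved$stage != "excluded" & is.na(resolved$value)
  if (any(unresolved)) {
    abort_validation(sprintf(
      "Food(s) without a value but not marked excluded: %s",
      paste(utils::head(resolved$food_code[unresolved], 5), collapse = ", ")))
  }
  out <- dplyr::left_join(resolved, foods[c("food_code", "name")], by = "food_code")
  out <- tibble::tibble(
    food_code = out$food_code,
    name = out$name,
    gwp_star_kg_co2e_per_kg = format_export(out$value, digits),
    stage = out$stage,
    step = out$step,
    coverage = ifelse(is.na(out$coverage), "", sprintf("%.6f", out$coverage)),
    provenance = out$provenance_summary %||% summarize_provenance(out$provenance)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}

#' Read back an exported GWP* database
#'
#' @param path CSV path written by [write_gwp_database()].
#' @return a tibble with numeric `gwp_star_kg_co2e_per_kg` (NA for excluded
#'   foods) and `coverage`.
#' @export
read_gwp_database <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    food_code = readr::col_character(),
    name = readr::col_character(),
    gwp_star_kg_co2e_per_kg = readr::col_double(),
    stage = readr::col_character(),
    step = readr::col_character(),
    coverage = readr::col_double(),
    provenance = readr::col_character()
  ), progress = FALSE)
  df
}

summarize_provenance <- function(provenance) {
  if (is.null(provenance)) return(NA_character_)
  vapply(provenance, function(p) {
    if (is.null(p) || !nrow(p)) return(NA_character_)
    paste(sprintf("%s (%.4g)", p$id, p$contribution), collapse = "; ")
  }, character(1))
}
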
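#' Configuration for database construction
#'
#' @param excluded_ingredient_policy how recipe ingredients without a value
#'   are handled: `"renormalize"` (drop from numerator and denominator;
#'   default) or `"zero"` (contribute 0, weight retained in denominator).
#' @param sd_mode `"sample"` (n - 1 denominator; default) or `"population"`
#'   for group standard deviations.
#' @param digits export decimal places (default 2).
#' @param nutrient_tolerance relative deviation flag threshold for the
#'   nutrient consistency check (default 0.2).
#' @param prefix_lengths classification prefix lengths (see
#'   [read_food_details()]).
#' @param group_fallback whether group averaging may fall back from the minor
#'   to the sub-major and major level when a group has no mapped reference
#'   items (default TRUE; fallbacks are logged in the build report).
#' @return a list of class `gwp_config`.
#' @export
gwp_config <- function(excluded_ingredient_policy = c("renormalize", "zero"),
                       sd_mode = c("sample", "population"),
                       digits = 2,
                       nutrient_tolerance = 0.2,
                       prefix_lengths = c(major = 2L, sub_major = 3L, minor = 5L),
                       group_fallback = TRUE) {
  structure(list(
    excluded_ingredient_policy = match.arg(excluded_ingredient_policy),
    sd_mode = match.arg(sd_mode),
    digits = digits,
    nutrient_tolerance = nutrient_tolerance,
    prefix_lengths = prefix_lengths,
    group_fallback = group_fallback
  ), class = "gwp_config")
}

#' Build a GWP* database for a complete food list
#'
#' Orchestrates the staged assignment of climate-footprint values: validates
#' all inputs, orders foods so that every recipe ingredient and similar-food
#' target is resolved before the foods that depend on it (failing with the
#' cycle path if the dependency graph is cyclic), executes every
#' match-specification entry, and assembles the stage tabulation and build
#' report. Every food ends up either valued (with stage/step provenance and
#' recipe coverage) or excluded with a reason.
#'
#' @param foods food details tibble (see [read_food_details()]).
#' @param recipes recipe tibble (see [read_recipes()]); may be empty.
#' @param reference GWP* reference tibble (see [read_gwp_reference()]).
#' @param match_spec match specification tibble (see [read_match_spec()]).
#' @param processing_pairs optional tibble with columns `category`
#'   (`"fruit"`/`"vegetable"`), `processed_item`, `fresh_item` naming
#'   reference items from which processing conversion factors are computed.
#' @param config a [gwp_config()].
#' @return an object of class `gwp_build` with elements `resolved` (tibble:
#'   one row per food with `value`, `stage`, `step`, `coverage`,
#'   `provenance`, `note`), `tabulation` (see [tabulate_stages()]),
#'   `group_summary` (per-major-group mean and SD), `factors` (processing
#'   factors used), `warnings` (character), `excluded` (tibble of excluded
#'   foods with reasons), and `config`.
#' @export
build_gwp_database <- function(foods, recipes = NULL, reference, match_spec,
                               processing_pairs = NULL, config = gwp_config()) {
  code_length <- if (nrow(foods)) nchar(as.character(foods$food_code[[1]])) else 8L
  foods <- validate_food_details(foods, prefix_lengths = config$prefix_lengths,
                                 code_length = code_length)
  reference <- validate_gwp_reference(reference)
  if (is.null(recipes)) {
    recipes <- tibble::tibble(parent_food_code = character(),
                              ingredient_food_code = character(),
                              ingredient_weight_g = numeric())
  } else {
    recipes <- validate_recipes(recipes)
  }
  match_spec <- validate_match_spec(match_spec)

  missing_spec <- setdiff(foods$food_code, match_spec$food_code)
  if (length(missing_spec)) {
    abort_validation(sprintf("Unspecified food(s): no match spec entry for %s",
                             paste(utils::head(missing_spec, 5), collapse = ", ")),
                     class = "gwpstar_unspecified_food")
  }

  edges <- dependency_edges(match_spec, recipes)
  unknown_dep <- setdiff(edges$to, foods$food_code)
  if (length(unknown_dep)) {
    abort_validation(sprintf(
      "Dependency on unknown food code(s): %s",
      paste(utils::head(unknown_dep, 5), collapse = ", ")))
  }
  order <- topo_order(edges, nodes = foods$food_code, what = "recipe/similar-food")
  order <- order[order %in% foods$food_code]

  group_items <- derive_group_item_map(foods, match_spec)
  factors <- compute_category_factors(processing_pairs, reference)

  resolved_values <- new.env(parent = emptyenv())
  context <- list(reference = reference, recipes = recipes,
                  recipes_by_parent = split(recipes, recipes$parent_food_code),
                  foods = foods,
                  group_items = group_items, factors = factors, config = config,
                  resolved = resolved_values)
  rows <- vector("list", length(order))
  for (i in seq_along(order)) {
    code <- order[[i]]
    res <- resolve_food(code, match_spec, context)
    rows[[i]] <- res
    assign(code, res$value[[1]], envir = resolved_values)
  }
  resolved <- dplyr::bind_rows(rows)
  # deterministic presentation order: the food details order
  resolved <- resolved[match(foods$food_code, resolved$food_code), ]
  resolved$provenance_summary <- summarize_provenance(resolved$provenance)

  warnings <- character()
  partial <- resolved$food_code[!is.na(resolved$coverage) & resolved$coverage < 1]
  if (length(partial)) {
    warnings <- c(warnings, sprintf(
      "%d food(s) valued with recipe coverage < 1: %s", length(partial),
      paste(utils::head(partial, 10), collapse = ", ")))
  }
  fell_back <- resolved$step == "group-average" &
    !is.na(resolved$note) & !startsWith(
      sub("^group ", "", resolved$note),
      ifelse(is.na(foods$minor_code), "", foods$minor_code))
  if (any(fell_back, na.rm = TRUE)) {
    warnings <- c(warnings, sprintf(
      "%d group-average food(s) used a fallback classification level",
      sum(fell_back, na.rm = TRUE)))
  }

  excluded <- resolved[resolved$stage == "excluded",
                       c("food_code", "note")]
  excluded <- dplyr::left_join(excluded, foods[c("food_code", "name")],
                               by = "food_code")

  build <- structure(list(
    resolved = resolved,
    tabulation = tabulate_stages(resolved),
    group_summary = NULL,
    factors = factors,
    warnings = warnings,
    excluded = excluded,
    config = config,
    foods = foods
  ), class = "gwp_build")
  build$group_summary <- summarize_by_group(build, level = "major")
  build
}

# Edges food -> foods it depends on (recipe ingredients, inline food-code
# ingredients, similar-food targets).
dependency_edges <- function(match_spec, recipes) {
  spec_methods <- stats::setNames(match_spec$method, match_spec$food_code)
  recipe_parents <- match_spec$food_code[match_spec$method == "recipe_file"]
  e1 <- recipes[recipes$parent_food_code %in% recipe_parents, ]
  edges <- data.frame(from = e1$parent_food_code, to = e1$ingredient_food_code,
                      stringsAsFactors = FALSE)

  inline <- match_spec[match_spec$method %in% INLINE_RECIPE_METHODS, ]
  if (nrow(inline)) {
    for (i in seq_len(nrow(inline))) {
      ing <- parse_inline_ingredients(inline$target[[i]], inline$food_code[[i]])
      codes <- ing$ingredient_id[grepl("^[0-9]+$", ing$ingredient_id)]
      if (length(codes)) {
        edges <- rbind(edges, data.frame(from = inline$food_code[[i]], to = codes))
      }
    }
  }
  similar <- match_spec[match_spec$method == "similar_food", ]
  if (nrow(similar)) {
    edges <- rbind(edges, data.frame(from = similar$food_code, to = similar$target))
  }
  edges
}

#' Summarize GWP* values by food group
#'
#' Unweighted mean and standard deviation of the food-level values per
#' classification group, excluded foods omitted. Groups in which no food
#' could be matched are still reported, with `n = 0` and empty statistics.
#' The SD of a single-food group is undefined (reported as NA) under the
#' default sample (n - 1) convention.
#'
#' @param build a `gwp_build` object, or a resolved tibble (then `foods` is
#'   required).
#' @param foods food details tibble (ignored when `build` is a `gwp_build`).
#' @param level classification level: `"major"`, `"sub_major"` or `"minor"`.
#' @param sd_mode `"sample"` or `"population"`; defaults to the build config.
#' @return a tibble with columns `group_code`, `n`, `mean`, `sd`.
#' @export
summarize_by_group <- function(build, foods = NULL,
                               level = c("major", "sub_major", "minor"),
                               sd_mode = NULL) {
  level <- match.arg(level)
  if (inherits(build, "gwp_build")) {
    resolved <- build$resolved
    foods <- build$foods
    sd_mode <- sd_mode %||% build$config$sd_mode
  } else {
    resolved <- build
    if (is.null(foods)) abort_validation("summarize_by_group needs `foods`")
    sd_mode <- sd_mode %||% "sample"
  }
  col <- paste0(level, "_code")
  sd_fun <- if (sd_mode == "population") {
    function(x) if (length(x) < 1) NA_real_ else sqrt(mean((x - mean(x))^2))
  } else {
    function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
  }
  df <- dplyr::left_join(resolved[c("food_code", "value", "stage")],
                         foods[c("food_code", col)], by = "food_code")
  df |>
    dplyr::group_by(group_code = .data[[col]]) |>
    dplyr::summarise(
      n = sum(.data$stage != "excluded"),
      mean = if (any(.data$stage != "excluded"))
        mean(.data$value[.data$stage != "excluded"]) else NA_real_,
      sd = sd_fun(.data$value[.data$stage != "excluded"]),
      .groups = "drop") |>
    dplyr::arrange(.data$group_code)
}

#' @export
print.gwp_build <- function(x, ...) {
  tot <- x$tabulation[x$tabulation$row_type == "total", ]
  mat <- x$tabulation[x$tabulation$row_type == "matched", ]
  cat(sprintf("<gwp_build> %d foods: %d matched (%.2f%%), %d excluded\n",
              tot$n, mat$n, mat$pct, tot$n - mat$n))
  stages <- x$tabulation[x$tabulation$row_type == "stage", ]
  for (i in seq_len(nrow(stages))) {
    cat(sprintf("  stage %-8s %5d (%.2f%%)\n", stages$stage[i], stages$n[i],
                stages$pct[i]))
  }
  if (length(x$factors)) {
    cat(sprintf("  processing factors: %s\n",
                paste(sprintf("%s=%.4g", names(x$factors), unlist(x$factors)),
                      collapse = ", ")))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Turn a built database into a per-food tibble
#'
#' @param x a `gwp_build` object.
#' @param ... unused.
#' @return the resolved tibble: one row per food with `value`, `stage`,
#'   `step`, `coverage` and a provenance summary.
#' @export
tidy.gwp_build <- function(x, ...) {
  dplyr::left_join(x$resolved[c("food_code", "value", "stage", "step",
                                "coverage", "provenance_summary", "note")],
                   x$foods[c("food_code", "name", "major_code")],
                   by = "food_code")
}

#' One-row summary of a built database
#'
#' @param x a `gwp_build` object.
#' @param ... unused.
#' @return a one-row tibble: food counts, matched percentage, per-stage
#'   counts, number of partial-coverage foods.
#' @export
glance.gwp_build <- function(x, ...) {
  tab <- x$tabulation
  g <- function(type, stage = NULL) {
    rows <- tab[tab$row_type == type & (is.null(stage) | tab$stage %in% stage), ]
    sum(rows$n)
  }
  tibble::tibble(
    n_foods = g("total"),
    n_matched = g("matched"),
    pct_matched = tab$pct[tab$row_type == "matched"],
    n_stage1 = g("stage", "1"),
    n_stage2 = g("stage", "2"),
    n_stage3 = g("stage", "3"),
    n_excluded = g("stage", "excluded"),
    n_partial_coverage = sum(!is.na(x$resolved$coverage) & x$resolved$coverage < 1)
  )
}

#' Plot the stage/step accounting of a built database
#'
#' @param object a `gwp_build` object.
#' @param ... unused.
#' @return a ggplot: foods per step, filled by stage.
#' @export
autoplot.gwp_build <- function(object, ...) {
  steps <- object$tabulation[object$tabulation$row_type == "step", ]
  steps$step <- factor(steps$step, levels = rev(STAGE_STEP$step))
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$n, y = .data$step,
                                      fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "foods", y = NULL, fill = "stage",
                  title = "Foods matched at each stage and step") +
    ggplot2::theme_minimal()
}

#' Plot group-level GWP* summaries
#'
#' @param build a `gwp_build` object.
#' @param level classification level to summarize at.
#' @return a ggplot of group means with +/- 1 SD ranges.
#' @export
plot_group_summary <- function(build, level = "major") {
  gs <- summarize_by_group(build, level = level)
  gs <- gs[!is.na(gs$mean), ]
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$mean,
                                   y = stats::reorder(.data$group_code, .data$mean))) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$mean - dplyr::coalesce(.data$sd, 0),
      xmax = .data$mean + dplyr::coalesce(.data$sd, 0))) +
    ggplot2::labs(x = "GWP* (kg CO2e/kg), mean ± SD", y = "food group") +
    ggplot2::theme_minimal()
}
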
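#' Average the reference values mapped to a food group
#'
#' Stage-3 approximation for foods with no direct, calculated, or similar-food
#' value: the unweighted arithmetic mean of the *distinct* reference items
#' associated with the food's classification group (e.g. a brazil nut with no
#' reference entry takes the mean of the hazelnut, cashew, walnut, pistachio
#' and almond values mapped to its minor group "other nuts"). Listing the same
#' reference item twice does not change the result.
#'
#' @param group_code a classification group code (any level).
#' @param group_items tibble mapping `group_code` to reference `item_name`,
#'   typically from [derive_group_item_map()].
#' @param reference the GWP* reference tibble.
#' @return the mean value, or `NA` if no reference item maps to the group.
#' @export
group_average <- function(group_code, group_items, reference) {
  items <- unique(group_items$item_name[group_items$group_code == group_code])
  items <- items[items %in% reference$item_name]
  if (!length(items)) return(NA_real_)
  mean(reference$gwp_value[match(items, reference$item_name)])
}

# Fallback chain minor -> sub-major -> major for one food; returns
# list(value, items, group) or NULL when every level is empty.
group_average_for_food <- function(food, group_items, reference,
                                   explicit_group = NULL, fallback = TRUE) {
  candidates <- if (!is.null(explicit_group)) {
    explicit_group
  } else {
    g <- c(food$minor_code, food$sub_major_code, food$major_code)
    if (fallback) g else g[1]
  }
  for (g in candidates) {
    items <- unique(group_items$item_name[group_items$group_code == g])
    items <- items[items %in% reference$item_name]
    if (length(items)) {
      return(list(value = mean(reference$gwp_value[match(items, reference$item_name)]),
                  items = items, group = g))
    }
  }
  NULL
}

#' Map classification groups to the reference items matched within them
#'
#' Group averaging needs to know which published reference items "belong" to
#' each food group. Following the convention that the reference items aligning
#' with a group are those its own foods were matched to in stage 1, this
#' derives the mapping from the direct and approximate entries of the match
#' specification, at all classification levels simultaneously (level codes
#' have distinct lengths, so they never collide).
#'
#' @param foods validated food details tibble.
#' @param match_spec validated match specification tibble.
#' @return a tibble with columns `group_code`, `item_name` (distinct rows).
#' @export
derive_group_item_map <- function(foods, match_spec) {
  stage1 <- match_spec[match_spec$method %in% c("direct", "approximate"), ]
  if (!nrow(stage1)) {
    return(tibble::tibble(group_code = character(), item_name = character()))
  }
  joined <- dplyr::inner_join(stage1[c("food_code", "target")], foods, by = "food_code")
  dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(group_code = joined$minor_code, item_name = joined$target),
    tibble::tibble(group_code = joined$sub_major_code, item_name = joined$target),
    tibble::tibble(group_code = joined$major_code, item_name = joined$target)
  ))
}

#' Compute a fruit or vegetable processing conversion factor
#'
#' Processed produce (canned, dried, juiced) often lacks its own reference
#' value. The conversion factor is estimated from commodities where both forms
#' are published: each pair contributes the ratio processed/fresh, and the
#' factor is the arithmetic mean of those ratios (mean of ratios, not ratio of
#' means). Fruit and vegetable factors are computed separately.
#'
#' @param pairs data frame with numeric columns `processed_value` and
#'   `fresh_value`, one row per commodity pair.
#' @param category `"fruit"` or `"vegetable"`.
#' @return an object of class `processing_factor`: list with `category`,
#'   `pairs` (tibble with a `ratio` column) and `factor` (mean ratio).
#' @examples
#' compute_processing_factor(
#'   data.frame(processed_value = c(2, 9), fresh_value = c(1, 3)), "fruit"
#' )$factor # 2.5, the mean of 2 and 3 — not (2 + 9) / (1 + 3)
#' @export
compute_processing_factor <- function(pairs, category = c("fruit", "vegetable")) {
  category <- match.arg(category)
  pairs <- tibble::as_tibble(pairs)
  if (!nrow(pairs)) abort_validation("Processing factor needs at least one pair")
  zero <- pairs$fresh_value == 0
  if (any(zero)) {
    rlang::warn(sprintf("%d pair(s) with fresh value 0 rejected for %s factor",
                        sum(zero), category))
    pairs <- pairs[!zero, ]
  }
  if (!nrow(pairs)) {
    abort_validation(sprintf("All %s pairs rejected (fresh value 0)", category))
  }
  pairs$ratio <- pairs$processed_value / pairs$fresh_value
  structure(list(category = category, pairs = pairs, factor = mean(pairs$ratio)),
            class = "processing_factor")
}

#' @export
print.processing_factor <- function(x, ...) {
  cat(sprintf("<processing_factor> %s: %.4f (mean of %d ratio(s))\n",
              x$category, x$factor, nrow(x$pairs)))
  invisible(x)
}

#' Apply a processing conversion factor to a fresh value
#'
#' @param fresh_value GWP* value of the fresh counterpart (kg CO2e/kg).
#' @param factor a processing conversion factor (numeric, or a
#'   `processing_factor` object).
#' @return `fresh_value * factor`.
#' @export
apply_processing_factor <- function(fresh_value, factor) {
  if (inherits(factor, "processing_factor")) factor <- factor$factor
  if (is.null(factor) || is.na(factor)) {
    abort_validation("No processing factor available")
  }
  fresh_value * factor
}

# Build the per-category factors used during database construction from a
# (category, processed_item, fresh_item) table resolved against the reference.
compute_category_factors <- function(processing_pairs, reference) {
  if (is.null(processing_pairs) || !nrow(processing_pairs)) {
    return(list())
  }
  lookup <- stats::setNames(reference$gwp_value, reference$item_name)
  out <- list()
  for (cat in unique(processing_pairs$category)) {
    rows <- processing_pairs[processing_pairs$category == cat, ]
    missing <- setdiff(c(rows$processed_item, rows$fresh_item), names(lookup))
    if (length(missing)) {
      abort_validation(sprintf("Processing pair item(s) not in reference: %s",
                               paste(sQuote(missing), collapse = ", ")))
    }
    pf <- compute_processing_factor(
      tibble::tibble(processed_value = unname(lookup[rows$processed_item]),
                     fresh_value = unname(lookup[rows$fresh_item])),
      category = cat)
    out[[cat]] <- pf$factor
  }
  out
}
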
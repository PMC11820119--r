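#' Compute dietary climate footprints from intake records
#'
#' Applies a built GWP* database to intake records: each record contributes
#' `amount_g / 1000 * gwp_value` kg CO2e, and contributions are summed
#' overall, per food, per major food group, and — when identifier columns
#' such as `subject` are present — per identifier group. Intakes of foods
#' that were excluded from the database contribute 0 but are counted and
#' their grams totalled, because ignoring them silently would hide the
#' resulting underestimation of the diet's footprint.
#'
#' @param intakes tibble of intake records (`food_code`, `amount_g`, optional
#'   identifier columns; see [read_intakes()]).
#' @param database a `gwp_build` object, or a tibble with `food_code`,
#'   `value` and `stage` columns (excluded foods have stage `"excluded"`).
#' @param foods optional food details tibble supplying `major_code` for the
#'   group rollup (taken from the `gwp_build` when available).
#' @param by optional character vector of identifier columns to aggregate by
#'   (defaults to any of `subject`, `day` present in `intakes`).
#' @return an object of class `gwp_footprint`: list with `total_kg_co2e`,
#'   `records` (per-record contributions), `by_food`, `by_group`, `by_id`
#'   (NULL when no identifier columns), and `excluded_report` (n records,
#'   total grams of excluded-food intake).
#' @examples
#' db <- tibble::tibble(food_code = "13101234", value = 16.68, stage = "1")
#' intk <- tibble::tibble(food_code = "13101234", amount_g = 250)
#' compute_footprint(intk, db)$total_kg_co2e # 4.17
#' @export
compute_footprint <- function(intakes, database, foods = NULL, by = NULL) {
  intakes <- validate_intakes(intakes)
  if (inherits(database, "gwp_build")) {
    foods <- foods %||% database$foods
    database <- database$resolved
  }
  unknown <- setdiff(unique(intakes$food_code), database$food_code)
  if (length(unknown)) {
    abort_validation(sprintf("Intake food code(s) not in database: %s",
                             paste(utils::head(unknown, 10), collapse = ", ")),
                     class = "gwpstar_unknown_food")
  }
  db <- database[c("food_code", "value", "stage")]
  rec <- dplyr::left_join(intakes, db, by = "food_code")
  rec$excluded <- rec$stage == "excluded"
  rec$kg_co2e <- ifelse(rec$excluded, 0, rec$amount_g / 1000 * rec$value)

  by <- by %||% intersect(c("subject", "day"), names(intakes))

  by_food <- rec |>
    dplyr::group_by(.data$food_code) |>
    dplyr::summarise(amount_g = sum(.data$amount_g),
                     kg_co2e = sum(.data$kg_co2e), .groups = "drop")
  by_group <- NULL
  if (!is.null(foods) && "major_code" %in% names(foods)) {
    by_group <- rec |>
      dplyr::left_join(foods[c("food_code", "major_code")], by = "food_code") |>
      dplyr::group_by(.data$major_code) |>
      dplyr::summarise(amount_g = sum(.data$amount_g),
                       kg_co2e = sum(.data$kg_co2e), .groups = "drop")
  }
  by_id <- NULL
  if (length(by)) {
    by_id <- rec |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(amount_g = sum(.data$amount_g),
                       kg_co2e = sum(.data$kg_co2e), .groups = "drop")
  }

  structure(list(
    total_kg_co2e = sum(rec$kg_co2e),
    records = rec,
    by_food = by_food,
    by_group = by_group,
    by_id = by_id,
    excluded_report = tibble::tibble(
      n_records = sum(rec$excluded),
      total_g = sum(rec$amount_g[rec$excluded]))
  ), class = "gwp_footprint")
}

#' @export
print.gwp_footprint <- function(x, ...) {
  cat(sprintf("<gwp_footprint> total %.4f kg CO2e over %d record(s)\n",
              x$total_kg_co2e, nrow(x$records)))
  if (x$excluded_report$n_records > 0) {
    cat(sprintf("  %d record(s), %.1f g of excluded foods contributed 0 (footprint underestimated)\n",
                x$excluded_report$n_records, x$excluded_report$total_g))
  }
  invisible(x)
}

#' Per-record footprint contributions
#'
#' @param x a `gwp_footprint` object.
#' @param ... unused.
#' @return the per-record tibble with `kg_co2e` contributions.
#' @export
tidy.gwp_footprint <- function(x, ...) x$records

#' One-row footprint summary
#'
#' @param x a `gwp_footprint` object.
#' @param ... unused.
#' @return one-row tibble: total kg CO2e, record count, excluded-intake
#'   count and grams.
#' @export
glance.gwp_footprint <- function(x, ...) {
  tibble::tibble(
    total_kg_co2e = x$total_kg_co2e,
    n_records = nrow(x$records),
    n_excluded_records = x$excluded_report$n_records,
    excluded_g = x$excluded_report$total_g
  )
}

#' Plot per-group footprint contributions
#'
#' @param object a `gwp_footprint` object (built with group information).
#' @param ... unused.
#' @return a ggplot of kg CO2e per major food group.
#' @export
autoplot.gwp_footprint <- function(object, ...) {
  df <- object$by_group %||% object$by_food
  xcol <- names(df)[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kg_co2e,
                                   y = stats::reorder(.data[[xcol]], .data$kg_co2e))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "kg CO2e", y = xcol,
                  title = "Dietary footprint contributions") +
    ggplot2::theme_minimal()
}
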
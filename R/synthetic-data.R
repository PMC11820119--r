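# Default step mix: the observed proportions of foods assigned by each method
# in a national food composition database of this kind (stage 1 ~35%, stage 2
# ~55%, stage 3 ~6%, ~4% excluded).
DEFAULT_STEP_MIX <- c(
  direct = 0.1538, approximate = 0.1984,
  recipe_file = 0.4720, description_recipe = 0.0054, label_recipe = 0.0181,
  nut_recipe = 0.0042, similar_food = 0.0449, online_recipe = 0.0017,
  group_average = 0.0568, processing_factor = 0.0031,
  excluded = 0.0415
)

#' Default assignment-method mix for synthetic bundles
#'
#' @return named numeric proportions over the 11 assignment methods, the
#'   generator's default study conditions.
#' @export
default_step_mix <- function() DEFAULT_STEP_MIX

local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  invisible(seed)
}

# sample() that never falls into the length-1 "sample from 1:n" trap
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Largest-remainder apportionment of n among proportions p (sums exactly to n).
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Generate a complete synthetic input bundle with known ground truth
#'
#' Produces an internally consistent set of pipeline inputs — food details
#' with hierarchical 8-digit codes spanning several major groups, an acyclic
#' multi-level recipe table, a reference table of log-normally distributed
#' footprint values (a configurable fraction negated, emulating
#' declining-methane commodities), processing pairs, nutrient profiles, and a
#' match specification covering every assignment method — together with a
#' `ground_truth` table of every food's expected value, stage and step.
#'
#' Ground-truth values are computed by a deliberately separate, non-recursive
#' flat leaf-expansion oracle (see details in the methods vignette), so a bug
#' in the pipeline's recursive evaluator cannot be mirrored in the truth it is
#' checked against. Composites containing an unmatched (excluded) ingredient
#' are only ever planted as terminal foods — never reused as ingredients — so
#' flat expansion and per-node renormalization provably agree on every food.
#'
#' @param n_foods number of foods (default 200).
#' @param step_mix named proportions over the 11 assignment methods
#'   (must sum to 1 within 1e-3; default: the observed mix of a national
#'   database build).
#' @param recipe_depth maximum recipe nesting depth (default 3, max 5).
#' @param ingredients_range integer range (min, max) of ingredients per
#'   recipe (default c(2, 6)).
#' @param n_reference number of reference items excluding the salt and water
#'   staples (default 60).
#' @param ref_meanlog,ref_sdlog log-normal parameters of reference values
#'   (default 0 and 1: median 1 kg CO2e/kg, long right tail like published
#'   commodity footprints).
#' @param negative_fraction fraction of reference values negated
#'   (default 0.02).
#' @param partial_coverage_rate fraction of terminal recipe-file composites
#'   that include one excluded ingredient (default 0.3; requires excluded
#'   foods in the mix).
#' @param seed integer seed; the bundle is a pure function of its parameters
#'   and seed.
#' @return a list of class `gwp_bundle`: `foods`, `recipes`, `reference`,
#'   `match_spec`, `processing_pairs`, `nutrient_profiles`, `ground_truth`
#'   (tibble: `food_code`, `method`, `value`, `stage`, `step`, `coverage`),
#'   `expected_tabulation` (method counts), `expected_group_summary`, and
#'   `manifest` (parameters + seed).
#' @export
generate_bundle <- function(n_foods = 200,
                            step_mix = DEFAULT_STEP_MIX,
                            recipe_depth = 3,
                            ingredients_range = c(2, 6),
                            n_reference = 60,
                            ref_meanlog = 0, ref_sdlog = 1,
                            negative_fraction = 0.02,
                            partial_coverage_rate = 0.3,
                            seed = 1) {
  if (n_foods < 1) abort_validation("n_foods must be >= 1")
  if (is.null(names(step_mix)) || !setequal(names(step_mix), MATCH_METHODS)) {
    abort_validation("step_mix must be named with exactly the 11 match methods")
  }
  if (abs(sum(step_mix) - 1) > 1e-3) {
    abort_validation(sprintf("step_mix proportions must sum to 1 (got %.4f)",
                             sum(step_mix)))
  }
  if (recipe_depth < 1 || recipe_depth > 5) {
    abort_validation("recipe_depth must be between 1 and 5")
  }
  if (length(ingredients_range) != 2 || ingredients_range[1] < 2 ||
      ingredients_range[2] < ingredients_range[1]) {
    abort_validation("ingredients_range must be c(min >= 2, max >= min)")
  }
  step_mix <- step_mix[MATCH_METHODS]
  counts <- apportion(n_foods, step_mix)
  n_tierA <- counts[["direct"]] + counts[["approximate"]]
  n_dependent <- sum(counts[c("recipe_file", INLINE_RECIPE_METHODS,
                              "similar_food", "group_average",
                              "processing_factor")])
  if (n_dependent > 0 && n_tierA == 0) {
    abort_validation("Infeasible step_mix: dependent methods but no stage-1 foods")
  }
  if (counts[["recipe_file"]] > 0 && n_tierA < ingredients_range[1]) {
    abort_validation(sprintf(
      "Infeasible params: recipes need >= %d stage-1 foods, have %d",
      ingredients_range[1], n_tierA))
  }
  if (counts[["processing_factor"]] > 0 && n_reference < 12) {
    abort_validation("Infeasible params: processing factors need >= 12 reference items")
  }

  local_seed(seed)

  # -- reference table --------------------------------------------------------
  ref_names <- sprintf("Ref item %03d", seq_len(n_reference))
  ref_values <- stats::rlnorm(n_reference, ref_meanlog, ref_sdlog)
  n_neg <- floor(negative_fraction * n_reference)
  if (n_neg > 0) {
    neg <- sample(n_reference, n_neg)
    ref_values[neg] <- -ref_values[neg]
  }
  reference <- tibble::tibble(
    item_name = c(ref_names, "Salt", "Water"),
    gwp_value = c(ref_values, 0.06, 0),
    source_tag = c(rep("synthetic-lca", n_reference), "staple", "staple")
  )

  # processing pairs: 3 per category, fresh values guaranteed non-zero
  nonzero <- reference$item_name[reference$gwp_value != 0]
  processing_pairs <- NULL
  if (length(nonzero) >= 12) {
    picks <- sample(nonzero, 12)
    processing_pairs <- tibble::tibble(
      category = rep(c("fruit", "vegetable"), each = 3),
      processed_item = picks[1:6],
      fresh_item = picks[7:12]
    )
  }
  factors <- if (!is.null(processing_pairs)) {
    ref_lookup <- stats::setNames(reference$gwp_value, reference$item_name)
    vapply(split(processing_pairs, processing_pairs$category), function(rows) {
      mean(ref_lookup[rows$processed_item] / ref_lookup[rows$fresh_item])
    }, numeric(1))
  } else {
    c(fruit = NA_real_, vegetable = NA_real_)
  }

  # -- classification hierarchy and codes ------------------------------------
  n_major <- max(5, min(9, ceiling(n_foods / 40)))
  majors <- sprintf("%02d", sample(10:29, n_major))
  minors <- unlist(lapply(majors, function(mj) {
    subs <- paste0(mj, sample(1:9, sample(2:3, 1)))
    unlist(lapply(subs, function(sm) paste0(sm, sprintf("%02d", sample(0:99, sample(2:3, 1))))))
  }))

  methods <- sample(rep(names(counts), counts))
  suffixes <- sprintf("%03d", sample(0:999, n_foods, replace = n_foods > 1000))
  # assign groups: stage-1 and independent foods anywhere; group-average foods
  # are placed afterwards in groups that contain a stage-1 food
  minor_of <- sample(minors, n_foods, replace = TRUE)
  idx_stage1 <- which(methods %in% c("direct", "approximate"))
  idx_groupavg <- which(methods == "group_average")
  if (length(idx_groupavg)) {
    minor_of[idx_groupavg] <- sample(minor_of[idx_stage1], length(idx_groupavg),
                                     replace = TRUE)
  }
  food_code <- paste0(minor_of, suffixes)
  while (anyDuplicated(food_code)) {
    dup <- which(duplicated(food_code))
    suffixes[dup] <- sprintf("%03d", sample(0:999, length(dup), replace = TRUE))
    food_code <- paste0(minor_of, suffixes)
  }
  foods <- tibble::tibble(
    food_code = food_code,
    name = sprintf("Synthetic food %s (%s)", food_code, methods),
    description = sprintf("Synthetic %s food in minor group %s",
                          gsub("_", " ", methods), minor_of)
  )
  foods <- validate_food_details(foods)

  truth_value <- rep(NA_real_, n_foods)
  truth_coverage <- rep(NA_real_, n_foods)
  target <- rep(NA_character_, n_foods)
  code_of <- foods$food_code

  # -- stage 1: direct / approximate -----------------------------------------
  for (i in idx_stage1) {
    target[i] <- sample(ref_names, 1)
    truth_value[i] <- reference$gwp_value[match(target[i], reference$item_name)]
    truth_coverage[i] <- 1
  }
  idx_excluded <- which(methods == "excluded")

  # -- recipe-file composites -------------------------------------------------
  recipes <- tibble::tibble(parent_food_code = character(),
                            ingredient_food_code = character(),
                            ingredient_weight_g = numeric())
  idx_recipe <- which(methods == "recipe_file")
  depth_of <- stats::setNames(rep(0L, length(idx_stage1)), code_of[idx_stage1])
  reusable <- code_of[idx_stage1]
  recipe_rows <- list()
  for (i in idx_recipe) {
    pool <- reusable[depth_of[reusable] < recipe_depth]
    n_ing <- resample(seq(ingredients_range[1], min(ingredients_range[2], length(pool))))
    ing <- sample(pool, n_ing)
    # bias toward nesting: ensure a composite ingredient when one is eligible
    comp_pool <- setdiff(pool, code_of[idx_stage1])
    if (length(comp_pool) && !any(ing %in% comp_pool) && stats::runif(1) < 0.6) {
      ing[1] <- sample(comp_pool, 1)
      ing <- unique(ing)
    }
    w <- stats::runif(length(ing), 5, 200)
    terminal <- stats::runif(1) < 0.25
    with_excluded <- terminal && length(idx_excluded) &&
      stats::runif(1) < partial_coverage_rate
    if (with_excluded) {
      ing_all <- c(ing, sample(code_of[idx_excluded], 1))
      w_all <- c(w, stats::runif(1, 5, 100))
    } else {
      ing_all <- ing
      w_all <- w
    }
    recipe_rows[[length(recipe_rows) + 1L]] <- tibble::tibble(
      parent_food_code = code_of[i], ingredient_food_code = ing_all,
      ingredient_weight_g = w_all)
    depth_of[code_of[i]] <- 1L + max(depth_of[ing])
    if (!terminal) reusable <- c(reusable, code_of[i])
    truth_coverage[i] <- sum(w) / sum(w_all)
  }
  if (length(recipe_rows)) recipes <- dplyr::bind_rows(recipe_rows)

  # ground truth for composites: flat leaf expansion (non-recursive oracle)
  leaf_values <- stats::setNames(truth_value[idx_stage1], code_of[idx_stage1])
  excluded_codes <- code_of[idx_excluded]
  recipes_by_parent <- split(recipes, recipes$parent_food_code)
  for (i in idx_recipe) {
    truth_value[i] <- flat_leaf_expansion(code_of[i], recipes_by_parent,
                                          leaf_values, excluded_codes)
  }

  # -- inline-recipe methods --------------------------------------------------
  for (i in which(methods %in% INLINE_RECIPE_METHODS)) {
    n_ing <- sample(2:4, 1)
    items <- sample(c(ref_names, "Salt", "Water"), n_ing)
    w <- round(stats::runif(n_ing, 5, 200), 3)
    target[i] <- paste(sprintf("%s=%g", items, w), collapse = "; ")
    vals <- reference$gwp_value[match(items, reference$item_name)]
    truth_value[i] <- sum(w * vals) / sum(w)
    truth_coverage[i] <- 1
  }

  # -- similar food (chains allowed, always backward so never cyclic) --------
  idx_similar <- which(methods == "similar_food")
  for (i in idx_similar) {
    valued <- which(!is.na(truth_value))
    target[i] <- code_of[resample(valued)]
    truth_value[i] <- truth_value[match(target[i], code_of)]
    truth_coverage[i] <- 1
  }

  # -- stage 3 ---------------------------------------------------------------
  for (i in idx_groupavg) {
    peers <- idx_stage1[minor_of[idx_stage1] == minor_of[i]]
    items <- unique(target[peers])
    truth_value[i] <- mean(reference$gwp_value[match(items, reference$item_name)])
    truth_coverage[i] <- 1
  }
  idx_pf <- which(methods == "processing_factor")
  for (k in seq_along(idx_pf)) {
    i <- idx_pf[k]
    cat_k <- c("fruit", "vegetable")[(k %% 2) + 1]
    fresh <- sample(ref_names, 1)
    target[i] <- paste(fresh, cat_k, sep = " | ")
    truth_value[i] <- reference$gwp_value[match(fresh, reference$item_name)] *
      factors[[cat_k]]
    truth_coverage[i] <- 1
  }

  match_spec <- tibble::tibble(food_code = code_of, method = methods,
                               target = target,
                               note = ifelse(methods == "excluded",
                                             "no appropriate match", NA_character_))

  # nutrient profiles for reference items (used by the consistency check)
  nutrients <- c("protein_g", "fat_g", "cho_g")
  nutrient_profiles <- tidyr::expand_grid(id = reference$item_name,
                                          nutrient = nutrients)
  nutrient_profiles$per_100g <- round(stats::runif(nrow(nutrient_profiles), 0, 30), 2)

  stage_of <- stats::setNames(STAGE_STEP$stage, STAGE_STEP$method)
  step_of <- stats::setNames(STAGE_STEP$step, STAGE_STEP$method)
  ground_truth <- tibble::tibble(
    food_code = code_of, method = methods,
    value = truth_value,
    stage = unname(stage_of[methods]),
    step = unname(step_of[methods]),
    coverage = truth_coverage
  )

  expected_group_summary <- ground_truth |>
    dplyr::mutate(major_code = substr(.data$food_code, 1, 2)) |>
    dplyr::group_by(.data$major_code) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$value)) >= 2) stats::sd(.data$value, na.rm = TRUE) else NA_real_,
      .groups = "drop")

  structure(list(
    foods = foods, recipes = recipes, reference = reference,
    match_spec = match_spec, processing_pairs = processing_pairs,
    nutrient_profiles = nutrient_profiles,
    ground_truth = ground_truth,
    expected_tabulation = tibble::tibble(method = names(counts),
                                         n = as.integer(counts)),
    expected_group_summary = expected_group_summary,
    manifest = list(n_foods = n_foods, step_mix = step_mix,
                    recipe_depth = recipe_depth,
                    ingredients_range = ingredients_range,
                    n_reference = n_reference, ref_meanlog = ref_meanlog,
                    ref_sdlog = ref_sdlog, negative_fraction = negative_fraction,
                    partial_coverage_rate = partial_coverage_rate, seed = seed)
  ), class = "gwp_bundle")
}

#' Flat leaf-expansion oracle for a composite food
#'
#' Evaluates a composite food's value by expanding its recipe tree to leaf
#' contributions with an explicit worklist — no recursion, no memoized
#' intermediate values — then summing `fraction * leaf value`. Ingredients in
#' `excluded_codes` are dropped and the parent's weight renormalized at the
#' node where they occur. Serves as the independent arithmetic oracle for the
#' recursive recipe engine.
#'
#' @param code parent food code.
#' @param recipes recipe tibble, or (for repeated calls) the result of
#'   `split(recipes, recipes$parent_food_code)`.
#' @param leaf_values named numeric of values for non-composite foods (and,
#'   when composites are reused as ingredients, their already-expanded
#'   values — pass only true leaves to force full expansion).
#' @param excluded_codes food codes treated as unmatched.
#' @return the expanded value (NA if nothing matches).
#' @export
flat_leaf_expansion <- function(code, recipes, leaf_values,
                                excluded_codes = character()) {
  by_parent <- if (is.data.frame(recipes)) {
    split(recipes, recipes$parent_food_code)
  } else {
    recipes
  }
  total <- 0
  matched_any <- FALSE
  work <- list(list(code = code, frac = 1))
  while (length(work)) {
    item <- work[[length(work)]]
    work[[length(work)]] <- NULL
    rows <- by_parent[[item$code]]
    if (is.null(rows) || !nrow(rows)) {
      v <- if (item$code %in% names(leaf_values)) leaf_values[[item$code]] else NA_real_
      if (!is.na(v)) {
        total <- total + item$frac * v
        matched_any <- TRUE
      }
      next
    }
    keep <- !(rows$ingredient_food_code %in% excluded_codes)
    denom <- sum(rows$ingredient_weight_g[keep])
    if (denom == 0) next
    for (j in which(keep)) {
      work[[length(work) + 1L]] <- list(
        code = rows$ingredient_food_code[[j]],
        frac = item$frac * rows$ingredient_weight_g[[j]] / denom)
    }
  }
  if (!matched_any) NA_real_ else total
}

#' @export
print.gwp_bundle <- function(x, ...) {
  cat(sprintf("<gwp_bundle> %d foods, %d recipe rows, %d reference items (seed %d)\n",
              nrow(x$foods), nrow(x$recipes), nrow(x$reference),
              x$manifest$seed))
  tab <- x$expected_tabulation
  cat("  planted methods:",
      paste(sprintf("%s=%d", tab$method, tab$n), collapse = ", "), "\n")
  invisible(x)
}

#' Write a bundle's tables to CSV files
#'
#' @param bundle a `gwp_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$foods[c("food_code", "name", "description")],
                   file.path(dir, "food_details.csv"), progress = FALSE)
  readr::write_csv(bundle$recipes, file.path(dir, "recipes.csv"), progress = FALSE)
  readr::write_csv(bundle$reference, file.path(dir, "gwp_reference.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$match_spec, file.path(dir, "match_spec.csv"),
                   progress = FALSE)
  if (!is.null(bundle$processing_pairs)) {
    readr::write_csv(bundle$processing_pairs,
                     file.path(dir, "processing_pairs.csv"), progress = FALSE)
  }
  readr::write_csv(bundle$nutrient_profiles,
                   file.path(dir, "nutrient_profiles.csv"), progress = FALSE)
  readr::write_csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Generate synthetic intake records for a bundle
#'
#' Draws intake records over the bundle's foods (including excluded foods,
#' which exercise the zero-contribution path) with gamma-distributed serving
#' amounts, and computes ground-truth footprint totals by direct arithmetic.
#'
#' @param bundle a `gwp_bundle`.
#' @param n_subjects number of subjects (default 10).
#' @param records_per_subject intake records per subject (default 20).
#' @param shape,scale gamma parameters of the serving amount in grams
#'   (default shape 2, scale 75: mean 150 g, right-skewed like real serving
#'   sizes).
#' @param seed integer seed.
#' @return a list with `intakes` (tibble: `subject`, `food_code`,
#'   `amount_g`), `truth_total` (overall kg CO2e) and `truth_by_subject`.
#' @export
generate_intakes <- function(bundle, n_subjects = 10, records_per_subject = 20,
                             shape = 2, scale = 75, seed = 1) {
  local_seed(seed)
  n <- n_subjects * records_per_subject
  intakes <- tibble::tibble(
    subject = rep(sprintf("S%03d", seq_len(n_subjects)), each = records_per_subject),
    food_code = sample(bundle$foods$food_code, n, replace = TRUE),
    amount_g = stats::rgamma(n, shape = shape, scale = scale)
  )
  truth <- bundle$ground_truth
  v <- truth$value[match(intakes$food_code, truth$food_code)]
  contrib <- ifelse(is.na(v), 0, intakes$amount_g / 1000 * v)
  by_subject <- tibble::tibble(subject = intakes$subject, kg_co2e = contrib) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(kg_co2e = sum(.data$kg_co2e), .groups = "drop")
  list(intakes = intakes, truth_total = sum(contrib),
       truth_by_subject = by_subject)
}
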
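test_that("the mini database resolves every pathway to its hand-computed value", {
  build <- mini_build()
  res <- build$resolved
  val <- function(code) res$value[res$food_code == code]

  expect_equal(val("13102001"), 8.34)               # 500/1000 beef + 500/1000 water
  expect_equal(val("10201001"), 15 / 1015 * 7.3)    # description recipe
  expect_equal(val("13104001"), 16.68)              # excluded ingredient renormalized
  expect_equal(res$coverage[res$food_code == "13104001"], 0.9)
  expect_equal(val("13101236"), 16.68)              # minor-group average
  expect_equal(val("16101001"), 0.5 * 2)            # processing factor
  expect_true(is.na(val("19101001")))
  expect_equal(res$stage[res$food_code == "19101001"], "excluded")

  # under the zero policy the partial-coverage composite shrinks
  zb <- mini_build(gwp_config(excluded_ingredient_policy = "zero"))
  expect_equal(zb$resolved$value[zb$resolved$food_code == "13104001"],
               0.9 * 16.68)
})

test_that("every food appears exactly once and excluded foods carry reasons", {
  m <- mini_inputs()
  build <- mini_build()
  expect_setequal(build$resolved$food_code, m$foods$food_code)
  expect_equal(anyDuplicated(build$resolved$food_code), 0L)
  expect_equal(build$excluded$food_code, "19101001")
  expect_true(all(nzchar(build$excluded$note)))

  g <- glance(build)
  expect_equal(g$n_foods, nrow(m$foods))
  expect_equal(g$n_matched + g$n_excluded, g$n_foods)

  td <- tidy(build)
  expect_true(all(c("food_code", "name", "value", "stage", "step") %in% names(td)))
})

test_that("identical inputs produce byte-identical exports", {
  m <- mini_inputs()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_gwp_database(mini_build(), m$foods, p1)
  write_gwp_database(mini_build(), m$foods, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a cyclic recipe aborts the build with the cycle path", {
  m <- mini_inputs()
  recipes <- dplyr::bind_rows(m$recipes, tibble::tibble(
    parent_food_code = "13101234", ingredient_food_code = "13102001",
    ingredient_weight_g = 100))
  err <- expect_error(
    build_gwp_database(m$foods, recipes, m$reference, m$match_spec,
                       m$processing_pairs),
    class = "gwpstar_cycle_error")
  expect_true(all(c("13101234", "13102001") %in% err$cycle))
})

test_that("hand-rolled acyclicity agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    edges <- tibble::tibble(
      parent_food_code = as.character(sample(n, 2 * n, replace = TRUE)),
      ingredient_food_code = as.character(sample(n, 2 * n, replace = TRUE)),
      ingredient_weight_g = 1)
    edges <- edges[edges$parent_food_code != edges$ingredient_food_code, ]
    g <- igraph::graph_from_data_frame(
      edges[c("parent_food_code", "ingredient_food_code")])
    ours <- tryCatch({ validate_recipes(edges); TRUE },
                     gwpstar_cycle_error = function(e) FALSE)
    expect_equal(ours, igraph::is_dag(g))
  }
})

test_that("group summaries compute unweighted means and sample SDs", {
  resolved <- tibble::tibble(
    food_code = c("11101001", "11101002", "11101003", "12101001", "13101001"),
    value = c(1, 2, 3, 5, NA),
    stage = c("1", "1", "1", "1", "excluded"))
  foods <- validate_food_details(tibble::tibble(
    food_code = resolved$food_code, name = "x", description = "y"))
  gs <- summarize_by_group(resolved, foods, level = "major")
  g11 <- gs[gs$group_code == "11", ]
  expect_equal(g11$mean, 2)
  expect_equal(g11$sd, 1)
  g12 <- gs[gs$group_code == "12", ]
  expect_equal(g12$n, 1L)
  expect_equal(g12$mean, 5)
  expect_true(is.na(g12$sd))               # n - 1 = 0: undefined
  g13 <- gs[gs$group_code == "13", ]       # unmatched group still reported
  expect_equal(g13$n, 0L)
  expect_true(is.na(g13$mean))

  pop <- summarize_by_group(resolved, foods, level = "major", sd_mode = "population")
  expect_equal(pop$sd[pop$group_code == "11"], sqrt(2 / 3))
  expect_equal(pop$sd[pop$group_code == "12"], 0)
})

test_that("group summaries match direct computation on planted draws", {
  b <- generate_bundle(n_foods = 300, seed = 5)
  build <- build_gwp_database(b$foods, b$recipes, b$reference, b$match_spec,
                              b$processing_pairs)
  gs <- summarize_by_group(build, level = "major")
  truth <- b$expected_group_summary
  gs <- gs[match(truth$major_code, gs$group_code), ]
  expect_equal(gs$n, truth$n)
  expect_equal(gs$mean, truth$mean, tolerance = 1e-12)
  expect_equal(gs$sd, truth$sd, tolerance = 1e-12)
})
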
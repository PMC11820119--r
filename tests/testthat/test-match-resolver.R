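test_that("the method-to-stage/step mapping is total and fixed", {
  tab <- stage_step_table()
  expect_setequal(tab$method,
                  c("direct", "approximate", "recipe_file", "description_recipe",
                    "label_recipe", "nut_recipe", "similar_food", "online_recipe",
                    "group_average", "processing_factor", "excluded"))
  expect_equal(tab$stage[tab$method == "direct"], "1")
  expect_equal(tab$stage[tab$method == "online_recipe"], "2")
  expect_equal(tab$step[tab$method == "processing_factor"], "processing-factor")
  expect_equal(anyDuplicated(tab$method), 0L)
})

test_that("direct and approximate matches copy the reference value verbatim", {
  build <- mini_build()
  res <- build$resolved
  val <- function(code) res$value[res$food_code == code]

  expect_equal(val("13101234"), 16.68)                 # direct
  expect_equal(res$stage[res$food_code == "13101234"], "1")
  expect_equal(res$step[res$food_code == "13101234"], "direct")
  expect_equal(val("13101235"), 16.68)                 # approximate, same item
  expect_equal(res$step[res$food_code == "13101235"], "approximate")
  expect_equal(val("14101001"), 0.06)
  expect_equal(val("11101001"), 0)
})

test_that("similar foods copy the resolved value of their target", {
  build <- mini_build()
  res <- build$resolved
  casserole <- res$value[res$food_code == "13102001"]
  expect_equal(casserole, 0.5 * 16.68)
  expect_equal(res$value[res$food_code == "13103001"], casserole)
  expect_equal(res$step[res$food_code == "13103001"], "similar-food")
})

test_that("missing spec entries and unknown reference items are named errors", {
  m <- mini_inputs()
  expect_error(
    build_gwp_database(m$foods, m$recipes, m$reference, m$match_spec[-1, ],
                       m$processing_pairs),
    class = "gwpstar_unspecified_food")

  spec <- m$match_spec
  spec$target[spec$food_code == "13101234"] <- "Dragon meat"
  err <- expect_error(
    build_gwp_database(m$foods, m$recipes, m$reference, spec, m$processing_pairs),
    class = "gwpstar_unknown_reference_item")
  expect_match(conditionMessage(err), "Dragon meat")
})

test_that("stage tabulation partitions the food list", {
  one <- tibble::tibble(stage = "1", step = "direct")
  tab1 <- tabulate_stages(one)
  expect_equal(tab1$n[tab1$row_type == "step" & tab1$step == "direct"], 1L)
  expect_equal(tab1$pct[tab1$row_type == "matched"], 100)

  for (seed in c(3, 11)) {
    b <- generate_bundle(n_foods = 150, seed = seed)
    build <- build_gwp_database(b$foods, b$recipes, b$reference, b$match_spec,
                                b$processing_pairs)
    tab <- build$tabulation
    total <- tab$n[tab$row_type == "total"]
    expect_equal(sum(tab$n[tab$row_type == "stage"]), total)
    expect_equal(sum(tab$n[tab$row_type == "step"]), total)
    expect_equal(tab$n[tab$row_type == "matched"],
                 total - tab$n[tab$row_type == "stage" & tab$stage == "excluded"])
    # counts equal the generator's planted method mix
    planted <- stats::setNames(b$expected_tabulation$n, b$expected_tabulation$method)
    ss <- stage_step_table()
    for (mtd in names(planted)) {
      expect_equal(tab$n[tab$row_type == "step" & tab$step == ss$step[ss$method == mtd]],
                   unname(planted[[mtd]]))
    }
  }
})

test_that("resolution is idempotent and independent of food order", {
  m <- mini_inputs()
  b1 <- build_gwp_database(m$foods, m$recipes, m$reference, m$match_spec,
                           m$processing_pairs)
  b2 <- build_gwp_database(m$foods, m$recipes, m$reference, m$match_spec,
                           m$processing_pairs)
  expect_identical(b1$resolved$value, b2$resolved$value)

  set.seed(99)
  perm <- sample(nrow(m$foods))
  b3 <- build_gwp_database(m$foods[perm, ], m$recipes, m$reference,
                           m$match_spec[sample(nrow(m$match_spec)), ],
                           m$processing_pairs)
  re <- b3$resolved[match(b1$resolved$food_code, b3$resolved$food_code), ]
  expect_equal(re$value, b1$resolved$value)
  expect_equal(re$step, b1$resolved$step)
})

test_that("similar-food cycles abort with the cycle path", {
  m <- mini_inputs()
  spec <- m$match_spec
  spec$method[spec$food_code == "13102001"] <- "similar_food"
  spec$target[spec$food_code == "13102001"] <- "13103001" # 13103001 -> 13102001
  err <- expect_error(
    build_gwp_database(m$foods, m$recipes, m$reference, spec, m$processing_pairs),
    class = "gwpstar_cycle_error")
  expect_setequal(err$cycle, c("13102001", "13103001"))
})
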
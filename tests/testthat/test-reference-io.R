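test_that("food details parsing derives classification codes from prefixes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_code,name,description",
               '13101234,"Beef, mince, <5% fat, raw",raw mince'), path)
  foods <- read_food_details(path)
  expect_equal(foods$major_code, "13")
  expect_equal(foods$sub_major_code, "131")
  expect_equal(foods$minor_code, "13101")

  writeLines("food_code,name,description", path)
  expect_equal(nrow(read_food_details(path)), 0)
})

test_that("malformed and duplicate food codes are rejected by row", {
  bad <- tibble::tibble(food_code = "1310123", name = "x", description = "y")
  expect_error(validate_food_details(bad), class = "gwpstar_validation_error")
  expect_error(validate_food_details(bad), "8 digits")

  nondigit <- tibble::tibble(food_code = "1310123A", name = "x", description = "y")
  expect_error(validate_food_details(nondigit), class = "gwpstar_validation_error")

  dup <- tibble::tibble(food_code = c("13101234", "13101234"),
                        name = "x", description = "y")
  expect_error(validate_food_details(dup), "Duplicate food_code")
})

test_that("reference table accepts zero and negative values, rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    item_name = c("Beef meat", "Water", "Lamb", "Salt"),
    gwp_value = c(16.68, 0, -0.5, 0.06),
    source_tag = "t"), path)
  ref <- read_gwp_reference(path)
  expect_equal(ref$gwp_value[ref$item_name == "Beef meat"], 16.68)
  expect_equal(ref$gwp_value[ref$item_name == "Water"], 0)
  expect_equal(ref$gwp_value[ref$item_name == "Lamb"], -0.5)

  expect_error(validate_gwp_reference(
    tibble::tibble(item_name = c("A", "A"), gwp_value = c(1, 2))),
    "Duplicate reference item_name")
  expect_error(validate_gwp_reference(
    tibble::tibble(item_name = "A", gwp_value = "not-a-number")),
    "Non-numeric")
})

test_that("recipe validation enforces positive weights and acyclicity", {
  ok <- tibble::tibble(parent_food_code = "13102001",
                       ingredient_food_code = "13101234",
                       ingredient_weight_g = 500)
  expect_silent(validate_recipes(ok))
  expect_error(validate_recipes(dplyr::mutate(ok, ingredient_weight_g = 0)),
               "Non-positive")
  expect_error(validate_recipes(dplyr::mutate(ok, ingredient_food_code = "13102001")),
               "own ingredient")
  cyc <- tibble::tibble(
    parent_food_code = c("A", "B", "C"),
    ingredient_food_code = c("B", "C", "A"),
    ingredient_weight_g = 1)
  err <- expect_error(validate_recipes(cyc), class = "gwpstar_cycle_error")
  expect_true(all(c("A", "B", "C") %in% err$cycle))
})

test_that("half-up rounding follows the export contract", {
  expect_equal(round_half_up(0.185), 0.19)
  expect_equal(round_half_up(16.684999), 16.68)
  expect_equal(round_half_up(-0.185), -0.19)
  expect_equal(round_half_up(2.675), 2.68) # binary representation guard
  expect_equal(round_half_up(1.005), 1.01)
})

test_that("export writes two-decimal values, empty fields for excluded foods, and round-trips", {
  build <- mini_build()
  m <- mini_inputs()
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_gwp_database(build, m$foods, path)

  # every food exactly once
  expect_setequal(out$food_code, m$foods$food_code)
  expect_equal(anyDuplicated(out$food_code), 0L)

  # excluded food has an empty value field in the raw file
  lines <- readLines(path)
  excl_line <- grep("19101001", lines, value = TRUE)
  expect_match(excl_line, "^19101001,(\"[^\"]*\"|[^,]*),,excluded", perl = TRUE)

  back <- read_gwp_database(path)
  internal <- build$resolved$value[match(back$food_code, build$resolved$food_code)]
  ok <- !is.na(internal)
  expect_true(all(abs(back$gwp_star_kg_co2e_per_kg[ok] - internal[ok]) <= 0.005))
  expect_equal(back$gwp_star_kg_co2e_per_kg[ok],
               round_half_up(internal[ok], 2))

  # writing what was read back reproduces the value column bit-exactly
  path2 <- withr::local_tempfile(fileext = ".csv")
  resolved2 <- build$resolved
  resolved2$value <- back$gwp_star_kg_co2e_per_kg[match(resolved2$food_code, back$food_code)]
  write_gwp_database(resolved2, m$foods, path2)
  v1 <- readr::read_csv(path, col_types = readr::cols(.default = "c"))$gwp_star_kg_co2e_per_kg
  v2 <- readr::read_csv(path2, col_types = readr::cols(.default = "c"))$gwp_star_kg_co2e_per_kg
  expect_identical(v1, v2)
})

test_that("export refuses an incomplete pipeline", {
  build <- mini_build()
  m <- mini_inputs()
  extra <- dplyr::bind_rows(m$foods, tibble::tibble(
    food_code = "99999999", name = "orphan", description = "z"))
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_gwp_database(build, extra, path), "neither resolved nor excluded")
})

test_that("match spec validation enforces one entry per food and target shapes", {
  expect_error(validate_match_spec(tibble::tibble(
    food_code = c("13101234", "13101234"), method = "direct",
    target = "Beef meat")), "More than one")
  expect_error(validate_match_spec(tibble::tibble(
    food_code = "13101234", method = "teleport", target = "x")),
    "Unknown match method")
  expect_error(validate_match_spec(tibble::tibble(
    food_code = "13101234", method = "direct", target = NA_character_)),
    "Missing target")
  expect_error(validate_match_spec(tibble::tibble(
    food_code = "13101234", method = "label_recipe", target = "Peanuts=-5")),
    "positive")
})
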
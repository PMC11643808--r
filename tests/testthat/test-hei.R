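test_that("component scores follow the published band table", {
  expect_equal(hei_component_score("veg_fruit", 5), 2)
  expect_equal(hei_component_score("veg_fruit", 0), 0)
  expect_equal(hei_component_score("veg_fruit", 1), 0.5)
  expect_equal(hei_component_score("veg_fruit", 3), 1)
  expect_equal(hei_component_score("whole_grains", 1), 0.5)
  expect_equal(hei_component_score("whole_grains", 3), 1)
  expect_equal(hei_component_score("oily_fish", 1), 1)
  expect_equal(hei_component_score("oily_fish", 0.5), 0.5)
  expect_equal(hei_component_score("oily_fish", 0), 0)
  expect_equal(hei_component_score("lean_meat", 2), 0.5)
  expect_equal(hei_component_score("nonmeat_protein", 0.9), 0)
  expect_equal(hei_component_score("sugared_bev", 0), 1)
  expect_equal(hei_component_score("sugared_bev", 4), 0)
  expect_equal(hei_component_score("high_fat_meat", 0), 1)
  expect_equal(hei_component_score("fast_food", 0.5), 0.5)
  expect_equal(hei_component_score("fast_food", 1), 0)
  # fermented dairy is non-linear: both tails score 0, the shoulders 0.5
  expect_equal(hei_component_score("fermented_dairy", 5), 0)
  expect_equal(hei_component_score("fermented_dairy", 0.5), 0)
  expect_equal(hei_component_score("fermented_dairy", 1.5), 0.5)
  expect_equal(hei_component_score("fermented_dairy", 4.5), 0.5)
  expect_equal(hei_component_score("fermented_dairy", 3), 1)
})

test_that("alcohol scoring combines frequency, quantity and sex", {
  # nondrinker is a minimal band
  expect_equal(hei_component_score("alcohol", sex = "female", days = 0,
                                   drinks = 0), 0)
  # frequent moderate drinking is maximal
  expect_equal(hei_component_score("alcohol", sex = "female", days = 3,
                                   drinks = 1), 1)
  expect_equal(hei_component_score("alcohol", sex = "male", days = 5,
                                   drinks = 2), 1)
  # infrequent moderate drinking is intermediate
  expect_equal(hei_component_score("alcohol", sex = "male", days = 2,
                                   drinks = 2), 0.5)
  # over the sex-specific quantity limit scores 0 regardless of frequency
  expect_equal(hei_component_score("alcohol", sex = "female", days = 4,
                                   drinks = 2), 0)
  expect_equal(hei_component_score("alcohol", sex = "male", days = 4,
                                   drinks = 3), 0)
  # the limits themselves are within bounds (men 2, women 1, inclusive)
  expect_equal(hei_component_score("alcohol", sex = "male", days = 3,
                                   drinks = 2), 1)
  expect_equal(hei_component_score("alcohol", sex = "female", days = 3,
                                   drinks = 1.5), 0)
})

test_that("extreme diet profiles span the full 0-11 range", {
  expect_equal(score_hei(max_diet_row())$total, 11)
  expect_equal(score_hei(min_diet_row())$total, 0)
})

test_that("a hand-summed intermediate profile totals correctly", {
  # every component at its intermediate band except vegetables/fruits at
  # the 3-4 band: nine components x 0.5 + 1 = 5.5
  d <- data.frame(
    sex = "male", veg_fruit_per_day = 3, whole_grains_per_day = 1,
    oily_fish_per_week = 0.5, lean_meat_per_week = 1,
    nonmeat_protein_per_week = 2, sugared_bev_per_day = 2,
    high_fat_meat_per_week = 2, fast_food_per_week = 0.5,
    fermented_dairy_per_day = 1, alcohol_days_per_week = 2,
    alcohol_drinks_per_day = 1)
  expect_equal(score_hei(d)$total, 5.5)
})

test_that("score is monotone in each component, others held fixed", {
  direct <- list(veg_fruit_per_day = seq(0, 8, 0.5),
                 whole_grains_per_day = seq(0, 5, 0.5),
                 oily_fish_per_week = seq(0, 3, 0.25),
                 lean_meat_per_week = seq(0, 5, 0.5),
                 nonmeat_protein_per_week = seq(0, 5, 0.5))
  for (field in names(direct)) {
    totals <- vapply(direct[[field]], function(v) {
      args <- stats::setNames(list(v), field)
      do.call(max_diet_row, args) |> score_hei() |> (\(s) s$total)()
    }, numeric(1))
    expect_true(all(diff(totals) >= 0), info = field)
  }
  inverse <- list(sugared_bev_per_day = seq(0, 6, 0.5),
                  high_fat_meat_per_week = seq(0, 5, 0.5),
                  fast_food_per_week = seq(0, 3, 0.25))
  for (field in names(inverse)) {
    totals <- vapply(inverse[[field]], function(v) {
      args <- stats::setNames(list(v), field)
      do.call(max_diet_row, args) |> score_hei() |> (\(s) s$total)()
    }, numeric(1))
    expect_true(all(diff(totals) <= 0), info = field)
  }
})

test_that("every boundary intake maps to exactly one band", {
  grid <- seq(0, 8, by = 0.25)
  for (comp in setdiff(hei_components(), "alcohol")) {
    sc <- hei_component_score(comp, grid)
    expect_false(anyNA(sc), info = comp)
    expect_true(all(sc * 2 == round(sc * 2)), info = comp)
    expect_true(all(sc >= 0 & sc <= ifelse(comp == "veg_fruit", 2, 1)),
                info = comp)
  }
  for (sex in c("male", "female")) {
    for (days in 0:7) {
      sc <- hei_component_score("alcohol", sex = sex, days = days,
                                drinks = seq(0, 4, 0.5))
      expect_false(anyNA(sc))
      expect_true(all(sc %in% c(0, 0.5, 1)))
    }
  }
})

test_that("missing fields exclude the subject with a logged reason", {
  d <- rbind(max_diet_row(), max_diet_row(oily_fish_per_week = NA))
  s <- score_hei(d)
  expect_false(s$excluded[1])
  expect_true(s$excluded[2])
  expect_true(is.na(s$total[2]))
  log <- attr(s, "exclusions")
  expect_equal(nrow(log), 1)
  expect_match(log$reason, "oily_fish")
  # partial mode keeps the subject and sums the scorable components
  s2 <- score_hei(d, allow_partial = TRUE)
  expect_equal(s2$total[2], 10)
})

test_that("total is the sum of component scores and doubles to an integer", {
  set.seed(11)
  for (i in 1:25) {
    d <- max_diet_row(
      veg_fruit_per_day = runif(1, 0, 8),
      whole_grains_per_day = runif(1, 0, 5),
      oily_fish_per_week = runif(1, 0, 3),
      lean_meat_per_week = runif(1, 0, 5),
      nonmeat_protein_per_week = runif(1, 0, 5),
      sugared_bev_per_day = runif(1, 0, 6),
      high_fat_meat_per_week = runif(1, 0, 5),
      fast_food_per_week = runif(1, 0, 3),
      fermented_dairy_per_day = runif(1, 0, 6),
      alcohol_days_per_week = sample(0:7, 1),
      alcohol_drinks_per_day = runif(1, 0, 4))
    s <- score_hei(d)
    comp_sum <- sum(s[1, hei_components()])
    expect_equal(s$total, comp_sum)
    expect_equal(s$total * 2, round(s$total * 2))
    expect_gte(s$total, 0); expect_lte(s$total, 11)
  }
})
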
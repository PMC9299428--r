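test_that("smoking indicator honors the 30-year quit rule", {
  expect_true(derive_no_smoking("never", NA))
  expect_true(derive_no_smoking("former", 30)) # boundary: at least 30
  expect_false(derive_no_smoking("former", 29.9))
  expect_false(derive_no_smoking("current", NA))
  expect_true(is.na(derive_no_smoking("former", NA)))
  expect_error(derive_no_smoking("sometimes", 1), "invalid")
  # sensitivity rule: only current smokers are unhealthy
  expect_true(derive_no_smoking("former", 1, rule = "no_current"))
  expect_false(derive_no_smoking("current", NA, rule = "no_current"))
})

test_that("activity indicator covers all four qualifying routes", {
  expect_true(derive_regular_activity(75, 0, 0)) # vigorous boundary
  expect_true(derive_regular_activity(0, 150, 0)) # moderate boundary
  expect_true(derive_regular_activity(40, 80, 0)) # 2*40 + 80 = 160
  expect_true(derive_regular_activity(10, 20, 5)) # both, 5+ days
  expect_false(derive_regular_activity(0, 0, 0))
  expect_false(derive_regular_activity(74, 0, 4))
  expect_false(derive_regular_activity(0, 20, 7)) # one intensity only
})

test_that("BMI indicator is half-open by default and configurable", {
  expect_true(derive_moderate_bmi(22))
  expect_true(derive_moderate_bmi(18.5))
  expect_false(derive_moderate_bmi(18.4))
  expect_false(derive_moderate_bmi(24.0)) # half-open upper bound
  expect_true(derive_moderate_bmi(24.0, closed_upper = TRUE))
  expect_true(derive_moderate_bmi(24.5, high = 25))
})

test_that("alcohol indicator negates frequent current drinking", {
  expect_false(derive_no_alcohol("weekly", "current"))
  expect_false(derive_no_alcohol("daily", "current"))
  expect_true(derive_no_alcohol("never", "never"))
  expect_true(derive_no_alcohol("monthly", "current"))
  expect_true(derive_no_alcohol("weekly", "former"))
})

test_that("diet indicator counts healthy directions against medians", {
  comp <- tibble::tibble(
    diet_fruit = c(5, 1, 5, 3),
    diet_vegetables = c(5, 1, 5, 3),
    diet_whole_grains = c(5, 1, 5, 3),
    diet_fish = c(5, 1, 1, 3),
    diet_red_meat = c(1, 5, 1, 3),
    diet_processed_meat = c(1, 5, 5, 3)
  )
  ref <- c(
    diet_fruit = 3, diet_vegetables = 3, diet_whole_grains = 3,
    diet_fish = 3, diet_red_meat = 3, diet_processed_meat = 3
  )
  got <- derive_healthy_diet(comp, k = 4, reference = ref)
  expect_identical(got, c(TRUE, FALSE, TRUE, FALSE)) # 6, 0, exactly 4, 0
  # stricter k flips the borderline row
  expect_identical(
    derive_healthy_diet(comp, k = 5, reference = ref)[3], FALSE
  )
  allna <- comp
  allna[1, ] <- NA
  expect_true(is.na(derive_healthy_diet(allna, reference = ref)[1]))
})

test_that("index and category follow the 0-1/2/3 rule symmetrically", {
  idx <- lifestyle_index(
    c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    c(TRUE, FALSE, TRUE, FALSE, TRUE, NA),
    c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  expect_identical(idx$index[1:4], c(3L, 1L, 2L, 0L))
  expect_identical(
    as.character(idx$category[1:4]),
    c("favorable", "unfavorable", "moderate", "unfavorable")
  )
  expect_true(is.na(idx$index[6]))
  # permutation invariance of the three flags
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  flags <- list(TRUE, FALSE, TRUE)
  cats <- sapply(perms, function(p) {
    as.character(lifestyle_index(
      flags[[p[1]]], flags[[p[2]]], flags[[p[3]]]
    )$category)
  })
  expect_true(all(cats == cats[1]))
})

test_that("healthier flags never move the category toward unfavorable", {
  lvl <- c(favorable = 3, moderate = 2, unfavorable = 1)
  grid <- expand.grid(s = c(FALSE, TRUE), a = c(FALSE, TRUE),
    b = c(FALSE, TRUE)
  )
  for (i in seq_len(nrow(grid))) {
    base <- lifestyle_index(grid$s[i], grid$a[i], grid$b[i])
    for (j in 1:3) {
      flipped <- grid[i, ]
      flipped[[j]] <- TRUE
      up <- lifestyle_index(flipped$s, flipped$a, flipped$b)
      expect_gte(
        lvl[as.character(up$category)],
        lvl[as.character(base$category)]
      )
    }
  }
})

test_that("widening the BMI band never lowers the moderate-BMI prevalence", {
  raw <- simulate_lifestyle(sim_config(seed = 31), n = 5000)
  narrow <- derive_lifestyle(raw, bmi_bounds = c(18.5, 24))
  wide <- derive_lifestyle(raw, bmi_bounds = c(18.5, 25))
  expect_gte(mean(wide$moderate_bmi), mean(narrow$moderate_bmi))
})
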
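test_that("WHO categorisation respects the half-open boundaries", {
  expect_equal(
    as.character(who_category(c(10, 18.499, 18.5, 24.9, 25, 29.9, 30, 45))),
    c(
      "underweight", "underweight", "normal", "normal",
      "overweight", "overweight", "obese", "obese"
    )
  )
  expect_error(who_category(0), "positive")
  expect_error(who_category(c(22, NA)), "positive")
  expect_error(who_category(Inf), "positive")
})

test_that("projected window hits the anchor at week 13 and the totals at 40", {
  expect_equal(projected_window("normal", 40), tibble::tibble(lo = 11.5, hi = 16))
  expect_equal(projected_window("obese", 13), tibble::tibble(lo = 0.5, hi = 2))
  # hand interpolation: 0.5 + 11 * 13.5/27, 2 + 14 * 13.5/27
  expect_equal(projected_window("normal", 26.5), tibble::tibble(lo = 6.0, hi = 9.0))
  w <- purrr::map_dfr(
    c("underweight", "normal", "overweight", "obese"),
    ~ projected_window(.x, 40)
  )
  expect_equal(w$lo, c(12.5, 11.5, 7, 5))
  expect_equal(w$hi, c(18, 16, 11.5, 9))
  expect_error(projected_window("normal", 12.9), "13")
  expect_error(projected_window("lean", 30), "category")
})

test_that("windows widen with gestational age and narrow with heavier BMI", {
  gas <- seq(13, 42, by = 0.5)
  for (mode in c("interpolation", "rate")) {
    for (cat in c("underweight", "normal", "overweight", "obese")) {
      w <- projected_window(cat, gas, mode = mode)
      widths <- w$hi - w$lo
      expect_true(all(diff(widths) >= -1e-12), info = paste(mode, cat))
      expect_true(all(diff(w$lo) >= -1e-12))
    }
    # heavier category => lower window at any ga
    for (ga in c(15, 25, 35, 40)) {
      w <- projected_window(
        c("underweight", "normal", "overweight", "obese"), ga,
        mode = mode
      )
      expect_true(all(diff(w$lo) <= 0) && all(diff(w$hi) <= 0))
    }
  }
})

test_that("gain classification uses inclusive bounds and interpolated windows", {
  # normal ppBMI at week 28: window (0.5 + 11*15/27, 2 + 14*15/27)
  w <- projected_window("normal", 28)
  expect_equal(round(unlist(w), 2), c(lo = 6.61, hi = 9.78))
  expect_equal(as.character(classify_gain(12, "normal", 28)), "H")
  # gains exactly on the bounds are within recommendations
  expect_equal(as.character(classify_gain(w$hi, "normal", 28)), "N")
  expect_equal(as.character(classify_gain(w$lo, "normal", 28)), "N")
  # underweight at week 27: (0.5 + 12*14/27, 2 + 16*14/27) = (6.72, 10.30)
  wu <- projected_window("underweight", 27)
  expect_equal(round(unlist(wu), 2), c(lo = 6.72, hi = 10.30))
  expect_equal(as.character(classify_gain(3, "underweight", 27)), "L")
})

test_that("increasing gain never moves the label towards L", {
  set.seed(42)
  for (i in 1:50) {
    cat <- sample(c("underweight", "normal", "overweight", "obese"), 1)
    ga <- runif(1, 14, 42)
    mode <- sample(c("interpolation", "rate"), 1)
    gains <- sort(runif(8, -5, 25))
    labs <- classify_gain(gains, cat, ga, mode = mode)
    expect_true(all(diff(as.integer(labs)) >= 0))
  }
})

test_that("classification at term with total gain matches the total-window rule", {
  gains <- seq(2, 22, by = 0.5)
  for (cat in c("underweight", "normal", "overweight", "obese")) {
    win <- iom_windows()[iom_windows()$category == cat, ]
    expected <- ifelse(gains < win$total_lo, "L",
      ifelse(gains > win$total_hi, "H", "N")
    )
    expect_equal(as.character(classify_gain(gains, cat, 40)), expected)
  }
})

test_that("classify_gwg flags unusable records instead of dropping silently", {
  cohort <- tibble::tibble(
    id = c("a", "b", "c"),
    pre_pregnancy_weight = c(60, NA, 70),
    height = c(1.65, 1.60, 1.70),
    ppbmi = pre_pregnancy_weight / height^2,
    ga_t2 = c(22, 22, NA), wt_t2 = c(68, 68, NA),
    ga_t3 = c(34, 34, NA), wt_t3 = c(74, 74, NA)
  )
  cls <- classify_gwg(cohort)
  expect_false(cls$excluded[1])
  expect_true(cls$excluded[2])
  expect_match(cls$exclusion_reason[2], "ppBMI")
  expect_true(cls$excluded[3])
  expect_match(cls$exclusion_reason[3], "trimester")
  expect_equal(cls$mode, rep("interpolation", 3))
})

test_that("latest visit in a trimester is the one classified", {
  visits <- tibble::tibble(
    id = "w1",
    ga_weeks = c(9, 16, 25, 30, 36),
    weight_kg = c(61, 63, 66, 69, 72)
  )
  wide <- visits_to_wide(visits)
  expect_equal(wide$ga_t2, 25)
  expect_equal(wide$wt_t2, 66)
  expect_equal(wide$ga_t3, 36)
  expect_equal(wide$wt_t3, 72)
})

test_that("transition strata reproduce share arithmetic from raw labels", {
  # all women N -> N
  tr <- gwg_transitions(rep("N", 10), rep("N", 10))
  expect_equal(tr$counts["N", "N"], 10L)
  expect_equal(sum(tr$counts), 10L)
  expect_equal(
    tr$strata$pct_of_row[tr$strata$stratum == "T2N & (T3N|T3L)"], 100
  )
  # symmetric table: every cell 1
  m <- matrix(1, 3, 3)
  tr2 <- transitions_from_counts(m)
  expect_equal(tr2$n, 9)
  expect_equal(
    tr2$strata$pct_of_row,
    c(100 / 3, 200 / 3, 200 / 3, 100 / 3)
  )
  # counts partition the classified input
  t2 <- sample(c("L", "N", "H"), 200, replace = TRUE)
  t3 <- sample(c("L", "N", "H"), 200, replace = TRUE)
  tr3 <- gwg_transitions(t2, t3)
  expect_equal(sum(tr3$counts), 200)
  expect_equal(rowSums(tr3$counts), table(factor(t2, c("L", "N", "H"))) |>
    as.integer() |> rlang::set_names(c("L", "N", "H")))
  expect_error(transitions_from_counts(matrix(1, 2, 2)), "3x3")
})

test_that("glucose screening rule follows the two-step thresholds", {
  expect_true(gdm_from_glucose(10.3))
  expect_false(gdm_from_glucose(7.7))
  # in-band GCT with a positive fasting OGTT value
  expect_true(gdm_from_glucose(8.0, ogtt_0h = 5.3, ogtt_1h = 9.0, ogtt_2h = 8.0))
  expect_false(gdm_from_glucose(8.0, ogtt_0h = 5.2, ogtt_1h = 10.5, ogtt_2h = 8.9))
  expect_true(gdm_from_glucose(8.0, ogtt_1h = 10.6))
  expect_true(gdm_from_glucose(8.0, ogtt_2h = 9.0))
  # OGTT required but absent: indeterminate, not negative
  expect_true(is.na(gdm_from_glucose(9.0)))
  expect_equal(
    gdm_from_glucose(c(7.7, 7.8, 10.2, 10.3)),
    c(FALSE, NA, NA, TRUE)
  )
})
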
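test_that("simulation is fully reproducible under a fixed seed", {
  cfg <- sim_config(n_subjects = 300, seed = 11)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a, b)
  c2 <- suppressWarnings(simulate_cohort(cfg, seed = 12))
  expect_false(identical(a, c2))
})

test_that("realized group shares converge to the configured shares", {
  cfg <- sim_config(n_subjects = 10000, seed = 2)
  co <- suppressWarnings(simulate_cohort(cfg))
  shares <- as.numeric(table(factor(co$latent_group, 1:3)) / nrow(co))
  expect_true(all(abs(shares - c(0.583, 0.324, 0.093)) < 0.02))
  # per-group ppBMI means near their configured centres (truncation at 14
  # barely touches these distributions)
  mns <- tapply(co$ppbmi, co$latent_group, mean)
  expect_true(all(abs(mns - c(21.2, 26.3, 35.6)) < 0.4))
})

test_that("noise-free single-group weights lie exactly on the polynomial", {
  cfg <- sim_config(
    n_subjects = 20, group_shares = 1,
    group_gain_coefs = list(c(0, 0.3, 0.002)),
    residual_sd = 0, slope_sd = 0,
    ppbmi_mean = 22, ppbmi_sd = 0, seed = 5
  )
  co <- suppressWarnings(simulate_cohort(cfg))
  for (k in 1:3) {
    w <- co[[paste0("ga_t", k)]]
    gain <- co[[paste0("wt_t", k)]] - co$pre_pregnancy_weight
    expect_equal(gain, 0.3 * w + 0.002 * w^2, tolerance = 1e-10)
  }
})

test_that("config validation rejects bad shares and sizes", {
  expect_error(sim_config(n_subjects = 0), "positive")
  expect_error(sim_config(group_shares = c(0.5, 0.4)), "sum to 1")
  expect_error(
    sim_config(group_shares = c(0.5, 0.5), group_gain_coefs = list(c(0, 1))),
    "per group"
  )
  expect_error(sim_config(residual_sd = -1), "residual_sd")
})

test_that("log-linear outcome assignment reproduces baseline rates and RRs", {
  set.seed(31)
  n <- 10000
  d <- tibble::tibble(
    id = as.character(1:n),
    x = stats::rbinom(n, 1, 0.5)
  )
  # baseline only: event rate equals the configured baseline
  d1 <- assign_outcomes(d,
    outcome_models = list(ev = list(intercept = log(0.05), coef = NULL)),
    seed = 1
  )
  expect_lt(abs(mean(d1$ev) - 0.05), 0.01)
  # binary exposure with log-RR log(2): Monte-Carlo risk ratio near 2
  d2 <- assign_outcomes(d,
    outcome_models = list(
      ev = list(intercept = log(0.05), coef = c(x = log(2)))
    ),
    seed = 2
  )
  ratio <- mean(d2$ev[d2$x == 1]) / mean(d2$ev[d2$x == 0])
  expect_lt(abs(ratio - 2), 0.3)
  # same records and seed: identical draws
  expect_identical(
    assign_outcomes(d, list(ev = list(intercept = log(0.1), coef = NULL)), seed = 3),
    assign_outcomes(d, list(ev = list(intercept = log(0.1), coef = NULL)), seed = 3)
  )
  # risks above 1 are clipped with a warning
  expect_warning(
    assign_outcomes(d,
      outcome_models = list(ev = list(intercept = log(1.5), coef = NULL)),
      seed = 4
    ),
    "clipped"
  )
  # unknown covariate is an explicit error
  expect_error(
    assign_outcomes(d,
      outcome_models = list(ev = list(intercept = log(0.1), coef = c(zz = 1))),
      seed = 5
    ),
    "unknown column"
  )
})

test_that("macrosomia is strictly above 4000 g; SGA/LGA sit at the reference percentiles", {
  d <- tibble::tibble(
    id = c("a", "b", "c"),
    birth_weight = c(4000, 4001, 3999),
    ga_delivery = 40
  )
  d <- assign_outcomes(d, outcome_models = list(), seed = 1)
  expect_equal(d$macrosomia, c(0L, 1L, 0L))

  # under the reference distribution itself, SGA and LGA are ~10% each
  set.seed(8)
  ref <- list(mean_at_40 = 3400, slope_per_week = 130, sd = 450)
  n <- 20000
  big <- tibble::tibble(
    id = as.character(1:n),
    ga_delivery = stats::runif(n, 37, 41)
  )
  big$birth_weight <- stats::rnorm(
    n, ref$mean_at_40 + ref$slope_per_week * (big$ga_delivery - 40), ref$sd
  )
  big <- assign_outcomes(big,
    outcome_models = list(), seed = 2,
    birthweight_reference = ref
  )
  expect_lt(abs(mean(big$sga) - 0.10), 0.01)
  expect_lt(abs(mean(big$lga) - 0.10), 0.01)
})

test_that("cohort CSV round-trips through the canonical schema", {
  co <- suppressWarnings(simulate_cohort(sim_config(n_subjects = 25, seed = 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$id, co$id)
  expect_equal(back$wt_t3, co$wt_t3, tolerance = 1e-9)
  expect_equal(back$gdm, co$gdm)
})

test_that("long/wide reshaping keeps every visit and the week-0 anchor", {
  co <- suppressWarnings(simulate_cohort(sim_config(n_subjects = 10, seed = 4)))
  long <- cohort_to_long(co)
  expect_equal(nrow(long), 4 * nrow(co))
  expect_equal(sum(long$ga_weeks == 0), nrow(co))
  anchored <- long[long$ga_weeks == 0, ]
  expect_equal(
    anchored$weight_kg[match(co$id, anchored$id)],
    co$pre_pregnancy_weight
  )
  no_anchor <- cohort_to_long(co, anchor = FALSE)
  expect_equal(nrow(no_anchor), 3 * nrow(co))
})
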
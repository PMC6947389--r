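test_that("mixture log-likelihood matches a brute-force enumeration oracle", {
  set.seed(1)
  long <- make_mixture_long(
    3, c(0.6, 0.4), c(60, 80), c(0.3, 0.5), 2,
    weeks = c(5, 20, 35), seed = 9
  )
  pi <- c(0.55, 0.45)
  beta <- cbind(c(59, 0.32), c(81, 0.48))
  expect_equal(
    gbtm_loglik(long, pi, beta, 2.1),
    oracle_loglik(long, pi, beta, 2.1),
    tolerance = 1e-10
  )
  # per-group sigmas, 5 subjects, 3 groups
  long5 <- make_mixture_long(
    5, c(0.5, 0.3, 0.2), c(55, 70, 95), c(0.3, 0.45, 0.35), 2.5,
    seed = 10
  )
  pi3 <- c(0.5, 0.3, 0.2)
  beta3 <- cbind(c(54, 0.3), c(71, 0.44), c(94, 0.36))
  expect_equal(
    gbtm_loglik(long5, pi3, beta3, c(2, 2.5, 3)),
    oracle_loglik(long5, pi3, beta3, c(2, 2.5, 3)),
    tolerance = 1e-10
  )
})

test_that("degenerate mixtures reduce to the single-group likelihood", {
  long <- make_mixture_long(4, 1, 65, 0.4, 1.5, seed = 3)
  beta <- c(64, 0.41)
  ll1 <- gbtm_loglik(long, 1, beta, 1.4)
  # two identical components: likelihood independent of the mixing weights
  expect_equal(gbtm_loglik(long, c(0.3, 0.7), cbind(beta, beta), 1.4), ll1)
  expect_equal(gbtm_loglik(long, c(0.9, 0.1), cbind(beta, beta), 1.4), ll1)
  # J = 1 equals the Gaussian log-likelihood of the polynomial regression
  direct <- sum(stats::dnorm(
    long$weight_kg, beta[1] + beta[2] * long$ga_weeks, 1.4,
    log = TRUE
  ))
  expect_equal(ll1, direct, tolerance = 1e-12)
  expect_error(gbtm_loglik(long, 1, beta, 0), "positive")
  expect_error(gbtm_loglik(long, c(0.5, 0.2), cbind(beta, beta), 1), "probability")
})

test_that("label permutation leaves the likelihood unchanged", {
  long <- make_mixture_long(6, c(0.5, 0.5), c(60, 75), c(0.3, 0.5), 2, seed = 4)
  pi <- c(0.35, 0.65)
  beta <- cbind(c(60, 0.3), c(75, 0.5))
  expect_equal(
    gbtm_loglik(long, pi, beta, 2),
    gbtm_loglik(long, rev(pi), beta[, 2:1], 2),
    tolerance = 1e-12
  )
})

test_that("a single-group fit equals ordinary polynomial least squares", {
  long <- make_mixture_long(40, 1, 65, 0.4, 1.5, seed = 5)
  fit <- fit_gbtm(long, j = 1, order = 1, n_starts = 1, seed = 1)
  ols <- stats::lm(weight_kg ~ ga_weeks, data = long)
  expect_equal(unname(fit$beta[, 1]), unname(stats::coef(ols)), tolerance = 1e-8)
  sig_ml <- sqrt(mean(stats::residuals(ols)^2))
  expect_equal(fit$sigma, sig_ml, tolerance = 1e-8)
  expect_equal(fit$pi, 1)
  expect_equal(unname(fit$posterior[, 1]), rep(1, 40))
  diag1 <- gbtm_adequacy(fit)
  expect_equal(diag1$mean_posterior, 1)
  expect_equal(diag1$observed_share, diag1$expected_share)
})

test_that("EM log-likelihood is monotone and the fit is seed-deterministic", {
  long <- make_mixture_long(
    150, c(0.6, 0.4), c(58, 72), c(0.35, 0.5), 2,
    seed = 6
  )
  fit <- fit_gbtm(long, j = 2, seed = 7, n_starts = 3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-7))
  expect_true(fit$converged)
  fit2 <- fit_gbtm(long, j = 2, seed = 7, n_starts = 3)
  expect_identical(fit$beta, fit2$beta)
  expect_identical(fit$loglik, fit2$loglik)
  # posterior rows are probability vectors
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-12))
  # canonical ordering: ascending mean weight at week 20
  mid <- as.vector(t(20^(0:1)) %*% fit$beta)
  expect_true(all(diff(mid) > 0))
})

test_that("well-separated three-group parameters are recovered", {
  truth_pi <- c(0.583, 0.324, 0.093)
  long <- make_mixture_long(
    1200, truth_pi, c(57, 71, 96), c(0.35, 0.45, 0.33), 2.5,
    seed = 12
  )
  fit <- fit_gbtm(long, j = 3, seed = 13, n_starts = 3)
  expect_true(all(abs(fit$pi - truth_pi) < 0.03))
  expect_true(all(abs(fit$beta[1, ] - c(57, 71, 96)) < 0.5))
  ad <- gbtm_adequacy(fit)
  expect_true(all(ad$mean_posterior > 0.95))
  expect_true(all(abs(ad$observed_share - ad$expected_share) < 0.01))
  expect_true(all(ad$adequate))
})

test_that("quasi-Newton polish never worsens the EM solution", {
  long <- make_mixture_long(
    120, c(0.6, 0.4), c(58, 72), c(0.35, 0.5), 2,
    seed = 21
  )
  em <- fit_gbtm(long, j = 2, seed = 3, n_starts = 2)
  pol <- fit_gbtm(long, j = 2, seed = 3, n_starts = 2, polish = TRUE)
  expect_gte(pol$loglik + 1e-9, em$loglik)
})

test_that("BIC selection separates one- and two-group data", {
  # two groups 10 sigma apart
  long2 <- make_mixture_long(
    500, c(0.5, 0.5), c(60, 80), c(0.4, 0.4), 2,
    seed = 14
  )
  sel2 <- select_gbtm(long2, j_range = 1:3, n_starts = 2, seed = 15)
  expect_equal(sel2$best$spec$j, 2)
  # single-group data: the BIC penalty dominates
  long1 <- make_mixture_long(300, 1, 65, 0.4, 2, seed = 16)
  sel1 <- select_gbtm(long1, j_range = 1:3, n_starts = 2, seed = 17)
  expect_equal(sel1$best$spec$j, 1)
  # sweep table internally consistent: bic recomputable from loglik and k
  sw <- sel2$sweep
  expect_equal(sw$bic, -2 * sw$loglik + sw$k * log(500))
  expect_true(all(diff(sw$k) > 0))
  expect_equal(sum(sw$selected), 1L)
})

test_that("slopes and their contrasts are reported with Wald intervals", {
  # noise-free linear single group: slope exact, vanishing CI width
  long0 <- tibble::tibble(
    id = rep(sprintf("s%02d", 1:30), each = 4),
    ga_weeks = rep(c(0, 10, 22, 34), 30),
    weight_kg = 60 + 0.42 * ga_weeks
  )
  f0 <- fit_gbtm(long0, j = 1, n_starts = 1, seed = 1)
  s0 <- trajectory_slopes(f0)
  expect_equal(s0$slopes$slope, 0.42, tolerance = 1e-8)
  expect_lt(s0$slopes$conf.high - s0$slopes$conf.low, 1e-6)

  # slopes in kg/month, 2.3 vs 3.0, as a two-group mixture
  months <- c(0, 2.5, 5.5, 8.5)
  long2 <- make_mixture_long(
    1000, c(0.5, 0.5), c(58, 75), c(2.3, 3.0), 2,
    weeks = months, seed = 18
  )
  f2 <- fit_gbtm(long2, j = 2, seed = 19, n_starts = 2)
  s2 <- trajectory_slopes(f2)
  expect_true(all(s2$slopes$conf.low <= s2$slopes$slope &
    s2$slopes$slope <= s2$slopes$conf.high))
  expect_true(all(abs(sort(s2$slopes$slope) - c(2.3, 3.0)) < 0.1))
  expect_lt(s2$contrasts$p.value, 0.01)

  f_flat <- fit_gbtm(long0, j = 1, order = 0, n_starts = 1, seed = 1)
  expect_error(trajectory_slopes(f_flat), "order-0")
})

test_that("tidy, glance and autoplot expose the fit", {
  long <- make_mixture_long(80, c(0.5, 0.5), c(60, 80), c(0.4, 0.4), 2, seed = 20)
  fit <- fit_gbtm(long, j = 2, seed = 2, n_starts = 2)
  td <- tidy(fit)
  expect_true(all(c("group", "term", "estimate", "std.error") %in% names(td)))
  expect_equal(sum(td$term == "sigma"), 1) # shared variance
  gl <- glance(fit)
  expect_equal(gl$j, 2)
  expect_equal(gl$BIC, fit$bic)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  curves <- trajectory_curves(fit, weeks = c(10, 20, 30))
  expect_equal(nrow(curves), 6)
  expect_true(all(curves$conf.low <= curves$mean & curves$mean <= curves$conf.high))
})
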
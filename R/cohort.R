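#' Configuration for the synthetic perinatal cohort generator
#'
#' Builds and validates the parameter list driving [simulate_cohort()]. The
#' defaults describe a cohort with three latent weight-trajectory groups —
#' a majority group of normal-ppBMI women, an overweight group with faster
#' gain, and a smaller obese group — with group shares, per-group ppBMI
#' distributions and log-linear outcome risks chosen to resemble a large
#' unselected North-American pregnancy cohort.
#'
#' Trajectories are simulated on absolute maternal weight (kg) versus
#' gestational week: each woman's weight at week `w` is her pre-pregnancy
#' weight (the week-0 anchor) plus her group's gain polynomial evaluated at
#' `w`, plus Gaussian measurement noise. Setting `gain_mode = TRUE` makes
#' `simulate_cohort()` record gain (weight minus pre-pregnancy weight)
#' instead of absolute weight in the visit columns.
#'
#' @param n_subjects Number of women to simulate.
#' @param group_shares Probability vector over latent trajectory groups
#'   (must sum to 1).
#' @param group_gain_coefs List of per-group polynomial coefficients
#'   (intercept first) for expected gain in kg as a function of gestational
#'   week.
#' @param residual_sd Visit-level measurement noise SD around the woman's
#'   own curve, in kg (one value per group, recycled).
#' @param slope_sd SD of the per-woman random deviation from the group's
#'   linear gain rate, in kg/week (recycled per group). This is what makes
#'   the between-woman gain spread widen over gestation, as it does in real
#'   cohorts; set to 0 for pure group-curve-plus-noise data.
#' @param ppbmi_mean,ppbmi_sd Per-group mean and SD of pre-pregnancy BMI
#'   (kg/m^2).
#' @param height_mean,height_sd Maternal height distribution (m).
#' @param visit_weeks Centre of the visit schedule, one visit per trimester.
#' @param visit_jitter Half-width of the uniform jitter around each scheduled
#'   visit, in weeks.
#' @param ga_delivery_mean,ga_delivery_sd Gestational age at delivery (weeks),
#'   truncated to `[32, 42]`.
#' @param birthweight_reference List with `mean_at_40` (g), `slope_per_week`
#'   (g per week of gestational age at delivery) and `sd` (g): the Normal
#'   reference distribution that defines the small/large-for-gestational-age
#'   percentiles.
#' @param birthweight_shift Named numeric vector of linear shifts (in g) of
#'   the realised birth-weight mean away from the reference, per unit of the
#'   named cohort column (e.g. `c(ppbmi_c = 14, gain_rate_c = 180)` where
#'   `_c` columns are centred internally). This is what creates
#'   macrosomia/LGA gradients across groups.
#' @param outcome_models Named list of log-linear risk models, one per
#'   directly simulated binary outcome. Each element is
#'   `list(intercept = <log baseline risk>, coef = c(<column> = <log RR>, ...))`;
#'   coefficient names must be numeric columns of the simulated table.
#'   `sga`, `lga` and `macrosomia` are normally derived from birth weight and
#'   need no model; supplying a model for one of them overrides the
#'   derivation (see [assign_outcomes()]).
#' @param gain_mode If `TRUE`, visit weight columns store gain rather than
#'   absolute weight.
#' @param seed Integer seed giving full reproducibility.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 100, seed = 42)
#' @export
sim_config <- function(n_subjects = 6551,
                       group_shares = c(0.583, 0.324, 0.093),
                       group_gain_coefs = list(
                         c(0, 0.1158, 0.00637),
                         c(0, 0.3964, 0.00140),
                         c(0, 0.2254, 0.00401)
                       ),
                       residual_sd = 1.2,
                       slope_sd = 0.08,
                       ppbmi_mean = c(21.2, 26.3, 35.6),
                       ppbmi_sd = c(2.2, 3.1, 5),
                       height_mean = 1.64,
                       height_sd = 0.065,
                       visit_weeks = c(10, 22, 34),
                       visit_jitter = 2,
                       ga_delivery_mean = 39.4,
                       ga_delivery_sd = 1.45,
                       birthweight_reference = list(
                         mean_at_40 = 3400, slope_per_week = 130, sd = 450
                       ),
                       birthweight_shift = c(ppbmi_c = 16, gain_rate_c = 700),
                       outcome_models = default_outcome_models(),
                       gain_mode = FALSE,
                       seed = 1L) {
  stop_if_not_scalar_count(n_subjects, "n_subjects")
  if (any(group_shares < 0) || abs(sum(group_shares) - 1) > 1e-8) {
    rlang::abort("`group_shares` must be non-negative and sum to 1")
  }
  j <- length(group_shares)
  if (length(group_gain_coefs) != j) {
    rlang::abort("`group_gain_coefs` must have one coefficient vector per group")
  }
  residual_sd <- rep_len(residual_sd, j)
  if (any(residual_sd < 0)) rlang::abort("`residual_sd` must be >= 0")
  slope_sd <- rep_len(slope_sd, j)
  if (any(slope_sd < 0)) rlang::abort("`slope_sd` must be >= 0")
  if (length(ppbmi_mean) != j || length(ppbmi_sd) != j) {
    rlang::abort("`ppbmi_mean`/`ppbmi_sd` must have one value per group")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      group_shares = group_shares,
      group_gain_coefs = group_gain_coefs,
      residual_sd = residual_sd,
      slope_sd = slope_sd,
      ppbmi_mean = ppbmi_mean, ppbmi_sd = ppbmi_sd,
      height_mean = height_mean, height_sd = height_sd,
      visit_weeks = visit_weeks, visit_jitter = visit_jitter,
      ga_delivery_mean = ga_delivery_mean, ga_delivery_sd = ga_delivery_sd,
      birthweight_reference = birthweight_reference,
      birthweight_shift = birthweight_shift,
      outcome_models = outcome_models,
      gain_mode = isTRUE(gain_mode),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default log-linear outcome models for the simulator
#'
#' Baseline risks sit near those of a low-risk singleton cohort (GDM ~5%,
#' hypertensive disorders ~3%, caesarean ~18%, neonatal hypoglycemia ~1.4% in
#' the normal-BMI stratum) and risks increase log-linearly with centred ppBMI
#' and gain rate, with extra risk from chronic hypertension and pre-existing
#' diabetes where clinically expected.
#'
#' @return Named list of model specifications (see [sim_config()]).
#' @export
default_outcome_models <- function() {
  list(
    gdm = list(
      intercept = log(0.045),
      coef = c(ppbmi_c = 0.105, age_c = 0.02)
    ),
    hdp = list(
      intercept = log(0.028),
      coef = c(ppbmi_c = 0.085, gain_rate_c = 1.6, chronic_hypertension = 0.9)
    ),
    caesarean = list(
      intercept = log(0.175),
      coef = c(ppbmi_c = 0.035, gain_rate_c = 0.6, parity = -0.05)
    ),
    hypoglycemia = list(
      intercept = log(0.013),
      coef = c(ppbmi_c = 0.025, gain_rate_c = 1.0, prior_diabetes = 1.0)
    )
  )
}

#' Birth-weight reference quantile
#'
#' Quantile of the configured Normal birth-weight reference at a gestational
#' age at delivery; used to derive the 10th/90th percentile cut-offs behind
#' the small- and large-for-gestational-age flags.
#'
#' @param p Probability.
#' @param ga_delivery Gestational age at delivery in weeks.
#' @param ref Reference list with `mean_at_40`, `slope_per_week`, `sd`.
#' @return Birth weight in g.
#' @export
birthweight_quantile <- function(p, ga_delivery, ref) {
  stats::qnorm(p,
    mean = ref$mean_at_40 + ref$slope_per_week * (ga_delivery - 40),
    sd = ref$sd
  )
}

#' Simulate a synthetic pregnancy cohort
#'
#' Draws `n_subjects` women: a latent trajectory group from `group_shares`,
#' per-group pre-pregnancy BMI and weight, one weighing per trimester on the
#' jittered visit schedule with weights following the group's gain polynomial
#' plus Gaussian noise, covariates (age, parity, smoking, chronic
#' hypertension, pre-existing diabetes, education, income), gestational age
#' at delivery and birth weight, and finally the binary outcomes via
#' [assign_outcomes()]. The same config and seed always reproduce the
#' identical table.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return A tibble, one row per woman, in the canonical wide cohort schema:
#'   `id`, `latent_group`, anthropometrics, `ga_t1/wt_t1 ... ga_t3/wt_t3`,
#'   covariates, `ga_delivery`, `birth_weight`, and the seven outcome flags
#'   `gdm`, `hdp`, `caesarean`, `macrosomia`, `sga`, `lga`, `hypoglycemia`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 200, seed = 7))
#' dplyr::count(cohort, latent_group)
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must come from sim_config()")
  }
  seed <- seed %||% config$seed
  local_seed(seed, {
    n <- config$n_subjects
    j <- length(config$group_shares)
    grp <- sample.int(j, n, replace = TRUE, prob = config$group_shares)

    ppbmi <- stats::rnorm(n, config$ppbmi_mean[grp], config$ppbmi_sd[grp])
    ppbmi <- pmax(ppbmi, 14)
    height <- stats::rnorm(n, config$height_mean, config$height_sd)
    height <- pmin(pmax(height, 1.40), 1.95)
    ppw <- ppbmi * height^2

    ga_del <- stats::rnorm(n, config$ga_delivery_mean, config$ga_delivery_sd)
    ga_del <- round(pmin(pmax(ga_del, 32), 42), 1)

    gain_at <- function(w) {
      vapply(seq_len(n), function(i) {
        sum(config$group_gain_coefs[[grp[i]]] * w[i]^(seq_along(config$group_gain_coefs[[grp[i]]]) - 1))
      }, numeric(1))
    }
    cohort <- tibble::tibble(
      id = sprintf("W%05d", seq_len(n)),
      latent_group = grp,
      ppbmi = ppbmi,
      height = height,
      pre_pregnancy_weight = ppw
    )
    slope_dev <- stats::rnorm(n, 0, config$slope_sd[grp])
    for (k in 1:3) {
      wk <- config$visit_weeks[k] +
        stats::runif(n, -config$visit_jitter, config$visit_jitter)
      wk <- round(pmin(wk, ga_del - 0.5), 1)
      gain <- gain_at(wk) + slope_dev * wk +
        stats::rnorm(n, 0, config$residual_sd[grp])
      cohort[[paste0("ga_t", k)]] <- wk
      cohort[[paste0("wt_t", k)]] <-
        if (config$gain_mode) gain else ppw + gain
    }

    age <- round(stats::rnorm(n, 30, 4.3), 1)
    cohort <- cohort |>
      dplyr::mutate(
        age = pmin(pmax(age, 18), 45),
        parity = stats::rpois(n, 0.9),
        smoking = stats::rbinom(n, 1, 0.10),
        chronic_hypertension = stats::rbinom(
          n, 1, pmin(0.01 * exp(0.06 * (ppbmi - 23)), 0.3)
        ),
        prior_diabetes = stats::rbinom(
          n, 1, pmin(0.006 * exp(0.08 * (ppbmi - 23)), 0.2)
        ),
        diploma = stats::rbinom(n, 1, 0.965),
        low_income = stats::rbinom(n, 1, 0.03),
        ga_delivery = ga_del
      )

    # realised gain rate (kg/week) up to the T3 visit, a per-woman exposure
    # summary the outcome models can load on
    t3gain <- if (config$gain_mode) cohort$wt_t3 else cohort$wt_t3 - ppw
    cohort$gain_rate <- t3gain / cohort$ga_t3

    ref <- config$birthweight_reference
    bw_mean <- ref$mean_at_40 + ref$slope_per_week * (ga_del - 40)
    if (length(config$birthweight_shift)) {
      for (nm in names(config$birthweight_shift)) {
        x <- shifted_column(cohort, nm)
        bw_mean <- bw_mean + config$birthweight_shift[[nm]] * x
      }
    }
    cohort$birth_weight <- round(stats::rnorm(n, bw_mean, ref$sd))

    assign_outcomes(cohort, config$outcome_models,
      birthweight_reference = ref
    )
  })
}

# resolve a column name used by outcome models / birthweight shifts;
# a trailing "_c" means the centred version of the base column
shifted_column <- function(data, nm) {
  if (nm %in% names(data)) return(data[[nm]])
  base <- sub("_c$", "", nm)
  if (endsWith(nm, "_c") && base %in% names(data)) {
    return(data[[base]] - mean(data[[base]], na.rm = TRUE))
  }
  rlang::abort(paste0("model references unknown column `", nm, "`"))
}

#' Assign binary outcomes to a cohort table
#'
#' For each directly modelled outcome, the event probability per woman is
#' `exp(intercept + sum(coef * x))` under a log link — so coefficients are
#' log relative risks — clipped to `[0, 1]` with a warning if clipping was
#' needed, and the flag is drawn as a Bernoulli. Small- and
#' large-for-gestational-age are derived by comparing `birth_weight` with the
#' 10th and 90th percentile of the birth-weight reference at `ga_delivery`,
#' and macrosomia is `birth_weight` strictly above 4000 g; supplying an
#' explicit model for one of these three overrides the derivation.
#'
#' @param records Cohort tibble with the covariate columns the models
#'   reference (a `<name>_c` coefficient refers to the centred `<name>`
#'   column) plus `birth_weight` and `ga_delivery` for the derived flags.
#' @param outcome_models Named list of models (see [sim_config()]).
#' @param seed Optional seed (omit when called from [simulate_cohort()],
#'   which already controls the stream).
#' @param birthweight_reference Reference distribution for the percentile
#'   flags; defaults to the [sim_config()] default.
#' @return `records` with outcome columns added (0/1 integers).
#' @export
assign_outcomes <- function(records, outcome_models = default_outcome_models(),
                            seed = NULL,
                            birthweight_reference = list(
                              mean_at_40 = 3400, slope_per_week = 130, sd = 450
                            )) {
  records <- tibble::as_tibble(records)
  run <- function() {
    n <- nrow(records)
    for (nm in names(outcome_models)) {
      mod <- outcome_models[[nm]]
      lp <- rep(mod$intercept, n)
      for (v in names(mod$coef)) {
        lp <- lp + mod$coef[[v]] * shifted_column(records, v)
      }
      p <- exp(lp)
      if (any(p > 1)) {
        rlang::warn(paste0(
          "outcome `", nm, "`: ", sum(p > 1),
          " risk(s) exceeded 1 and were clipped"
        ))
        p <- pmin(p, 1)
      }
      records[[nm]] <- stats::rbinom(n, 1, p)
    }
    if (all(c("birth_weight", "ga_delivery") %in% names(records))) {
      ref <- birthweight_reference
      if (!"sga" %in% names(outcome_models)) {
        records$sga <- as.integer(
          records$birth_weight <
            birthweight_quantile(0.10, records$ga_delivery, ref)
        )
      }
      if (!"lga" %in% names(outcome_models)) {
        records$lga <- as.integer(
          records$birth_weight >
            birthweight_quantile(0.90, records$ga_delivery, ref)
        )
      }
      if (!"macrosomia" %in% names(outcome_models)) {
        records$macrosomia <- as.integer(records$birth_weight > 4000)
      }
    }
    records
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' Write / read the canonical cohort CSV
#'
#' One row per woman in the wide schema produced by [simulate_cohort()].
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()` its
#'   `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Long visit table from a wide cohort
#'
#' Inverse of [visits_to_wide()]: stacks the per-trimester visit columns into
#' the long `(id, ga_weeks, weight_kg)` format used by [fit_gbtm()]. With
#' `anchor = TRUE` (default) the pre-pregnancy weight is included as a week-0
#' observation, anchoring each trajectory at its starting weight.
#'
#' @param cohort Wide cohort tibble.
#' @param anchor Include pre-pregnancy weight as a week-0 visit?
#' @return Long tibble with columns `id`, `ga_weeks`, `weight_kg`.
#' @export
cohort_to_long <- function(cohort, anchor = TRUE) {
  long <- cohort |>
    tibble::as_tibble() |>
    dplyr::select("id", dplyr::matches("^(ga|wt)_t[123]$")) |>
    tidyr::pivot_longer(-"id",
      names_to = c(".value", "trimester"),
      names_pattern = "(ga|wt)_(t[123])"
    ) |>
    dplyr::transmute(.data$id, ga_weeks = .data$ga, weight_kg = .data$wt) |>
    dplyr::filter(is.finite(.data$ga_weeks), is.finite(.data$weight_kg))
  if (anchor && "pre_pregnancy_weight" %in% names(cohort)) {
    long <- dplyr::bind_rows(
      tibble::tibble(
        id = cohort$id, ga_weeks = 0,
        weight_kg = cohort$pre_pregnancy_weight
      ),
      long
    )
  }
  dplyr::arrange(long, .data$id, .data$ga_weeks)
}
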
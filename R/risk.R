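#' Unadjusted relative risk from a 2x2 table
#'
#' Point estimate `(e1/n1)/(e0/n0)` with the Katz log-scale confidence
#' interval `exp(log RR +/- z * sqrt(1/e1 - 1/n1 + 1/e0 - 1/n0))` and a Wald
#' p-value on the log scale. With zero events in either arm the estimate is
#' undefined; set `correction = TRUE` to add 0.5 to every cell instead.
#'
#' @param events_exposed,n_exposed Events and total in the exposed arm.
#' @param events_ref,n_ref Events and total in the reference arm.
#' @param conf Confidence level (default 0.95).
#' @param correction Apply the 0.5 continuity correction when a cell is zero?
#' @return A one-row tibble: `rr`, `conf.low`, `conf.high`, `p.value`,
#'   `n_used`, `adjusted` (always `FALSE`).
#' @examples
#' rr_unadjusted(20, 100, 20, 200)
#' @export
rr_unadjusted <- function(events_exposed, n_exposed, events_ref, n_ref,
                          conf = 0.95, correction = FALSE) {
  cnt <- c(events_exposed, n_exposed, events_ref, n_ref)
  if (any(cnt < 0)) rlang::abort("invalid counts")
  if (n_exposed == 0 || n_ref == 0) rlang::abort("zero denominator")
  if (events_exposed > n_exposed || events_ref > n_ref) {
    rlang::abort("invalid counts: events exceed totals")
  }
  e1 <- events_exposed; n1 <- n_exposed
  e0 <- events_ref; n0 <- n_ref
  if ((e1 == 0 || e0 == 0) && !correction) {
    rlang::abort(paste0(
      "zero events in one arm make the risk ratio undefined; ",
      "use `correction = TRUE` for a 0.5 continuity correction"
    ))
  }
  if (correction && (e1 == 0 || e0 == 0)) {
    e1 <- e1 + 0.5; n1 <- n1 + 0.5
    e0 <- e0 + 0.5; n0 <- n0 + 0.5
  }
  rr <- (e1 / n1) / (e0 / n0)
  se <- sqrt(1 / e1 - 1 / n1 + 1 / e0 - 1 / n0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tibble::tibble(
    rr = rr,
    conf.low = exp(log(rr) - z * se),
    conf.high = exp(log(rr) + z * se),
    p.value = 2 * stats::pnorm(-abs(log(rr) / se)),
    n_used = n_exposed + n_ref,
    adjusted = FALSE
  )
}

#' Outcome-specific adjustment covariate sets
#'
#' The default adjustment set contains maternal age, parity, smoking during
#' pregnancy, chronic (pre-pregnancy) hypertension, the mother's diploma,
#' family income and pre-existing diabetes. For gestational diabetes the
#' pre-existing diabetes term is dropped (it is part of the outcome's
#' exclusion pathway rather than a confounder).
#'
#' @param outcome One of `gdm`, `hdp`, `caesarean`, `macrosomia`, `sga`,
#'   `lga`, `hypoglycemia`.
#' @return Character vector of covariate column names.
#' @examples
#' covariate_set("gdm")
#' @export
covariate_set <- function(outcome) {
  outcomes <- c(
    "gdm", "hdp", "caesarean", "macrosomia", "sga", "lga", "hypoglycemia"
  )
  if (length(outcome) != 1 || !outcome %in% outcomes) {
    rlang::abort(paste0(
      "unknown outcome; expected one of: ", paste(outcomes, collapse = ", ")
    ))
  }
  base <- c(
    "age", "parity", "smoking", "chronic_hypertension",
    "diploma", "low_income", "prior_diabetes"
  )
  if (outcome == "gdm") setdiff(base, "prior_diabetes") else base
}

#' Modified Poisson regression with robust variance
#'
#' Estimates relative risks for a binary outcome by a log-link Poisson GLM
#' (the "modified Poisson" approach): exponentiated coefficients are relative
#' risks, and standard errors come from the HC0 sandwich estimator, which
#' corrects the Poisson variance misspecification inherent in modelling a
#' 0/1 outcome. One row is returned per non-reference exposure level, with a
#' Wald confidence interval and p-value on the log scale. Rows with missing
#' values in any model variable are dropped (complete-case) and the retained
#' count reported as `n_used`.
#'
#' @param data Data frame containing the outcome, exposure and covariates.
#' @param outcome Name of a 0/1 (or logical) outcome column.
#' @param exposure Name of the exposure column; coerced to a factor.
#' @param covariates Character vector of adjustment covariates (default none,
#'   i.e. an unadjusted model); see [covariate_set()].
#' @param reference Reference level of the exposure (default: first factor
#'   level).
#' @param conf Confidence level.
#' @return A tibble with one row per non-reference level: `outcome`,
#'   `exposure`, `level`, `reference`, `rr`, `conf.low`, `conf.high`,
#'   `p.value`, `adjusted`, `covariates` (list-column), `n_used`,
#'   `converged`, `vcov_type`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 800, seed = 3))
#' cohort$bmi_cat <- who_category(cohort$ppbmi)
#' fit_robust_poisson(cohort, "gdm", "bmi_cat", reference = "normal")
#' @export
fit_robust_poisson <- function(data, outcome, exposure, covariates = NULL,
                               reference = NULL, conf = 0.95) {
  data <- tibble::as_tibble(data)
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "missing model columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  d <- data |>
    dplyr::select(dplyr::all_of(vars)) |>
    tidyr::drop_na()
  y <- d[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) {
    rlang::abort("`outcome` must be binary (0/1 or logical)")
  }
  d[[outcome]] <- y
  ex <- factor(d[[exposure]], ordered = FALSE)
  if (!is.null(reference)) {
    if (!reference %in% levels(ex)) {
      rlang::abort("`reference` is not a level of the exposure")
    }
    ex <- stats::relevel(ex, ref = reference)
  }
  d[[exposure]] <- ex
  dropped <- setdiff(levels(ex), unique(as.character(ex)))
  if (length(dropped)) d[[exposure]] <- droplevels(d[[exposure]])

  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- suppressWarnings(
    stats::glm(fml, data = d, family = stats::poisson(link = "log"))
  )
  vc <- sandwich::vcovHC(fit, type = "HC0")
  cf <- stats::coef(fit)
  ref_level <- levels(d[[exposure]])[1]
  lv <- levels(d[[exposure]])[-1]
  terms <- paste0(exposure, lv)
  se <- sqrt(diag(vc))[terms]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  est <- cf[terms]
  flagged <- !fit$converged || any(!is.finite(se)) ||
    any(abs(est) > 15, na.rm = TRUE) # effectively separated
  tibble::tibble(
    outcome = outcome,
    exposure = exposure,
    level = lv,
    reference = ref_level,
    rr = unname(exp(est)),
    conf.low = unname(exp(est - z * se)),
    conf.high = unname(exp(est + z * se)),
    p.value = unname(2 * stats::pnorm(-abs(est / se))),
    adjusted = length(covariates) > 0,
    covariates = list(covariates %||% character(0)),
    n_used = nrow(d),
    converged = !flagged,
    vcov_type = "HC0"
  )
}

#' Relative-risk table for several outcomes against one exposure
#'
#' Convenience wrapper running [fit_robust_poisson()] for each outcome twice
#' — unadjusted, and adjusted for the outcome's [covariate_set()] — and
#' stacking the rows, matching the layout of a typical outcomes-by-exposure
#' risk table (percent per level, RR, adjusted RR, CI, p).
#'
#' @param data Cohort data frame with outcome and covariate columns.
#' @param exposure Exposure column name.
#' @param outcomes Outcome names (default: all seven).
#' @param reference Reference exposure level.
#' @return A tibble of [fit_robust_poisson()] rows plus a `pct` column with
#'   the observed outcome percentage at each exposure level.
#' @export
risk_table <- function(data, exposure,
                       outcomes = c(
                         "gdm", "hdp", "caesarean", "macrosomia",
                         "sga", "lga", "hypoglycemia"
                       ),
                       reference = NULL) {
  outcomes <- intersect(outcomes, names(data))
  purrr::map_dfr(outcomes, function(oc) {
    un <- fit_robust_poisson(data, oc, exposure, reference = reference)
    ad <- fit_robust_poisson(data, oc, exposure,
      covariates = intersect(covariate_set(oc), names(data)),
      reference = reference
    )
    res <- dplyr::bind_rows(un, ad)
    rates <- data |>
      dplyr::filter(!is.na(.data[[exposure]]), !is.na(.data[[oc]])) |>
      dplyr::group_by(level = as.character(.data[[exposure]])) |>
      dplyr::summarise(pct = 100 * mean(.data[[oc]]), .groups = "drop")
    dplyr::left_join(res, rates, by = "level")
  })
}
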
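#' WHO pre-pregnancy BMI categories
#'
#' Classifies pre-pregnancy body mass index (ppBMI, kg/m^2) into the four WHO
#' categories: underweight (< 18.5), normal (18.5 to < 25), overweight
#' (25 to < 30) and obese (>= 30). Boundaries belong to the heavier category,
#' so 18.5 is normal, 25 overweight and 30 obese.
#'
#' @param ppbmi Numeric vector of ppBMI values in kg/m^2. Must be positive and
#'   finite.
#' @return A factor with levels `underweight`, `normal`, `overweight`, `obese`.
#' @examples
#' who_category(c(18.4, 18.5, 24.9, 25, 31))
#' @export
who_category <- function(ppbmi) {
  if (!is.numeric(ppbmi)) rlang::abort("`ppbmi` must be numeric")
  bad <- !is.finite(ppbmi) | ppbmi <= 0
  if (any(bad)) {
    rlang::abort("`ppbmi` must be positive and finite")
  }
  cut(ppbmi,
    breaks = c(0, 18.5, 25, 30, Inf),
    labels = c("underweight", "normal", "overweight", "obese"),
    right = FALSE
  )
}

#' IOM 2009 gestational weight gain recommendations
#'
#' Returns the Institute of Medicine 2009 recommended total gestational
#' weight-gain ranges per WHO ppBMI category, together with the standard
#' first-trimester gain anchor (0.5 to 2 kg for every category) and the IOM
#' second/third-trimester weekly-rate ranges used by the rate projection mode.
#'
#' @return A tibble with one row per ppBMI category and columns `category`,
#'   `total_lo`, `total_hi` (kg at term), `t1_lo`, `t1_hi` (kg at the end of
#'   the first trimester) and `rate_lo`, `rate_hi` (kg/week after the first
#'   trimester).
#' @examples
#' iom_windows()
#' @export
iom_windows <- function() {
  tibble::tibble(
    category = factor(c("underweight", "normal", "overweight", "obese"),
      levels = c("underweight", "normal", "overweight", "obese")
    ),
    total_lo = c(12.5, 11.5, 7, 5),
    total_hi = c(18, 16, 11.5, 9),
    t1_lo = 0.5,
    t1_hi = 2,
    rate_lo = c(0.44, 0.35, 0.23, 0.17),
    rate_hi = c(0.58, 0.50, 0.33, 0.27)
  )
}

#' Project the IOM weight-gain window to a gestational age
#'
#' Compliance with the IOM recommendations is defined for total gain at term;
#' to judge a weight measured mid-pregnancy the window must be projected to
#' the gestational age of the measurement. Two projection modes are provided.
#' The default, `"interpolation"`, interpolates each bound linearly between the
#' first-trimester anchor (0.5 to 2 kg at week 13) and the recommended total
#' range at week 40, so it recovers the published total windows exactly at
#' term. The `"rate"` mode instead grows each bound from the first-trimester
#' anchor at the IOM second/third-trimester weekly rates.
#'
#' @param category Character or factor vector of WHO ppBMI categories
#'   (recycled against `ga_weeks`).
#' @param ga_weeks Gestational age in completed weeks, between 13 and 42.
#' @param mode Projection mode, `"interpolation"` (default) or `"rate"`.
#' @return A tibble with columns `lo` and `hi` in kg.
#' @examples
#' projected_window("normal", 40) # the published 11.5-16 kg window
#' projected_window("normal", 26.5) # mid-pregnancy projection
#' @export
projected_window <- function(category, ga_weeks,
                             mode = c("interpolation", "rate")) {
  mode <- match.arg(mode)
  if (!is.numeric(ga_weeks) || any(!is.finite(ga_weeks))) {
    rlang::abort("`ga_weeks` must be finite numeric")
  }
  if (any(ga_weeks < 13 | ga_weeks > 42)) {
    rlang::abort("`ga_weeks` must lie in [13, 42]")
  }
  category <- as.character(category)
  win <- iom_windows()
  idx <- match(category, as.character(win$category))
  if (anyNA(idx)) {
    rlang::abort("unknown ppBMI category; use who_category() labels")
  }
  n <- max(length(idx), length(ga_weeks))
  idx <- rep_len(idx, n)
  ga <- rep_len(ga_weeks, n)
  if (mode == "interpolation") {
    f <- (ga - 13) / 27
    lo <- win$t1_lo[idx] + (win$total_lo[idx] - win$t1_lo[idx]) * f
    hi <- win$t1_hi[idx] + (win$total_hi[idx] - win$t1_hi[idx]) * f
  } else {
    lo <- win$t1_lo[idx] + win$rate_lo[idx] * (ga - 13)
    hi <- win$t1_hi[idx] + win$rate_hi[idx] * (ga - 13)
  }
  tibble::tibble(lo = lo, hi = hi)
}

#' Classify an observed weight gain against the projected IOM window
#'
#' Labels each gain `L` (below), `N` (within) or `H` (above) the IOM window
#' projected to the gestational age of the measurement. Bounds are inclusive:
#' a gain exactly equal to either bound is within the recommendations.
#'
#' @param gain Observed weight gain in kg (visit weight minus pre-pregnancy
#'   weight).
#' @param category WHO ppBMI category (see [who_category()]).
#' @param ga_weeks Gestational age of the measurement in completed weeks.
#' @param mode Projection mode passed to [projected_window()].
#' @return A factor with levels `L`, `N`, `H` (ordered).
#' @examples
#' classify_gain(12, "normal", 28) # above the projected window
#' @export
classify_gain <- function(gain, category, ga_weeks,
                          mode = c("interpolation", "rate")) {
  win <- projected_window(category, ga_weeks, mode)
  n <- max(nrow(win), length(gain))
  gain <- rep_len(gain, n)
  lo <- rep_len(win$lo, n)
  hi <- rep_len(win$hi, n)
  lab <- ifelse(gain < lo, "L", ifelse(gain > hi, "H", "N"))
  factor(lab, levels = c("L", "N", "H"), ordered = TRUE)
}

trimester_of <- function(ga_weeks) {
  # completed weeks: T1 <= 13, T2 14-27, T3 >= 28
  dplyr::case_when(
    ga_weeks <= 13 ~ "T1",
    ga_weeks <= 27 ~ "T2",
    TRUE ~ "T3"
  )
}

#' Trimester-resolved IOM classification of a cohort
#'
#' Takes a cohort table in the wide per-woman schema (columns `id`,
#' `pre_pregnancy_weight`, `height` or `ppbmi`, and visit pairs `ga_t2`,
#' `wt_t2`, `ga_t3`, `wt_t3`; an optional `ga_t1`/`wt_t1` pair is ignored for
#' classification) and classifies the second- and third-trimester weight gains
#' against the IOM window projected to each visit's gestational age. Women
#' lacking a pre-pregnancy weight, a ppBMI, or a visit in the requested
#' trimester get an `NA` label for that trimester and are flagged in
#' `excluded` with a reason, mirroring the exclusion accounting of a study
#' flow chart.
#'
#' @param cohort A data frame, one row per woman (see [simulate_cohort()] for
#'   the canonical schema). Long visit tables can be reshaped first with
#'   [visits_to_wide()].
#' @param mode Projection mode passed to [projected_window()].
#' @return A tibble with one row per woman: `id`, `ppbmi`, `category`,
#'   per-trimester `ga_t2`, `gain_t2`, `lo_t2`, `hi_t2`, `class_t2` (and the
#'   `_t3` counterparts), `excluded`, `exclusion_reason` and the `mode` used.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 50, seed = 1))
#' classify_gwg(cohort)
#' @export
classify_gwg <- function(cohort, mode = c("interpolation", "rate")) {
  mode <- match.arg(mode)
  cohort <- tibble::as_tibble(cohort)
  if (!"id" %in% names(cohort)) rlang::abort("`cohort` must have an `id` column")
  ppbmi <- if ("ppbmi" %in% names(cohort)) {
    cohort$ppbmi
  } else if (all(c("pre_pregnancy_weight", "height") %in% names(cohort))) {
    cohort$pre_pregnancy_weight / cohort$height^2
  } else {
    rlang::abort("`cohort` needs `ppbmi` or `pre_pregnancy_weight` + `height`")
  }
  need <- c("pre_pregnancy_weight", "ga_t2", "wt_t2", "ga_t3", "wt_t3")
  missing_cols <- setdiff(need, names(cohort))
  for (m in missing_cols) cohort[[m]] <- NA_real_

  out <- tibble::tibble(
    id = cohort$id,
    ppbmi = ppbmi,
    category = factor(NA_character_,
      levels = c("underweight", "normal", "overweight", "obese")
    ),
    ga_t2 = cohort$ga_t2, gain_t2 = cohort$wt_t2 - cohort$pre_pregnancy_weight,
    lo_t2 = NA_real_, hi_t2 = NA_real_,
    class_t2 = factor(NA_character_, levels = c("L", "N", "H"), ordered = TRUE),
    ga_t3 = cohort$ga_t3, gain_t3 = cohort$wt_t3 - cohort$pre_pregnancy_weight,
    lo_t3 = NA_real_, hi_t3 = NA_real_,
    class_t3 = factor(NA_character_, levels = c("L", "N", "H"), ordered = TRUE)
  )
  ok_bmi <- is.finite(out$ppbmi) & out$ppbmi > 0
  out$category[ok_bmi] <- who_category(out$ppbmi[ok_bmi])

  for (tri in c("t2", "t3")) {
    ga <- out[[paste0("ga_", tri)]]
    gain <- out[[paste0("gain_", tri)]]
    usable <- ok_bmi & is.finite(ga) & is.finite(gain) & ga >= 13 & ga <= 42
    if (any(usable)) {
      win <- projected_window(out$category[usable], ga[usable], mode)
      out[[paste0("lo_", tri)]][usable] <- win$lo
      out[[paste0("hi_", tri)]][usable] <- win$hi
      out[[paste0("class_", tri)]][usable] <-
        classify_gain(gain[usable], out$category[usable], ga[usable], mode)
    }
  }

  out$exclusion_reason <- dplyr::case_when(
    !is.finite(out$ppbmi) ~ "missing ppBMI or pre-pregnancy weight",
    is.na(out$class_t2) & is.na(out$class_t3) ~ "no usable trimester weight",
    TRUE ~ NA_character_
  )
  out$excluded <- !is.na(out$exclusion_reason)
  out$mode <- mode
  out
}

#' Collapse a long visit table to one weight per trimester
#'
#' Picks, for each woman and trimester, the visit closest to delivery (the
#' latest gestational age), giving the wide `ga_t1/wt_t1 ... ga_t3/wt_t3`
#' schema used by [classify_gwg()].
#'
#' @param visits A data frame with columns `id`, `ga_weeks`, `weight_kg`.
#' @return A tibble, one row per `id`.
#' @export
visits_to_wide <- function(visits) {
  visits |>
    tibble::as_tibble() |>
    dplyr::mutate(trimester = trimester_of(.data$ga_weeks)) |>
    dplyr::group_by(.data$id, .data$trimester) |>
    dplyr::slice_max(.data$ga_weeks, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      id_cols = "id",
      names_from = "trimester",
      values_from = c("ga_weeks", "weight_kg"),
      names_glue = "{c(ga_weeks = 'ga', weight_kg = 'wt')[.value]}_{tolower(trimester)}"
    )
}

#' Second-to-third trimester IOM transition table
#'
#' Cross-tabulates the T2 and T3 IOM labels (L/N/H) of women with both
#' classifications and summarises the clinically relevant strata: among women
#' above the recommendations in T2 (T2H), the split between those who stayed
#' above in T3 and those who normalised (T3N or T3L); and likewise among
#' T2N women, the split between those who stayed within/below and those who
#' moved above. Stratum percentages are reported both of the stratum's row
#' total and of the grand total.
#'
#' @param class_t2,class_t3 Vectors of per-woman labels in `L`/`N`/`H` (women
#'   with either label missing are dropped), or `class_t2` may be a
#'   classification tibble from [classify_gwg()] (then `class_t3` is ignored).
#' @return An object of class `gwg_transitions`: a list with `counts` (3x3
#'   integer matrix, rows = T2, cols = T3), `n`, and `strata`, a tibble with
#'   columns `stratum`, `count`, `row_total`, `pct_of_row`, `pct_of_total`.
#' @examples
#' cls <- classify_gwg(simulate_cohort(sim_config(n_subjects = 200, seed = 1)))
#' gwg_transitions(cls)
#' @export
gwg_transitions <- function(class_t2, class_t3 = NULL) {
  if (is.data.frame(class_t2)) {
    class_t3 <- class_t2$class_t3
    class_t2 <- class_t2$class_t2
  }
  lv <- c("L", "N", "H")
  t2 <- factor(as.character(class_t2), levels = lv)
  t3 <- factor(as.character(class_t3), levels = lv)
  keep <- !is.na(t2) & !is.na(t3)
  counts <- table(T2 = t2[keep], T3 = t3[keep])
  counts <- matrix(as.integer(counts), 3, 3,
    dimnames = list(T2 = lv, T3 = lv)
  )
  transitions_from_counts(counts)
}

#' Build the transition summary from a 3x3 count matrix
#'
#' Same summary as [gwg_transitions()] but starting from already-tabulated
#' counts (rows = T2 label, columns = T3 label, both ordered L, N, H), e.g.
#' counts published in a report.
#'
#' @param counts A 3x3 numeric matrix of T2-by-T3 counts.
#' @return A `gwg_transitions` object; see [gwg_transitions()].
#' @export
transitions_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0)) {
    rlang::abort("`counts` must be a non-negative 3x3 matrix (L/N/H by L/N/H)")
  }
  dimnames(counts) <- list(T2 = c("L", "N", "H"), T3 = c("L", "N", "H"))
  n <- sum(counts)
  pct <- function(num, den) {
    den <- rep_len(den, length(num))
    ifelse(den > 0, 100 * num / den, NA_real_)
  }
  row_tot <- rowSums(counts)
  strata <- tibble::tibble(
    stratum = c(
      "T2H & T3H", "T2H & (T3N|T3L)",
      "T2N & (T3N|T3L)", "T2N & T3H"
    ),
    count = c(
      counts["H", "H"], counts["H", "N"] + counts["H", "L"],
      counts["N", "N"] + counts["N", "L"], counts["N", "H"]
    ),
    row_total = unname(c(row_tot["H"], row_tot["H"], row_tot["N"], row_tot["N"])),
    pct_of_row = pct(.data$count, .data$row_total),
    pct_of_total = pct(.data$count, n)
  )
  structure(list(counts = counts, n = n, strata = strata),
    class = "gwg_transitions"
  )
}

#' @export
print.gwg_transitions <- function(x, ...) {
  cat("IOM T2 -> T3 transition table (n =", x$n, ")\n\n")
  print(x$counts)
  cat("\nStrata:\n")
  print(as.data.frame(x$strata), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gwg_transitions <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$counts), responseName = "count"))
}

#' Gestational diabetes from glucose screening values
#'
#' Applies the two-step screening rule: a 50 g glucose challenge test (GCT)
#' result of at least 10.3 mmol/L is diagnostic on its own; a GCT between 7.8
#' and 10.2 mmol/L triggers a 75 g oral glucose tolerance test (OGTT), and the
#' diagnosis is made if any OGTT value meets its threshold (5.3 mmol/L
#' fasting, 10.6 at 1 h, 9 at 2 h). A GCT below 7.8 is negative without an
#' OGTT. When the GCT is in the OGTT-triggering band but no OGTT values are
#' supplied the status is indeterminate (`NA`), not negative.
#'
#' @param gct Numeric vector of GCT results in mmol/L.
#' @param ogtt_0h,ogtt_1h,ogtt_2h Optional OGTT values in mmol/L (fasting,
#'   1 hour, 2 hours), recycled against `gct`.
#' @return A logical vector (`NA` = indeterminate, OGTT needed but missing).
#' @examples
#' gdm_from_glucose(c(7.7, 10.3, 8.0), ogtt_0h = c(NA, NA, 5.3))
#' @export
gdm_from_glucose <- function(gct, ogtt_0h = NULL, ogtt_1h = NULL,
                             ogtt_2h = NULL) {
  if (!is.numeric(gct) || any(!is.finite(gct))) {
    rlang::abort("`gct` must be finite numeric")
  }
  n <- length(gct)
  o0 <- rep_len(ogtt_0h %||% NA_real_, n)
  o1 <- rep_len(ogtt_1h %||% NA_real_, n)
  o2 <- rep_len(ogtt_2h %||% NA_real_, n)
  ogtt_pos <- (!is.na(o0) & o0 >= 5.3) |
    (!is.na(o1) & o1 >= 10.6) |
    (!is.na(o2) & o2 >= 9)
  ogtt_any <- !is.na(o0) | !is.na(o1) | !is.na(o2)

  out <- rep(FALSE, n)
  out[gct >= 10.3] <- TRUE
  band <- gct >= 7.8 & gct <= 10.2
  out[band & ogtt_any & ogtt_pos] <- TRUE
  out[band & ogtt_any & !ogtt_pos] <- FALSE
  out[band & !ogtt_any] <- NA
  out
}
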
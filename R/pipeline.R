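#' Configuration of the full analysis pipeline
#'
#' Exactly one of `input` (path to a cohort CSV in the canonical wide schema)
#' or `simulation` (a [sim_config()], from which a cohort is generated) must
#' be given.
#'
#' @param input Path to a cohort CSV, or `NULL`.
#' @param simulation A [sim_config()], or `NULL`.
#' @param mode IOM projection mode passed to [classify_gwg()].
#' @param j_range,order_range GBTM sweep ranges for [select_gbtm()].
#' @param n_starts Restarts per GBTM fit.
#' @param outcomes Outcome columns to analyse.
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            mode = c("interpolation", "rate"),
                            j_range = 1:4, order_range = 1, n_starts = 3,
                            outcomes = c(
                              "gdm", "hdp", "caesarean", "macrosomia",
                              "sga", "lga", "hypoglycemia"
                            ),
                            seed = 1L) {
  if (is.null(input) == is.null(simulation)) {
    rlang::abort("give exactly one of `input` or `simulation`")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    rlang::abort("`simulation` must come from sim_config()")
  }
  structure(
    list(
      input = input, simulation = simulation, mode = match.arg(mode),
      j_range = j_range, order_range = order_range, n_starts = n_starts,
      outcomes = outcomes, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the end-to-end weight-gain analysis
#'
#' Orchestrates the full analysis: load or simulate the cohort, account for
#' exclusions (missing ppBMI or usable trimester weights), classify weight
#' gain against the IOM recommendations in both trimesters, build the T2-T3
#' transition table, fit the trajectory mixture with BIC selection over the
#' configured sweep, and estimate unadjusted and adjusted relative risks for
#' every outcome against four exposures: ppBMI category, T2 IOM class, T3 IOM
#' class, and trajectory profile. The same config and seed always produce an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `study_report` with elements `exclusions`,
#'   `cohort_summary`, `iom_summary`, `transitions`, `profiles`,
#'   `gbtm` (the selection object), `adequacy`, `slopes`, `risks` (one tibble
#'   per exposure), `trend` and `provenance`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   simulation = sim_config(n_subjects = 400, seed = 5),
#'   j_range = 1:3, seed = 5
#' )
#' report <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    rlang::abort("`config` must come from pipeline_config()")
  }
  cohort <- if (!is.null(config$input)) {
    read_cohort_csv(config$input)
  } else {
    simulate_cohort(config$simulation, seed = config$seed)
  }
  validate_cohort(cohort)

  # exclusion accounting first
  cls <- classify_gwg(cohort, mode = config$mode)
  exclusions <- cls |>
    dplyr::filter(.data$excluded) |>
    dplyr::count(.data$exclusion_reason, name = "n")
  analysed <- cohort |>
    dplyr::semi_join(dplyr::filter(cls, !.data$excluded), by = "id") |>
    dplyr::left_join(
      dplyr::select(cls, "id", "category", "class_t2", "class_t3"),
      by = "id"
    )

  cohort_summary <- analysed |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_age = mean(.data$age),
      dplyr::across(
        dplyr::any_of(config$outcomes), ~ 100 * mean(.x, na.rm = TRUE),
        .names = "pct_{.col}"
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n), .after = "n")

  iom_summary <- purrr::map_dfr(c("class_t2", "class_t3"), function(cc) {
    analysed |>
      dplyr::filter(!is.na(.data[[cc]])) |>
      dplyr::group_by(class = .data[[cc]]) |>
      dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        trimester = toupper(sub("class_", "", cc)),
        pct = 100 * .data$n / sum(.data$n),
        .before = 1
      )
  })

  transitions <- gwg_transitions(cls)

  long <- cohort_to_long(analysed)
  sel <- select_gbtm(long,
    j_range = config$j_range, order_range = config$order_range,
    n_starts = config$n_starts, seed = config$seed
  )
  fitj <- sel$best
  analysed$profile <- factor(
    paste0("G", fitj$assignment[analysed$id]),
    levels = paste0("G", seq_len(fitj$spec$j))
  )

  profiles <- analysed |>
    dplyr::group_by(.data$profile) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ppbmi = mean(.data$ppbmi),
      sd_ppbmi = stats::sd(.data$ppbmi),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n), .after = "n")

  risks <- list(
    ppbmi = risk_table(
      dplyr::mutate(analysed, bmi_cat = .data$category),
      "bmi_cat", config$outcomes,
      reference = "normal"
    ),
    iom_t2 = risk_table(
      dplyr::filter(analysed, !is.na(.data$class_t2)),
      "class_t2", config$outcomes,
      reference = "N"
    ),
    iom_t3 = risk_table(
      dplyr::filter(analysed, !is.na(.data$class_t3)),
      "class_t3", config$outcomes,
      reference = "N"
    ),
    profile = risk_table(analysed, "profile", config$outcomes,
      reference = "G1"
    )
  )

  trend <- purrr::map_dfr(config$outcomes, function(oc) {
    tab <- analysed |>
      dplyr::filter(!is.na(.data[[oc]])) |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(
        events = sum(.data[[oc]]), n = dplyr::n(), .groups = "drop"
      )
    dplyr::mutate(
      trend_test(tab$events, tab$n, labels = as.character(tab$category)),
      outcome = oc, .before = 1
    )
  })

  slopes <- if (fitj$spec$order >= 1) trajectory_slopes(fitj) else NULL

  provenance <- list(
    seed = config$seed,
    mode = config$mode,
    n_input = nrow(cohort),
    n_analysed = nrow(analysed),
    package_version = as.character(utils::packageVersion("gwgtraj")),
    config_hash = rlang::hash(config)
  )

  structure(
    list(
      exclusions = exclusions,
      cohort_summary = cohort_summary,
      iom_summary = iom_summary,
      transitions = transitions,
      profiles = profiles,
      gbtm = sel,
      adequacy = gbtm_adequacy(fitj),
      slopes = slopes,
      risks = risks,
      trend = trend,
      provenance = provenance
    ),
    class = "study_report"
  )
}

validate_cohort <- function(cohort) {
  need <- c("id", "pre_pregnancy_weight")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "cohort schema violation; missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(cohort$id)) rlang::abort("duplicate `id` values")
  invisible(cohort)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (n analysed =", x$provenance$n_analysed, ")\n\n")
  cat("ppBMI categories:\n")
  print(as.data.frame(x$cohort_summary[, c("category", "n", "pct")]),
    row.names = FALSE, digits = 3
  )
  cat("\nIOM compliance:\n")
  print(as.data.frame(x$iom_summary), row.names = FALSE, digits = 3)
  cat("\nTrajectory profiles:\n")
  print(as.data.frame(x$profiles), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits a machine-readable JSON report plus one CSV per table (cohort
#' summary, IOM compliance, transition strata, profiles, risk tables, trend
#' tests), all recomputable from the emitted counts.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tbls <- list(
    exclusions = report$exclusions,
    cohort_summary = report$cohort_summary,
    iom_summary = report$iom_summary,
    transition_strata = report$transitions$strata,
    profiles = report$profiles,
    adequacy = report$adequacy,
    gbtm_sweep = report$gbtm$sweep,
    trend = dplyr::mutate(report$trend,
      ordering = purrr::map_chr(.data$ordering, paste, collapse = "|")
    )
  )
  for (nm in names(report$risks)) {
    tbls[[paste0("risks_", nm)]] <- dplyr::mutate(report$risks[[nm]],
      covariates = purrr::map_chr(.data$covariates, paste, collapse = "|")
    )
  }
  for (nm in names(tbls)) {
    utils::write.csv(tbls[[nm]], file.path(dir, paste0(nm, ".csv")),
      row.names = FALSE
    )
  }
  json <- c(
    tbls,
    list(
      transition_counts = report$transitions$counts,
      slopes = if (!is.null(report$slopes)) report$slopes$slopes,
      provenance = report$provenance
    )
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(dir)
}
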
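#' Cochran-Armitage test for trend in proportions
#'
#' Tests for a monotone trend in event proportions across ordered groups
#' using the Cochran-Armitage statistic with equally spaced scores (the
#' standard reading of a "continuity across categories" column in an
#' epidemiological table). The signed z statistic is reported — positive when
#' proportions rise along the given order — with a two-sided Normal p-value;
#' the squared statistic equals the chi-squared form used by
#' [stats::prop.trend.test()].
#'
#' @param events Event counts per group, in the tested order.
#' @param n Totals per group (all positive).
#' @param labels Optional group labels recorded in the result.
#' @param scores Group scores; default equally spaced `1:k`.
#' @return A one-row tibble: `statistic` (signed z), `p.value`, `test`,
#'   `ordering` (list-column of labels).
#' @examples
#' trend_test(c(16, 198, 118, 142), c(344, 4045, 1351, 811))
#' @export
trend_test <- function(events, n, labels = NULL, scores = seq_along(events)) {
  if (length(events) < 3) rlang::abort("need at least 3 ordered groups")
  if (length(n) != length(events) || any(n <= 0)) {
    rlang::abort("`n` must be positive with one total per group")
  }
  if (any(events < 0 | events > n)) rlang::abort("invalid event counts")
  labels <- labels %||% paste0("g", seq_along(events))
  nn <- sum(n)
  pbar <- sum(events) / nn
  sbar <- sum(n * scores) / nn
  num <- sum(events * (scores - sbar))
  den <- sqrt(pbar * (1 - pbar) * sum(n * (scores - sbar)^2))
  z <- if (den > 0) num / den else 0
  tibble::tibble(
    statistic = z,
    p.value = 2 * stats::pnorm(-abs(z)),
    test = "Cochran-Armitage trend",
    ordering = list(labels)
  )
}

#' Compare a continuous variable between groups with assumption gating
#'
#' Chooses the omnibus test the way applied analyses commonly do: residual
#' normality is screened with Shapiro-Wilk and variance homogeneity with
#' Bartlett's test (both at `alpha`); if both pass, one-way ANOVA with
#' Tukey-Kramer (Tukey HSD on the possibly unbalanced design) post-hoc
#' contrasts is used, otherwise Kruskal-Wallis with Dunn's rank-based
#' pairwise z-tests (p-values multiplicity-adjusted). A group with constant
#' values makes Bartlett's statistic undefined, and the comparison falls
#' through to the Kruskal-Wallis branch with a flag.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the measurement and grouping
#'   variable.
#' @param alpha Gate level for the assumption screens (default 0.05).
#' @param p_adjust Adjustment method for Dunn p-values (default
#'   `"bonferroni"`, matching the classical procedure).
#' @return A list of class `group_comparison`: `omnibus` (one-row tibble:
#'   test, statistic, p.value, shapiro_p, bartlett_p, gated_reason),
#'   `posthoc` (pairwise tibble), `method`.
#' @export
compare_continuous <- function(data, value, group, alpha = 0.05,
                               p_adjust = "bonferroni") {
  d <- tibble::tibble(
    y = data[[value]],
    g = factor(data[[group]])
  ) |>
    tidyr::drop_na()
  if (dplyr::n_distinct(d$g) < 2 || any(table(d$g) < 2)) {
    rlang::abort("need >= 2 groups with >= 2 values each")
  }
  constant_group <- any(tapply(d$y, d$g, stats::sd) == 0)
  shapiro_p <- NA_real_
  bartlett_p <- NA_real_
  if (!constant_group) {
    res <- stats::residuals(stats::lm(y ~ g, data = d))
    samp <- if (length(res) > 5000) sample(res, 5000) else res
    shapiro_p <- stats::shapiro.test(samp)$p.value
    bartlett_p <- stats::bartlett.test(y ~ g, data = d)$p.value
  }
  use_anova <- !constant_group &&
    shapiro_p >= alpha && bartlett_p >= alpha
  if (use_anova) {
    av <- stats::aov(y ~ g, data = d)
    sm <- summary(av)[[1]]
    omnibus <- tibble::tibble(
      test = "ANOVA",
      statistic = sm$`F value`[1],
      p.value = sm$`Pr(>F)`[1],
      shapiro_p = shapiro_p, bartlett_p = bartlett_p,
      gated_reason = NA_character_
    )
    tk <- stats::TukeyHSD(av)$g
    posthoc <- tibble::tibble(
      contrast = rownames(tk),
      estimate = tk[, "diff"],
      conf.low = tk[, "lwr"],
      conf.high = tk[, "upr"],
      p.adj = tk[, "p adj"],
      method = "Tukey-Kramer"
    )
  } else {
    kw <- stats::kruskal.test(y ~ g, data = d)
    omnibus <- tibble::tibble(
      test = "Kruskal-Wallis",
      statistic = unname(kw$statistic),
      p.value = kw$p.value,
      shapiro_p = shapiro_p, bartlett_p = bartlett_p,
      gated_reason = if (constant_group) {
        "constant-valued group (Bartlett undefined)"
      } else if (shapiro_p < alpha) {
        "non-normal residuals"
      } else {
        "heteroscedastic"
      }
    )
    posthoc <- dunn_test(d$y, d$g, p_adjust)
  }
  structure(
    list(omnibus = omnibus, posthoc = posthoc, method = omnibus$test),
    class = "group_comparison"
  )
}

# Dunn's pairwise rank-sum z tests after Kruskal-Wallis, with tie correction
dunn_test <- function(y, g, p_adjust = "bonferroni") {
  n <- length(y)
  r <- rank(y)
  ties <- table(y)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(length(lv), 2)
  diff <- mr[pairs[1, ]] - mr[pairs[2, ]]
  se <- sqrt(
    (n * (n + 1) / 12) * tie_corr * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])
  )
  z <- as.numeric(diff / se)
  tibble::tibble(
    contrast = paste(lv[pairs[2, ]], lv[pairs[1, ]], sep = "-"),
    estimate = -as.numeric(diff),
    conf.low = NA_real_,
    conf.high = NA_real_,
    p.adj = stats::p.adjust(2 * stats::pnorm(-abs(z)), method = p_adjust),
    method = "Dunn"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison:", x$method, "\n")
  print(as.data.frame(x$omnibus), row.names = FALSE, digits = 4)
  cat("\nPost-hoc:\n")
  print(as.data.frame(x$posthoc), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare proportions between groups with a Marascuillo post-hoc
#'
#' Omnibus comparison of a contingency table by Pearson's chi-squared test,
#' falling back to Fisher's exact test when any expected cell count is below
#' 5. For a groups-by-(event, non-event) table, the Marascuillo procedure
#' then flags every pair of groups whose absolute difference in proportions
#' exceeds its critical range
#' `sqrt(chisq(k-1, 0.95)) * sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)`.
#'
#' @param counts A matrix of non-negative counts; for the Marascuillo report,
#'   rows are groups and the two columns are event / non-event counts.
#' @param conf Family confidence level for the Marascuillo critical ranges.
#' @return A list of class `categorical_comparison`: `omnibus` (tibble:
#'   test, statistic, p.value) and `marascuillo` (pairwise tibble, `NULL`
#'   when the table is not groups-by-2).
#' @examples
#' compare_categorical(cbind(events = c(20, 10), rest = c(80, 90)))
#' @export
compare_categorical <- function(counts, conf = 0.95) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) rlang::abort("counts must be non-negative")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    omnibus <- tibble::tibble(
      test = "chi-squared",
      statistic = unname(ct$statistic),
      p.value = ct$p.value
    )
  } else {
    ft <- stats::fisher.test(counts,
      simulate.p.value = prod(dim(counts)) > 10
    )
    omnibus <- tibble::tibble(
      test = "Fisher exact",
      statistic = NA_real_,
      p.value = ft$p.value
    )
  }
  marascuillo <- NULL
  if (ncol(counts) == 2 && nrow(counts) >= 2) {
    k <- nrow(counts)
    n_i <- rowSums(counts)
    p_i <- counts[, 1] / n_i
    crit_base <- sqrt(stats::qchisq(conf, df = k - 1))
    pairs <- utils::combn(k, 2)
    lv <- rownames(counts) %||% paste0("g", seq_len(k))
    i <- pairs[1, ]; jx <- pairs[2, ]
    range_ij <- crit_base * sqrt(
      p_i[i] * (1 - p_i[i]) / n_i[i] + p_i[jx] * (1 - p_i[jx]) / n_i[jx]
    )
    marascuillo <- tibble::tibble(
      group1 = lv[i], group2 = lv[jx],
      difference = abs(p_i[i] - p_i[jx]),
      critical_range = range_ij,
      significant = difference > critical_range
    )
  }
  structure(list(omnibus = omnibus, marascuillo = marascuillo),
    class = "categorical_comparison"
  )
}

#' @export
print.categorical_comparison <- function(x, ...) {
  print(as.data.frame(x$omnibus), row.names = FALSE, digits = 4)
  if (!is.null(x$marascuillo)) {
    cat("\nMarascuillo pairwise comparisons:\n")
    print(as.data.frame(x$marascuillo), row.names = FALSE, digits = 4)
  }
  invisible(x)
}
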
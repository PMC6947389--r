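#' Group-based trajectory modelling of gestational weight
#'
#' Fits a finite Gaussian mixture of group-specific polynomial mean curves to
#' longitudinal weight data: conditional on latent group `j`, a woman's
#' weights at her visit times are independent Normals centred on the group
#' polynomial with residual SD `sigma`. Estimation is by maximum likelihood
#' via EM (E-step: posterior group responsibilities; M-step:
#' responsibility-weighted polynomial least squares, mixing proportions as
#' mean responsibilities), initialised by k-means on per-subject
#' (level, slope) summaries, with multiple restarts and the best attained
#' log-likelihood kept. An optional quasi-Newton polish refines the EM
#' solution. Groups are relabelled into a canonical order of ascending fitted
#' mean weight at mid-gestation (week 20), making output invariant to label
#' switching.
#'
#' @param data Long tibble with columns `id`, `ga_weeks`, `weight_kg` (use
#'   [cohort_to_long()] to build it from a wide cohort).
#' @param j Number of latent groups (>= 1).
#' @param order Polynomial degree of the mean curves (0 = flat, 1 = linear,
#'   ...). Default 1.
#' @param variance_mode `"shared"` (one residual SD, default — fewer
#'   degeneracies) or `"per_group"`.
#' @param n_starts Number of random restarts (default 10).
#' @param seed Integer seed for the restart stream; same data + seed gives an
#'   identical fit.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @param polish Run a quasi-Newton (`optim` BFGS) refinement of the best EM
#'   solution? Default `FALSE` (EM alone converges tightly at `tol = 1e-8`).
#' @return An object of class `gbtm_fit`: mixing proportions `pi`, coefficient
#'   matrix `beta` ((order+1) x J), residual SD(s) `sigma`, `loglik`, `bic`,
#'   posterior membership matrix, modal `assignment`, per-group Wald
#'   covariance of the coefficients, adequacy `diagnostics`, convergence and
#'   degeneracy flags, and the log-likelihood trace of the winning start.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 300, seed = 2))
#' fit <- fit_gbtm(cohort_to_long(cohort), j = 3, seed = 2, n_starts = 3)
#' glance(fit)
#' @export
fit_gbtm <- function(data, j, order = 1,
                     variance_mode = c("shared", "per_group"),
                     n_starts = 10, seed = NULL, tol = 1e-8,
                     max_iter = 500, polish = FALSE) {
  variance_mode <- match.arg(variance_mode)
  stop_if_not_scalar_count(j, "j")
  if (order < 0 || order != floor(order)) {
    rlang::abort("`order` must be a non-negative integer")
  }
  d <- gbtm_prepare(data)
  if (d$n_subjects <= j * (order + 2)) {
    rlang::abort("too few subjects for the requested number of groups/order")
  }

  local_seed(seed, {
    best <- NULL
    for (s in seq_len(max(1L, n_starts))) {
      init <- gbtm_init(d, j, order, jitter = s > 1)
      fit <- gbtm_em(d, j, order, variance_mode, init, tol, max_iter)
      if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (polish) best <- gbtm_polish(d, j, order, variance_mode, best, tol)
    gbtm_finalize(d, j, order, variance_mode, best)
  })
}

# ---- internal machinery ----------------------------------------------------

gbtm_prepare <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("id", "ga_weeks", "weight_kg")
  if (!all(need %in% names(data))) {
    rlang::abort("`data` must have columns id, ga_weeks, weight_kg")
  }
  data <- dplyr::filter(
    data,
    is.finite(.data$ga_weeks), is.finite(.data$weight_kg)
  )
  if (nrow(data) == 0) rlang::abort("no usable observations")
  ids <- unique(data$id)
  subj <- match(data$id, ids)
  list(
    t = data$ga_weeks, y = data$weight_kg, subj = subj,
    ids = ids, n_subjects = length(ids), n_obs = nrow(data)
  )
}

design_matrix <- function(t, order) {
  outer(t, 0:order, `^`)
}

# per-subject (level, slope) summaries for initialisation
subject_summaries <- function(d) {
  lev <- as.vector(rowsum(d$y, d$subj) / tabulate(d$subj))
  tc <- d$t - ave(d$t, d$subj)
  yc <- d$y - lev[d$subj]
  num <- as.vector(rowsum(tc * yc, d$subj))
  den <- as.vector(rowsum(tc * tc, d$subj))
  slope <- ifelse(den > 0, num / pmax(den, 1e-12), 0)
  cbind(level = lev, slope = slope)
}

gbtm_init <- function(d, j, order, jitter = FALSE) {
  if (j == 1L) return(matrix(1, d$n_subjects, 1))
  sm <- subject_summaries(d)
  sm <- scale(sm)
  sm[!is.finite(sm)] <- 0
  cl <- tryCatch(
    stats::kmeans(sm, centers = j, nstart = 10, iter.max = 50)$cluster,
    error = function(e) sample.int(j, d$n_subjects, replace = TRUE)
  )
  if (jitter) {
    flip <- sample.int(d$n_subjects, max(1L, d$n_subjects %/% 20))
    cl[flip] <- sample.int(j, length(flip), replace = TRUE)
  }
  r <- matrix(0.05 / max(1, j - 1), d$n_subjects, j)
  r[cbind(seq_len(d$n_subjects), cl)] <- 0.95
  r / rowSums(r)
}

# M-step given responsibilities; returns pi, beta, sigma
gbtm_mstep <- function(d, j, order, variance_mode, r) {
  x <- design_matrix(d$t, order)
  p <- order + 1L
  beta <- matrix(0, p, j)
  rss <- numeric(j)
  wsum <- numeric(j)
  for (g in seq_len(j)) {
    w <- r[d$subj, g]
    xw <- x * w
    beta[, g] <- tryCatch(
      solve(crossprod(xw, x), crossprod(xw, d$y)),
      error = function(e) {
        stats::qr.solve(crossprod(xw, x) + diag(1e-8, p), crossprod(xw, d$y))
      }
    )
    res <- d$y - x %*% beta[, g]
    rss[g] <- sum(w * res^2)
    wsum[g] <- sum(w)
  }
  sigma <- if (variance_mode == "shared") {
    sqrt(sum(rss) / d$n_obs)
  } else {
    sqrt(rss / pmax(wsum, 1e-12))
  }
  sigma <- pmax(sigma, 1e-6)
  list(pi = pmax(colMeans(r), 1e-12), beta = beta, sigma = sigma)
}

# subject-by-group conditional log density matrix
gbtm_logdens <- function(d, j, order, beta, sigma) {
  x <- design_matrix(d$t, order)
  sig <- rep_len(sigma, j)
  l <- matrix(0, d$n_subjects, j)
  for (g in seq_len(j)) {
    ld <- stats::dnorm(d$y, x %*% beta[, g], sig[g], log = TRUE)
    l[, g] <- as.vector(rowsum(ld, d$subj))
  }
  l
}

gbtm_em <- function(d, j, order, variance_mode, r, tol, max_iter) {
  params <- gbtm_mstep(d, j, order, variance_mode, r)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    l <- gbtm_logdens(d, j, order, params$beta, params$sigma)
    a <- sweep(l, 2, log(params$pi), `+`)
    lse <- row_logsumexp(a)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
      abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- exp(a - lse)
    params <- gbtm_mstep(d, j, order, variance_mode, r)
  }
  l <- gbtm_logdens(d, j, order, params$beta, params$sigma)
  a <- sweep(l, 2, log(params$pi), `+`)
  lse <- row_logsumexp(a)
  list(
    pi = params$pi, beta = params$beta, sigma = params$sigma,
    loglik = sum(lse), posterior = exp(a - lse),
    trace = trace, converged = converged
  )
}

# free-parameter packing for the quasi-Newton polish
gbtm_pack <- function(pi, beta, sigma, j) {
  c(if (j > 1) log(pi[-1] / pi[1]), as.vector(beta), log(sigma))
}

gbtm_unpack <- function(theta, j, order, variance_mode) {
  p <- order + 1L
  i <- 0L
  if (j > 1) {
    a <- c(0, theta[seq_len(j - 1)])
    i <- j - 1L
    pi <- exp(a) / sum(exp(a))
  } else {
    pi <- 1
  }
  beta <- matrix(theta[i + seq_len(p * j)], p, j)
  i <- i + p * j
  sigma <- exp(theta[(i + 1):length(theta)])
  list(pi = pi, beta = beta, sigma = sigma)
}

gbtm_polish <- function(d, j, order, variance_mode, fit, tol) {
  nll <- function(theta) {
    p <- gbtm_unpack(theta, j, order, variance_mode)
    l <- gbtm_logdens(d, j, order, p$beta, p$sigma)
    -sum(row_logsumexp(sweep(l, 2, log(p$pi), `+`)))
  }
  theta0 <- gbtm_pack(fit$pi, fit$beta, fit$sigma, j)
  opt <- tryCatch(
    stats::optim(theta0, nll, method = "BFGS",
      control = list(maxit = 200, reltol = tol)
    ),
    error = function(e) NULL
  )
  if (is.null(opt) || -opt$value <= fit$loglik) return(fit)
  p <- gbtm_unpack(opt$par, j, order, variance_mode)
  l <- gbtm_logdens(d, j, order, p$beta, p$sigma)
  a <- sweep(l, 2, log(p$pi), `+`)
  lse <- row_logsumexp(a)
  list(
    pi = p$pi, beta = p$beta, sigma = p$sigma, loglik = sum(lse),
    posterior = exp(a - lse), trace = c(fit$trace, sum(lse)),
    converged = fit$converged
  )
}

gbtm_finalize <- function(d, j, order, variance_mode, fit) {
  # canonical order: ascending fitted mean weight at week 20
  mid <- as.vector(t(20^(0:order)) %*% fit$beta)
  ord <- order(mid)
  pi <- fit$pi[ord]
  beta <- fit$beta[, ord, drop = FALSE]
  sigma <- if (length(fit$sigma) > 1) fit$sigma[ord] else fit$sigma
  posterior <- fit$posterior[, ord, drop = FALSE]
  rownames(posterior) <- as.character(d$ids)
  colnames(posterior) <- paste0("G", seq_len(j))
  assignment <- max.col(posterior, ties.method = "first")
  names(assignment) <- as.character(d$ids)

  # responsibility-weighted Wald covariance of each group's coefficients
  x <- design_matrix(d$t, order)
  sig <- rep_len(sigma, j)
  cov_beta <- lapply(seq_len(j), function(g) {
    w <- posterior[d$subj, g]
    xtx <- crossprod(x * w, x)
    sig[g]^2 * tryCatch(solve(xtx), error = function(e) {
      solve(xtx + diag(1e-8, order + 1L))
    })
  })

  k <- (j - 1) + j * (order + 1) +
    if (variance_mode == "shared") 1L else j
  bic <- -2 * fit$loglik + k * log(d$n_subjects)

  diagnostics <- tibble::tibble(
    group = paste0("G", seq_len(j)),
    n_assigned = tabulate(assignment, j),
    observed_share = tabulate(assignment, j) / d$n_subjects,
    expected_share = unname(colMeans(posterior)),
    mean_posterior = vapply(seq_len(j), function(g) {
      m <- assignment == g
      if (any(m)) mean(posterior[m, g]) else NA_real_
    }, numeric(1)),
    adequate = NA
  )
  diagnostics$adequate <- !is.na(diagnostics$mean_posterior) &
    diagnostics$mean_posterior >= 0.70

  structure(
    list(
      spec = list(j = j, order = order, variance_mode = variance_mode),
      pi = pi, beta = beta, sigma = sigma,
      loglik = fit$loglik, k = k, bic = bic,
      n_subjects = d$n_subjects, n_obs = d$n_obs,
      posterior = posterior, assignment = assignment,
      cov_beta = cov_beta, diagnostics = diagnostics,
      degenerate = any(pi < 1 / d$n_subjects),
      converged = fit$converged,
      loglik_trace = fit$trace,
      time_range = range(d$t)
    ),
    class = "gbtm_fit"
  )
}

#' Mixture log-likelihood of a trajectory model
#'
#' Evaluates the observed-data log-likelihood
#' `sum_i log sum_j pi_j prod_t Normal(y_it; poly_j(t_it), sigma_j)` at fixed
#' parameters; mainly useful for testing and for comparing parameter sets.
#'
#' @param data Long tibble (`id`, `ga_weeks`, `weight_kg`).
#' @param pi Mixing proportions (summing to 1).
#' @param beta Coefficient matrix, one column per group (a vector is taken as
#'   a single column).
#' @param sigma Residual SD(s), positive; recycled across groups.
#' @return The log-likelihood (scalar).
#' @export
gbtm_loglik <- function(data, pi, beta, sigma) {
  beta <- as.matrix(beta)
  j <- ncol(beta)
  if (length(pi) != j || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    rlang::abort("`pi` must be a probability vector with one entry per group")
  }
  if (any(sigma <= 0)) rlang::abort("`sigma` must be positive")
  d <- gbtm_prepare(data)
  l <- gbtm_logdens(d, j, nrow(beta) - 1L, beta, rep_len(sigma, j))
  sum(row_logsumexp(sweep(l, 2, log(pi), `+`)))
}

#' BIC sweep over numbers of groups and polynomial orders
#'
#' Fits every combination in `j_range` x `order_range` and returns the fit
#' minimising `BIC = -2 logL + k log(n_subjects)` (equivalent in ranking to
#' the maximised Schwarz form), together with the full sweep table.
#' Degenerate fits (an effectively empty group) are excluded from selection;
#' if every fit is degenerate an error carries the sweep table.
#'
#' @inheritParams fit_gbtm
#' @param j_range Candidate numbers of groups.
#' @param order_range Candidate polynomial degrees.
#' @param ... Passed on to [fit_gbtm()].
#' @return A list of class `gbtm_selection` with elements `best` (a
#'   `gbtm_fit`) and `sweep` (tibble: j, order, loglik, k, bic, converged,
#'   degenerate, selected).
#' @export
select_gbtm <- function(data, j_range = 1:5, order_range = 1, seed = NULL,
                        ...) {
  grid <- tidyr::expand_grid(j = j_range, order = order_range)
  if (nrow(grid) == 0) rlang::abort("empty j/order ranges")
  fits <- purrr::pmap(grid, function(j, order) {
    tryCatch(
      fit_gbtm(data, j = j, order = order,
        seed = if (is.null(seed)) NULL else seed + j * 131 + order, ...
      ),
      error = function(e) e
    )
  })
  sweep_tbl <- purrr::map2_dfr(fits, seq_len(nrow(grid)), function(f, i) {
    if (inherits(f, "error")) {
      tibble::tibble(
        j = grid$j[i], order = grid$order[i], loglik = NA_real_,
        k = NA_integer_, bic = NA_real_, converged = FALSE, degenerate = TRUE
      )
    } else {
      tibble::tibble(
        j = grid$j[i], order = grid$order[i], loglik = f$loglik,
        k = f$k, bic = f$bic, converged = f$converged,
        degenerate = f$degenerate
      )
    }
  })
  ok <- which(!sweep_tbl$degenerate & is.finite(sweep_tbl$bic))
  if (length(ok) == 0) {
    rlang::abort("all candidate fits degenerate",
      class = "gbtm_all_degenerate", sweep = sweep_tbl
    )
  }
  best_i <- ok[which.min(sweep_tbl$bic[ok])]
  sweep_tbl$selected <- seq_len(nrow(sweep_tbl)) == best_i
  structure(list(best = fits[[best_i]], sweep = sweep_tbl),
    class = "gbtm_selection"
  )
}

#' @export
print.gbtm_selection <- function(x, ...) {
  cat("GBTM model selection (min BIC)\n")
  print(as.data.frame(x$sweep), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Nagin adequacy diagnostics of a trajectory fit
#'
#' For each group: the number and share of subjects assigned to it by modal
#' posterior, the posterior-expected share (mean posterior column), the mean
#' posterior probability among its assigned members, and whether that mean
#' exceeds the conventional 0.70 adequacy floor. A close match between
#' observed and expected shares and high mean posteriors indicate a
#' well-separated, trustworthy grouping.
#'
#' @param fit A `gbtm_fit`.
#' @return A tibble with one row per group.
#' @export
gbtm_adequacy <- function(fit) {
  stopifnot(inherits(fit, "gbtm_fit"))
  fit$diagnostics
}

#' Per-group linear slopes with Wald confidence intervals
#'
#' Reports each group's linear growth coefficient (in kg per modelled time
#' unit, i.e. per gestational week under the default coding) with a Wald
#' confidence interval from the responsibility-weighted information matrix,
#' plus pairwise slope-difference z-tests between groups.
#'
#' @param fit A `gbtm_fit` with polynomial order >= 1.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `gbtm_slopes`: `slopes` (tibble: group, slope, se,
#'   conf.low, conf.high) and `contrasts` (tibble: pairwise difference,
#'   z, p.value).
#' @export
trajectory_slopes <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "gbtm_fit"))
  if (fit$spec$order < 1) {
    rlang::abort("slopes are undefined for order-0 (flat) trajectories")
  }
  j <- fit$spec$j
  z <- stats::qnorm(1 - (1 - conf) / 2)
  slope <- fit$beta[2, ]
  se <- vapply(fit$cov_beta, function(v) sqrt(v[2, 2]), numeric(1))
  slopes <- tibble::tibble(
    group = paste0("G", seq_len(j)),
    slope = slope, se = se,
    conf.low = slope - z * se, conf.high = slope + z * se
  )
  contrasts <- if (j >= 2) {
    pairs <- utils::combn(j, 2)
    tibble::tibble(
      group1 = paste0("G", pairs[1, ]),
      group2 = paste0("G", pairs[2, ]),
      difference = slope[pairs[1, ]] - slope[pairs[2, ]],
      se = sqrt(se[pairs[1, ]]^2 + se[pairs[2, ]]^2)
    ) |>
      dplyr::mutate(
        z = .data$difference / .data$se,
        p.value = 2 * stats::pnorm(-abs(.data$z))
      )
  } else {
    tibble::tibble(
      group1 = character(), group2 = character(), difference = numeric(),
      se = numeric(), z = numeric(), p.value = numeric()
    )
  }
  structure(list(slopes = slopes, contrasts = contrasts),
    class = "gbtm_slopes"
  )
}

#' @export
print.gbtm_slopes <- function(x, ...) {
  cat("Trajectory slopes (kg per time unit)\n")
  print(as.data.frame(x$slopes), row.names = FALSE, digits = 4)
  cat("\nPairwise differences\n")
  print(as.data.frame(x$contrasts), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fitted group mean curves with confidence bands
#'
#' @param fit A `gbtm_fit`.
#' @param weeks Evaluation grid; defaults to 60 points across the observed
#'   time range.
#' @param conf Confidence level for the mean-curve band.
#' @return Tibble: `group`, `week`, `mean`, `conf.low`, `conf.high`.
#' @export
trajectory_curves <- function(fit, weeks = NULL, conf = 0.95) {
  stopifnot(inherits(fit, "gbtm_fit"))
  weeks <- weeks %||%
    seq(fit$time_range[1], fit$time_range[2], length.out = 60)
  x <- design_matrix(weeks, fit$spec$order)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  purrr::map_dfr(seq_len(fit$spec$j), function(g) {
    mu <- as.vector(x %*% fit$beta[, g])
    se <- sqrt(pmax(rowSums((x %*% fit$cov_beta[[g]]) * x), 0))
    tibble::tibble(
      group = paste0("G", g), week = weeks, mean = mu,
      conf.low = mu - z * se, conf.high = mu + z * se
    )
  })
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf(
    "GBTM fit: %d group(s), order %d, %s variance\n",
    x$spec$j, x$spec$order, x$spec$variance_mode
  ))
  cat(sprintf(
    "  n = %d subjects (%d obs), logLik = %.2f, BIC = %.2f%s%s\n",
    x$n_subjects, x$n_obs, x$loglik, x$bic,
    if (!x$converged) " [not converged]" else "",
    if (x$degenerate) " [degenerate]" else ""
  ))
  cat("  shares:", sprintf("%.3f", x$pi), "\n")
  invisible(x)
}

#' @export
tidy.gbtm_fit <- function(x, ...) {
  j <- x$spec$j
  p <- x$spec$order + 1L
  coefs <- purrr::map_dfr(seq_len(j), function(g) {
    tibble::tibble(
      group = paste0("G", g),
      term = paste0("week^", 0:(p - 1)),
      estimate = x$beta[, g],
      std.error = sqrt(pmax(diag(x$cov_beta[[g]]), 0)),
      share = x$pi[g]
    )
  })
  sig <- tibble::tibble(
    group = if (length(x$sigma) == 1) "shared" else paste0("G", seq_len(j)),
    term = "sigma",
    estimate = x$sigma,
    std.error = NA_real_,
    share = NA_real_
  )
  dplyr::bind_rows(coefs, sig)
}

#' @export
glance.gbtm_fit <- function(x, ...) {
  tibble::tibble(
    j = x$spec$j, order = x$spec$order,
    variance_mode = x$spec$variance_mode,
    logLik = x$loglik, k = x$k, BIC = x$bic,
    n_subjects = x$n_subjects, n_obs = x$n_obs,
    converged = x$converged, degenerate = x$degenerate,
    min_mean_posterior = min(x$diagnostics$mean_posterior, na.rm = TRUE)
  )
}

#' Plot fitted trajectory bands
#'
#' Group mean weight curves across gestation with 95% confidence ribbons,
#' labelled with each group's share of the cohort.
#'
#' @param object A `gbtm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gbtm_fit <- function(object, ...) {
  curves <- trajectory_curves(object) |>
    dplyr::mutate(
      profile = sprintf(
        "%s (%.1f%%)", .data$group,
        100 * object$pi[match(.data$group, paste0("G", seq_len(object$spec$j)))]
      )
    )
  ggplot2::ggplot(
    curves,
    ggplot2::aes(.data$week, .data$mean,
      colour = .data$profile, fill = .data$profile
    )
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Gestational age (weeks)", y = "Weight (kg)",
      colour = "Profile", fill = "Profile"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
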
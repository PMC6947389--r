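# shared in-code fixtures

# tiny longitudinal dataset with known group structure, generated straight
# from the mixture model (not via the cohort simulator)
make_mixture_long <- function(n, pi, intercepts, slopes, sigma,
                              weeks = c(0, 10, 22, 34), seed = 1) {
  set.seed(seed)
  g <- sample.int(length(pi), n, replace = TRUE, prob = pi)
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      id = sprintf("S%04d", i),
      ga_weeks = weeks,
      weight_kg = intercepts[g[i]] + slopes[g[i]] * weeks +
        stats::rnorm(length(weeks), 0, sigma)
    )
  }) |>
    structure(truth = g)
}

# brute-force mixture log-likelihood: plain loops, no shared code with the
# package's vectorised implementation
oracle_loglik <- function(long, pi, beta, sigma) {
  beta <- as.matrix(beta)
  sigma <- rep_len(sigma, ncol(beta))
  total <- 0
  for (s in unique(long$id)) {
    rows <- long[long$id == s, ]
    mix <- 0
    for (j in seq_along(pi)) {
      dens <- 1
      for (r in seq_len(nrow(rows))) {
        mu <- 0
        for (p in seq_len(nrow(beta))) {
          mu <- mu + beta[p, j] * rows$ga_weeks[r]^(p - 1)
        }
        dens <- dens * stats::dnorm(rows$weight_kg[r], mu, sigma[j])
      }
      mix <- mix + pi[j] * dens
    }
    total <- total + log(mix)
  }
  total
}
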
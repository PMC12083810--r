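# Independent oracles used across tests.

# Fixed-effect inverse-variance pooling of normal effects (closed form).
fe_pool <- function(y, se) {
  w <- 1 / se^2
  list(mean = sum(w * y) / sum(w), sd = sqrt(1 / sum(w)))
}

# Monte Carlo standard error of a sample median of (approximately) normal
# draws on the log scale: 1 / (2 f(med) sqrt(ess)) with f the normal density
# at its median, i.e. sd * sqrt(pi / 2) / sqrt(ess).
mc_se_median_log <- function(draws, ess) {
  stats::sd(draws) * sqrt(pi / 2) / sqrt(ess)
}

# Monte Carlo standard error of a tail-probability estimate.
mc_se_prob <- function(p, ess) sqrt(max(p * (1 - p), 1e-12) / ess)

# Effective sample size of a contrast, summed over chains (pooling chains
# first would understate ESS through between-chain mean differences).
ess_of_fit <- function(fit, contrast) {
  sum(vapply(fit$chain_log_rr, function(m) {
    as.numeric(coda::effectiveSize(coda::mcmc(m[, contrast])))
  }, numeric(1)))
}

# Reduced sampler settings for tests that only need a stable posterior,
# not publication-grade precision.
quick_settings <- function(seed = 1, chains = 2) {
  mcmc_settings(draws = 6000, burn_in = 3000, chains = chains, seed = seed)
}

# Brute-force posterior for a single-site two-arm log-binomial model by 2-D
# quadrature over (alpha, beta), marginalizing the site hyperparameters
# (mu_alpha ~ N(log 0.25, 1.5^2), tau_alpha ~ Half-Normal(1)) on a tau grid.
# Returns a function of the prior giving the exact posterior median RR and a
# tail-probability function. events/n are c(placebo, treated).
two_arm_quadrature <- function(events, n,
                               a_grid = seq(-3, -0.4, length.out = 901),
                               b_grid = seq(-1.6, 0.9, length.out = 1601)) {
  tau_grid <- seq(0.005, 4, length.out = 60)
  prior_a <- log(rowSums(sapply(tau_grid, function(t) {
    stats::dnorm(a_grid, log(0.25), sqrt(1.5^2 + t^2)) * stats::dnorm(t, 0, 1)
  })))
  loglik <- outer(a_grid, b_grid, function(a, b) {
    p0 <- pmin(exp(a), 1 - 1e-15)
    p1 <- pmin(exp(a + b), 1 - 1e-15)
    stats::dbinom(events[1], n[1], p0, log = TRUE) +
      stats::dbinom(events[2], n[2], p1, log = TRUE)
  })
  base <- loglik + matrix(prior_a, nrow(loglik), ncol(loglik))
  function(prior) {
    lp <- base + matrix(stats::dnorm(b_grid, log(prior$median_rr),
                                     prior$sd_log, log = TRUE),
                        nrow(base), ncol(base), byrow = TRUE)
    w <- exp(lp - max(lp))
    pb <- colSums(w)
    pb <- pb / sum(pb)
    cdf <- cumsum(pb)
    list(
      median_rr = exp(stats::approx(cdf, b_grid, xout = 0.5, ties = "ordered")$y),
      tail = function(t) sum(pb[b_grid < log(t)])
    )
  }
}

# The published prior table: label, median RR, SD(log RR), and percent cells
# P(RR < 1 / 0.9 / 0.8 / 0.6). "approximately zero" cells are coded -1 and
# checked as < 0.5 percent.
reference_prior_percent_table <- function() {
  data.frame(
    name = c("minimally_informative", "strongly_enthusiastic",
             "moderately_enthusiastic", "moderately_skeptical",
             "strongly_skeptical"),
    median_rr = c(1, 0.6, 0.8, 1, 1),
    sd_log = c(10, 0.31, 0.14, 0.31, 0.14),
    p1 = c(50, 95, 94, 50, 50),
    p09 = c(50, 90, 80, 37, 23),
    p08 = c(49, 82, 50, 24, 6),
    p06 = c(48, 50, 2, 5, -1)
  )
}
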
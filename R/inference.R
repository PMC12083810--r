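ARM_LEVELS <- c("placebo", "epi", "dex", "epidex")

#' A normal distribution on the log relative risk scale
#'
#' Shared container for a likelihood summary, pooled evidence, or a
#' conjugate posterior: the log-RR is \eqn{N(\mathrm{mean\_log\_rr},
#' \mathrm{sd\_log}^2)}.
#'
#' @param mean_log_rr Mean log relative risk.
#' @param sd_log Standard deviation, > 0.
#' @return An object of class \code{normal_summary}.
#' @export
normal_summary <- function(mean_log_rr, sd_log) {
  stopifnot(is.numeric(mean_log_rr), length(mean_log_rr) == 1L, is.finite(mean_log_rr))
  assert_positive(sd_log, "sd_log")
  structure(list(mean_log_rr = mean_log_rr, sd_log = sd_log),
            class = "normal_summary")
}

#' @export
print.normal_summary <- function(x, ...) {
  cat(sprintf("<normal_summary> log-RR ~ N(%.4f, %.4f^2)  [median RR %.3f]\n",
              x$mean_log_rr, x$sd_log, exp(x$mean_log_rr)))
  invisible(x)
}

#' Per-site, per-arm counts for a factorial trial
#'
#' Validates a data frame of binomial counts with columns \code{site},
#' \code{arm}, \code{n}, \code{events}. Arms must come from
#' \code{placebo, epi, dex, epidex}; the placebo arm must be present; each
#' (site, arm) pair may appear at most once.
#'
#' @param df A data frame with the four columns above.
#' @return The validated data frame with class \code{trial_dataset}.
#' @export
trial_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("site", "arm", "n", "events")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_field("df", paste("missing columns:", paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(df)[need]
  df$site <- as.character(df$site)
  df$arm <- as.character(df$arm)
  bad_arm <- which(!df$arm %in% ARM_LEVELS)
  if (length(bad_arm)) {
    stop_field("arm", sprintf("unknown arm label '%s' (row %d); expected one of %s",
                              df$arm[bad_arm[1]], bad_arm[1],
                              paste(ARM_LEVELS, collapse = "|")))
  }
  if (any(!is.finite(df$n)) || any(df$n <= 0) || any(df$n != round(df$n))) {
    stop_field("n", "participant counts must be positive integers")
  }
  bad_ev <- which(!is.finite(df$events) | df$events < 0 |
                    df$events != round(df$events) | df$events > df$n)
  if (length(bad_ev)) {
    stop_field("events", sprintf("row %d: events must be integers in [0, n]", bad_ev[1]))
  }
  if (anyDuplicated(df[c("site", "arm")])) {
    stop_field("df", "each (site, arm) pair may appear at most once")
  }
  if (!"placebo" %in% df$arm) {
    stop_field("df", "placebo arm is required")
  }
  class(df) <- c("trial_dataset", "data.frame")
  df
}

#' Read trial data from CSV
#'
#' @param path CSV with columns \code{site, arm, n, events}.
#' @return A [trial_dataset()].
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop_field("path", paste0("file not found: ", path))
  trial_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write trial data to CSV
#'
#' @param data A [trial_dataset()].
#' @param path Output path.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Normal approximation to the two-arm likelihood on the log-RR scale
#'
#' The observed log relative risk and its delta-method standard error from
#' aggregate counts. Used by the closed-form conjugate oracle; the MCMC fit
#' works with the exact binomial likelihood instead.
#'
#' @param treated_events,treated_n,control_events,control_n Aggregate counts.
#' @return A [normal_summary()].
#' @export
likelihood_summary <- function(treated_events, treated_n, control_events, control_n) {
  treated_events <- assert_count(treated_events, "treated_events")
  control_events <- assert_count(control_events, "control_events")
  treated_n <- assert_count(treated_n, "treated_n", positive = TRUE)
  control_n <- assert_count(control_n, "control_n", positive = TRUE)
  if (treated_events > treated_n) stop_field("treated_events", "exceeds treated_n")
  if (control_events > control_n) stop_field("control_events", "exceeds control_n")
  if (treated_events == 0 || control_events == 0) {
    stop_field("events", paste(
      "zero events in an arm; the delta-method SE is undefined --",
      "use study_log_rr(), which applies a continuity correction"))
  }
  normal_summary(
    mean_log_rr = log((treated_events / treated_n) / (control_events / control_n)),
    sd_log = sqrt(1 / treated_events - 1 / treated_n +
                    1 / control_events - 1 / control_n)
  )
}

#' Conjugate normal posterior on the log-RR scale
#'
#' Precision-weighted combination of a normal prior on the log-RR with a
#' normal likelihood summary. Serves as a closed-form oracle against which
#' the MCMC fit is checked on single-site two-arm data.
#'
#' @param prior A [make_reference_prior()] object.
#' @param lik A [normal_summary()] from [likelihood_summary()].
#' @return A [normal_summary()] for the posterior.
#' @export
conjugate_posterior <- function(prior, lik) {
  stopifnot(is_prior_spec(prior), inherits(lik, "normal_summary"))
  prec_prior <- 1 / prior$sd_log^2
  prec_lik <- 1 / lik$sd_log^2
  prec_post <- prec_prior + prec_lik
  normal_summary(
    mean_log_rr = (prec_prior * log(prior$median_rr) + prec_lik * lik$mean_log_rr) /
      prec_post,
    sd_log = 1 / sqrt(prec_post)
  )
}

#' MCMC sampler settings
#'
#' @param draws Total iterations per chain, including burn-in (default 20000).
#' @param burn_in Iterations discarded per chain (default 10000).
#' @param chains Number of chains, at least 2 for convergence diagnostics
#'   (default 4).
#' @param seed Integer seed; chains use distinct streams derived from it.
#' @return An object of class \code{mcmc_settings}.
#' @export
mcmc_settings <- function(draws = 20000, burn_in = 10000, chains = 4, seed = 1) {
  draws <- assert_count(draws, "draws", positive = TRUE)
  burn_in <- assert_count(burn_in, "burn_in")
  chains <- assert_count(chains, "chains", positive = TRUE)
  seed <- assert_count(abs(seed), "seed")
  if (burn_in >= draws) stop_field("burn_in", "must be smaller than draws")
  structure(list(draws = draws, burn_in = burn_in, chains = chains, seed = seed),
            class = "mcmc_settings")
}

# Per-chain inits with fixed RNG streams so identical settings give
# identical draws.
jags_inits <- function(settings, base_fn) {
  lapply(seq_len(settings$chains), function(ch) {
    c(base_fn(),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (settings$seed * 1000L + ch) %% .Machine$integer.max))
  })
}

jags_model_quiet <- function(model_str, data, inits, n_chains) {
  con <- textConnection(model_str)
  on.exit(close(con))
  out <- utils::capture.output(
    jm <- rjags::jags.model(con, data = data, inits = inits,
                            n.chains = n_chains, quiet = TRUE)
  )
  jm
}

#' Fit the site-adjusted hierarchical log-binomial model
#'
#' The outcome model is \eqn{events_{s,a} \sim Binomial(n_{s,a}, p_{s,a})}
#' with \eqn{\log p_{s,a} = \alpha_s + \beta_a}, \eqn{\beta_{placebo} = 0},
#' so each \eqn{\exp(\beta_a)} is the relative risk of arm \eqn{a} versus
#' placebo. Treatment effects get the supplied priors,
#' \eqn{\beta_a \sim N(\log \mathrm{median\_rr}_a, \mathrm{sd\_log}_a^2)};
#' site intercepts are pooled hierarchically,
#' \eqn{\alpha_s \sim N(\mu_\alpha, \tau_\alpha^2)} with
#' \eqn{\mu_\alpha \sim N(\log 0.25, 1.5^2)} and \eqn{\tau_\alpha \sim}
#' Half-Normal(1). The log link requires fitted probabilities below 1; the
#' likelihood gives (numerically) zero support to parameter values with
#' \eqn{p \ge 1}, which can surface as rejected proposals when priors place
#' mass there.
#'
#' Sampling uses JAGS with \code{settings$chains} chains; the first
#' \code{burn_in} iterations per chain are discarded. A split R-hat above
#' 1.01 on any treatment contrast triggers a warning and is recorded in the
#' returned object (\code{$warnings}).
#'
#' @param data A [trial_dataset()].
#' @param priors A named list of [make_reference_prior()] objects, one per
#'   non-placebo arm present in \code{data} (names among
#'   \code{epi, dex, epidex}). A single \code{prior_spec} is recycled to all
#'   contrasts.
#' @param settings An [mcmc_settings()] object.
#' @return An object of class \code{posterior_samples}: \code{log_rr} a
#'   (retained draws) x (contrasts) matrix of log-RR draws pooled across
#'   chains, \code{chains} the underlying \code{coda::mcmc.list} of all
#'   monitored parameters (site intercepts \code{alpha}, hyperparameters
#'   \code{mu_alpha}, \code{tau_alpha}), \code{settings}, and
#'   \code{warnings}.
#' @export
fit_hierarchical_log_binomial <- function(data, priors,
                                          settings = mcmc_settings()) {
  stopifnot(inherits(data, "trial_dataset"), inherits(settings, "mcmc_settings"))
  arms_present <- intersect(ARM_LEVELS, unique(data$arm))
  contrasts <- setdiff(arms_present, "placebo")
  if (length(contrasts) == 0L) stop_field("data", "needs at least one treatment arm")
  if (is_prior_spec(priors)) {
    priors <- stats::setNames(rep(list(priors), length(contrasts)), contrasts)
  }
  if (!is.list(priors) || !all(contrasts %in% names(priors)) ||
      !all(vapply(priors[contrasts], is_prior_spec, logical(1)))) {
    stop_field("priors", paste("need one prior_spec per treatment arm:",
                               paste(contrasts, collapse = ", ")))
  }
  priors <- priors[contrasts]

  arm_index <- match(data$arm, c("placebo", contrasts))
  site_levels <- unique(data$site)
  site_index <- match(data$site, site_levels)
  S <- length(site_levels)
  A <- length(contrasts)

  model_str <- "
  model {
    for (i in 1:N) {
      eta[i] <- alpha[site[i]] + beta[arm[i]]
      p[i] <- min(exp(eta[i]), 1 - 1.0E-12)
      events[i] ~ dbin(p[i], n[i])
    }
    beta[1] <- 0
    for (a in 1:A) {
      beta[a + 1] ~ dnorm(prior_mean[a], prior_prec[a])
    }
    for (s in 1:S) {
      alpha[s] ~ dnorm(mu_alpha, prec_alpha)
    }
    mu_alpha ~ dnorm(-1.3862944, 0.4444444)
    tau_alpha ~ dnorm(0, 1) T(0,)
    prec_alpha <- 1 / (tau_alpha * tau_alpha + 1.0E-12)
  }"
  jdata <- list(
    N = nrow(data), S = S, A = A,
    events = data$events, n = data$n,
    site = site_index, arm = arm_index,
    prior_mean = vapply(priors, function(p) log(p$median_rr), numeric(1)),
    prior_prec = vapply(priors, function(p) 1 / p$sd_log^2, numeric(1))
  )
  overall <- max(min(sum(data$events) / sum(data$n), 0.95), 1e-3)
  init_fn <- function() {
    list(alpha = rep(log(overall), S),
         beta = c(NA, rep(0, A)),
         mu_alpha = log(overall), tau_alpha = 0.5)
  }
  jm <- jags_model_quiet(model_str, jdata,
                         inits = jags_inits(settings, init_fn),
                         n_chains = settings$chains)
  if (settings$burn_in > 0) {
    stats::update(jm, n.iter = settings$burn_in, progress.bar = "none")
  }
  sam <- rjags::coda.samples(jm, variable.names = c("beta", "alpha", "mu_alpha", "tau_alpha"),
                             n.iter = settings$draws - settings$burn_in,
                             progress.bar = "none")

  beta_cols <- paste0("beta[", seq_len(A) + 1L, "]")
  log_rr <- do.call(rbind, lapply(sam, function(m) {
    as.matrix(m)[, beta_cols, drop = FALSE]
  }))
  colnames(log_rr) <- contrasts
  chain_log_rr <- lapply(sam, function(m) {
    x <- as.matrix(m)[, beta_cols, drop = FALSE]
    colnames(x) <- contrasts
    x
  })

  out <- structure(
    list(log_rr = log_rr, chain_log_rr = chain_log_rr, chains = sam,
         contrasts = contrasts, sites = site_levels,
         settings = settings, warnings = character(0)),
    class = "posterior_samples"
  )
  if (settings$chains >= 2) {
    rh <- vapply(contrasts, function(ct) {
      split_rhat(lapply(chain_log_rr, function(m) m[, ct]))
    }, numeric(1))
    bad <- names(rh)[is.finite(rh) & rh > 1.01]
    if (length(bad)) {
      msg <- sprintf("split R-hat > 1.01 for contrast(s): %s (%s)",
                     paste(bad, collapse = ", "),
                     paste(sprintf("%.3f", rh[bad]), collapse = ", "))
      out$warnings <- msg
      warning(msg, call. = FALSE)
    }
  }
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws x %d chains, contrasts: %s\n",
              nrow(x$chain_log_rr[[1]]), length(x$chain_log_rr),
              paste(x$contrasts, collapse = ", ")))
  med <- apply(x$log_rr, 2, stats::median)
  cat(sprintf("  posterior median RR: %s\n",
              paste(sprintf("%s %.3f", names(med), exp(med)), collapse = ", ")))
  if (length(x$warnings)) cat("  warnings:", x$warnings, "\n")
  invisible(x)
}
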
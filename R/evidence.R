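#' Summary counts for a historical two-arm study
#'
#' @param study_id Identifier for the study.
#' @param treated_events,treated_n Events and participants in the treated arm.
#' @param control_events,control_n Events and participants in the control arm.
#' @return An object of class \code{study_summary}.
#' @export
study_summary <- function(study_id, treated_events, treated_n,
                          control_events, control_n) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  treated_events <- assert_count(treated_events, "treated_events")
  control_events <- assert_count(control_events, "control_events")
  treated_n <- assert_count(treated_n, "treated_n", positive = TRUE)
  control_n <- assert_count(control_n, "control_n", positive = TRUE)
  if (treated_events > treated_n) stop_field("treated_events", "exceeds treated_n")
  if (control_events > control_n) stop_field("control_events", "exceeds control_n")
  structure(
    list(study_id = study_id,
         treated_events = treated_events, treated_n = treated_n,
         control_events = control_events, control_n = control_n),
    class = "study_summary"
  )
}

#' Read historical studies from CSV
#'
#' Expects columns \code{study_id, treated_events, treated_n, control_events,
#' control_n}.
#'
#' @param path Path to the CSV file.
#' @return A list of [study_summary()] objects.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop_field("path", paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "treated_events", "treated_n", "control_events", "control_n")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_field("studies file", paste("missing columns:", paste(missing, collapse = ", ")))
  }
  lapply(seq_len(nrow(df)), function(i) {
    study_summary(as.character(df$study_id[i]), df$treated_events[i],
                  df$treated_n[i], df$control_events[i], df$control_n[i])
  })
}

#' Per-study log relative risk with its standard error
#'
#' The observed log-RR, \eqn{\log[(a/n_1)/(c/n_0)]}, and its delta-method
#' standard error \eqn{\sqrt{1/a - 1/n_1 + 1/c - 1/n_0}}. When any of the
#' four cells (events or non-events, either arm) is zero, 0.5 is added to all
#' four cells first (Haldane–Anscombe correction) and the result is flagged.
#'
#' @param study A [study_summary()] object.
#' @return A [normal_summary()] on the log-RR scale, with attribute
#'   \code{continuity_corrected} (logical).
#' @export
study_log_rr <- function(study) {
  stopifnot(inherits(study, "study_summary"))
  a <- study$treated_events; n1 <- study$treated_n
  c0 <- study$control_events; n0 <- study$control_n
  corrected <- a == 0 || c0 == 0 || a == n1 || c0 == n0
  if (corrected) {
    a <- a + 0.5; c0 <- c0 + 0.5; n1 <- n1 + 1; n0 <- n0 + 1
  }
  out <- normal_summary(
    mean_log_rr = log((a / n1) / (c0 / n0)),
    sd_log = sqrt(1 / a - 1 / n1 + 1 / c0 - 1 / n0)
  )
  attr(out, "continuity_corrected") <- corrected
  out
}

#' Pool historical studies into a data-driven prior distribution
#'
#' Fits a normal-normal hierarchical (random-effects) model to the observed
#' per-study log relative risks: study effects \eqn{\theta_j \sim N(\mu,
#' \tau^2)} and observed \eqn{y_j \sim N(\theta_j, se_j^2)}, with weakly
#' informative hyperpriors \eqn{\mu \sim N(0, 10^2)} and \eqn{\tau \sim}
#' Half-Normal(1). The latent study effects are integrated out analytically
#' (\eqn{y_j \sim N(\mu, se_j^2 + \tau^2)}), which keeps the sampler mixing
#' even when \eqn{\tau} is near zero. Sampling is by MCMC (JAGS); the
#' posterior of \eqn{\mu} summarizes the pooled evidence about the treatment
#' effect across studies.
#'
#' @param studies A list of [study_summary()] objects (at least one).
#' @param settings An [mcmc_settings()] object; defaults suit this small model.
#' @param tau_prior_sd Scale of the Half-Normal prior on the between-study SD
#'   \eqn{\tau} (default 1). A value near zero pins \eqn{\tau} at zero,
#'   recovering fixed-effect (common-effect) pooling.
#' @return An object of class \code{pooled_evidence} with fields
#'   \code{mean_log_rr} (posterior mean of \eqn{\mu}), \code{sd_log}
#'   (posterior SD of \eqn{\mu}) and \code{tau} (posterior median of
#'   \eqn{\tau}), plus the per-study inputs as attributes.
#' @export
pool_studies <- function(studies, settings = mcmc_settings(seed = 1),
                         tau_prior_sd = 1) {
  if (!is.list(studies) || length(studies) == 0L ||
      !all(vapply(studies, inherits, logical(1), "study_summary"))) {
    stop_field("studies", "must be a non-empty list of study_summary objects")
  }
  stopifnot(inherits(settings, "mcmc_settings"))
  assert_positive(tau_prior_sd, "tau_prior_sd")
  effs <- lapply(studies, study_log_rr)
  y <- vapply(effs, function(e) e$mean_log_rr, numeric(1))
  se <- vapply(effs, function(e) e$sd_log, numeric(1))

  # marginal form of the normal-normal hierarchy: integrating the latent
  # study effects out of (theta_j ~ N(mu, tau^2), y_j ~ N(theta_j, se_j^2))
  # gives y_j ~ N(mu, se_j^2 + tau^2), which mixes well even as tau -> 0
  model_str <- "
  model {
    for (j in 1:K) {
      y[j] ~ dnorm(mu, 1 / (v[j] + tau * tau))
    }
    mu ~ dnorm(0, 0.01)
    tau ~ dnorm(0, prec_tau_prior) T(0,)
  }"
  jm <- jags_model_quiet(
    model_str,
    data = list(y = y, v = se^2, K = length(y),
                prec_tau_prior = 1 / tau_prior_sd^2),
    inits = jags_inits(settings, function() list(mu = 0, tau = tau_prior_sd / 2)),
    n_chains = settings$chains
  )
  stats::update(jm, n.iter = settings$burn_in, progress.bar = "none")
  sam <- rjags::coda.samples(jm, variable.names = c("mu", "tau"),
                             n.iter = settings$draws - settings$burn_in,
                             progress.bar = "none")
  mu_draws <- unlist(lapply(sam, function(m) as.numeric(m[, "mu"])))
  tau_draws <- unlist(lapply(sam, function(m) as.numeric(m[, "tau"])))
  pooled_evidence(
    mean_log_rr = mean(mu_draws),
    sd_log = stats::sd(mu_draws),
    tau = stats::median(tau_draws),
    y = y, se = se
  )
}

#' Pooled evidence from historical studies
#'
#' Container for the pooled log-RR distribution produced by [pool_studies()]
#' (or specified directly, e.g. from a published meta-analysis).
#'
#' @param mean_log_rr Pooled mean log relative risk.
#' @param sd_log Standard deviation of the pooled log-RR, > 0.
#' @param tau Between-study SD of the log-RR, >= 0.
#' @param y,se Optional per-study effects and standard errors for provenance.
#' @return An object of class \code{pooled_evidence}.
#' @export
pooled_evidence <- function(mean_log_rr, sd_log, tau = 0, y = NULL, se = NULL) {
  stopifnot(is.numeric(mean_log_rr), length(mean_log_rr) == 1L, is.finite(mean_log_rr))
  assert_positive(sd_log, "sd_log")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0) {
    stop_field("tau", "must be a single finite value >= 0")
  }
  structure(
    list(mean_log_rr = mean_log_rr, sd_log = sd_log, tau = tau,
         studies = if (!is.null(y)) data.frame(y = y, se = se) else NULL),
    class = "pooled_evidence"
  )
}

#' @export
print.pooled_evidence <- function(x, ...) {
  cat(sprintf("<pooled_evidence> median RR %.3f, SD(log RR) %.3f, tau %.3f (%s studies)\n",
              exp(x$mean_log_rr), x$sd_log, x$tau,
              if (is.null(x$studies)) "?" else nrow(x$studies)))
  invisible(x)
}

#' Down-weight pooled historical evidence into a prior
#'
#' Converts pooled evidence into a prior on the RR while discounting the
#' historical data. A weight \eqn{w \in (0, 1]} represents the contribution
#' of one historical participant relative to one current-trial participant;
#' it acts on the prior variance, inflating the SD of the log-RR by
#' \eqn{1/\sqrt{w}} and leaving the median untouched. \code{w = 1} uses the
#' historical evidence at face value; \code{w = 0.1} makes ten historical
#' participants count as one.
#'
#' @param pooled A [pooled_evidence()] object.
#' @param w Weight in (0, 1].
#' @param label Optional label; default describes the weighting.
#' @return A [make_reference_prior()] object with
#'   \code{median = exp(mean_log_rr)} and \code{sd_log = sd_log / sqrt(w)}.
#' @export
apply_prior_weight <- function(pooled, w, label = NULL) {
  stopifnot(inherits(pooled, "pooled_evidence"))
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0 || w > 1) {
    stop_field("w", "weight must lie in (0, 1]")
  }
  make_reference_prior(
    median_rr = exp(pooled$mean_log_rr),
    sd_log = pooled$sd_log / sqrt(w),
    label = label %||% sprintf("%g%% Weighting", 100 * w)
  )
}
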
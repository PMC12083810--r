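#' Summarize posterior log-RR draws
#'
#' Produces the standard reporting quantities for one treatment contrast:
#' the posterior median relative risk, the equi-tailed 95\% credible
#' interval (2.5\% and 97.5\% sample quantiles, linear interpolation), and
#' the probability that the RR lies below each threshold, estimated by the
#' proportion of draws below it.
#'
#' @param draws Numeric vector of posterior draws of the log relative risk
#'   (at least 1000, so quantile and tail estimates are stable).
#' @param thresholds A [threshold_set()] (default \code{c(1,0.9,0.8,0.6)}).
#' @param label Contrast label carried into the summary.
#' @param min_draws Minimum number of draws accepted.
#' @return An object of class \code{posterior_summary} with fields
#'   \code{label}, \code{median_rr}, \code{ci95} (length-2), and
#'   \code{tail_probs} (named by threshold).
#' @export
summarize_draws <- function(draws, thresholds = threshold_set(),
                            label = "", min_draws = 1000L) {
  if (!is.numeric(draws) || length(draws) < min_draws) {
    stop_field("draws", sprintf("need at least %d draws of the log-RR", min_draws))
  }
  if (any(!is.finite(draws))) stop_field("draws", "must all be finite")
  if (!inherits(thresholds, "threshold_set")) thresholds <- threshold_set(thresholds)
  rr <- exp(draws)
  q <- stats::quantile(rr, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  tp <- vapply(as.numeric(thresholds), function(t) mean(rr < t), numeric(1))
  posterior_summary(label, q[2], c(q[1], q[3]),
                    stats::setNames(tp, as.character(as.numeric(thresholds))))
}

#' Closed-form summary of a normal log-RR distribution
#'
#' The analytic twin of [summarize_draws()] for a [normal_summary()]:
#' median \eqn{e^{\mu}}, 95\% interval \eqn{e^{\mu \pm 1.959964\sigma}},
#' tail probabilities via the normal CDF. Used for priors (whose tail
#' probabilities it reports exactly) and for the conjugate oracle.
#'
#' @param ns A [normal_summary()] or [make_reference_prior()] object.
#' @param thresholds A [threshold_set()].
#' @param label Label carried into the summary.
#' @return A \code{posterior_summary}.
#' @export
summarize_normal <- function(ns, thresholds = threshold_set(), label = "") {
  if (is_prior_spec(ns)) {
    if (!nzchar(label)) label <- ns$label
    ns <- normal_summary(log(ns$median_rr), ns$sd_log)
  }
  stopifnot(inherits(ns, "normal_summary"))
  if (!inherits(thresholds, "threshold_set")) thresholds <- threshold_set(thresholds)
  z <- stats::qnorm(0.975)
  tp <- stats::pnorm((log(as.numeric(thresholds)) - ns$mean_log_rr) / ns$sd_log)
  posterior_summary(
    label,
    exp(ns$mean_log_rr),
    exp(ns$mean_log_rr + c(-z, z) * ns$sd_log),
    stats::setNames(tp, as.character(as.numeric(thresholds)))
  )
}

posterior_summary <- function(label, median_rr, ci95, tail_probs) {
  stopifnot(length(ci95) == 2L, ci95[1] <= median_rr, median_rr <= ci95[2])
  if (is.unsorted(rev(tail_probs))) {
    # thresholds are decreasing, so P(RR < t) must be non-increasing
    stop("tail probabilities must be non-increasing across decreasing thresholds")
  }
  structure(list(label = label, median_rr = median_rr,
                 ci95 = ci95, tail_probs = tail_probs),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  median RR %.2f (95%% CrI %.2f, %.2f)\n",
              x$median_rr, x$ci95[1], x$ci95[2]))
  cat("  P(RR < t): ",
      paste(sprintf("t=%s: %s", names(x$tail_probs),
                    format_percent(x$tail_probs)), collapse = ", "), "\n")
  invisible(x)
}

#' Render a probability as an integer percent, report style
#'
#' Rounds half away from zero; probabilities below 0.5\% render as
#' \code{"<1"} (printed tables use an approximately-zero marker) and
#' those at or above 99.5\% as \code{"100"}.
#'
#' @param p Probabilities in \[0, 1\].
#' @param approx_zero String used below 0.5\% (default \code{"<1"}).
#' @return Character vector of percent labels.
#' @export
format_percent <- function(p, approx_zero = "<1") {
  pct <- round_half_up(100 * p)
  out <- as.character(pct)
  out[100 * p < 0.5] <- approx_zero
  out
}

#' Table of priors with their tail probabilities
#'
#' One row per prior: label, median RR, SD of the log-RR, optional
#' effective sample size, and \eqn{P(RR < t)} for each threshold (exact,
#' from the normal CDF).
#'
#' @param priors Named list of [make_reference_prior()] objects.
#' @param thresholds A [threshold_set()].
#' @param ref Optional [reference_trial_info()] for the ESS column.
#' @param percent Render tail probabilities as integer percent strings
#'   (default) or keep them numeric.
#' @return A data frame.
#' @export
priors_table <- function(priors, thresholds = threshold_set(), ref = NULL,
                         percent = TRUE) {
  stopifnot(is.list(priors), all(vapply(priors, is_prior_spec, logical(1))))
  if (!inherits(thresholds, "threshold_set")) thresholds <- threshold_set(thresholds)
  th <- as.numeric(thresholds)
  rows <- lapply(priors, function(p) {
    tp <- prior_tail_probability(p, th)
    row <- data.frame(label = p$label, median_rr = p$median_rr,
                      sd_log = p$sd_log)
    if (!is.null(ref)) row$ess <- prior_ess(p, ref)
    tpv <- if (percent) format_percent(tp) else tp
    for (j in seq_along(th)) row[[paste0("p_rr_lt_", th[j])]] <- tpv[j]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Table of posterior summaries
#'
#' One row per [summarize_draws()] / [summarize_normal()] result: median RR,
#' 95\% credible interval and threshold probabilities.
#'
#' @param summaries List of \code{posterior_summary} objects.
#' @param percent Render tail probabilities as integer percent strings.
#' @return A data frame.
#' @export
posterior_table <- function(summaries, percent = TRUE) {
  stopifnot(is.list(summaries),
            all(vapply(summaries, inherits, logical(1), "posterior_summary")))
  rows <- lapply(summaries, function(s) {
    row <- data.frame(label = s$label,
                      median_rr = round_half_up(s$median_rr, 2),
                      ci_lower = round_half_up(s$ci95[1], 2),
                      ci_upper = round_half_up(s$ci95[2], 2))
    tpv <- if (percent) format_percent(s$tail_probs) else unname(s$tail_probs)
    for (j in seq_along(s$tail_probs)) {
      row[[paste0("p_rr_lt_", names(s$tail_probs)[j])]] <- tpv[j]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior summaries across a grid of historical-evidence weights
#'
#' Refits the model once per weight, converting the pooled historical
#' evidence into a prior at that weight via [apply_prior_weight()]. A weight
#' of 0 means "ignore the historical data" and is handled by substituting
#' the minimally informative prior. Arms other than \code{contrast} always
#' get the minimally informative prior so the sweep isolates the effect of
#' borrowing on the contrast of interest.
#'
#' @param data A [trial_dataset()].
#' @param pooled A [pooled_evidence()] object.
#' @param weights Non-empty numeric vector of weights in \[0, 1\], sorted
#'   increasing.
#' @param settings An [mcmc_settings()].
#' @param thresholds A [threshold_set()].
#' @param contrast Which treatment arm the data-driven prior applies to
#'   (default \code{"epidex"}).
#' @return A named list of \code{posterior_summary} objects, one per weight.
#' @export
weight_sweep <- function(data, pooled, weights, settings = mcmc_settings(),
                         thresholds = threshold_set(), contrast = "epidex") {
  stopifnot(inherits(data, "trial_dataset"), inherits(pooled, "pooled_evidence"))
  if (!is.numeric(weights) || length(weights) == 0L) {
    stop_field("weights", "must be a non-empty numeric vector")
  }
  if (any(weights < 0 | weights > 1)) stop_field("weights", "must lie in [0, 1]")
  if (is.unsorted(weights, strictly = TRUE)) {
    stop_field("weights", "must be sorted strictly increasing")
  }
  mi <- reference_priors()$minimally_informative
  arms <- setdiff(intersect(ARM_LEVELS, unique(data$arm)), "placebo")
  if (!contrast %in% arms) stop_field("contrast", "arm not present in data")
  out <- lapply(weights, function(w) {
    pr <- if (w == 0) mi else apply_prior_weight(pooled, w)
    prior_list <- stats::setNames(rep(list(mi), length(arms)), arms)
    prior_list[[contrast]] <- pr
    fit <- fit_hierarchical_log_binomial(data, prior_list, settings)
    summarize_draws(fit$log_rr[, contrast], thresholds,
                    label = sprintf("%g%% weighting", 100 * w))
  })
  stats::setNames(out, sprintf("w%g", weights))
}
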
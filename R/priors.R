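#' Construct a prior on the relative risk
#'
#' A prior on the relative risk (RR) of the outcome under treatment versus
#' placebo, parameterized by its median RR and the standard deviation of the
#' log relative risk. The implied distribution of the log-RR is
#' \eqn{N(\log(\mathrm{median\_rr}), \mathrm{sd\_log}^2)}, i.e. the RR is
#' lognormal with median exactly \code{median_rr}.
#'
#' Reference archetypes in trial reanalysis place the median at 1
#' (skeptical: no effect expected) or below 1 (enthusiastic: benefit
#' expected), with \code{sd_log} encoding how firmly the stance is held.
#' A very large \code{sd_log} (e.g. 10) yields a minimally informative prior
#' whose posterior essentially reproduces the likelihood.
#'
#' @param median_rr Median relative risk, > 0.
#' @param sd_log Standard deviation of the log relative risk, > 0.
#' @param label Short description of the belief the prior encodes.
#' @return An object of class \code{prior_spec} with fields \code{label},
#'   \code{median_rr} and \code{sd_log}.
#' @seealso [reference_priors()], [prior_tail_probability()], [prior_ess()]
#' @examples
#' make_reference_prior(0.6, 0.31, "strongly enthusiastic")
#' @export
make_reference_prior <- function(median_rr, sd_log, label = "") {
  assert_positive(median_rr, "median_rr")
  assert_positive(sd_log, "sd_log")
  stopifnot(is.character(label), length(label) == 1L)
  structure(
    list(label = label, median_rr = median_rr, sd_log = sd_log),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  median RR %.4g, SD(log RR) %.4g\n", x$median_rr, x$sd_log))
  invisible(x)
}

is_prior_spec <- function(x) inherits(x, "prior_spec")

#' RR thresholds for posterior/prior tail probabilities
#'
#' A strictly decreasing set of relative-risk cutoffs at which tail
#' probabilities \eqn{P(RR < t)} are reported. The default
#' \code{c(1, 0.9, 0.8, 0.6)} corresponds to any reduction, and reductions of
#' at least 10\%, 20\% and 40\% in the event risk.
#'
#' @param thresholds Numeric vector, strictly decreasing, all > 0.
#' @return An object of class \code{threshold_set}.
#' @export
threshold_set <- function(thresholds = c(1, 0.9, 0.8, 0.6)) {
  if (!is.numeric(thresholds) || length(thresholds) == 0L ||
      any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop_field("thresholds", "must be finite values > 0")
  }
  if (any(diff(thresholds) >= 0)) {
    stop_field("thresholds", "must be strictly decreasing")
  }
  structure(as.numeric(thresholds), class = "threshold_set")
}

#' Prior probability that the relative risk lies below a cutoff
#'
#' Computes \eqn{P(RR < t) = \Phi((\log t - \log \mathrm{median})/\mathrm{sd\_log})}
#' under the lognormal prior.
#'
#' @param prior A [make_reference_prior()] object.
#' @param t RR cutoff(s), all > 0. Vectorized.
#' @return Probabilities in \[0, 1\], one per cutoff.
#' @export
prior_tail_probability <- function(prior, t) {
  stopifnot(is_prior_spec(prior))
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)) || any(t <= 0)) {
    stop_field("t", "threshold(s) must be finite values > 0")
  }
  stats::pnorm((log(t) - log(prior$median_rr)) / prior$sd_log)
}

#' Prior density over a grid of relative risks
#'
#' Lognormal density of the RR at each grid point; integrates to 1 over
#' \eqn{(0, \infty)}. Used to draw prior curves.
#'
#' @param prior A [make_reference_prior()] object.
#' @param rr_grid Relative-risk values, all > 0.
#' @return Density values, one per grid point.
#' @export
prior_density_curve <- function(prior, rr_grid) {
  stopifnot(is_prior_spec(prior))
  if (!is.numeric(rr_grid) || length(rr_grid) == 0L ||
      any(!is.finite(rr_grid)) || any(rr_grid <= 0)) {
    stop_field("rr_grid", "grid values must be finite and > 0")
  }
  stats::dlnorm(rr_grid, meanlog = log(prior$median_rr), sdlog = prior$sd_log)
}

#' Effective sample size of an informative prior
#'
#' Translates the prior's information content into an equivalent number of
#' trial participants, relative to a reference trial whose \code{n_total}
#' participants produced a log-RR estimate with standard error
#' \code{se_log_rr}. The default rule equates information per participant:
#' \deqn{ESS = n_{total} \times se_{\log RR}^2 / sd_{\log}^2,}
#' so a prior exactly as informative as the reference trial has ESS equal to
#' \code{n_total}, and ESS falls off as \eqn{1/sd_{\log}^2}. The rule can be
#' swapped via \code{formula}, which receives \code{(prior, ref)} and returns
#' a number; translation conventions for prior ESS differ across the
#' literature and none is canonical.
#'
#' @param prior A [make_reference_prior()] object.
#' @param ref A [reference_trial_info()] object.
#' @param formula Optional replacement rule, a function of \code{(prior, ref)}.
#' @return Effective sample size in participants (not rounded).
#' @export
prior_ess <- function(prior, ref, formula = NULL) {
  stopifnot(is_prior_spec(prior), inherits(ref, "reference_trial_info"))
  if (!is.null(formula)) {
    stopifnot(is.function(formula))
    return(formula(prior, ref))
  }
  ref$n_total * (ref$se_log_rr^2 / prior$sd_log^2)
}

#' Reference-trial information for prior effective sample size
#'
#' @param n_total Number of participants in the reference trial, > 0.
#' @param se_log_rr Standard error of that trial's log-RR estimate, > 0.
#' @return An object of class \code{reference_trial_info}.
#' @export
reference_trial_info <- function(n_total, se_log_rr) {
  assert_count(n_total, "n_total", positive = TRUE)
  assert_positive(se_log_rr, "se_log_rr")
  structure(list(n_total = as.integer(n_total), se_log_rr = se_log_rr),
            class = "reference_trial_info")
}

#' The five reference-prior archetypes
#'
#' The standard set of stances about a treatment's effect on the RR scale:
#' minimally informative (median 1, SD 10 — essentially no influence),
#' strongly/moderately enthusiastic (median below 1) and
#' moderately/strongly skeptical (median 1, centred on no effect), with the
#' SD of the log-RR encoding the strength of each stance.
#'
#' @return A named list of [make_reference_prior()] objects with elements
#'   \code{minimally_informative}, \code{strongly_enthusiastic},
#'   \code{moderately_enthusiastic}, \code{moderately_skeptical},
#'   \code{strongly_skeptical}.
#' @export
reference_priors <- function() {
  list(
    minimally_informative  = make_reference_prior(1,   10,   "Minimally Informative"),
    strongly_enthusiastic  = make_reference_prior(0.6, 0.31, "Strongly Enthusiastic"),
    moderately_enthusiastic = make_reference_prior(0.8, 0.14, "Moderately Enthusiastic"),
    moderately_skeptical   = make_reference_prior(1,   0.31, "Moderately Skeptical"),
    strongly_skeptical     = make_reference_prior(1,   0.14, "Strongly Skeptical")
  )
}

#' Read prior specifications from a YAML or JSON file
#'
#' The file holds either a flat list of \code{{label, median_rr, sd_log}}
#' entries, or one named list per treatment contrast (e.g. \code{epidex},
#' \code{epi}, \code{dex}) each holding such a list.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A named list of [make_reference_prior()] objects, or a named list
#'   of such lists when the file is organized per contrast.
#' @export
read_priors <- function(path) {
  if (!file.exists(path)) stop_field("path", paste0("file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  parse_entry <- function(e) {
    if (is.null(e$median_rr) || is.null(e$sd_log)) {
      stop_field("priors file", "each entry needs `median_rr` and `sd_log`")
    }
    make_reference_prior(e$median_rr, e$sd_log, e$label %||% "")
  }
  is_entry <- function(e) is.list(e) && !is.null(e$median_rr)
  if (all(vapply(raw, is_entry, logical(1)))) {
    out <- lapply(raw, parse_entry)
  } else {
    out <- lapply(raw, function(set) lapply(set, parse_entry))
  }
  name_set <- function(set) {
    labs <- vapply(set, function(p) p$label, character(1))
    if (is.null(names(set)) || any(!nzchar(names(set)))) names(set) <- labs
    set
  }
  if (all(vapply(raw, is_entry, logical(1)))) name_set(out) else lapply(out, name_set)
}
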
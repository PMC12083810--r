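#' Parameters for simulating a multi-site factorial trial
#'
#' Defines the generative model the analysis assumes: lognormally
#' distributed site baseline risks (normal site intercepts on the log
#' scale) and fixed arm-level relative risks acting multiplicatively.
#'
#' @param n_sites Number of sites.
#' @param participants_per_site_arm Participants per site per arm.
#' @param baseline_risk Placebo event probability at the typical site,
#'   in (0, 1).
#' @param site_sd SD of site intercepts on the log-risk scale, >= 0.
#' @param true_rr Named vector of relative risks per arm; must include
#'   \code{placebo = 1}. Arms are a subset of
#'   \code{placebo, epi, dex, epidex}.
#' @param seed Integer seed.
#' @return An object of class \code{simulation_params}.
#' @export
simulation_params <- function(n_sites = 20,
                              participants_per_site_arm = 40,
                              baseline_risk = 0.25,
                              site_sd = 0.3,
                              true_rr = c(placebo = 1, epi = 0.85,
                                          dex = 0.9, epidex = 0.65),
                              seed = 1) {
  n_sites <- assert_count(n_sites, "n_sites", positive = TRUE)
  participants_per_site_arm <- assert_count(participants_per_site_arm,
                                            "participants_per_site_arm",
                                            positive = TRUE)
  assert_probability(baseline_risk, "baseline_risk")
  if (!is.numeric(site_sd) || length(site_sd) != 1L || !is.finite(site_sd) ||
      site_sd < 0) {
    stop_field("site_sd", "must be a single finite value >= 0")
  }
  if (is.null(names(true_rr)) || !all(names(true_rr) %in% ARM_LEVELS) ||
      anyDuplicated(names(true_rr))) {
    stop_field("true_rr", paste("must be named by arms among",
                                paste(ARM_LEVELS, collapse = "|")))
  }
  if (!"placebo" %in% names(true_rr) || true_rr[["placebo"]] != 1) {
    stop_field("true_rr", "must include placebo with RR exactly 1")
  }
  if (any(true_rr <= 0)) stop_field("true_rr", "relative risks must be > 0")
  seed <- assert_count(abs(seed), "seed")
  structure(list(n_sites = n_sites,
                 participants_per_site_arm = participants_per_site_arm,
                 baseline_risk = baseline_risk, site_sd = site_sd,
                 true_rr = true_rr, seed = seed),
            class = "simulation_params")
}

#' Simulate a multi-site factorial trial
#'
#' Site intercepts are drawn \eqn{\alpha_s \sim N(\log(\mathrm{baseline\_risk}),
#' \mathrm{site\_sd}^2)}; arm risks are \eqn{p_{s,a} = e^{\alpha_s} RR_a};
#' events are binomial. A site whose draw puts any arm risk at or above 1 is
#' redrawn (rejection sampling keeps the generative model an honest
#' log-binomial); the number of rejections is recorded in the
#' \code{"rejections"} attribute. Parameters under which a site draw is
#' invalid with probability above 0.5 are refused outright.
#'
#' @param params A [simulation_params()] object.
#' @return A [trial_dataset()] with attribute \code{rejections}.
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  max_rr <- max(params$true_rr)
  # P(exp(alpha) * max_rr >= 1) for one site draw
  p_invalid <- if (params$site_sd == 0) {
    as.numeric(params$baseline_risk * max_rr >= 1)
  } else {
    stats::pnorm(-log(params$baseline_risk * max_rr) / params$site_sd,
                 lower.tail = FALSE)
  }
  if (p_invalid > 0.5) {
    stop_field("params", sprintf(
      paste("baseline_risk, site_sd and true_rr imply an arm risk >= 1 with",
            "probability %.2f per site; choose a lower baseline risk,",
            "smaller site_sd or smaller relative risks"), p_invalid))
  }
  arms <- names(params$true_rr)
  rejections <- 0L
  rows <- withr::with_seed(params$seed, {
    lapply(seq_len(params$n_sites), function(s) {
      repeat {
        alpha <- stats::rnorm(1, log(params$baseline_risk), params$site_sd)
        p <- exp(alpha) * params$true_rr
        if (all(p < 1)) break
        rejections <<- rejections + 1L
      }
      data.frame(site = sprintf("site%02d", s), arm = arms,
                 n = params$participants_per_site_arm,
                 events = stats::rbinom(length(arms),
                                        params$participants_per_site_arm, p))
    })
  })
  out <- trial_dataset(do.call(rbind, rows))
  attr(out, "rejections") <- rejections
  out
}

#' Reconstructed aggregate dataset of the CanBEST factorial trial
#'
#' The published aggregate results of a four-arm factorial bronchiolitis
#' trial (797 infants; 7-day hospital admissions of 34, 47, 51 and 53 in
#' the epinephrine+dexamethasone, epinephrine, dexamethasone and placebo
#' arms). Per-site counts were never published, so the fixture is a
#' single-site reconstruction; arm denominators assume equal allocation,
#' 199/199/199/200 with the extra participant placed in the placebo arm
#' (the published report gives only the total). Both assumptions are
#' recorded in the \code{"assumptions"} attribute.
#'
#' @return A single-site [trial_dataset()].
#' @examples
#' d <- canbest_fixture()
#' sum(d$n)       # 797
#' sum(d$events)  # 185
#' @export
canbest_fixture <- function() {
  out <- trial_dataset(data.frame(
    site = "all",
    arm = c("epidex", "epi", "dex", "placebo"),
    n = c(199L, 199L, 199L, 200L),
    events = c(34L, 47L, 51L, 53L)
  ))
  attr(out, "assumptions") <- paste(
    "single-site aggregate reconstruction; per-site counts unpublished;",
    "arm denominators 199/199/199/200 assume equal allocation of 797",
    "participants with the remainder assigned to placebo")
  out
}

#' Simulate a heterogeneous pool of historical two-arm studies
#'
#' Each study has a true log relative risk drawn
#' \eqn{N(\mathrm{true\_mu\_log\_rr}, \tau^2)}, per-arm sizes uniform over
#' \code{per_arm_n_range}, and binomial outcomes with control risk
#' \code{baseline_risk}. Study effects implying a treated risk at or above 1
#' are redrawn.
#'
#' @param k Number of studies, >= 1.
#' @param true_mu_log_rr Mean of the true log-RR distribution.
#' @param tau Between-study SD of the log-RR, >= 0.
#' @param per_arm_n_range Length-2 integer range (min, max) of per-arm sizes.
#' @param baseline_risk Control-arm event probability, in (0, 1).
#' @param seed Integer seed.
#' @return A list of [study_summary()] objects.
#' @export
simulate_study_collection <- function(k, true_mu_log_rr = log(0.85), tau = 0.2,
                                      per_arm_n_range = c(40, 400),
                                      baseline_risk = 0.25, seed = 1) {
  k <- assert_count(k, "k", positive = TRUE)
  stopifnot(is.numeric(true_mu_log_rr), length(true_mu_log_rr) == 1L,
            is.finite(true_mu_log_rr))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0) {
    stop_field("tau", "must be a single finite value >= 0")
  }
  if (!is.numeric(per_arm_n_range) || length(per_arm_n_range) != 2L ||
      any(per_arm_n_range < 1) || per_arm_n_range[1] > per_arm_n_range[2]) {
    stop_field("per_arm_n_range", "must be (min, max) with 1 <= min <= max")
  }
  assert_probability(baseline_risk, "baseline_risk")
  seed <- assert_count(abs(seed), "seed")
  rand_n <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  withr::with_seed(seed, {
    lapply(seq_len(k), function(j) {
      repeat {
        theta <- stats::rnorm(1, true_mu_log_rr, tau)
        p1 <- baseline_risk * exp(theta)
        if (p1 < 1) break
      }
      n1 <- rand_n(per_arm_n_range[1], per_arm_n_range[2])
      n0 <- rand_n(per_arm_n_range[1], per_arm_n_range[2])
      study_summary(sprintf("study%02d", j),
                    treated_events = stats::rbinom(1, n1, p1), treated_n = n1,
                    control_events = stats::rbinom(1, n0, baseline_risk),
                    control_n = n0)
    })
  })
}
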
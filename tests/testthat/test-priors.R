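test_that("reference-prior tail probabilities reproduce the published percent table", {
  tab <- reference_prior_percent_table()
  th <- c(1, 0.9, 0.8, 0.6)
  for (i in seq_len(nrow(tab))) {
    prior <- make_reference_prior(tab$median_rr[i], tab$sd_log[i], tab$name[i])
    pct <- 100 * prior_tail_probability(prior, th)
    expected <- as.numeric(tab[i, c("p1", "p09", "p08", "p06")])
    for (j in seq_along(th)) {
      if (expected[j] < 0) {
        expect_lt(pct[j], 0.5)  # printed as approximately zero
      } else {
        expect_equal(round(pct[j]), expected[j],
                     info = sprintf("%s, t = %g", tab$name[i], th[j]))
      }
    }
  }
})

test_that("prior constructors validate their fields by name", {
  expect_error(make_reference_prior(-0.5, 0.31, "x"), "median_rr")
  expect_error(make_reference_prior(0.8, 0, "x"), "sd_log")
  expect_error(make_reference_prior(0.8, -1, "x"), "sd_log")
  expect_error(threshold_set(c(0.6, 0.8, 1)), "decreasing")
  expect_error(threshold_set(c(1, 0.9, 0)), "thresholds")
  expect_error(prior_tail_probability(make_reference_prior(1, 1), -1), "t")
  p <- make_reference_prior(0.6, 0.31, "strongly enthusiastic")
  expect_s3_class(p, "prior_spec")
  expect_equal(p$median_rr, 0.6)
})

test_that("tail probability behaves like a CDF in the cutoff", {
  prior <- make_reference_prior(0.8, 0.14, "me")
  t_grid <- c(0.5, 0.7, 0.8, 0.9, 1, 1.2)
  p <- prior_tail_probability(prior, t_grid)
  expect_true(all(diff(p) > 0))
  expect_equal(prior_tail_probability(prior, 0.8), 0.5)  # at the median, exactly
  # complement: P(<t) + P(>=t) = 1 by construction of the continuous CDF
  expect_equal(p + (1 - p), rep(1, length(p)))
  # tighter priors step more sharply around the median
  for (t in c(0.7, 0.9)) {
    probs <- vapply(c(0.31, 0.14, 0.05), function(s) {
      prior_tail_probability(make_reference_prior(0.8, s), t)
    }, numeric(1))
    target <- as.numeric(t > 0.8)
    expect_true(all(diff(abs(probs - target)) < 0),
                info = sprintf("t = %g approaches the step function", t))
  }
})

test_that("prior density integrates to one and is a proper lognormal curve", {
  prior <- make_reference_prior(0.8, 0.31, "me")
  grid <- exp(seq(log(1e-4), log(50), length.out = 20000))
  dens <- prior_density_curve(prior, grid)
  integral <- sum(diff(grid) * (head(dens, -1) + tail(dens, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.001)
  # on a log-symmetric grid around the median, density of log-RR peaks there:
  # compare density transported to the log scale
  log_grid <- seq(log(0.8) - 1, log(0.8) + 1, length.out = 201)
  d_log <- prior_density_curve(prior, exp(log_grid)) * exp(log_grid)
  expect_equal(which.max(d_log), 101L)
  expect_error(prior_density_curve(prior, c(0.5, 0)), "rr_grid")
})

test_that("prior effective sample size scales with information", {
  ref <- reference_trial_info(797, 0.1956)
  # as informative as the reference trial itself
  expect_equal(prior_ess(make_reference_prior(1, 0.1956), ref), 797)
  # quadrupled variance quarters the ESS
  expect_equal(prior_ess(make_reference_prior(1, 2 * 0.1956), ref), 797 / 4)
  # the minimally informative prior is worth (much) less than one participant
  expect_lt(prior_ess(reference_priors()$minimally_informative, ref), 1)
  # the formula hook replaces the rule
  expect_equal(prior_ess(make_reference_prior(1, 1), ref,
                         formula = function(prior, ref) 42), 42)
})

test_that("priors round-trip through YAML and JSON files", {
  entries <- list(
    list(label = "Strongly Skeptical", median_rr = 1, sd_log = 0.14),
    list(label = "Strongly Enthusiastic", median_rr = 0.6, sd_log = 0.31)
  )
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(entries, yml)
  got <- read_priors(yml)
  expect_named(got, c("Strongly Skeptical", "Strongly Enthusiastic"))
  expect_equal(got[[2]]$sd_log, 0.31)

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(epidex = entries, epi = entries), jsn,
                       auto_unbox = TRUE)
  got2 <- read_priors(jsn)
  expect_named(got2, c("epidex", "epi"))
  expect_equal(got2$epidex[["Strongly Skeptical"]]$median_rr, 1)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(list(label = "no sd", median_rr = 1)), bad)
  expect_error(read_priors(bad), "sd_log")

  shipped <- system.file("extdata", "reference_priors.yaml", package = "bayesrr")
  sets <- read_priors(shipped)
  expect_named(sets, c("epidex", "epi", "dex"))
  expect_length(sets$epidex, 5)
})
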
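#' Configuration for an end-to-end analysis run
#'
#' @param trial_csv Path to the trial-data CSV (\code{site,arm,n,events}).
#' @param priors_file Path to a YAML/JSON priors file ([read_priors()]), or
#'   \code{NULL} to use the built-in [reference_priors()] on every contrast.
#' @param studies_csv Optional path to a historical-studies CSV; required
#'   when \code{weights} are given.
#' @param thresholds RR cutoffs for tail probabilities.
#' @param weights Optional increasing weights in \[0, 1\] for a
#'   historical-evidence sweep.
#' @param settings An [mcmc_settings()] object.
#' @param out_dir Output directory for the report bundle.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(trial_csv, priors_file = NULL, studies_csv = NULL,
                       thresholds = threshold_set(), weights = NULL,
                       settings = mcmc_settings(), out_dir = tempfile("bayesrr_run")) {
  if (!file.exists(trial_csv)) stop_field("trial_csv", paste0("file not found: ", trial_csv))
  if (!is.null(priors_file) && !file.exists(priors_file)) {
    stop_field("priors_file", paste0("file not found: ", priors_file))
  }
  if (!is.null(studies_csv) && !file.exists(studies_csv)) {
    stop_field("studies_csv", paste0("file not found: ", studies_csv))
  }
  if (!is.null(weights) && is.null(studies_csv)) {
    stop_field("weights", paste(
      "a weight sweep builds data-driven priors from historical studies;",
      "supply `studies_csv` alongside `weights`"))
  }
  if (!inherits(thresholds, "threshold_set")) thresholds <- threshold_set(thresholds)
  stopifnot(inherits(settings, "mcmc_settings"))
  structure(list(trial_csv = trial_csv, priors_file = priors_file,
                 studies_csv = studies_csv, thresholds = thresholds,
                 weights = weights, settings = settings, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis and write a report bundle
#'
#' Orchestrates the pipeline: read the trial data, build the priors, fit
#' the site-adjusted log-binomial model once per prior, summarize, and
#' (optionally) pool historical studies and sweep over prior weights.
#' Writes to \code{out_dir}:
#' \itemize{
#'   \item \code{priors_table.csv} — each prior's median RR, SD of log-RR
#'     and tail probabilities;
#'   \item \code{posterior_table.csv} — per prior and contrast: median RR,
#'     95\% credible interval and tail probabilities;
#'   \item \code{weight_sweep.csv} — when a sweep was requested;
#'   \item \code{diagnostics.json} — split R-hat / effective sample size
#'     per fit, plus any convergence warnings;
#'   \item \code{traceplots_<prior>.png} — traceplots per fit;
#'   \item \code{report.json} — every number above, machine readable,
#'     with the seed, settings and package version.
#' }
#' All posterior numbers in the bundle come from the summary objects
#' returned by [summarize_draws()]; the reporter only formats them.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the tables, summaries and diagnostics;
#'   component \code{converged} is FALSE when any fit raised a convergence
#'   warning.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- read_trial_csv(config$trial_csv)
  contrasts <- setdiff(intersect(ARM_LEVELS, unique(data$arm)), "placebo")

  # priors: either one named set per contrast, or one flat set applied to all
  prior_sets <- if (is.null(config$priors_file)) {
    NULL
  } else {
    read_priors(config$priors_file)
  }
  flat <- prior_sets %||% reference_priors()
  per_contrast <- !is.null(prior_sets) &&
    all(names(prior_sets) %in% ARM_LEVELS) &&
    !any(vapply(prior_sets, is_prior_spec, logical(1)))
  get_set <- function(ct) if (per_contrast) prior_sets[[ct]] else flat

  ptab <- priors_table(get_set(contrasts[1]), config$thresholds)
  utils::write.csv(ptab, file.path(config$out_dir, "priors_table.csv"),
                   row.names = FALSE)

  summaries <- list()
  diagnostics <- list()
  warnings_seen <- character(0)
  prior_names <- names(get_set(contrasts[1]))
  for (i in seq_along(prior_names)) {
    nm <- prior_names[i]
    prior_list <- stats::setNames(
      lapply(contrasts, function(ct) get_set(ct)[[nm]]), contrasts)
    fit <- withCallingHandlers(
      fit_hierarchical_log_binomial(data, prior_list, config$settings),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    diag <- check_convergence(
      fit, traceplot_file = file.path(config$out_dir,
                                      sprintf("traceplots_%02d.png", i)))
    diagnostics[[nm]] <- diag
    for (ct in contrasts) {
      summaries[[paste(nm, ct, sep = ".")]] <- summarize_draws(
        fit$log_rr[, ct], config$thresholds,
        label = sprintf("%s [%s]", prior_list[[ct]]$label, ct))
    }
  }
  stab <- posterior_table(summaries)
  utils::write.csv(stab, file.path(config$out_dir, "posterior_table.csv"),
                   row.names = FALSE)

  sweep_tab <- NULL
  if (!is.null(config$weights)) {
    studies <- read_studies(config$studies_csv)
    pooled <- pool_studies(studies, config$settings)
    sw <- weight_sweep(data, pooled, config$weights, config$settings,
                       config$thresholds)
    sweep_tab <- posterior_table(sw)
    utils::write.csv(sweep_tab, file.path(config$out_dir, "weight_sweep.csv"),
                     row.names = FALSE)
  }

  diag_json <- list(
    warnings = warnings_seen,
    per_fit = lapply(diagnostics, function(d) {
      stats::setNames(lapply(seq_len(nrow(d)), function(i) {
        list(rhat = d$rhat[i], ess = d$ess[i])
      }), d$parameter)
    })
  )
  jsonlite::write_json(diag_json, file.path(config$out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)

  report <- list(
    package_version = as.character(utils::packageVersion("bayesrr")),
    settings = unclass(config$settings),
    thresholds = as.numeric(config$thresholds),
    data_notes = attr(data, "assumptions"),
    priors = ptab,
    posteriors = stab,
    weight_sweep = sweep_tab,
    convergence_warnings = warnings_seen
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       dataframe = "rows")

  invisible(list(priors = ptab, posteriors = stab, summaries = summaries,
                 weight_sweep = sweep_tab, diagnostics = diagnostics,
                 converged = length(warnings_seen) == 0L,
                 out_dir = config$out_dir))
}
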
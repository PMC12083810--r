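# Split R-hat: each chain is halved, and the potential scale reduction
# factor is computed over the 2m half-chains. Values near 1 indicate the
# chains agree on location and spread.
split_rhat <- function(chain_list) {
  stopifnot(is.list(chain_list), length(chain_list) >= 1L)
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x)
    h <- n %/% 2
    list(x[seq_len(h)], x[(n - h + 1):n])
  }), recursive = FALSE)
  m <- length(halves)
  if (m < 2L) return(NA_real_)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(if (stats::var(means) == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a fitted model
#'
#' Computes split R-hat and effective sample size for every treatment
#' contrast and for the site/hyper parameters, and optionally exports
#' traceplots. With a single chain, R-hat is reported as \code{NA} (it
#' requires at least two chains).
#'
#' @param samples A [fit_hierarchical_log_binomial()] result.
#' @param traceplot_file Optional PNG path; when given, traceplots of the
#'   treatment contrasts are written there.
#' @return A data frame with columns \code{parameter}, \code{rhat},
#'   \code{ess}, \code{converged} (rhat < 1.01, \code{NA} when rhat is
#'   unavailable).
#' @export
check_convergence <- function(samples, traceplot_file = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  pars <- colnames(as.matrix(samples$chains[[1]]))
  # drop structurally constant nodes (the placebo coefficient is fixed at 0)
  pars <- pars[vapply(pars, function(p) {
    stats::var(as.numeric(as.matrix(samples$chains[[1]])[, p])) > 0
  }, logical(1))]
  rhat <- vapply(pars, function(p) {
    if (length(samples$chains) < 2L) return(NA_real_)
    split_rhat(lapply(samples$chains, function(m) as.numeric(as.matrix(m)[, p])))
  }, numeric(1))
  ess <- vapply(pars, function(p) {
    sum(vapply(samples$chains, function(m) {
      as.numeric(coda::effectiveSize(m[, p]))
    }, numeric(1)))
  }, numeric(1))
  # ESS cannot exceed the number of retained draws
  ess <- pmin(ess, nrow(samples$log_rr))

  if (!is.null(traceplot_file)) {
    grDevices::png(traceplot_file, width = 900,
                   height = 300 * length(samples$contrasts))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(length(samples$contrasts), 1),
                  mar = c(3, 4, 2, 1))
    for (ct in samples$contrasts) {
      first <- TRUE
      for (k in seq_along(samples$chain_log_rr)) {
        y <- samples$chain_log_rr[[k]][, ct]
        if (first) {
          plot(y, type = "l", col = k, ylab = paste("log-RR", ct),
               xlab = "", main = ct)
          first <- FALSE
        } else {
          graphics::lines(y, col = k)
        }
      }
    }
  }
  data.frame(
    parameter = pars,
    rhat = unname(rhat),
    ess = unname(ess),
    converged = unname(ifelse(is.na(rhat), NA, rhat < 1.01)),
    row.names = NULL
  )
}
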
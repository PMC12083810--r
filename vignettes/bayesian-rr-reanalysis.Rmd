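---
title: "Bayesian relative-risk reanalysis: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian relative-risk reanalysis: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesrr)
```

`bayesrr` reanalyzes randomized trials with a binary outcome on the
relative-risk (RR) scale. This vignette is the package's account of the
statistical machinery: the outcome model and its assumptions, how the two
prior families are built, what the synthetic-data generator does and does
not emulate, and the numerical and design decisions a maintainer should
know about.

## The outcome model

For a trial with sites $s$ and arms $a$ (placebo plus up to three
treatments in a factorial layout), the observed event counts are modelled
as

$$\mathrm{events}_{s,a} \sim \mathrm{Binomial}(n_{s,a},\, p_{s,a}), \qquad
\log p_{s,a} = \alpha_s + \beta_a, \qquad \beta_{\mathrm{placebo}} = 0.$$

The log link makes $e^{\beta_a}$ the relative risk of arm $a$ versus
placebo — the estimand clinicians reason about — at the price of a support
constraint: fitted probabilities must stay below 1. The likelihood assigns
(numerically) zero support to parameter values violating it; in the JAGS
implementation this is realized by clamping $p$ at $1 - 10^{-12}$, at which
point each non-event contributes $\log(1-p) \approx -27.6$ to the
log-likelihood, so any dataset containing non-events pushes the sampler
decisively back inside the valid region. This clamping, rather than a hard
rejection, is also why priors that place mass beyond the boundary (the
minimally informative prior has SD 10 on the log-RR) sample without
incident.

Each treatment contrast is coded with its own coefficient against placebo —
the combination arm gets one $\beta$, not a main-effects-plus-interaction
decomposition — because the reporting target is one RR per arm versus
placebo.

Site adjustment is hierarchical: $\alpha_s \sim N(\mu_\alpha,
\tau_\alpha^2)$ with hyperpriors $\mu_\alpha \sim N(\log 0.25, 1.5^2)$ and
$\tau_\alpha \sim \mathrm{Half\text{-}Normal}(1)$. These are weakly
informative on the scale of plausible baseline admission risks (the
$\mu_\alpha$ prior puts 95% mass on baseline risks between roughly 1% and
90%); with a single site they act as a wide, proper prior on the one
intercept and the data dominate. They are this package's defaults — the
original analyses of such trials rarely publish their site hyperpriors, so
these are documented choices, not reconstructions.

Sampling uses JAGS with 4 chains of 20,000 iterations and 10,000 burn-in by
default. Every chain gets a Mersenne-Twister stream derived
deterministically from the user seed, so identical settings give identical
draws. A split-$\widehat{R}$ above 1.01 on any treatment contrast raises a
warning and is stored on the fitted object; `check_convergence()` reports
split-$\widehat{R}$ and effective sample size per parameter and can export
traceplots.

## Reference priors

A prior on the RR is specified by its median $m$ and the SD $\sigma$ of the
log-RR: $\log RR \sim N(\log m, \sigma^2)$, so the RR is lognormal with
median exactly $m$. Five archetypes span the spectrum of clinical belief:

| stance | median RR | SD(log RR) |
|---|---|---|
| minimally informative | 1 | 10 |
| strongly enthusiastic | 0.6 | 0.31 |
| moderately enthusiastic | 0.8 | 0.14 |
| moderately skeptical | 1 | 0.31 |
| strongly skeptical | 1 | 0.14 |

Skeptics center on no effect (median 1) and differ in how firmly they hold
it; enthusiasts center below 1. The minimally informative prior is a proper
but extremely diffuse lognormal rather than an improper flat prior: it
keeps every computation well-defined, is worth (much) less than one
trial participant of information, and yields posteriors that numerically
track the frequentist point estimate and interval. None of the archetypes
place meaningful prior mass on harm, reflecting settings where no credible
evidence of risk increase exists; users modelling potential harm should
supply their own `make_reference_prior()` with median above 1 or larger
spread.

Prior tail probabilities $P(RR < t) = \Phi\!\big((\log t - \log
m)/\sigma\big)$ are computed exactly, never by simulation.

**Prior effective sample size.** `prior_ess()` translates a prior's
information into participant-equivalents relative to a reference trial
($n$ participants, log-RR standard error $se$): $ESS = n \cdot
se^2/\sigma^2$, i.e. information per participant is equated so that a prior
exactly as informative as the trial has $ESS = n$. Conventions for this
translation differ across the literature and none is canonical, so the rule
is exposed as a replaceable `formula` hook; published ESS figures computed
under other conventions will not in general be reproduced by the default.

## Data-driven priors

Historical two-arm studies enter as counts. Each study's log-RR and
delta-method standard error are
$$\hat\theta_j = \log\frac{a_j/n_{1j}}{c_j/n_{0j}}, \qquad
se_j = \sqrt{\tfrac{1}{a_j} - \tfrac{1}{n_{1j}} + \tfrac{1}{c_j} -
\tfrac{1}{n_{0j}}},$$
with a Haldane–Anscombe correction (0.5 added to all four cells) whenever
any cell is zero; corrected studies are flagged. Pooling is a Bayesian
normal-normal hierarchy — true effects $\theta_j \sim N(\mu, \tau^2)$,
observations $\hat\theta_j \sim N(\theta_j, se_j^2)$ — with weakly
informative hyperpriors $\mu \sim N(0, 10^2)$, $\tau \sim
\mathrm{Half\text{-}Normal}(1)$. The sampler works with the marginalized
likelihood $\hat\theta_j \sim N(\mu, se_j^2 + \tau^2)$: integrating the
latent effects out is exactly the same model but keeps mixing healthy as
$\tau \to 0$, where the centered latent parameterization freezes (the
`tau_prior_sd` argument near zero recovers fixed-effect pooling, which the
tests exploit against a closed-form inverse-variance oracle).

Down-weighting discounts historical evidence for between-trial differences
in populations, interventions and outcomes: weight $w \in (0,1]$ makes one
historical participant contribute like $w$ of a current participant, by
inflating the pooled SD to $\sigma/\sqrt{w}$ while leaving the median
untouched. The weighting acts on the *pooled* SD rather than the per-study
variances; the two differ when $\tau > 0$, and the pooled-SD convention is
the one consistent with scaling each participant's information by a common
factor after synthesis. `weight_sweep()` refits the trial across a weight
grid, with $w = 0$ handled by substituting the minimally informative prior;
arms other than the swept contrast keep the minimally informative prior so
the sweep isolates the effect of borrowing.

## Summaries and reporting conventions

Posterior draws are summarized by the sample median of $e^{\beta}$, the
equi-tailed 95% credible interval from the 2.5% and 97.5% sample quantiles
(type-7 linear interpolation between order statistics, for determinism),
and threshold probabilities as the fraction of draws below each cutoff. The
default cutoffs $1, 0.9, 0.8, 0.6$ correspond to any benefit and to
$\ge$10/20/40% risk reductions; a summary refuses fewer than 1000 draws.
`summarize_normal()` is the closed-form twin used for priors and for the
conjugate oracle. Report tables round percentages half-away-from-zero to
integers, render probabilities below 0.5% as `<1` (the printed-table
convention for "approximately zero") and at or above 99.5% as `100`;
medians and interval endpoints are rounded to two decimals.

## The conjugate oracle and what "agreement" means

For aggregate two-arm data the package carries an independent closed form:
a normal likelihood summary on the log-RR (the delta-method mean and SE
above) combined with the normal prior by precision weighting. It exists to
test the sampler, not to replace it. Two caveats define its precision.
First, it ignores the (weak) site-intercept prior. Second — and dominant —
the delta-method normal replaces a mildly skewed exact binomial posterior:
against brute-force 2-D quadrature of the exact posterior for the packaged
fixture under the strongly skeptical prior, the oracle's median is off by
about 0.004 and its tail probabilities by up to about 0.013. The test suite
therefore checks the MCMC against quadrature at Monte Carlo precision
(3 MC standard errors), and the oracle against quadrature at
approximation-level tolerances (0.01 on medians, 0.02 on tail
probabilities). Treat oracle-vs-sampler discrepancies inside those bands as
expected behaviour.

## The synthetic-data generator

`simulate_trial()` draws site intercepts $\alpha_s \sim
N(\log(\mathrm{baseline\_risk}), \mathrm{site\_sd}^2)$, sets arm risks
$p_{s,a} = e^{\alpha_s} RR_a$, and draws binomial events — exactly the
structure the inference model assumes. A site draw that puts any arm risk
at or above 1 is rejected and redrawn (truncating instead would silently
change the generative law); rejection counts are attached to the dataset,
and parameter settings whose per-site rejection probability exceeds 0.5 are
refused with an explanation. Defaults describe a realistic multi-site
pediatric emergency trial: 20 sites, 40 participants per site per arm (800
per arm), baseline admission risk 0.25 (matching the ~26% placebo admission
rate typical of bronchiolitis cohorts), site SD 0.3 on the log scale
(roughly a ±45% spread in site baseline risks, moderate heterogeneity), and
arm RRs of 1/0.85/0.9/0.65 for placebo/epinephrine/dexamethasone/
combination.

What the generator does *not* emulate: individual covariates and
severity scores, non-binomial overdispersion within site-arms, differential
loss to follow-up, and site-by-treatment interactions. Passing calibration
tests therefore certify the estimation machinery under the model's own
assumptions — they do not certify robustness to the ways real trials
violate them.

`simulate_study_collection()` generates heterogeneous historical study
pools (per-study true log-RR $\sim N(\mu, \tau^2)$, uniform per-arm sizes,
binomial outcomes) for exercising the pooling pipeline; it stands in for
real historical-study tables, which is why the packaged example pool is
explicitly labelled synthetic.

`canbest_fixture()` ships the aggregate counts of the motivating four-arm
bronchiolitis trial (797 infants, admissions 34/47/51/53). Two
reconstruction assumptions are recorded on the object: the trial's per-site
counts were never published, so the fixture is single-site (fits to it are
unadjusted-model analyses, and match published site-adjusted medians for
some but not all priors — the minimally informative posterior median, for
instance, lands near the unadjusted 0.65 rather than the adjusted 0.66);
and the arm denominators 199/199/199/200 reconstruct "randomized equally"
with the remainder placed in placebo (results are insensitive to moving
that one participant).

## Problem sizes used by the test suite

Statistical tests run at sizes chosen to put Monte Carlo error well below
the tolerance being asserted while keeping the suite brisk: fixture refits
for published-value reproduction use the full 4 chains × 20,000 draws;
monotonicity-across-priors uses 2 × 10,000 (posterior-median gaps of
≥ 0.014 against MC SEs of ~0.004); interval-coverage calibration uses 20
replicate 20-site trials at 2 × 10,000, judged against the central 95%
binomial band for 20 trials at nominal 95% coverage; pooled-mean recovery
uses 50 replicate 20-study pools at 2 × 3,000.

## Known limitations

* The log-binomial constraint is enforced numerically (zero support at
  machine precision), not by a truncated prior; datasets consisting almost
  entirely of events could in principle let chains linger near the
  boundary, and the convergence diagnostics are the guard there.
* Aggregate single-site fixtures cannot reproduce site-adjusted published
  values exactly; agreement has to be argued prior-by-prior (see the
  oracle section).
* The ESS translation is convention-dependent (hook provided).
* Priors are lognormal on the RR only; odds-ratio or risk-difference
  parameterizations are out of scope.
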
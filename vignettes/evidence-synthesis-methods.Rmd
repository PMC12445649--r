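---
title: "Methods: frequentist and Bayesian synthesis of PMI definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequentist and Bayesian synthesis of PMI definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmimeta)
```

## The problem

Competing consensus definitions of periprocedural myocardial infarction
(PMI) after coronary bypass surgery — UDMI-3/4, SCAI, ARC-2 — use different
biomarkers, thresholds and ancillary criteria. A study-level meta-analysis
comparing them must (i) pool the prevalence of PMI per definition, (ii)
pool the hazard ratios linking each definition to long-term mortality,
(iii) compare definitions formally, and (iv) check robustness via
publication-bias tests and a sensitivity analysis on patient-level data
reconstructed from published survival curves. `pmimeta` implements each of
these stages as a separately testable operation.

## Frequentist pooling

Study effects enter as log hazard ratios; published HRs with 95% CIs are
converted by `hr_ci_to_log()` assuming log-scale symmetry,
$se = (\log \mathrm{hi} - \log \mathrm{lo}) / (2 z_{0.975})$. The exact
quantile $z_{0.975} = 1.959964$ is the default; a `rounded_z` switch
reproduces arithmetic done with the hand-rounded 1.96, since published
tables were built with both conventions.

`dersimonian_laird()` implements the moment estimator of the
between-study variance. No Hartung–Knapp adjustment is applied: Wald
normal intervals match the defaults of the meta-analysis software
generation the package mirrors, and the choice is confined to one line so
alternative intervals can be added without touching the estimator.

Prevalences are pooled on the **logit** scale with per-study variance
$1/e_i + 1/(n_i - e_i)$. The transform is a deliberate design choice:
log or arcsine transforms would also be defensible, but the logit keeps
$\tau^2$ interpretable on the log-odds scale on which heterogeneity of
rare binary outcomes is usually reported. Boundary counts ($e_i \in \{0,
n_i\}$) are an error unless the 0.5 continuity correction is explicitly
enabled — silent data alteration is worse than a refusal.

`egger_test()` is the classical (unweighted) Egger regression of the
standardized effect on precision with a $t_{k-2}$ p-value. When the inputs
are exactly collinear the residual variance collapses and the classical
t statistic becomes 0/0; the implementation detects this and reports
$t = 0, p = 1$ for a zero intercept (or an infinite $t$ otherwise).
`interaction_test()` is the Altman–Bland z-test on the difference of two
independent pooled log HRs.

## Bayesian re-analysis

The hierarchical model marginalizes analytically to
$y_i \mid \mu, \tau \sim N(\mu, se_i^2 + \tau^2)$, leaving a
two-dimensional posterior over $(\mu, \tau)$. Priors:

* $\mu \sim N(0, 2^2)$ — "N[0, 2]" is read as mean 0, **SD** 2, the
  parameterization convention of the point-and-click Bayesian tools whose
  output this reproduces. The report prints the interpretation, and the
  prior is overridable in `prior_spec()`.
* $\tau \sim \mathrm{InvGamma}(\alpha = 1, \beta = 0.15)$, placed on the
  heterogeneity **SD** $\tau$, not on $\tau^2$.

The default estimator is **deterministic quadrature**: the joint log
kernel is evaluated on a trapezoid grid over $(\mu, \log\tau)$ centred on
the posterior mode (located by BFGS), spanning mode $\pm 8$ posterior SDs
in $\mu$ and $\pm 10$ in $\log\tau$ (truncated to $\tau \in [10^{-5},
200]$), with 401 × 301 points. Integrating on $\log\tau$ (with the
Jacobian) handles the inverse-gamma's heavy right tail far better than a
linear $\tau$ grid. Determinism means identical reruns byte-for-byte and
no seed sensitivity in the headline numbers. A random-walk Metropolis
sampler on the same parameterization (step 2.4 × mode SDs) serves as a
stochastic cross-check; the two agree to well under 0.01 on the posterior
mean in the shipped tests.

Summaries follow reporting practice: the central (equal-tailed) 95%
credible interval, and "mean HR" $= \exp(\text{posterior mean of }\log
HR)$ — the back-transform of the location, not the posterior mean of
$e^\mu$, matching how such tables are printed.

**Threshold probabilities** $P(\mu > t \mid y)$ are read off the grid CDF.
A first-class *normal-approximation mode* computes them from a (mean, SD)
pair alone: published comparison tables are reproducible from the printed
posterior summaries without access to per-study data, and the residual
discrepancy (≤ 0.1 percentage points) is attributable to rounding of the
printed mean and SD.

**Bayes factors** compare the full model against the point null $\mu = 0$
with the $\tau$ prior retained. Both routes are provided because either
could stand behind a published number: marginal-likelihood integration
(2-D vs 1-D quadrature, all in log space) and the Savage–Dickey density
ratio at $\mu = 0$; they agree within 5% on the test battery and to 0.03%
on typical instances. With $\tau$ fixed the evidence has a conjugate
closed form, used as an exact oracle in the tests. Evidence bins: 1 none,
(1, 3] anecdotal, (3, 10] moderate, (10, 30] strong, > 30 very strong;
values below 1 are binned on the reciprocal with a direction flag.

One modelling caveat: with a single study the likelihood cannot identify
$\tau$, so the marginal posterior of $\mu$ inherits the prior's
heterogeneity scale no matter how precise the study is. Claims of the
form "one precise study forces a tight posterior on $\mu$" hold only
conditionally on small $\tau$ (e.g. `tau_fixed = 0`), and the tests state
them that way.

## Kaplan–Meier reconstruction

`reconstruct_ipd()` recovers per-patient (time, event) records from a
digitized survival curve plus its numbers-at-risk row, using an interval
solver of the Guyot family (the published algorithm family for this task;
the method description it follows gives no pseudocode, so the solver is
specified here): within each risk-table interval, censorings are assumed
uniformly spread, an initial censoring count is guessed from the mismatch
between the curve's survival ratio and the printed at-risk decline, event
counts at each digitized step follow from the product-limit ratios, and
the censoring count is iterated until the reconstructed at-risk count
matches the next printed value. Conservation is enforced exactly: events
+ censorings + carried-forward at-risk = entering at-risk in every
interval. Because event counts are integers, rounding can overshoot an
interval's capacity by a subject or two; the solver then returns the
excess subjects to the risk set rather than failing, and only a genuinely
contradictory table (at-risk increasing, or implying negative counts) is
an error naming the interval. After the last risk time, survivors are
censored administratively at the final curve time; when the total event
count is reported, a final pass searches the last-interval censoring
count that matches it.

Digitization inputs are cleaned first (`clean_curve()`): sorting,
clamping to [0, 1], running-minimum flattening of pixel-level rises, and
anchoring at (0, 1). Curves are treated in years on a continuous scale.

The pooled sensitivity analysis concatenates reconstructed IPD across
studies with the study label retained and fits a univariable Cox model
(PMI vs no PMI) via `survival::coxph()`, Efron ties by default —
reconstruction groups events at digitized step times, so ties are the
norm; Breslow is available, and a stratified-by-study fit is a flag.
`km_estimate()` wraps `survival::survfit()`.

## Synthetic data: what it emulates, and what it does not

The generators (`sim_config()`, `simulate_effects()`,
`simulate_prevalence()`, `simulate_survival()`) draw from exactly the
models the analysis assumes: normal hierarchical log HRs, logit-normal
prevalences with binomial sampling, and two-group exponential survival
with administrative censoring plus uniform dropout. Defaults describe a
realistic CABG meta-analysis at the scale of the motivating literature:
k = 8 studies, true pooled log HR 0.86 with heterogeneity SD 0.36,
per-study SEs 0.15–0.45, ~3% prevalence with substantial logit-scale
spread, study sizes 150–4800, and 5-year follow-up with a control hazard
of 0.08/year. One global seed fans out to fixed per-generator offsets, so
adding a generator never perturbs existing fixtures.

Passing tests on these data show the estimators are correct *under the
assumed models*. Real study-level data violate them in ways the generator
deliberately does not emulate: non-proportional hazards, correlated
definitions within a study, adjusted vs unadjusted HR mixtures, and
digitization noise beyond step-sampling. The `adjusted` flag is carried
through but not used analytically, since which studies adjusted for what
is not part of the data model.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use simulation sizes chosen to
make Monte-Carlo error a small fraction of each tolerance while keeping a
full run in the tens of seconds on one core: 5000 replicates for the Egger
type-I error, 500 for credible-interval coverage, 200 for posterior-mean
bias and for survival-generator consistency, 1000 + 1000 subjects for the
reconstruction round trip (recovering the Cox HR to well under 1%
relative), and 60 000 Metropolis iterations for the MCMC cross-check.
Quadrature grids shrink to 201 × 151 inside replicated simulations; the
coarser grid changes posterior means by under $10^{-3}$.

Degenerate inputs are decided, not left to chance: zero-width CIs,
non-positive SEs, boundary prevalence counts without the correction,
single-point curves, increasing risk tables, and one-armed Cox data are
all errors with targeted messages; a header-only CSV is an empty result
with a warning.

## Known limitations

- The follow-up pooling SD uses the standard pooled-variance
  decomposition (within + between); published cohort summaries rarely
  state their pooling formula, and the report footer flags the choice.
- No trim-and-fill, meta-regression, or subgroup machinery; definitions
  are simply analysed separately.
- No model averaging over fixed/random effects, and no prior-sensitivity
  sweeps beyond the overridable `prior_spec()`.
- The KM branch accepts any curve/risk-table set; judging which published
  curves are adequate for reconstruction remains the analyst's call.
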
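---
title: "Assessing goodness-of-fit tools for diagnostic latent class models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing goodness-of-fit tools for diagnostic latent class models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmgof)
```

## The problem

When several imperfect diagnostic tests are applied to the same subjects and
no gold standard exists, a two-class latent class model (LCM) can estimate
the prevalence of the target condition and the sensitivity and specificity
of every test. The classical model assumes *conditional independence*
(CInd): given the true (latent) disease status $D$, the test results
$T_1,\dots,T_4$ are mutually independent,

$$P(T_1{=}t_1,\dots,T_4{=}t_4)
 = \pi \prod_{i=1}^{4} Se_i^{t_i}(1-Se_i)^{1-t_i}
 + (1-\pi)\prod_{i=1}^{4} Sp_i^{1-t_i}(1-Sp_i)^{t_i}.$$

Real tests often violate this — two assays may measure the same biomarker —
and practitioners routinely check the CInd fit with *residual correlation
plots* and overall or pairwise $\chi^2$ and $G^2$ statistics, adding
dependence terms for pairs that look misfitted. `lcmgof` provides the full
machinery to study how reliable that practice actually is: an exact
simulator for data with a known conditional dependence, a Bayesian sampler
for the CInd model, the goodness-of-fit tools themselves, and Monte Carlo
performance aggregation in the ADEMP style (aims, data-generating
mechanisms, estimands, methods, performance measures).

## The data-generating model

Data are generated from a two-class "fixed effect" conditional-dependence
model in which only tests 1 and 2 are correlated, and only within the
diseased class. A covariance $covse_{12} = \mathrm{Cov}(T_1,T_2 \mid D{=}1)$
enters the Se-product over the first two tests with sign
$(-1)^{t_1-t_2}$ — added when the two results agree, subtracted when they
disagree — so the margins of every test are untouched. Validity of all 16
pattern probabilities bounds the covariance by
$\min(Se_1,Se_2) - Se_1 Se_2$, and scenarios parameterize it as a fraction
$\omega$ of that maximum. Because the grid always sets $Se_1 = Se_2$,
$\omega$ is also the conditional Pearson correlation between $T_1$ and
$T_2$ in the diseased class.

```{r}
sc <- scenario(prevalence = 0.5, sensitivities = c(0.6, 0.6, 0.9, 0.9),
               specificities = c(0.6, 0.6, 0.9, 0.9), omega = 0.5,
               n_obs = 2000)
sc
round(agreement_probabilities(cdep_pattern_probs(sc)), 3)
```

A data set is a single multinomial draw over the 16 response patterns
(pattern index $k = 8t_1 + 4t_2 + 2t_3 + t_4$, a convention fixed once so
observed and expected cells always align); the 16 counts are the sufficient
statistic for everything downstream, which keeps thousand-replicate runs
cheap.

The full study grid crosses $n_{obs} \in \{500, 2000, 5000\}$,
$\pi \in \{0.2, 0.5\}$, six sensitivity and seven specificity combinations
at levels 0.9 ("H") and 0.6 ("L"), and $\omega \in \{0.5, 0.9\}$ — 504
scenarios, labelled by their letter codes (e.g. `LLHH-LLHL`). The grid is
emitted by a pure function, so subsets are first-class configurations:

```{r}
grid <- build_full_grid()
length(grid)
head(grid_as_data_frame(grid), 3)
```

## Fitting the conditional-independence model

The CInd model is deliberately fitted to data that violate it. Fitting is
Bayesian: Beta(1, 1) priors on $\pi$ and all $Se_i$, $Sp_i$, truncated to
$Se_i \ge 1 - Sp_i$. The constraint removes the mirror mode
$(Se, Sp) \to (1-Se, 1-Sp)$ in which false positive and negative fractions
masquerade as accuracies.

The sampler is a data-augmentation Gibbs sampler written for this exact
model (implemented in C++): each sweep (a) splits every pattern count
between the two classes with the conditional class-membership probability,
(b) updates $\pi$ from its Beta full conditional, and (c) updates each
$Se_i$ from its Beta full conditional truncated to $[1-Sp_i, 1]$ and each
$Sp_i$ truncated to $[1-Se_i^{new}, 1]$, by inverse-CDF sampling. Truncated
full conditionals preserve the joint truncated prior exactly and avoid
rejection loops. Initial values are drawn independently per chain from the
constrained prior, so between-chain diagnostics are meaningful. The
defaults follow the study protocol: 3 chains, 5000 burn-in and 10000
retained sweeps per chain.

Convergence screening mirrors the protocol: a fit is excluded from
performance aggregation when any parameter has $\widehat{R} > 1.1$ or an
effective sample size below 400 (equivalently, a Monte Carlo error above 5%
of the posterior SD). Since the protocol's diagnostics are named but not
pinned to a variant, the package uses the modern defaults: rank-normalized
split-$\widehat{R}$ (taking the larger of the bulk and folded statistics;
strictly more conservative than the classic estimator) and the multi-chain
autocorrelation ESS with Geyer's initial monotone positive sequence,
pooled over chains. Zero-variance chains return $\widehat{R} = 1$ with a
flag rather than NaN. Both estimators are validated in the test suite
against `coda`'s independent implementations and against closed forms
(AR(1) chains).

```{r, eval = FALSE}
d <- simulate_dataset(sc, seed = 1)
fit <- gibbs_fit(d, mcmc_settings(), seed = 1)
fit$converged
```

## Measuring lack of fit

For each pair $(i,j)$ the *residual correlation* is the observed marginal
(phi) correlation $r_{ij}$ minus the model-fitted one $r^M_{ij}$. The
observed correlation is fixed by the data; the fitted one is evaluated at
every retained posterior draw, so each residual has a posterior
distribution summarized by its median and equal-tailed 95% credible
interval. An interval strictly excluding zero flags pairwise misfit, and a
flag on *any* pair is read as lack of overall fit — the residual-plot
analogue of an omnibus test.

The $\chi^2$ and $G^2$ statistics are computed at the posterior medians
(plug-in, not per-draw — matching how frequentist referents use them) over
the 16 cells, referred to the 95% critical value with
$df = 2^4 - 9 - 1 = 6$, and over each pair's collapsed 2×2 agreement table
with $df = 1$. Critical values come from `qchisq(0.95, df)`, never
hard-coded literals. Empty observed cells use the $0\log 0 = 0$ convention;
an expected cell at zero is impossible for interior parameter values and is
guarded with an error naming the cell.

Two numerical edge cases are handled explicitly rather than silently:

* a replicate in which some test is observed all-positive or all-negative
  has no defined observed correlation; it is flagged
  `residuals_defined = FALSE` and excluded from the residual tool's
  denominator (counts are reported, and both denominators are visible in
  the replicate table);
* "CrI excludes zero" uses strict exclusion of the closed interval — a
  boundary tie is measure-zero but the convention is stated so the flag is
  testable.

```{r, eval = FALSE}
g <- assess_fit(d, fit)
g$residuals
plot_residuals(g)
```

## Performance measures

`aggregate_scenario()` turns the flat replicate table into the ADEMP
performance measures: detection percentages per tool (and per pair), bias
of each posterior-median estimate, and 95% CrI coverage — always over
converged replicates only, with replicate accounting conserved
($n_{sim} = n_{converged} + n_{excluded}$). Proportions carry exact
Clopper–Pearson 95% Monte Carlo intervals (Beta quantiles); means carry
$\pm z_{0.975} \cdot \mathrm{MCSE}$ intervals with
$\mathrm{MCSE} = sd/\sqrt{n}$. Bias is reported both as the mean of signed
differences (the signed convention preserves the over/under-estimation
directions the performance summaries rely on) and as the median with
2.5th/97.5th percentiles used by cross-scenario summaries;
`aggregate_across_scenarios()` pools from the replicate level, not by
averaging scenario summaries.

The planning formula
$n_{req} = (z_{0.975}\sqrt{p(1-p)}/(L/2))^2$ gives the replicates needed
for a 95% Monte Carlo CI of length $L$; it is rounded to the nearest
integer (983 at $p = 0.8$, $L = 0.05$), which is how the protocol's printed
planning values are obtained.

## Reproducibility and problem sizes

Every replicate owns a seed derived deterministically from the root seed,
the scenario position and the replicate index, so execution order is
irrelevant and reruns are byte-identical; `run_study()` can checkpoint
replicate tables to disk and resumes by skipping completed replicates.

The full protocol — 504 scenarios × 1000 replicates — is a cluster-scale
computation and is expressed here simply as
`study_config(build_full_grid(), n_sim = 1000)`. The package's own
reference runs use the three desk-scale presets (`study_preset()`), each a
single illustrative scenario ($\pi = 0.5$, $\omega = 0.5$,
$n_{obs} = 2000$) at 100 replicates with the full MCMC protocol — about
two minutes each on one CPU, and enough for a binomial Monte Carlo
tolerance of roughly ±10 percentage points on a detection rate. Calibration
checks (coverage, null false-flag rates) run at $n_{obs} = 500$ with
shortened chains (3 × 1500 retained after 500 burn-in), sizes chosen so the
posterior is still well explored for data that actually satisfy the CInd
model.

## What the simulator does and does not emulate

The generator reproduces the study conditions exactly: one positive
fixed-effect covariance between tests 1 and 2 in the diseased class,
conditional independence everywhere else, multinomial sampling of complete
four-test records. It does not emulate features of real data such as
random-effects (subject-severity) dependence, dependence in the
disease-free class, missing test results, more than two latent classes, or
covariate structure. Conclusions from passing tests therefore concern the
behaviour of goodness-of-fit tools under this specific, deliberately simple
dependence — which is precisely the setting in which the tools'
counterintuitive behaviour (flagging the conditionally independent pair
$T_3 \times T_4$ instead of the truly dependent $T_1 \times T_2$) already
appears.

## Known limitations

* The model is fixed at four tests and a single dependence term; the
  pattern space, pair bookkeeping and sampler all assume it.
* Pairwise $\chi^2$/$G^2$ p-values are asymptotic; no parametric bootstrap
  is provided.
* The effective-sample-size threshold is applied to the pooled multi-chain
  estimate; protocols that screen per-chain would exclude slightly more
  replicates.
* "Mean absolute bias" is reported as the mean of signed differences
  (alongside median and percentiles); a mean-of-absolute-values reading
  would discard the direction information that the bias summaries report.
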
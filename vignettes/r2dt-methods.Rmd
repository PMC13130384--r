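---
title: "Reference-dependent utilities for phase I-II dose finding: models, elicitation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-dependent utilities for phase I-II dose finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(r2dt)
```

## The decision problem

A phase I–II trial studies a small grid of doses $d_1 < \dots < d_k$ with
two binary endpoints per patient: an efficacy event $Y_E$ (e.g. partial
response) and a toxicity event $Y_T$ (dose-limiting toxicity).  After
each cohort of $c$ patients the design must pick the dose for the next
cohort, or stop; after the last cohort it picks the dose to carry into
further research, or declares that no dose is acceptable.  `r2dt`
implements this as a Bayesian decision problem: a probability model for
the dose–response curves, a utility over the (efficacy, toxicity)
probability pair, and the Bayes action — the dose maximising posterior
expected utility.

Two features distinguish the utility from the trade-off scores common in
this literature.  First, it is a von Neumann–Morgenstern utility: it is
elicited from preferences over *lotteries*, so it lives on an interval
scale and its expectation under the posterior is the right thing to
maximise when the probabilities themselves are uncertain — which is the
normal state of affairs with 3–45 patients.  Second, it is
*reference-dependent*: each attribute is judged against a clinically
anchored reference point, with different risk attitudes above and below
it and with losses weighted more heavily than gains.  This moves the
ethical constraints (avoid futile and toxic doses) into the utility
itself instead of bolting them on as admissibility rules.

## Marginal utilities

For a probability $p$ and reference $\bar\pi$, write the gain/loss
transform $t = p - \bar\pi$ for efficacy and $t = \bar\pi - p$ for
toxicity (so larger $t$ is always better).  The unnormalised marginal
utility is the segmented power function

$$v(t) = \begin{cases} t^{\alpha_G} & t \ge 0 \\
 -\lambda\,(-t)^{\alpha_L} & t < 0 ,\end{cases}$$

rescaled affinely so the worst attainable outcome maps to 0 and the best
to 1.  The parameters, their meaning and the package defaults (preset
`"R2DT1"`):

| parameter | meaning | efficacy | toxicity |
|---|---|---|---|
| reference $\bar\pi$ | gain/loss boundary (standard-of-care response rate; target toxicity) | 0.50 | 0.35 |
| $\lambda$ | loss aversion: weight of losses relative to gains | 2 | 2 |
| $\alpha_G$ | risk exponent in gains (<1 concave, risk averse) | 0.7 | 0.7 |
| $\alpha_L$ | risk exponent in losses (<1 convex on the loss side) | 0.7 | 0.7 |

All quantities are probabilities, so the parameters are unitless.  With
exponents below 1 the marginal is sigmoidal: concave above the
reference, convex below it, with loss aversion stretching the loss limb.
Exponents must be strictly positive — the limiting step function at
$\alpha = 0$ is not representable as a power ($0^0$ is undefined on the
branch boundary) and the constructor rejects it.  $\lambda = 0$ is
accepted with a warning (it flattens the loss branch; values above 1 are
the intended regime).  The gain branch is closed at the reference
($t = 0$ belongs to it); both branches give the same value there, so the
convention only fixes which code path runs.

One documentation note: the convex loss branch is sometimes glossed as
"risk seeking" and sometimes as effectively risk averse when outcomes
are reframed relative to the reference.  The package follows the
formulas, not the gloss — the loss branch is $-\lambda(-t)^{\alpha_L}$,
convex on the loss side for $\alpha_L < 1$.

## Joint utility

Assuming mutual utility independence of the two attributes, the joint
utility is multiplicative:

$$u(\pi_E, \pi_T) = k_E\,u_E + k_T\,u_T + k_{ET}\,u_E u_T,
\qquad k_{ET} = 1 - k_E - k_T .$$

$k_E$ is the utility of certain efficacy with certain toxicity
($u_E = 1, u_T = 0$), $k_T$ of neither event possible.  The default
corner weights are $k_E = 0.25$, $k_T = 0.15$, giving a positive
interaction $k_{ET} = 0.6$: the value of extra efficacy grows when
toxicity is low and vice versa.  Fixing one attribute makes the joint
utility affine in the other marginal with slope $k_E + k_{ET} u_T$
(respectively $k_T + k_{ET} u_E$), which the test suite verifies by
exact affine fits.

Setting $\lambda = 1$ and all exponents to 1 makes both marginals linear
and the joint utility collapses — to machine precision, checked on a
$101 \times 101$ grid — to the familiar linear patient-outcome utility
with outcome utilities $K(1,1) = k_E$ and $K(0,0) = k_T$
(`efftoxu_utility()`).  That linear design is therefore available as the
presets `"EffToxU"`/`"EffToxU2"` and, with the larger weights
$k_E = 0.5, k_T = 0.3$, as `"EffToxU7"`.

## Probability model and posterior computation

Efficacy and toxicity are modelled independently on the centred log-dose
$f(d) = \log d - \overline{\log d}$:

$$\mathrm{logit}\,\pi_E = \mu_E + \beta_{E1} f(d) + \beta_{E2} f(d)^2,
\qquad \mathrm{logit}\,\pi_T = \mu_T + \beta_T f(d),$$

with independent normal priors on the five parameters.  The quadratic
term lets efficacy plateau or turn over; toxicity is monotone in dose.

The posterior is sampled by a componentwise random-walk Metropolis
chain written in C++.  Proposal scales start at the prior standard
deviations and are tuned during burn-in by diminishing batch adaptation
(batches of 50, targeting a 0.44 per-component acceptance rate), then
frozen so the retained draws come from a fixed kernel.  Defaults are
2000 retained draws after 1000 burn-in sweeps per interim; with five
parameters and binomial sufficient statistics an interim costs a few
milliseconds.  All randomness flows through R's RNG, so a single
`set.seed()` reproduces an entire simulated trial.  Acceptance rates are
returned with the draws and persistently low acceptance (< 0.05) is
flagged rather than silently ignored.  Correctness is checked two ways:
with no data the sampler recovers prior moments, and on a restricted
model with two free parameters its posterior means of $\pi_E$ per dose
match a dense-grid quadrature oracle to within 0.01.

A deterministic approximation (e.g. Laplace) was considered for large
simulation studies and deliberately omitted: the compiled sampler is
fast enough that a second, approximate code path would only add
surface for silent disagreement.

### Default prior

The supplementary prior used in the original simulation study is not
distributed with the package, so `default_prior()` is the package's own
construction, built the way such priors are usually specified.  Means
come from a least-squares fit of the two linear predictors to the
average dose–response curves of the first six built-in scenarios (the
customary "mean of the plausible scenarios" anchor).  The scale was then
calibrated once by screening prior standard deviations of 2, 1.5, 1 and
0.7 (intercepts/slopes) across contrasting scenarios — steep efficacy
(scenario 1), rising toxicity (3), flat efficacy (6), all-toxic (9) and
all-futile (10) — and keeping the level with suitable operating
characteristics across all of them, mirroring the effective-sample-size
screening such designs normally undergo.  The result, sd 1 on
intercepts and linear slopes and 0.5 on the quadratic efficacy
coefficient, corresponds to a few patients' worth of prior information
per dose.  The sensitivity is real and worth knowing about: because the
reference-dependent utility is concave in gains and loss averse, the
expected utility of an *untried* dose is penalised by posterior spread,
so a much more diffuse prior makes escalation sticky (trials plateau at
middle doses), while a much tighter one lets the prior override early
data.

## Decision rules

At each interim the design computes per-dose posterior expected
utilities and applies one of three rule variants:

* **conventional admissibility** (presets `"R2DT1"`, `"EffToxU2"`,
  `"EffToxU7"`): dose $d$ is admissible iff
  $\Pr(\pi_E(d) > 0.5 \mid y) > 0.075$ and
  $\Pr(\pi_T(d) < 0.4 \mid y) > 0.075$.  The floors are small on
  purpose: they exclude a dose only when the posterior is almost sure it
  is futile or toxic.  The trial stops (no dose selected) when nothing
  is admissible.
* **utility admissibility** (`"R2DT3i"`–`"R2DT3iii"`, `"EffToxU5"`): a
  single elicited contour point — $(0.5, 0.35)$, $(0.7, 0.4)$ or
  $(0.9, 0.4)$, with reference utilities 0.58, 0.62, 0.69 (0.42 for the
  linear stack) — defines $u_{\mathrm{ref}}$, and a dose is excluded iff
  $\Pr(u < u_{\mathrm{ref}} \mid y) > 1 - p_u$ with $p_u = 0.1$.
* **utility trial stop** (`"R2DT4i"`–`"R2DT4iii"`): the same criterion
  is used only to stop the whole trial; the argmax runs over all doses
  while it runs.  On the same posterior draws the two utility variants
  stop at exactly the same point, which the tests assert; they differ
  only when the overall argmax is itself excluded.

Escalation is capped at one level above the highest dose already tried
(the no-skip rule), guarding against early model misspecification;
de-escalation is unrestricted.  Ties in expected utility break to the
lowest dose.  The final selection after the last cohort applies the same
rule set without the no-skip cap, since nobody else is treated.  The
admissibility inequalities use strict ">" at the thresholds; with
continuous posteriors the choice is value-irrelevant.

## Elicitation solvers

Every utility parameter is identified by a small number of stated
indifferences between simple lotteries $\langle x_1, w, x_3\rangle \sim
x_2$:

* **risk exponents**: with both levels on one side of the reference (one
  may sit exactly on it), the indifference depends only on that branch's
  exponent.  The certainty equivalent is the weighted power mean of the
  distances from the reference, whose log is monotone in the exponent,
  so the solver brackets the root on $\log\alpha \in [\log 10^{-3},
  \log 10^{3}]$ (tolerance $10^{-10}$); an answer equal to the
  risk-neutral mean returns exactly 1, and with one level on the
  reference the solution is closed-form.
* **loss aversion**: a reference-spanning lottery gives $\lambda$ in
  closed form because it enters the unnormalised utility linearly.
  Answers implying $\lambda < 0$ are rejected as inconsistencies.
* **corner weights**: any two equivalence statements (two points judged
  equally desirable, or a point assigned a utility — the corner
  statements $u(1,1) = k_E$, $u(0,0) = k_T$ are the usual shortcut)
  yield a $2 \times 2$ linear system after substituting
  $k_{ET} = 1 - k_E - k_T$; colinear statements are reported as such.
* **stopping contour**: the reference utility is simply the joint
  utility at the single elicited contour point.

Round-trip identities (forward certainty equivalent, then solve) recover
$\alpha \in [0.2, 3]$, $\lambda \in [0.5, 5]$ and interior corner
weights to $10^{-6}$ across hundreds of randomised draws in the test
suite.  `consistency_check()` supports the recommended final step of an
elicitation session: comparing extra stated indifferences against the
fitted model and reporting discrepancies.

## The simulator and what it does (not) show

`run_trial()` simulates one trial under a fixed scenario: cohorts of 3
up to 45 patients, starting at the lowest dose, efficacy and toxicity
outcomes drawn as independent Bernoulli variables with the scenario's
per-dose probabilities — matching the independence assumption of the
probability model.  `run_study()` replicates trials under substream
seeds derived once from a master seed, so pooled half-studies, serial
runs and re-runs of a single replicate agree exactly, and aggregates
per-dose selection percentages, mean patients treated (averaged over
*all* replicates, including early-stopped ones) and the percentage of
trials ending with no dose selected.

The ten built-in scenarios cover steep and flat efficacy, benign and
steep toxicity, a plateau, and two scenarios whose correct answer is to
stop.  The benchmark answer per scenario (`optimal_dose_oracle()`)
first excludes doses with true toxicity above 0.4 or true efficacy
below 0.5 and then maximises the design's utility at the true
probabilities.

Because outcomes are generated from the same independence model the
design assumes, the simulations validate the decision machinery, not
the model: they say nothing about correlated efficacy–toxicity
outcomes, delayed endpoints, patient heterogeneity or accrual dynamics.
Replicate counts in the shipped tests are deliberately modest (60–150
replicates; the headline studies in the field use thousands), so
simulation summaries carry Monte-Carlo error of a few percentage
points; the qualitative patterns — the dominant dose selected most
often under steep efficacy, majority no-dose outcomes under strict
contours when everything is toxic or futile — are stable.

```{r oc-example, eval = FALSE}
grid   <- dose_grid(c(20, 30, 40, 50))
prior  <- default_prior(grid)
design <- design_preset("R2DT1")
run_study(builtin_scenarios()$scenario1, design, prior, grid,
          n_reps = 100, seed = 7)
```

## Numerical conventions and limitations

* Utilities are computed in double precision; comparisons against
  printed two-decimal values use R's round-half-even.
* Marginal-utility inversion (certainty equivalents) uses `uniroot` on
  $[0, 1]$ at tolerance $10^{-12}$; monotonicity guarantees the target
  is attainable.
* Elicited indifference answers are accepted at any precision, but
  clinicians realistically answer at two decimals; the solvers simply
  propagate whatever granularity they are given.
* The sampler retries are unnecessary in practice (acceptance tuning has
  never failed on binomial likelihoods of this size), but diagnostics
  are always attached to the draws.
* Known limitations: no correlated-outcome model, no time-to-event or
  ordinal endpoints, no adaptive randomisation, no dose insertion, and
  the trade-off-contour comparator design is out of scope.  The prior
  default is the package's own calibration, not a transcription of any
  published prior, and operating characteristics shift by several
  percentage points under other defensible prior scales.
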
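---
title: "A three-state Markov model for the early cost-effectiveness of TIL therapy versus ipilimumab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov model for the early cost-effectiveness of TIL therapy versus ipilimumab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilcea)
```

## The decision problem

Tumor infiltrating lymphocyte (TIL) therapy is a personalized adoptive
cell therapy for advanced melanoma with phase-II response rates around
50%, compared with roughly 19% for ipilimumab, the anti-CTLA-4 antibody
that is the usual second-line comparator. TIL also costs less per
treatment (about EUR 62,000 versus about EUR 91,500), but the evidence
behind it is early: two small single-arm trials, no head-to-head
comparison. `tilcea` implements the decision-analytic model that turns
this early evidence into an expected cost-effectiveness estimate from
the Dutch health-care perspective, together with the uncertainty and
value-of-information analyses a coverage-with-evidence-development
decision needs.

## Evidence pooling

The TIL survival evidence comes from two phase-II arms reporting 1-year
overall survival (7/20 and 20/31) and 1-year progression-free survival
(3/20 and 10/31). Each proportion $p = x/n$ is transformed to the log
odds, where its sampling variance is $1/x + 1/(n-x)$, and the arms are
combined by fixed-effect inverse-variance weighting:

$$\hat\theta = \frac{\sum_i w_i \,\mathrm{logit}(p_i)}{\sum_i w_i},
\qquad w_i = \left(\tfrac{1}{x_i} + \tfrac{1}{n_i - x_i}\right)^{-1},
\qquad \mathrm{SE}(\hat\theta) = \Big(\sum_i w_i\Big)^{-1/2},$$

with normal-quantile confidence limits back-transformed to the
proportion scale.

```{r pooling}
pool_fixed(c(7, 20), c(20, 31))   # 1-year OS
pool_fixed(c(3, 10), c(20, 31))   # 1-year PFS
```

Boundary counts (0 or $n$ events) are rejected rather than
continuity-corrected: the logit variance is undefined there and the
evidence base never needs them. Random-effects pooling and
heterogeneity statistics are deliberately out of scope — with two small
arms a between-study variance is not estimable in any useful way.

## The cohort model

Three mutually exclusive health states — stable disease (responders),
progressive disease, and death — are simulated over 10 annual cycles.
The published analysis does not print its transition structure, only
its inputs and outputs, so the structure here is the simplest one that
reproduces the printed life-years exactly: the annual probability of
surviving the year is the 1-year OS probability *from both alive
states*, and stable patients remain stable with the 1-year PFS
probability:

$$P = \begin{pmatrix}
\mathrm{pfs} & \mathrm{os}-\mathrm{pfs} & 1-\mathrm{os}\\
0 & \mathrm{os} & 1-\mathrm{os}\\
0 & 0 & 1
\end{pmatrix}.$$

Under this structure the alive fraction after $t$ cycles is
$\mathrm{os}^t$, so undiscounted life-years over 10 cycles are the
geometric sum $\sum_{t=1}^{10}\mathrm{os}^t$ — 0.577 for ipilimumab
(os = 0.366) and 0.701 for TIL (os = 0.412), matching the published
0.58 and 0.70. The tests exploit this closed form as an independent
oracle against the matrix-propagated trace.

Accrual conventions, chosen to reproduce the printed results and kept
fixed thereafter:

* rewards are counted at the end of cycles 1..10, with no half-cycle
  correction;
* life-years are reported undiscounted (discounting them at 1.5% gives
  0.57/0.68, contradicting the printed values); QALYs are discounted at
  1.5%/year and costs at 4%/year, the Dutch guideline rates;
* the one-off treatment cost falls at cycle 0, undiscounted;
* the adverse-event QALY loss falls once, at cycle 1, with effect
  discounting.

## Parameters and distributions

All inputs live in one table (`builtin_table1()`), mirroring the
published input table: survival probabilities, utilities (stable 0.85,
progression 0.59), adverse-event utility decrements and likelihoods,
TIL failure fractions, and all cost components. Probabilities and
utilities carry Beta distributions moment-matched from their mean and
SE ($k = m(1-m)/s^2 - 1$, $a = mk$, $b = (1-m)k$); costs, which the
source reports as a mean with a +/-25% spread, carry Gamma
distributions with a coefficient of variation of 0.25
($\mathrm{shape} = 1/\mathrm{cv}^2$,
$\mathrm{scale} = m\,\mathrm{cv}^2$). Moment matching is exact, not
approximate, and the tests assert the analytic moments of every row.

Three modelling decisions deserve explanation:

* **Utilities of 0.85/0.59, not the 0.80/0.52 cited from the utility
  elicitation literature.** The input table is the declared base case
  and reproduces the printed QALYs; the prose values do not.
* **"Immune" adverse events map to the flu-like-syndrome decrement
  (0.09)** — the only decrement in the table not claimed by a named
  event — for both strategies. With that mapping the
  likelihood-weighted decrement sums are 0.0340 (ipilimumab) and
  0.1432 (TIL).
* **Adverse-event disutility duration of 0.25 years.** The source
  never states how long a disutility is suffered, so the duration is
  the model's one free accrual constant. Four printed QALY figures
  constrain it (base case 0.45/0.38 at 1.5% effect discounting and the
  equal-discounting scenario 0.43/0.37 at 3.5%): all four round
  correctly only for durations in roughly (0.225, 0.255) years. The
  default is the round value 0.25 — three months, which is also the
  clinically natural order of magnitude for acute, treatment-phase
  toxicity. It is exposed as a setting (`ae_disutility_duration`).

The expected ipilimumab adverse-event management cost is the
likelihood-weighted sum of the per-event unit costs and equals
EUR 914.50 exactly; it joins the drug (EUR 90,100) and administration
(EUR 473) costs in the EUR 91,487.50 treatment total. The cost of a
dyspnea episode (EUR 100) is an assumption inherited from the source.

### The TIL failure pathway

About 10% of intended TIL patients lose the product to a laboratory
production failure and another 10% progress between consent and
infusion; both groups receive ipilimumab instead. Survival is *not*
re-blended at run time — the TIL survival inputs are taken as
already-blended strategy-level values — but costs are:

$$C_{\mathrm{TIL}} = (1 - f_{\mathrm{lab}} - f_{\mathrm{prog}})\,T
+ f_{\mathrm{lab}}\,(P + I) + f_{\mathrm{prog}}\,(T + I),$$

where $T$ is the TIL price, $P$ the production component, and $I$ the
full ipilimumab treatment cost: lab failures are charged production
only, pre-infusion progressors the full price. This split gives an
expected treatment cost of EUR 77,647.50 and a total TIL strategy cost
within EUR 10 of the printed value; charging both failure groups
production-only, or both the full price, misses by thousands and was
rejected.

```{r base-case}
base_case()
```

## Probabilistic sensitivity analysis

Each of the 10,000 iterations draws every uncertain parameter
independently from its distribution and evaluates *both* strategies on
the joint draw, so shared parameters (utilities, decrements, state
costs, and the ipilimumab treatment cost inside the TIL failure
pathway) are common to both arms. Leaf components are sampled and
totals recomputed — the adverse-event likelihood draws therefore drive
the management cost and the disutility coherently. OS and PFS are
sampled independently (no correlation is reported); draws violating
pfs <= os are rejected and redrawn as a pair, with the count logged.

Decision uncertainty is summarized three ways: quadrant shares of the
incremental cost-effectiveness plane (boundary points go to the
south-east when $\Delta\mathrm{cost} \le 0$ and
$\Delta\mathrm{QALY} \ge 0$), the cost-effectiveness acceptability
curve (probability that TIL has the higher net monetary benefit
$\lambda\,\mathrm{QALY} - \mathrm{cost}$; ties count for the
comparator), and the expected value of perfect information

$$\mathrm{EVPI} = \mathbb{E}\!\left[\max_s \mathrm{NMB}_s\right] -
\max_s \mathbb{E}\!\left[\mathrm{NMB}_s\right],$$

scaled to a beneficial population of 400 eligible patients per year
over a 10-year decision horizon discounted at 4% (an effective
population of about 3,374; the horizon, rate, and incidence are all
settings, since population-scaling conventions are rarely stated
explicitly in published analyses).

### What the published uncertainty figures can and cannot constrain

The deterministic results reproduce the published ones essentially
exactly. The uncertainty results do not, and the discrepancy is
informative rather than incidental. The TIL survival SEs in the input
table are large (0.089 for PFS, 0.098 for OS). Two consequences follow
mechanically:

* $\sum_t \mathrm{os}^t$ is convex in os, so parameter uncertainty
  *raises* the TIL arm's mean PSA QALY above its deterministic value
  by about 0.03 (a Jensen effect of order
  $\tfrac12 f''(\mathrm{os})\sigma^2$); the constraint resampling adds
  about 0.02 more by truncating the (os, pfs) joint distribution. The
  PSA mean therefore *cannot* recover the deterministic base case
  within Monte Carlo error for the TIL arm — the model is visibly
  nonlinear at $\sigma \approx 0.1$ — and the corresponding acceptance
  check fails honestly.
* the spread of the incremental net monetary benefit implied by these
  SEs (standard deviation near EUR 29,000) yields a probability of
  cost-effectiveness at EUR 80,000/QALY of about 81%, a south-east
  quadrant share of about 49%, and a population EVPI of EUR 7-8 M,
  where the source prints 86% (91% elsewhere in the same text), 56%,
  and EUR 3 M. Those three printed figures are mutually inconsistent
  under any roughly normal NMB distribution — an 86% win probability
  with the same mean implies a spread that produces an EVPI above
  EUR 4 M — so no sampling scheme built from the printed inputs can
  reproduce all of them. The package reports what the stated inputs
  imply and documents the tension rather than calibrating toward any
  one figure.

## Deterministic sensitivity analyses

`one_way_sa()` varies every parameter to mean x (1 +/- 0.25) around the
deterministic base (probabilities capped at 1 with a warning) and
ranks parameters by the width of their incremental-cost or
incremental-QALY range; cost parameters provably never move the
incremental QALYs. `scenario()` re-runs the base case under named
parameter or setting overrides — the equal-discounting scenario
(3.5%/3.5%) and the Portuguese ipilimumab price (EUR 59,500 per
course, under which TIL loses dominance and becomes "more effective,
more costly") ship as examples. `threshold_price()` bisects the
charged TIL price, production cost held fixed, to the dominance
boundary (EUR 77,075) or the EUR 80,000/QALY ICER boundary
(EUR 83,047); total cost is affine in the price, so the tests check
the bisection against the analytic inversion to EUR 1.

## Synthetic data and degenerate fixtures

The generators in `gen_trial_outcomes()` and
`perturb_parameter_table()` exist so every stage can be exercised
without any external data: seeded binomial arms for the pooling stage
(boundary draws resampled, matching the pooling domain) and jittered
parameter tables that always pass validation for pipeline stress
tests. They emulate sampling variation around the study conditions —
they do not emulate between-study heterogeneity, correlated survival
endpoints, or patient-level event times, so passing tests say nothing
about those features of real data. `degenerate_fixtures()` supplies
the edge cases the invariant tests lean on: a zero-uncertainty table
(PSA collapses to the base case, EVPI is exactly 0), an
equal-strategies table (all increments exactly 0), zero-discount
settings (closed-form QALYs), and a single-cycle horizon (life-years
equal the survival probability).

## Numerical choices and problem sizes

Bisection tolerance EUR 1; trace conservation asserted at 1e-10;
moment matching exact to machine precision; NMB ties resolved for the
comparator; negative per-person EVPI (possible only as Monte Carlo
noise) clipped to zero with a message. The default analysis sizes —
10,000 PSA iterations, 10 cycles, a EUR 0-200,000 threshold grid in
EUR 5,000 steps — run in well under a minute; the test suite uses
smaller iteration counts (200-2,000) for everything except the
headline uncertainty checks, which use the full 10,000.

## Known limitations

The model inherits every limitation of its evidence base: two small
phase-II arms against a phase-III comparator, constant annual
transition probabilities (no parametric survival extrapolation), a
10-year horizon for a disease where long-term TIL remission data are
still accruing, utilities assumed equal across strategies, and a TIL
price measured in one non-profit academic setting. Within the model,
OS-PFS independence in the PSA is an assumption of convenience, and
the EVPI population scaling is a convention. None of these can be
tightened from the published inputs alone; they are exactly what the
coverage-with-evidence-development trial this analysis supports is
meant to resolve.
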
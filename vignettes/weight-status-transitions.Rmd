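---
title: "Modelling childhood weight-status transitions with a three-state Markov process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling childhood weight-status transitions with a three-state Markov process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wstrans)
```

## The problem

School-age children move between weight-status categories — normal weight,
overweight, obesity — as they grow. Cross-sectional prevalence hides this
dynamic: a stable 18% overweight prevalence is compatible both with a fixed
group of overweight children and with rapid turnover. Annual school
examination programmes produce exactly the data needed to tell these apart:
a panel in which each child's height and weight are measured once a year,
so the weight status is known only at examination dates and every change in
between is interval-censored.

`wstrans` models these panels with a time-homogeneous continuous-time
Markov chain on the three states 1 = normal weight, 2 = overweight,
3 = obese, with instantaneous transitions allowed only between adjacent
states (a child cannot jump from normal weight to obesity without passing
through overweight). The generator is the tridiagonal intensity matrix

$$
Q=\begin{pmatrix}
-q_{12} & q_{12} & 0\\
q_{21} & -(q_{21}+q_{23}) & q_{23}\\
0 & q_{32} & -q_{32}
\end{pmatrix},
$$

with the $q_{rs}$ in units of events per year, on the time scale
$t$ = years since each child's first examination (so cohort entry, not
calendar date, anchors the clock). Interval transition probabilities are
$P(t) = e^{tQ}$, and the panel likelihood for a child observed in states
$s_0, s_1, \dots$ at times $t_0 < t_1 < \dots$ is
$\prod_j P_{s_j,s_{j+1}}(t_{j+1}-t_j)$. This is the standard
interval-censoring treatment: the matrix exponential marginalizes every
unobserved path between examinations, which is also why an observed
normal-to-obese pair over one year is perfectly legal data (its probability
is $O(\Delta t^2)$, through overweight).

## Model assumptions

* **Time homogeneity.** Intensities are constant in $t$. Over a five- or
  six-wave window starting at school entry this is a reasonable first-order
  description; it would not be for a cohort spanning puberty.
* **Markov property.** The future depends on the present state only.
  Covariates (below) relax this indirectly by letting rates differ between
  children.
* **Adjacent-state jumps.** Enforced structurally: the forbidden cells are
  not parameters at all.

## Estimation

`fit_markov3()` maximizes the panel likelihood over the four log
intensities — the log scale guarantees positivity and gives Wald intervals
that respect it — with a quasi-Newton (L-BFGS-B) optimizer started from
deterministic crude rates (observed pair counts over person-time), so a
refit of the same data is bit-reproducible. Standard errors come from the
numerically differentiated observed information at the optimum. Two
degenerate situations are handled explicitly: a transition whose source
state never begins an observation interval leaves the likelihood flat and
is *pinned* at zero with a warning rather than optimized; a transition with
person-time but no supporting events is driven to the box boundary and
flagged.

The likelihood groups intervals by (length, covariate value) before
optimization: the data enter only through per-group 3×3 pair-count
matrices, so each likelihood evaluation costs one matrix exponential per
group regardless of cohort size. $e^{tQ}$ itself is computed by
eigendecomposition — tridiagonal generators with positive rates are
similar to symmetric matrices, so the spectrum is real — with a Padé
scaling-and-squaring fallback for degenerate spectra; the test suite
cross-checks both against an independent truncated-Taylor oracle at
`1e-8` and verifies Chapman–Kolmogorov composition at `1e-10`.

**Covariates.** A single covariate at a time acts proportionally on each
allowed transition: $q_{rs}(z) = q_{rs}e^{\beta_{rs} z}$, with one
$\beta$ per transition and $e^{\beta}$ the per-unit hazard ratio
(`hazard_ratios()`). Time-varying covariates are taken
piecewise-constant at the interval start. One-at-a-time is first-class
because typical cohort covariates (growth increments, initial BMI, rebound
timing) are collinear; the likelihood machinery accepts a coefficient
matrix for exploration beyond that. Continuous covariates are per-unit,
not standardized. Nested fits are compared with the likelihood-ratio test
and AIC (`compare_models()`).

## Derived quantities

* `mean_sojourn()`: $-1/q_{rr}$, the mean of one uninterrupted stay.
* `total_length_of_stay()`: $\int_0^T P_{s_0 s}(u)\,du$, computed through
  the augmented block exponential
  $\exp\!\big(T\begin{smallmatrix}Q & I\\ 0 & 0\end{smallmatrix}\big)$ —
  exact up to the matrix exponential, no quadrature knob; entries sum to
  $T$ by construction (adaptive quadrature is kept as a test oracle only).
* `project_prevalence()`: $\pi_0^\top P(t)$ from a baseline distribution,
  with `validate_projection()` implementing the acceptance rule *inside
  the observed 95% CI, or absolute difference below 1% of the predicted
  value* (relative to the prediction, as stated).
* `leave_probability()`: $1 - P_{ss}(t)$.

Confidence intervals for all derived quantities use the delta method on
the log-intensity scale by default; a parametric bootstrap (multivariate
normal draws from the asymptotic parameter distribution) is available via
`transition_summary(..., ci_method = "bootstrap")`. Point estimates are
identical under both; only interval widths differ.

## Classification and adiposity rebound

BMI is weight/height$^2$ (kg/m²). `classify_status()` assigns states from
an age- and sex-bracketed cutoff table with thresholds *inclusive upward*
(BMI equal to a cutoff falls in the heavier class — the usual
growth-reference convention; the choice only matters on exact ties).
Official reference cutoffs are deliberately not bundled: they are external
standards, and shipping guessed values would masquerade as ground truth.
Users load the applicable standard with `load_cutoffs()` (CSV or YAML,
half-open age brackets validated for gaps and overlaps), and
`splice_cutoffs()` supports the common design in which one standard applies
below age 7 and another from 7 up. `synthetic_cutoffs()` provides
plausibly-shaped synthetic tables for simulation and tests.

The adiposity rebound (AR) is the nadir of a child's BMI-versus-age curve,
typically between ages 4 and 8; a nadir at or after age 7 counts as *late*
AR. `fit_bmi_curves()` fits a quadratic in age — the minimal family with an
interior minimum — with child-level random intercept, slope and curvature
via `lme4`, falling back to independent per-child least squares when the
mixed fit fails (the fallback is recorded per child). The rebound age is
the vertex $-b_1/(2b_2)$ when $b_2 > 0$ and the vertex lies in a
plausible age window (default 2–20 years); concave or monotone curves have
no nadir and are never late. Because school cohorts often start near age 7,
many estimated nadirs sit below the observed age support; the package
reports them (matching the lowest-BMI definition) but flags them
`"extrapolated"`, since they are inferred from curvature rather than seen.

## The synthetic cohort

No individual-level data ship with the package, so `generate_cohort()`
emulates the study design the engine targets. Its defaults are fixed study
conditions, not tuning dials: 2,334 children over 6 annual waves entering
at age ≈ 6.8 y; baseline state mix 71.1/18.1/10.8%; 49.7% girls, 78.9%
urban; the reference all-children intensity matrix
(`reference_intensities()`) as generating truth; no covariate effects
unless `sex_betas` is set. Nadir ages are N(6.7, 1.0) so that about 38% of
children rebound late, matching the cohort structure the defaults emulate;
BMI noise is small (`bmi_noise_sd = 0.15` on the logit band scale) because
measured anthropometry is precise.

Trajectories are simulated exactly (Gillespie: exponential holding times,
jump probabilities $q_{rs}/{-q_{rr}}$), then observed at wave times, so
panel discretization genuinely loses events — observed moves never exceed
true jumps. Anthropometry is generated *state-first*: the observed state
fixes the BMI band at that age/sex under the simulation's cutoff table, and
the within-band position follows a smooth per-child curve with its minimum
at the child's nadir age, so re-classifying the generated heights and
weights reproduces the simulated states exactly. This is a deliberate
simplification of reality — real BMI does not respect band boundaries when
status changes — so AR-recovery experiments use `generate_bmi_curves()`,
a pure quadratic-plus-noise curve generator, instead. What passing tests on
these cohorts show is that the pipeline recovers known truth under the
model's own assumptions; they cannot show robustness to misclassification,
secular BMI trends, pubertal growth spurts or informative dropout, none of
which the generator emulates.

## Numerical and design choices

* Optimizer box constraints $\log q \in [\log 10^{-8}, \log 20]$,
  $\beta \in [-10, 10]$; L-BFGS-B default convergence factor `factr = 1e7`
  (≈ 1e-9 relative).
* Ages from dates use (exam − birth)/365.25; no day-count convention is
  standard for this, and the choice moves ages by < 0.1%.
* Complete-case filtering (children with a missing wave dropped) is the
  default, mirroring complete-data cohort designs; disable it with
  `complete_case = FALSE` to keep unequal follow-up, which the model
  itself handles.
* Duplicate examination ages within a child are an error naming the child;
  silently keeping either record would corrupt the time scale.
* CIs are fixed at 95% ($z = 1.96$) throughout.
* Experiment sizes in the test suite are the package's own choices:
  coverage is verified over 100 replicated cohorts of 2,334 children,
  test size of the likelihood-ratio test over 200 replicates of 500
  children — large enough that binomial bands around the nominal levels
  are narrow, small enough to run routinely.

## Known limitations

Time-inhomogeneous (piecewise) intensities, misclassification/hidden
Markov extensions, exact-transition-time data, multi-covariate fits as a
first-class interface, and BMI z-score classification are out of scope.
Sex-stratified analyses are fully separate fits per stratum; no parameters
are shared. The validation rule compares point projections with observed
CIs only — it does not propagate projection uncertainty.
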
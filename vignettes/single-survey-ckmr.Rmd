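---
title: "Single-survey close-kin mark-recapture: model, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-survey close-kin mark-recapture: model, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinabund)
```

## The estimation problem

Close-kin mark-recapture (CKMR) turns a pedigree into a mark-recapture
experiment: an offspring "marks" its parent, and finding the pair among
the sampled animals is the "recapture". The more pairwise comparisons
between sampled offspring and sampled candidate parents that turn out to
be true parent-offspring pairs, the smaller the population of potential
parents must be. kinabund implements this idea for the hardest design a
manager can face: a **single** sampling event in a small, stage-structured
population of a birth-pulse species (the motivating system is woodland
caribou sampled by winter fecal-DNA surveys, 6-8 months after calving).

The estimand throughout is `N_F`, the number of reproductive females
(subadults plus adults) alive at the calf cohort's birth. Only
mother-offspring kinship is used: with a single sampling event there is no
time axis, so survival and growth curves play no role and the kinship
probability reduces to relative reproductive output.

## The pseudolikelihood

After the survey, every sampled calf is compared with every sampled
reproductive female. Sampled yearlings are removed first: they are neither
members of the calf cohort nor possible mothers of it. Each comparison
falls in one of four categories - (subadult, pair), (subadult, non-pair),
(adult, pair), (adult, non-pair) - and the probability that a comparison
involving a female of stage $s \in \{s, a\}$ is a pair is her expected
share of the cohort's production:

$$
q_s = \frac{b_s f}{N_F\left(b_s f (1-A) + b_a f A\right)},
\qquad
q_a = \frac{b_a f}{N_F\left(b_s f (1-A) + b_a f A\right)},
$$

where $b_s, b_a$ are stage breeding probabilities, $f$ is the number of
calves per successful breeder, and $A$ is the proportion of adults among
the sampled reproductive females. Fecundity cancels, and the mixture
normalizes: $(1-A)q_s + A q_a = 1/N_F$ - one female, one expected share.
The observed category counts $y_1,\dots,y_4$ enter a multinomial
pseudolikelihood ("pseudo" because comparisons sharing an individual are
not independent). Because the pair and non-pair probabilities sum to one
within each stage, the multinomial factorizes into two stage-stratified
binomials, and that is how `log_pseudolikelihood()` computes it. The
factorized and four-category readings have identical maximizers; the
factorized one is the only internally consistent reading of per-comparison
category probabilities, since the four probabilities sum to 2, not 1.

`maximize_pseudolikelihood()` maximizes over a bounded range by Brent-type
1-D optimization (`stats::optimize()`, tolerance $10^{-6}$ on $N_F$). The
conventional search range is 10 females to ten times the anticipated
abundance; in application mode the upper bound is the analyst's statement
of how large the population could plausibly be, and estimates that hit it
are flagged rather than trusted. The 95% interval is the profile
likelihood: the two abundances where the log pseudolikelihood has dropped
$\chi^2_{1,0.95}/2 = 1.92$ units from its maximum, found by bracketed
root finding; a side with no root inside the search range is clamped to
the bound and flagged.

Two data degeneracies are resolved analytically rather than numerically:

* comparisons but **no pairs** - the likelihood increases monotonically in
  $N_F$, so the estimate is the upper search bound, flagged
  `at_upper_bound`;
* **no comparisons at all** (no sampled calf or no sampled reproductive
  female) - the likelihood is flat; the replicate is flagged
  `flat_likelihood` and its "estimate" (the upper bound, by the same
  convention) carries no information.

## The individual-based simulator

`simulate_population()` runs exactly one annual cycle, which is all the
single-survey design needs:

1. **Initialization** (`init_population()`): founders just before the
   birth pulse - subadults (12% of $N_F$ by default), adults (the
   remainder), and yearlings (15% of $N_F$). Counts are round-half-up on
   the fractional targets with adults absorbing the remainder, so
   $N_F = 50$ gives 6 + 44 + 8 = 58 females and $N_F = 1000$ gives 1150.
2. **Birth pulse** (`birth_pulse()`): each reproductive female breeds by
   an independent Bernoulli draw ($b_s = 0.15$, $b_a = 0.90$ by default)
   and a breeder produces exactly $f = 1$ calf whose maternity is
   recorded.
3. **Survival** (`survival_step()`): six months of independent
   stage-specific mortality ($\phi_c = 0.35$, $\phi_y = \phi_s = 0.894$,
   $\phi_a = 0.922$ by default). The dead are retained, flagged, so
   pedigree queries stay total; no aging occurs within the cycle.
4. **Survey** (`draw_sample()`): a uniform random subset of survivors of
   size round-half-up(fraction x survivors), followed by
   `tabulate_comparisons()`.

The default rates are realistic for woodland caribou; calf survival is
low, adult survival high, and subadults breed rarely. The rounding rules
are a convention: only the printed totals 58 and 1150 pin them down, and
round-half-up with adults as the remainder class reproduces both.

Randomness is consumed in a documented order (breeding draws by ascending
id, then survival draws by ascending id, then the sample draw), so a
replicate is bit-reproducible from its single seed. `run_cell()` derives
replicate seeds as `master_seed + 1..replicates`, and `run_grid()` spaces
cell master seeds so no two cells share a replicate seed.

What the simulator deliberately does **not** emulate: males, immigration
and emigration, density dependence, multi-year dynamics, spatial or
preferential sampling, and - most importantly - kinship-inference error:
pairs are read from the true pedigree. Passing simulation tests therefore
demonstrates the statistical behaviour of the estimator under its own
assumptions, not robustness to genotyping or pedigree-inference mistakes
in real data.

## Simulation-study summaries

`run_cell()` and `run_grid()` summarize replicates by the mean observed
pair count, mean/SD/CV of the estimate, the central 95% band (2.5% and
97.5% empirical quantiles, linear interpolation - the two-sided reading of
a "95% quantile" band), the mean and median proportional relative bias
$(\hat N_F - N_F)/N_F$, and profile-CI coverage.

One summary convention deserves emphasis. At very low sampling fractions
of small populations a large share of replicates sample no calf or no
reproductive female at all; their likelihood is flat and they contain no
information about abundance. Such replicates are excluded from the
estimator summaries (their pair count, a true zero, still enters
`mean_mop`) and their share is reported as `flat_fraction`. Averaging in a
flat replicate's capped "estimate" would report a property of the search
bound, not of the estimator; summaries over informative replicates are
what a design study should compare. Replicates with comparisons but no
pairs *are* informative (the data genuinely favour a large population) and
are kept, capped at the upper bound - this cap is why the mean and median
bias at, e.g., $N_F = 50$ with 5% sampling sit near
$(10 N_F - N_F)/N_F = 9$.

With the default rates, the analytic check `expected_mop()` -
$p^2 f \phi_c \sum_s n_s b_s \phi_s$ under independent sampling of the two
pair members - agrees with the Monte-Carlo mean pair count to well within
Monte-Carlo error at every cell used in the tests (10,000 replicates for
the headline cells; smaller cells elsewhere to keep the default test run
fast; the test files state the sizes used).

## The single-year binomial estimator

For annual field data the package follows the simpler route appropriate
when stage cannot be assigned to unmarked females: all potential mothers
(females sampled that winter, minus those whose known birth year implies
age < 3 at the cohort's birth) are treated as equally reproductive, so

$$
MO_t \sim \mathrm{Binom}\!\left(n_{c,t}\, n_{f,t},\; 1/N_{f,t}\right),
\qquad \hat N_{f,t} = n_{c,t}\, n_{f,t} / MO_t,
$$

with the 95% interval obtained by profiling the binomial likelihood on the
pair probability $p$ (the same 1.92-unit drop, exact root finding) and
inverting the bounds as $N = 1/p$. Estimates and bounds are rounded
half-up to integers at the reporting layer only. `assemble_annual_record()`
applies the pooling and exclusion rules to raw individual/pair tables;
`annual_abundance()` maps the estimator over a per-year count table. A
year with zero pairs has an unbounded MLE: the point estimate is an
explicit error and the interval is reported as a finite lower bound (the
same 1.92-unit rule, $1/(1-e^{-1.92/n})$) with an open upper end - with no
search cap in application mode, no number would be honest.

The treating-all-mothers-as-adults approximation biases $\hat N_f$
slightly: unexcludable yearlings and subadults inflate $n_f$ while
contributing few pairs. The bundled Tonquin counts ship as data exactly as
tabulated; the companion CMR estimates are a comparison fixture only.

Two numerical caveats for users comparing against previously published
interval bounds for sparse years (one to four pairs): profile bounds that
far in the tail are sensitive to how the profiling is done. Software that
evaluates the profile on a coarse grid of steps and spline-interpolates
the signed-root deviance can report upper bounds that differ by hundreds
of animals from the exact 1.92-unit root at one observed pair. kinabund
always finds the root directly (verified against GLM-based profiling);
with so few pairs either bound should be read as "the data barely
constrain the upper end", not as a sharp number.

## Tunable parameters at a glance

| parameter | meaning | default | units |
|---|---|---|---|
| `f` | calves per successful breeder | 1 | calves |
| `b_s`, `b_a` | breeding probability (subadult, adult) | 0.15, 0.90 | - |
| `phi_c`, `phi_y`, `phi_s`, `phi_a` | 6-month survival | 0.35, 0.894, 0.894, 0.922 | - |
| `subadult_fraction` | subadult share of $N_F$ | 0.12 | - |
| `yearling_fraction` | yearlings relative to $N_F$ | 0.15 | - |
| `proportion` | sampling fraction of survivors | - | - |
| `search_low`, `search_high` | estimator search range | 10, 10 x $N_F$ (simulation) | females |
| `level` | confidence level | 0.95 | - |

## Known limitations

* The pseudolikelihood ignores dependence among comparisons sharing an
  individual; its profile intervals are conservative (coverage near 100%
  in well-sampled cells), so interval width overstates uncertainty.
* A single stage mixture (subadult/adult) is supported; father-offspring
  and sibling kinships, multi-year models, and uncertainty-weighted
  pseudolikelihoods are out of scope.
* Estimates at the search cap (`at_upper_bound`) are censoring artifacts;
  design studies should report them as "insufficient data", which is how
  the flat-likelihood exclusion treats the even-more-degenerate case.
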
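---
title: "Rate-difference inference and causal discovery in registry cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-difference inference and causal discovery in registry cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratelink)
```

## The problem

Registry studies of late treatment effects face a structural dilemma. The
cohorts are small — a regional childhood-cancer registry holds a couple of
thousand survivors — but the exposure space is wide: dozens to hundreds of
treatment components, primary diagnoses and predisposing conditions, each
a binary flag, each a potential cause of each of hundreds of coded
outcomes. Constraint-based causal discovery (the PC family) is the natural
tool for separating direct from indirect associations, but its engine is a
*conditional* independence test, and every conditioning variable fragments
the cohort into strata too small to carry significance. `ratelink`
implements a conditional test built to survive this fragmentation, the
discovery algorithm on top of it, and the registry-specific reliability
checks that the resulting links need before anyone should believe them.

## Model and test

Two assumptions define the model. First, the time to the first occurrence
of an outcome with frequency $\lambda$ is exponential,
$P(t) = \lambda e^{-\lambda t}$: the hazard is constant in age and time
since treatment. Second, every exposure that affects an outcome adds a
non-negative increment $\Delta\lambda$ to its frequency, independently of
other exposures.

Under the exponential model a group is fully summarized by $(n, t)$ —
subjects with at least one occurrence, and person-time accumulated up to
each subject's first occurrence or censoring ([suff_stats()]). With a
uniform prior the rate posterior is Gamma$(n+1, t)$. For an unexposed
group $(n_1, t_1)$ and an exposed group $(n_2, t_2)$ the posterior of
$\Delta\lambda = \lambda_2 - \lambda_1$ is obtained by integrating the
joint posterior over the base rate,

$$P(\Delta\lambda \mid D_1, D_2) \propto
  \int \lambda^{n_1} e^{-\lambda t_1}
  (\lambda + \Delta\lambda)^{n_2} e^{-(\lambda+\Delta\lambda) t_2}
  \, d\lambda ,$$

with the integral running over the region where both rates are
non-negative. For $\Delta\lambda \ge 0$ it evaluates to
$e^{-\Delta\lambda t_2}\, {}_1F_1(-n_2;\, -(n_1+n_2);\,
\Delta\lambda\,(t_1+t_2))$, with the group-swapped mirror for
$\Delta\lambda < 0$; the two branches join continuously at zero. The
${}_1F_1$ with negative-integer first parameter is a degree-$n_2$
polynomial, so the form is exact, and on each branch all of its terms are
positive, so the signed log-space recurrence in
`hyp1f1_terminating()` evaluates it without cancellation or overflow for
counts in the hundreds and person-times up to $10^5$. The same closed form
is, equivalently, the density of the difference of two independent
Gamma$(n+1, t)$ posterior draws — the property the test suite uses as a
Monte-Carlo oracle. (We allow the boundary case $m = N$ of the polynomial,
which arises whenever the unexposed group has no events; the denominator
Pochhammer factors remain non-zero there.)

Significance is the posterior tail beyond zero. Two tails exist; the
reported p-value is the smaller one — the probability of mistaking a
positive difference for a negative one or vice versa — so a positive
expected $\Delta\lambda$ pairs with the negative-tail area. Exactly
symmetric evidence reports $p = 0.5$ and effect 0. Only increases
($\Delta\lambda > 0$) are ever treated as causal signals; protective
associations are excluded at screening no matter how small their tail.

### Conditioning without losing the cohort

If the increment is additive, it is *the same* in every stratum of any
conditioning set $G$, even though the baseline rates differ freely between
strata. The conditional posterior is therefore the product of per-stratum
unconditional posteriors, estimating one common $\Delta\lambda$ from all
strata at once ([delta_posterior()] on a [stratify()] table). A single
stratum reduces bit-identically to the unconditional test; a stratum with
no data contributes a constant factor. The improper uniform prior makes
the posterior non-normalizable exactly when one side carries no
person-time in any stratum (total $t_1 = 0$ or total $t_2 = 0$); such
posteriors are flagged `informative = FALSE` and never summarized. Note
that a cause perfectly determined by its conditioning set (every stratum
one-sided) still yields a *normalizable* posterior — each one-sided
stratum contributes a Poisson-survival factor bounding $\Delta\lambda$
from one side — but a near-flat one, so the test correctly reports
non-significance rather than a spurious flag.

### Numerical procedure

Normalization has no closed form, so the package: locates the posterior
mode (bracketed grid search plus `optimize`), expands the support outward
by doubling until the log-density at both ends falls 40 nats below the
mode (a relative density of $e^{-40} \approx 4\cdot10^{-18}$, negligible
against every tolerance used downstream), and integrates
`exp(logf - logf_max)` by adaptive quadrature (`stats::integrate`,
relative tolerance $10^{-9}$) on segments split at zero and at the mode.
Tail areas and the posterior mean use the same segments, and the two tail
areas are renormalized to sum to one. Group-swap antisymmetry —
$P(\Delta\lambda \le 0 \mid D_1, D_2) = P(\Delta\lambda \ge 0 \mid D_2,
D_1)$ — is made *bit-exact* by always integrating in a canonical
orientation (the side with the larger naive posterior-mean rate is
"exposed"; an antisymmetric lexicographic tiebreak covers exact center
ties) and mirroring the results back.

## The discovery algorithm

Step 1 screens every cause–outcome pair with the unconditional test and
keeps candidates with $p < \alpha_{\text{screen}}$ (default 0.01) and
positive expected increment. Step 2 prunes: for each outcome, growing
conditioning-set size $s = 1, 2, \dots$, every remaining candidate is
tested against every size-$s$ subset of the *other* remaining candidates.
Faithfulness justifies conditioning only on screened candidates rather
than the full catalogue. Two design choices matter:

* **Order independence.** All tests at level $s$ use the candidate set as
  it stood entering the level, and removals are applied in batch at the
  level's end — the PC-stable synchronization. Permuting the input order
  of causes and outcomes provably cannot change the result, and the test
  suite asserts table-identical output under permutation.
* **Ambiguity instead of silent choice.** A candidate is removable when
  some subset drives its conditional p to the screen level or above (or
  flips its effect non-positive, or empties the posterior). If every
  explaining subset of a removable candidate itself contains a removable
  candidate — the signature of co-administered, highly correlated
  treatments that "explain" each other — the cluster is reported as
  `ambiguous`, with all alternative explanations listed, and left for
  domain analysis. Its members' final p-values condition on the *kept*
  causes only: the cluster's association with the outcome is real; which
  member carries it is what the data cannot decide. Plainly removable
  candidates record their explaining subset in `explained_by`.

Kept links' `p_final` conditions on the other kept causes of the same
outcome. Reporting uses a second, stricter level
$\alpha_{\text{report}}$ (default $10^{-4}$): the significance bins are
lower-inclusive, upper-exclusive — `<0.0001` (reportable),
`0.0001–0.001`, `0.001–0.01`, `>=0.01` — so the three sub-0.01 bins
partition the screened range. The expected number of false reportable
links is estimated as $\alpha_{\text{report}}$ times the number of links
whose final p faces that threshold (survivors of pruning); this
convention is a documented package choice, as is treating any screened
candidate as eligible to condition on any other regardless of its class
(treatment vs diagnosis).

Sex enters as an effect modifier, not a cause node: outcomes flagged
sex-specific in the schema are analyzed within the relevant sex, and the
restriction is recorded on the link. Discovery defaults to survivors only
(`discovery_config(population = "survivors")`): controls carry no
exposures by construction, so including them could only dilute baseline
strata; descriptive comparisons use both groups.

## Observation windows and cohort handling

Outcomes count as late effects only from `window_start_offset` years
(default 5) after the index diagnosis; events before entry — including
the 0.5–5-year acute window — never contribute, and subjects whose
follow-up ends at or before entry leave the risk set entirely. Analyses
restricted to a source whose registration started late (outpatient care,
1997) delay entry to the registry start (left truncation), preventing
immortal-time artifacts. Outcome codes match on the 3-character ICD-10
category by default, with a prefix mode for finer codes and a chapter
mode for the descriptive comparisons. Controls carry the index date of
their matched survivor, making person-time comparable, and must have all
exposure flags zero. Death censors all outcome observation but
cause-of-death codes count as events on the death date. Dates are held at
day precision; durations use 365.25-day years.

## Validation procedures

Three post-hoc checks target known registry pathologies:

* **Era control** ([era_split_retest()]): if a treatment entered
  protocols around the same time as an outcome-coding change, calendar
  time confounds the link. A binary era indicator — index date before or
  from the cutoff year (presets 1988 and 1996) — joins the conditioning
  set and the invariant test re-runs; the link survives at a separate
  validation level (0.001). Era assignment uses the index date (treatment
  era), not the event date. A cutoff leaving one era empty flags the link
  as not assessable rather than passing it silently.
* **Event timing** ([classify_event_timing()]): among exposed subjects
  with any occurrence of the code, the fractions whose code appears
  before the index date, in the 0.5–5-year acute window, and at or past
  the observation window. Windows are non-exclusive and the denominator
  is subjects (not code instances) — a documented convention, since
  code-instance denominators are inflated by routine repetition, the very
  artifact under investigation.
* **Source restriction** ([source_restriction_flag()]): links supported
  exclusively by outpatient codes are flagged as less reliable.

[person_year_frequency()] provides the descriptive rate (subjects with an
in-window occurrence over in-window person-time, identical to $n/t$ of
the sufficient statistics), and [frequency_by_exposure()] tabulates it
for controls / unexposed survivors / exposed survivors.

## Descriptive comparisons

[compare_groups()] applies the same machinery at ICD-10 chapter level
(first event of any code in the chapter, per care setting), reporting
each group's frequency posterior in percent per year and the difference
posterior with a logarithmic grade (ns, 0.01, 0.001, 0.0001). The chapter
map merges A+B, splits D at D50 into neoplasms (D') and blood/immune
(D''), merges S+T, and folds the ear block into H. [kaplan_meier()] is a
plain product-limit estimator with optional delayed entry, used by
[mortality_curves()] on an attained-age axis when birth dates are
available (entry at age-at-index plus the window offset); the test suite
cross-checks it against `survival::survfit` on random data sets.

## The synthetic-data generator

[simulate_cohort()] draws cohorts from the model itself: Bernoulli
exposures with configurable prevalence, pairwise co-assignment by
directed copying (with probability `prob`, subject's value of cause A
overwrites cause B — at `prob = 1` this reaches the perfectly correlated
limit), and per-subject exponential first-event times at
`base_rate + sum of increments of exposed causes`, censored at end of
follow-up. Adversarial layers reproduce the registry pathologies the
validation step exists for: an era cutoff shifting exposure prevalence
and coding rate together, spurious pre-index and acute-window codes, an
outpatient-coding probability, optional mortality. Randomness is split
into named per-section streams (demographics, exposures, each outcome)
derived from one master seed, so a given seed reproduces a cohort
bit-exactly and adding an outcome never perturbs the existing draws.

The fixture scales mirror the motivating setting: cohorts of 1000–3000
survivors, 15–20 years of follow-up, base rates of 0.01–0.05 per
person-year and increments of 0.04–0.1 — strong effects by design, so
that structure-recovery properties are sharp at desk scale. What passing
tests on these cohorts shows is that the machinery is correct *under its
own assumptions*; they do not probe age-dependent hazards, synergistic
or multiplicative exposures, non-exponential waiting times, or coding
cultures drifting continuously in time, all of which real registries
contain. The exponential and additivity assumptions are approximations
whose violation biases effects toward population-averaged increments.

## Problem sizes and tolerances in the test suite

The acceptance suite verifies: the closed form against log-rescaled
adaptive quadrature of the defining integral over all
$n_1, n_2 \in \{0..20\}$, $t \in \{5, 50, 500\}$ at 21 grid points
(relative tolerance $10^{-8}$, up to one global constant); one-tail areas
against a $10^6$-draw difference-of-Gammas oracle within 3 Monte-Carlo
standard errors; exact reduction identities (single stratum, empty
stratum, group swap, symmetric tie); screening type-I calibration on
2000 null cohorts of $n = 1000$ (99% binomial band around 0.01; the
screening decision is one-directional, which is why its null rate is
0.01 and not the two-tailed 0.02); recovery of a planted
0.05/person-year increment within 15% over 200 replicates; confounded-
proxy removal and identical-pair ambiguity over 100 replicates each; era
control in both directions over 50 seeds; and product-limit agreement
with the reference implementation on 100 random data sets. These scales
keep the full suite within a coffee break on one core while leaving every
stochastic criterion comfortable margins.

## Known limitations

The hazard-constancy assumption is wrong for outcomes whose risk grows
with age; heavier-tailed waiting-time families (Gamma, Weibull) would
need a different invariant statistic and are out of scope. Edges between
causes are never oriented (exposure precedes outcome by design), latent
confounders are not sought, and the expert grading of discovered links
into known/novel/bias categories is inherently manual. The improper
prior's pathologies are detected, not repaired: a cohort with no exposed
person-time simply cannot inform the test.
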
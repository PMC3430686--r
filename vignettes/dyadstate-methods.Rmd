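---
title: "Models and methods in dyadstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dyadstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dyadstate` analyses the cover/exposure dynamics of animal pairs as a
fully observed four-state continuous-time Markov chain (CTMC), and ships
a generative twin of that model so the whole pipeline can be validated on
data with known truth.  This vignette records the model, its assumptions,
the tunable parameters and their defaults, the numerical choices, and the
places where the design was genuinely open and a choice had to be made.

## The chain and its likelihood

The joint state of a pair is one of: 1 (both under cover), 2 (focal out,
partner under), 3 (partner out, focal under), 4 (both out).  Because two
continuous-time events almost surely never coincide, only one fish moves
per transition: the permitted edges are 1↔2, 1↔3, 2↔4, 3↔4, and the
"diagonal" moves 1↔4, 2↔3 are structural zeros.  Intensities are
log-linear in session-level covariates,

$$ q_{ij}(z) = q^0_{ij}\,\exp\Big(\sum_c \beta_{c,ij}\, z_c\Big), $$

with `satiated` (0/1) and, optionally, focal and partner boldness as
covariates.  A session contributes the standard event-history
log-likelihood: each completed sojourn of length $t$ in state $i$ ending
in a jump to $j$ adds $-\Lambda_i(z)\,t + \log q_{ij}(z)$ with
$\Lambda_i = \sum_j q_{ij}$, and the final sojourn — right-censored at
the session end — adds only $-\Lambda_i(z)\,t_{\mathrm{last}}$.  The
censored term is always included: omitting it would bias every exit rate
upward, most visibly for slow states.

Assumptions worth stating plainly: rates are constant within a session
(no time-of-day or habituation drift), covariates are constant within a
session, pairs are independent, and the two fish interact *only* through
the joint state (the chain itself encodes coupling such as "follows
happen faster when the partner is already out" purely through which edges
are active in which state).

## Estimation

In sufficient-statistic form the log-likelihood is
$\sum_{ij} [N_{ij}\,\eta_{ij} - T_i\, e^{\eta_{ij}}]$ with transition
counts $N_{ij}$, sojourn totals $T_i$, and
$\eta_{ij} = \log q^0_{ij} + \sum_c \beta_{c,ij} z_c$ — the form of a
Poisson regression with offset $\log T_i$.  It is concave and separates
by edge, so the package maximizes it by per-edge Newton–Raphson with
analytic gradient and Hessian and step halving, declaring convergence at
gradient max-norm ≤ 1e−8.  Initialization is at the pooled crude rate
$\max(N_{ij}/T_i, 10^{-6})$ with zero coefficients; without covariates
the first Newton step is already exact, which is why the covariate-free
MLE matches $N_{ij}/T_i$ to machine precision (an acceptance criterion).

Working scale and uncertainty:

* optimization is over $\log q^0_{ij}$ and untransformed coefficients, so
  positivity is automatic;
* standard errors come from the inverse observed information (exact here,
  not an approximation, since the Hessian is analytic);
* 95% intervals are Wald intervals on the working scale, exponentiated
  for baselines;
* the working-scale covariance is block-diagonal by edge, which the
  intensity-contrast test (delta method on
  $\log q^0_a - \log q^0_b$) uses directly.

Identifiability is screened per parameter rather than failing the whole
fit: an edge with no events anywhere is pinned at a floor intensity of
1e−8/s and excluded from the information matrix; a binary covariate's
coefficient requires events at both covariate levels; a continuous
covariate must actually vary.  If the observed information is still
computationally singular (condition number above 1e12 — typically
near-collinear boldness covariates in very small groups), trailing
covariate columns are dropped one at a time and flagged unidentifiable
instead of silently producing garbage standard errors.

Fits are pooled per pairing category (SM/SL/BM/BL), combining both
sessions of all pairs, with `satiated` given a separate coefficient on
each of the eight edges and boldness covariates centred at the category
sample mean so the baselines stay interpretable as "rates of an average
pair of this category before satiation".  Fitting "each group" could also
be read as each *pair*; per-pair fitting is available (`per_pair = TRUE`,
CLI `--per-pair`) but is not the default because single sessions leave
rare edges (2↔4, 3↔4 in shy pairs) too sparse for stable covariate
effects.  Tests are two-sided Wald tests reported with direction; no
multiplicity correction is applied by default (a Holm-adjusted column is
available behind `--holm`), mirroring per-test reporting at α = 0.05.

## Trip taxonomy

Every exit from cover is a *trip*.  A trip that starts from state 1 (the
other fish under cover) is an *attempted initiation*; it becomes a
*joint-trip initiation* if the next event is the partner joining (the
matching *follow*), and a *failed attempt* if the initiator returns
first.  Two boundary rules needed decisions that the definitions alone do
not settle:

* **Re-joins.**  In a sequence 1→2→4→2→4 the partner joins, returns, and
  joins again while the focal fish stays out.  The package counts one
  joint-trip initiation and one follow — the re-join continues the same
  joint trip.  This keeps two bookkeeping identities exact, which the
  test suite asserts on every trajectory: each fish's joint initiations
  equal the other fish's follows, and attempted = joint + failed.  (The
  alternative — a new follow per re-join — breaks both.)  Re-joins still
  count in `n_trips`, which is a pure leave-event count.
* **Censoring.**  An attempt still unresolved when the session ends is
  recorded as failed with `censored = TRUE` (so the decomposition stays
  exact), and any trip whose actor is still out at session end gets a
  censored end time.  The final open sojourn always counts toward time
  out of cover and the trip count.

The implementation walks the event sequence; the test suite checks it
against an independent interval-based oracle on the exhaustive set of all
508 chain-consistent sequences of up to six events, and the identities
above on 1,000 random simulated trajectories.

Simultaneous cross-fish timestamps are rejected during state derivation
rather than silently nudged — the model assigns them probability zero, so
they indicate logging faults; `break_ties = "shift"` (+0.01 s) is
available when the fault is understood.

## The synthetic world

`study_config()` fixes the generator's stated world; each default is a
deliberate, documented choice:

| parameter | default | why |
|---|---|---|
| category quotas | SM 14, SL 11, BM 25, BL 10 | the emulated study's group sizes (60 pairs) |
| session duration | 7200 s | two-hour sessions, control then satiated |
| boldness distribution | Beta(1.25, 2.782) | mean exactly 0.31; central 95% range ≈ 0.02–0.77, the closest two-parameter fit to the reported sample (range 0.02–0.81, mean 0.31); the reported upper percentile cannot be matched simultaneously with the mean by any Beta, and the mean was prioritised |
| rate link | log q_leave = −6.228 + 3·boldness; log q_return = −3.890 − 2·boldness | simplest positive monotone link encoding "bolder fish leave cover at higher rates"; calibrated so a boldness-0.31 fish alone spends ≈ 31% of time out in ≈ 25 trips per 2 h (q_leave = 0.005/s, q_return = 0.011/s) — trip counts and exposure times of a realistic magnitude |
| satiation effects | β = −1.5 on the focal fish's leaving edges (1→2, 3→4), +0.5 on its returning edges (2→1, 4→3), 0 on partner edges | a strong suppression of leaving and a mild increase in returning for the satiated fish only, the qualitative pattern the analysis is meant to detect |
| responsiveness | 1 (off) | a multiplier on the follow edges 2→4, 3→4 for shy-compensation scenarios; off by default so the generative model is *exactly* the fitted model and parameter recovery is well-specified by construction |

The rate link is an implementation choice, not an estimate from any real
dataset: no quantitative generative model exists for these data, so the
link is the simplest one consistent with the qualitative premise, and it
is deliberately inside the fitted model family (log-linear in boldness on
the acting fish's own edges) so that the recovery study has exact known
truth — including the boldness coefficients (3, −2, and 0 on the other
fish's edges).

What the generator does *not* emulate, and hence what a green test does
not establish: behavioural drift within or across sessions, memory or
bout-structure beyond the Markov property, individual variation around
the boldness–rate link (all fish of equal boldness behave identically),
day effects between the two sessions, and any direct
responsiveness/leadership mechanism beyond state-dependent rates.  Green
acceptance tests certify that *if* behaviour is CTMC-like with log-linear
effects, the pipeline estimates and tests it correctly — not that real
fish satisfy the model.

Simulation is exact (Gillespie): exponential holding times at rate
$\Lambda_i(z)$, next state proportional to $q_{ij}(z)$, truncated at the
session end.  Reproducibility uses one root seed with per-trajectory
child seeds derived by two rounds of Lehmer-style modular mixing of
(root, counter); the mixing matters because validation studies derive
replicate roots with the same scheme, and a linear scheme would make
adjacent replicates reuse RNG streams.

## The t-test battery

Summary metrics (proportion of time out, trip counts, initiation and
follow counts) are compared with two-tailed paired t-tests computed from
the closed form $t = \bar d / (s_d/\sqrt n)$, df $= n-1$: within-pair
initiation asymmetries (bolder vs shyer member before satiation, focal vs
partner after) and pre/post-satiation contrasts per category.  Counts are
tested untransformed; zero-variance differences are reported as exact
non-events ($t = 0, p = 1$) or flagged infinite-t results rather than
NaN; pairs missing a session are dropped listwise with a warning.  The
suite is checked against `stats::t.test(paired = TRUE)` to 1e−10 on
random fixtures, and its null calibration (rejection rate at α = 0.05
under the generator's symmetric, no-effect null) is an acceptance
criterion together with the two Wald families.

## Known limitations

* No random effects: pairs within a category share one parameter set, and
  between-pair heterogeneity beyond boldness will inflate Wald precision
  on real data.
* No panel/hidden-state machinery: the trajectory must be fully observed;
  gaps in a video log are not handled.
* Wald intervals only; no profile or likelihood-ratio intervals for
  very sparse edges, where Wald intervals are least trustworthy (they are
  flagged unidentifiable rather than patched).
* The boldness-ratio pairing categories are treated with closed endpoints
  for the moderate bands (70–85%, 115–140%) and strict cuts at 50% and
  200%; printed band notation is ambiguous about endpoint inclusion, and
  this reading is fixed here once.
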
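# dyadstate

Continuous-time Markov chain analysis of leadership in foraging dyads.

## The problem

When a pair of animals forages together between a safe covered area and a
risky exposed feeding area, who leads and who follows?  Two forces shape
the answer: **temperament** (bold individuals accept exposure more readily
than shy ones) and **physiological state** (a satiated animal has less
reason to risk leaving cover).  `dyadstate` is a pipeline for studying
this interaction in pairs — e.g. three-spined sticklebacks in a
cover/feeding-lane tank — from time-stamped logs of when each fish left
and re-entered cover, across a control session and a session in which one
pair member (the *focal* fish) was satiated first.

Because behavioural event logs of this kind are rarely deposited, the
package ships a fully specified synthetic-study generator with known
ground truth, so every stage of the analysis is exercisable and testable
end to end.

## The model

The joint behaviour of a pair is a fully observed four-state
continuous-time Markov chain:

```
1 = both under cover        2 = focal out, partner under
3 = partner out, focal under 4 = both out
```

Only one fish moves per event, so the eight permitted transitions are
1↔2, 1↔3, 2↔4 and 3↔4; transitions 1↔4 and 2↔3 are structural zeros.
Transition intensities carry log-linear covariate effects,

> q_ij(z) = q0_ij · exp( Σ_c β_c,ij · z_c ),

with `satiated` ∈ {0,1} and (centred) focal/partner boldness as the
standard covariates.  For fully observed trajectories the log-likelihood
is the usual event-history sum over sojourns, −Λ_i(z)·t + log q_ij(z),
plus a right-censored term for the final sojourn.  It is concave and
separates by edge, so maximum likelihood is solved by per-edge
Newton–Raphson with analytic gradient and Hessian; standard errors come
from the inverse observed information, and Wald machinery provides
coefficient tests (is β_12 < 0 after satiation?) and intensity contrasts
(does the bolder fish leave cover alone at a higher rate, q_12 > q_13?).

On top of the chain, trips out of cover are classified in the field's
leadership taxonomy: an **attempted initiation** (leaving while the other
fish is under cover) becomes a **joint trip** if the partner **follows**,
and failed attempts are kept on the ledger.  Behavioural summaries
(proportion of time out, trip counts, initiation/follow counts) feed a
battery of two-tailed paired t-tests: within-pair initiation asymmetries
and pre/post-satiation contrasts, per pairing category (SM, SL, BM, BL —
focal moderately/a-lot shyer/bolder than its partner, defined by boldness
ratio bands 70–85%, <50%, 115–140%, >200%).

## Worked example

```r
library(dyadstate)

cfg   <- study_config(n_pairs_per_category = c(SM = 6, SL = 6, BM = 6, BL = 6))
study <- generate_study(cfg, seed = 42)      # 24 pairs x 2 sessions, known truth

fits <- fit_by_category(study$trajectories)
fits$BL
#> <ctmc_fit: 12 trajectories, logLik -5136.67, converged in 35 Newton steps>
#>    parameter        covariate edge    estimate         se ...
#> 1      logq0             <NA>   12 -5.11686518 0.08713263
#> 2       coef         satiated   12 -1.27166098 0.15721828
#> ...

# Does the bolder (focal, in BL) fish leave cover alone at a higher rate?
wald_test_intensity_contrast(fits$BL, "12", "13")
#> $log_diff 0.911   $z 5.63   $p 1.77e-08   $direction "a>b"

# Effect of satiation on the focal fish's leaving rate (truth: -1.5)
wald_test_coefficient(fits$BL, "satiated", "12")
#> $estimate -1.27   $se 0.157   $z -8.09   $p 6.04e-16

s <- summaries_table(study$trajectories)
initiation_asymmetry_tests(s, session = "control")$BL
#> paired t-test: t_5 = 2.030, p = 0.09811 (mean diff 2.5, n = 6)

pre_post_tests(s, metric = "n_trips", fish = "focal")$BL
#> paired t-test: t_5 = 4.234, p = 0.008217 (mean diff 14, n = 6)
```

Read as: in the BL group the bolder fish's lone-exit intensity exceeds its
partner's (q̂_12/q̂_13 = e^0.91 ≈ 2.5, p ≈ 2e−8); satiating it multiplies
that intensity by e^−1.27 ≈ 0.28 (95% CI for β_12: −1.58 to −0.96,
covering the generative truth −1.5); and its trips out of cover drop by
14 per two-hour session on average (t_5 = 4.23, p = 0.008).

The same stages run from the shell on CSV event logs:

```sh
Rscript exec/dyadstate simulate  --config config.json --out sim --seed 7
Rscript exec/dyadstate fit       --events sim/events.csv --sessions sim/sessions.csv --out fit
Rscript exec/dyadstate summarize --events sim/events.csv --sessions sim/sessions.csv --out sum
Rscript exec/dyadstate analyze   --summaries sum/summaries.csv --out tests --holm
```

Exit codes: 0 ok, 2 usage/config, 3 input validation, 4 non-convergence.
Every output directory gets a `manifest.json` (command, config digest,
seed, paths, version) so runs are auditable.

## Package layout

- `R/eventlog_io.R` — event-log data model, validation, CSV I/O
- `R/behaviour_metrics.R` — boldness scores, state derivation, sufficient
  statistics, trip taxonomy, session summaries, pairing categories
- `R/ctmc_model.R` — likelihood, MLE, Wald tests, per-category fitting
- `R/synthetic_data.R` — study configuration, boldness population,
  Gillespie simulator, ground-truth study generator
- `R/stats_suite.R` — paired t-test battery
- `R/validation.R` — simulation studies behind the acceptance criteria
- `R/cli.R`, `exec/dyadstate` — command-line pipeline
- `vignettes/dyadstate-methods.Rmd` — modelling assumptions, parameter
  choices and limitations
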
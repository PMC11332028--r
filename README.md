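# rpemem

Reward prediction errors, perceptual memorability, and recognition memory:
a simulation and analysis toolkit for a two-stage behavioural paradigm in
computational psychiatry.

## The problem

In a two-arm bandit with unsignalled reward reversals (60 trials, win
probabilities 0.8/0.2 yoked across arms, reversing every 12 ± 1 trials),
every choice is followed by a unique, highly memorable face stimulus. A
surprise-laden outcome attaches a reward prediction error (RPE) to that
stimulus; the stimulus also carries an intrinsic perceptual memorability
(PM) score from population norming. A subsequent old/new recognition test
(60 old probes + 60 lures) asks which of these two information streams —
extrinsic reward surprise or intrinsic perceptual quality — drives memory,
and whether affective phenotype moderates the RPE–memory link.

rpemem implements the full analysis chain for researchers working with this
class of paradigm, plus a synthetic-data generator that makes every stage
runnable and testable with no data download.

## What's inside

* **Decision models** — Rescorla–Wagner (`Q ← Q + α(r − Q)`, softmax with
  inverse temperature β), win-stay/lose-shift (adherence ε), and a
  two-state Bayesian filter (`p_reward`, `p_switch`); per-subject Bayesian
  fitting (adaptive MCMC, 4 chains × 4000 draws by default, split-chain
  Gelman–Rubin diagnostics), WAIC comparison with a chi-square test of
  winner proportions, trial-level RPE extraction, parameter recovery,
  identifiability confusion matrices, and a reward landscape over (α, β).
* **Recognition memory** — response labelling (hit / miss / correct
  rejection / false alarm), clamped d′, the 2-SD standardization rule, and
  a Bayesian mixed-effects logistic regression of memory success
  (`correct ~ RPE + PM + within-block trial + subject covariates`, random
  intercept and RPE/PM slopes per subject; JAGS backend) with 95%
  highest-density-interval decisions.
* **Drift diffusion** — a compiled Wiener first-passage-time density
  (dual-series expansion), standard RT exclusion rules (300 ms / 10 s /
  3 subject-level SDs), and hierarchical
  drift regressions (`v ~ RPE` or `v ~ PM`, random intercept + slope per
  subject; pooled boundary, start point, non-decision time) compared by
  WAIC.
* **Transdiagnostic factors** — KMO and Bartlett adequacy checks, the
  Cattell–Nelson–Gorsuch factor-count test, maximum-likelihood factor
  analysis with promax rotation, ten Berge correlation-preserving factor
  scores.
* **Subject-level inference** — moderation regressions (memory outcome ~
  random slope × factor score) and TOST equivalence tests with bounds
  [−0.1, 0.1].
* **Synthetic data** — seeded generators for schedules, agents,
  recognition outcomes/RTs (logistic- or diffusion-generated), and Likert
  survey matrices with an oblique 3-factor structure.

## Worked example

```r
library(rpemem)

# one agent on the reversal bandit
sch <- generate_task_schedule(task_config(seed = 5))
dat <- simulate_agent(agent_spec("rw", alpha = 0.7, beta = 5), sch, seed = 2)
fit <- fit_model("rw", dat, seed = 3)
print(fit)
#> Bayesian rw fit: 60 trials
#>   alpha = 0.843 (R-hat 1.003); beta = 5.215 (R-hat 1.010)
#>   WAIC 45.7 (SE 8.0)
```

The posterior mean learning rate (0.84) and inverse temperature (5.2) sit
near the generating values (0.7, 5) to within what 60 trials can identify;
R-hat below 1.01 indicates the four chains agree; WAIC is the deviance-scale
information criterion used for model comparison.

```r
# the full synthetic pipeline: simulate, exclude, fit, compare, moderate
bundle <- run_pipeline(run_config(seed = 7, n_subjects = 14,
  rl_sampler  = list(chains = 2, draws = 600, warmup = 600),
  glm_sampler = list(chains = 2, draws = 600, warmup = 600),
  ddm_sampler = list(chains = 2, draws = 500, warmup = 500),
  surveys = survey_gen_params(n_respondents = 150)))
print(bundle)
#> Synthetic pipeline report
#>   subjects retained: 11 of 14
#>   decision-model winners:  rw=9, wsls=0, bayes=2
#>   drift-regression ranking: pm > rpe
#>   factor adequacy: KMO 0.88
#>   moderation interaction p = 0.271; TOST p_eq = 0.833
```

Three simulated subjects fail the above-chance binomial retention rule; the
Rescorla–Wagner model wins the WAIC comparison for most retained subjects
(it generated the data); at this small scale the drift-regression ranking
and the moderation test are underpowered, as the near-1 p-values show. A
command-line wrapper lives at `inst/scripts/run-pipeline.R`.

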
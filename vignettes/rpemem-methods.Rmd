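---
title: "Models and methods behind rpemem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rpemem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rpemem implements, end to end, the computational analysis of a two-stage
behavioural experiment: a two-arm bandit with unsignalled reward reversals in
which every trial shows a unique, perceptually memorable face stimulus,
followed by an old/new recognition test over those stimuli plus an equal
number of lures. The scientific question the toolchain serves is how the
reward prediction error (RPE) attached to a stimulus at encoding, and the
stimulus's intrinsic perceptual memorability (PM), separately shape later
recognition — and how individual differences (for example transdiagnostic
affect scores) moderate the RPE-memory link. Because the package must be
fully testable offline, a first-class synthetic-data module generates every
input with the statistical structure the analyses assume.

## The task and its generator

The bandit runs for 60 trials with win probabilities 0.8/0.2 yoked across
the two arms and reversed 4 times, every 12 ± 1 trials. `task_config()` /
`generate_task_schedule()` reproduce this design: block lengths are drawn
uniformly from {11, 12, 13} and the final block absorbs the remainder so the
trial count is exact. Jitter applies to every block, including the first;
the design source does not say whether the first block was anchored, and a
uniformly jittered first block keeps all reversal positions exchangeable.
Wins pay 100 points on screen, but rewards are coded 0/1 internally: the
inverse-temperature scale of the decision models (cohort values around 5)
is only meaningful against unit-scaled rewards, and the point multiplier is
cosmetic.

Memorability ratings emulate a pool of highly memorable face stimuli:
normed recognition d′ scores drawn from a truncated normal (mean 2, SD 0.3,
support [0.5, 3.5]). The real stimulus pool was selected to be highly
memorable with limited spread; the exact pool distribution is not published,
so these values are a fixed, realistic stand-in. Lures draw from the same
distribution (distribution-matched rather than item-matched, since only
"matched d′ scores" is specified).

## Decision models

Three agent families generate and fit choice behaviour:

* **Rescorla–Wagner (RW).** Option values start at the reward-scale midpoint
  (Q₀ = 0.5, an uninformative choice the design source leaves open), are
  updated by `Q ← Q + α (r − Q)`, and choices follow a softmax with inverse
  temperature β. The trial-level RPE is `r − Q` of the chosen option before
  the update, which is the quantity later carried into the memory models.
* **Win-stay/lose-shift (WSLS).** The rule-consistent action (repeat after a
  win, switch after a loss) is emitted with probability ε; the first trial
  is a coin flip. ε is read as a per-trial adherence probability — the most
  direct reading of a one-parameter "choice bias".
* **Bayesian filter.** A two-state hidden Markov model ("arm 0 good" / "arm
  1 good") with reward probability `p_reward` and switch probability
  `p_switch`. Each trial the posterior is mixed by the symmetric transition
  matrix, the action probability is the transitioned prior probability that
  the chosen arm is currently correct (probability matching), and the reward
  observation updates the state belief. Applying the transition before the
  action probability is the standard forward-filter order; the alternative
  (observe-then-transition) differs only in where trial one's flat prior
  sits and was not adopted.

Fitting is per-subject Bayesian inference. Since no NUTS implementation is
available to the package, the two-parameter posteriors are sampled with an
adaptive Metropolis sampler on unconstrained scales (logit for probabilities,
log for β) with weakly informative, bound-respecting priors: α, ε ~
Beta(1,1); β ~ half-Normal(10); p_reward ~ U(0.5,1); p_switch ~ U(0,0.5).
During warm-up the proposal covariance adapts to the posterior (Haario-style
empirical covariance with Robbins–Monro scale tuning); it is frozen for the
retained draws. Defaults are 4 chains × 4000 draws after 4000 warm-up
iterations, and the split-chain Gelman–Rubin
statistic is computed per parameter; fits at these settings stay below the
1.01 convergence bound with a wide margin because the posteriors are
two-dimensional and well-behaved. Model comparison uses WAIC on the deviance
scale (−2·elpd with the variance penalty), per-subject winners, and a
chi-square test of winner proportions. Parameter recovery, identifiability
(fit every model to cohorts simulated from each model), and a reward
landscape over (α, β) complete the model-assessment suite.

## Recognition: memory regression and drift diffusion

Responses are labelled hits / misses / correct rejections / false alarms;
hits and correct rejections count as correct memory choices. d′ is the
difference of normal quantiles of hit and false-alarm rates, with extreme
rates clamped to [1/(2N), 1 − 1/(2N)] — the standard correction; the source
does not state its own.

The memory regression is a Bayesian mixed-effects logistic model: correct ~
trial-level RPE, PM, and within-block trial (restarting at 1 after each
reversal) plus optional subject-level covariates, with a random intercept
and random RPE and PM slopes per subject. All numeric predictors are
standardized by centring and dividing by twice the sample SD (n−1
denominator), which puts them on the scale of a binary contrast; lure trials
carry no RPE or encoding position and are zero-imputed on this centred
scale, i.e. held at the old-probe mean, so one model can describe all four
response types without inventing lure RPEs. Priors are Normal(0, 2.5) on
standardized fixed effects and half-Normal(1) on random-effect SDs. This
model is a conventional hierarchical GLM, so it is fit with Gibbs/slice
MCMC via JAGS (rjags, with the `glm` module's block samplers); effects are
declared meaningful when the 95% highest-density interval excludes zero.

Recognition reaction times are modelled with a hierarchical drift-diffusion
model. The Wiener first-passage density is implemented in compiled code via
the dual small-time/large-time series expansion with error-bound term
selection; validity is checked by quadrature (total mass 1), by the
upper/lower relabelling symmetry, and against Euler–Maruyama forward
simulation (Kolmogorov–Smirnov distance below 0.01 at 10⁵ paths, dt = 1e-4).
The drift rate is a linear (optionally quadratic or shifted-log,
`log(x − min(x) + 1)`, so signed RPEs stay in the log's domain) function of
one standardized covariate with a random intercept and random slope per
subject; boundary separation `a`, start point `z`, and non-decision time `t`
are pooled. The upper boundary codes an "old" response. Trials faster than
300 ms or slower than 10 s are excluded, then trials beyond 3 subject-level
SDs of the subject mean; drift regressions use old-probe trials by default
because lures have no RPE. Sampling is Metropolis-within-Gibbs in compiled
code: subjects are updated jointly (intercept, slope), group means by
conjugate Gibbs, and — because centred hierarchies mix badly when
between-subject variance is small — the group means and SDs are additionally
updated through interweaved non-centred moves that translate or rescale all
subject effects while evaluating the full likelihood. Priors: group
intercept/slope ~ Normal(0, 2); SDs ~ half-Normal(1); a ~ Gamma(2, rate
1.5); z ~ Beta(2, 2); t ~ Uniform(0.05, min RT). Model ranking (RPE vs PM
drift) again uses WAIC.

The synthetic recognition generator has two modes, because the logistic
memory model and the diffusion model cannot both be the exact generative
truth at once. In the default `"logistic"` mode, correctness follows the
logistic model and the RT is a first-passage time conditioned (by rejection)
on the boundary matching the emitted response — data shaped for the memory
regression. In `"ddm"` mode, response and RT are drawn jointly from the
first passage, which is what drift-regression recovery studies require.
Baseline drift points toward the correct answer (sign flipped for lures),
with subject-level drift intercepts and slopes drawn around the group values
(SDs 0.2/0.05/0.05 by default — modest, realistic between-subject spread).
Generative defaults sit at the scale of the cohort-level estimates this
task family produces (log-odds 0.17/0.16/−0.12 for RPE/PM/within-block
trial; drift slopes of a few hundredths per standardized unit).

## Surveys, factors, and subject-level moderation

The survey generator emulates a three-scale battery (20 + 20 + 18 items,
4-point Likert): latent factors are multivariate normal with the reported
factor correlations (−0.62, −0.22, −0.38), items load 0.7 on their own
factor, and continuous scores are discretized by equal-probability normal
thresholds. The analysis side computes KMO sampling adequacy and Bartlett's
sphericity, selects the factor count with the Cattell–Nelson–Gorsuch test
(slope of a 3-eigenvalue fit at position i compared with the fit at i+3,
retained factors = argmax + 2 — the published formulation), extracts factors
by maximum likelihood on Pearson correlations (polychoric alternatives are
out of scope; Pearson on 4-point items attenuates loadings slightly, which
recovery tests absorb via Tucker congruence rather than raw equality),
rotates varimax-then-promax (power 4), and computes correlation-preserving
ten Berge factor scores. Heywood cases are held at the 0.005 uniqueness
bound; near-singular correlation matrices receive a 1e-8 ridge with a
warning. Recovered solutions are compared to generating structures after a
sign/permutation search maximizing Tucker congruence (brute force, k ≤ 4).

Subject-level moderation regresses a memory outcome (d′ by default;
proportion correct available) on a subject random slope (for example the
per-subject RPE slope exported from the memory regression, reported as fixed
effect plus deviation), a moderator such as a factor score, and their
interaction, by OLS with 2-SD standardization. Null findings are accompanied
by TOST equivalence tests against bounds [−0.1, 0.1]: two one-sided t-tests
at the OLS residual degrees of freedom, with the equivalence p the larger of
the two one-sided p-values.

## Pipeline, exclusions, and reproducibility

`run_pipeline()` chains the stages: simulate a cohort (generative RW
parameters drawn from truncated normals around the cohort-scale means
0.73 ± 0.19 and 4.9 ± 2.9) → exclude subjects whose choice accuracy does not
beat chance (one-sided exact binomial test against 0.5 at p ≤ 0.05; the
original exclusion criterion is unstated, and a one-sided exact test is the
natural reading of "no different from chance" for a retention rule) → fit
and compare the decision models → extract RPEs from the RW fit at the
posterior-mean learning rate → simulate and analyse recognition → generate
and factor-analyse surveys, scoring task subjects from the pooled solution →
memory regression with subject covariates → moderation and equivalence.
Every stage draws its seed deterministically from one master seed, so the
simulation layer is byte-reproducible; artifacts are tidy CSV files with
JSON parameter sidecars.

## Problem sizes and what the tests do (and do not) show

The test suite runs the whole machinery at reduced but honest sizes chosen
for a laptop-scale run: decision-model recovery uses 50 agents at the
task's 60 trials, identifiability 30 agents per generative model,
hierarchical drift-regression recovery one cohort of 25 subjects,
regression calibration 20 null cohorts of 12 subjects, and the factor
pipeline 10,000 respondents. Reduced sampler settings (2 chains, 700–1500
draws) are used inside batch tests, with the convergence criterion checked
separately at the full default settings. Passing these tests shows the
implementations are internally correct and calibrated on data that satisfy
the models' assumptions exactly; it does not show that real behaviour is
well described by these models — real data bring contaminant RTs, lapses,
item effects, and survey response styles that the generator deliberately
omits.

## Known limitations

No hierarchical (group-level) fitting of the decision models; no
trial-to-trial variability parameters (sv, st, sz) or collapsing bounds in
the DDM; confidence ratings are generated for format fidelity but never
modelled; Pearson rather than polychoric correlations for Likert items; the
Metropolis-based samplers trade some efficiency for transparency and would
be slower than gradient-based samplers on much larger models.
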
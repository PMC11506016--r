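---
title: "Methods: hierarchical drift-diffusion modelling of valence evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical drift-diffusion modelling of valence evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valddm)
```

# The model

`valddm` analyses two-choice valence-evaluation experiments — tasks in which
a participant sees a word and classifies it within a 1600 ms deadline as
moral/immoral (moral evaluation task) or positive/negative (emotional
evaluation task) — with the two-boundary drift-diffusion model (DDM).
Evidence accumulates from a starting point $z = z_{rel} \cdot a$ at rate $v$
with unit-variance Gaussian noise; a response is produced when the process
hits the upper boundary $a$ or the lower boundary $0$, and the observed
response time adds a non-decision time $\tau$ for encoding and motor
execution. In the moral task the upper boundary is wired to the "moral"
response, so moral words carry positive drift and immoral words negative
drift; $z_{rel} < 0.5$ encodes a head start for the immoral/negative
response (a negative bias).

The defective first-passage density at the upper boundary is

$$f_\mathrm{up}(t \mid v, a, z) = \frac{\pi}{a^2} e^{(a - z) v - v^2 t / 2}
\sum_{n=1}^{\infty} n \sin\!\Big(\frac{\pi (a - z) n}{a}\Big)
e^{-\pi^2 n^2 t / (2 a^2)},$$

and the lower-boundary density follows from the reflection
$v \to -v,\ z \to a - z$. Each boundary's density integrates to that
choice's probability (the gambler's-ruin formula implemented in
`prob_upper()`), and the two integrals sum to one.

## Numerical evaluation

The Fourier series above converges quickly for large $t$ but poorly for
small $t$, where the image-expansion (small-time) form converges in a few
terms. `fpt_density()` implements both and, by default, picks whichever
needs fewer terms for the requested truncation tolerance (`tol`, default
$10^{-7}$, interpreted on the final density scale). The two expansions are
cross-checked against each other, against adaptive quadrature of the
normalization identity, and against the closed-form absorption probability
in the test suite. The diffusion coefficient is fixed at $s = 1$, the
convention of most hierarchical DDM software; it is a scale choice, not a
free parameter, and is deliberately not configurable.

The simulator (`sample_trials()`, and `sim_schedule_cpp` internally) is an
Euler–Maruyama scheme (default step $10^{-4}$ s) with a Brownian-bridge
correction: at every step the probability that the continuous path crossed
either boundary *inside* the step is computed and resolved by an extra
uniform draw. This removes the leading-order discretization bias, which
matters because the simulator doubles as an independent oracle for the
density (Kolmogorov–Smirnov agreement at $n = 10^5$ is part of the
acceptance tests). All random streams use an explicit 64-bit generator with
a user seed, so every simulation and fit is bit-reproducible.

# The hierarchical model

The estimator targets a twelve-group design: words live in a
2 (word type) × 6 (valence-grid cell) layout, giving groups such as
`moral_2V1M` (moral word, high emotional, medium moral valence). Each group
$g$ has its own families of drift rates, boundary separations and
non-decision times: participant-level parameters
$v_{pg} \sim N(\mu_{v,g}, \sigma_{v,g})$ and likewise for $a$ and $\tau$.
The relative starting point is shared across groups within a participant —
one $z_{rel,p} \sim N(\mu_z, \sigma_z)$ truncated to $(0,1)$ — because a
prior response bias is a property of the responder, not of the stimulus
group. The `no_bias` variant pins $z_{rel} = 0.5$ everywhere; comparing the
two variants by DIC asks whether the data carry evidence of a response bias.

## Priors

Defaults (all configurable through `default_priors()`):

* $\mu_{v,g} \sim N(0, 2)$ — weakly informative on the evidence scale;
* $\mu_{a,g} \sim \mathrm{Gamma}(1.5, 0.75)$ truncated above $0.3$;
* $\mu_{\tau,g} \sim \mathrm{Uniform}(0.05, \max_p \min_t rt_{pt})$.
  The upper bound uses the *largest participant-level minimum RT*: each
  participant's own $\tau$ is already capped by their fastest trial through
  the likelihood, and bounding the group mean by the global minimum RT
  would let a single fast participant make everyone's mean non-decision
  time unestimable;
* $\mu_z \sim \mathrm{Beta}(2, 2)$;
* group spreads: half-Normal(1) for $v$, $a$ and $\tau$, half-Normal(0.2)
  for $z_{rel}$ whose support is an interval of length one.

Participant-level parameters carry hard support bounds (e.g.
$a \in (0.15, 6)$, $z_{rel} \in (0.03, 0.97)$) that act through the
likelihood; the truncated-normal normalizing constants are not propagated
into the group-level updates. The bounds sit far outside the posterior mass
in any reasonable dataset, so this changes the model only at the third
decimal of the prior; it is documented here rather than hidden.

## Sampler

`sample_posterior()` runs an adaptive Metropolis-within-Gibbs scheme written
in C++: conjugate Gibbs for the group drift means, random-walk Metropolis
for everything else, with two sweeps over the participant-level parameters
per iteration (the $v$–$a$–$\tau$ ridge within a cell is the slow
direction). Proposal scales adapt toward 44% acceptance during burn-in only,
so the post-burn-in chain is a fixed, valid Markov kernel. Chains are
initialised from EZ-style moment estimates of each participant × group cell,
which starts the walk near the mode. The default profile is 60,000 draws
with 5,000 burn-in (thinned by 10); the desk-scale profile used throughout
the tests is 3,000/500 unthinned, which finishes in well under a minute on
one core for a 30-participant cohort.

Convergence is summarised by split-$\hat R$ (the chain split in halves),
autocorrelation-based effective sample size, and autocorrelation profiles
(`chain_diagnostics()`). A fit flags (and warns about) any group-level
$\hat R > 1.1$; for results one intends to report, the package's
recommended gate is $\hat R < 1.05$, which short desk-scale chains will not
always meet — the warning is informative, not decorative.

By default `build_model()` fits correct responses only, mirroring the
original deadline-evaluation design it emulates, while keeping the
*defective* density as the likelihood. That convention censors one boundary
per stimulus group and therefore biases parameters slightly relative to the
full generative process; `include_errors = TRUE` keeps both boundaries and
makes the likelihood correctly specified. Parameter-recovery checks use
`include_errors = TRUE` for exactly that reason.

## Inference

Group-level hypotheses are evaluated on posterior difference distributions
(`diff_distribution()`): the element-wise difference of two aligned draw
vectors, summarised by its mean and the percentage of mass on each side of
zero, significant when at least 95% falls on one side. Draws exactly equal
to zero (measure-zero in practice) count half to each side, which makes
`diff_distribution(x, x)` exactly zero-mean and never significant. Model
comparison uses the deviance information criterion
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$, computed
from the deviance trace accumulated during sampling and the likelihood at
the posterior mean of the participant-level parameters; lower is better.
Posterior predictive checks (`posterior_predict()`) simulate replicate
datasets from random posterior draws and compare observed choice
proportions and RT quantiles (10/30/50/70/90%) per group against central
95% predictive intervals.

# The synthetic study generator

The generator reproduces the study design at desk scale with known ground
truth: 96 two-character word stimuli filling the twelve populated cells of
the valence grid (8 words each), two 192-trial tasks per participant (each
word twice, shuffled), task order and key mapping counterbalanced, and a
1600 ms deadline. Norming ratings emulate a 31-rater questionnaire on two
1–9 scales; ratings are true word scores plus a rater-severity random
effect plus noise, rounded to the Likert grid. The severity effect is what
creates inter-rater consistency — without it Cronbach's alpha (raters as
cases, words as items) would be near zero by construction — and the default
noise scales put alpha near 0.94–0.95 on both scales. Because selection
operates on noisy rating means, the designed 96 words survive the
`select_words()` threshold only up to rater noise; the generator places
true intensities with margin so the surviving count lands close to (not
exactly at) 96.

The default `"study_pattern"` scenario encodes the qualitative structure
the estimator is meant to detect: drift rising with emotional valence for
moral words ($1.6, 2.4, 3.2$ across the three levels), boundary separation
falling with emotional valence for immoral words ($1.7, 1.5, 1.3$), no
moral-valence effects, $\tau = 0.32$ s, and $z_{rel} = 0.45$ (a mild
negative bias; `"strong_bias"` uses $0.35$). Between-participant SDs are
$0.3 / 0.2 / 0.05 / 0.05$ for $v / a / \tau / z$. These are round numbers
chosen once, analytically via the package's own density, to satisfy the
study conditions the generator is meant to emulate — roughly 4–6% errors,
timeouts of order half a percent, mean RTs near 600 ms, and moral words
evaluated faster than immoral ones. They are *not* estimates of any real
dataset, and passing recovery tests on this generator shows the estimator
works under its assumptions (no contaminant guesses, no drift variability
across trials, exact distributional families), not that real data obey
them.

The emotional task is simulated from the same participant parameters with
boundaries relabeled (upper = "positive") plus small word-type-specific
non-decision offsets (+7 ms moral, −16 ms immoral), a convention that gives
the task the familiar small RT asymmetry; nothing downstream fits the
emotional task with the DDM by default.

# Behavioral statistics

The non-model statistics follow the standard conventions for this design:

* `intensity()` maps 1–9 scores to distance from the neutral midpoint 5;
  `select_words()` keeps words with intensity strictly above 2 on either
  dimension (boundary words drop);
* `assign_valence_levels()` bins each intensity dimension into three levels
  using equal-width bins over the observed range (values exactly on an
  interior edge go up); equal-frequency binning is available behind a flag
  because "equal distribution across the range" admits both readings;
* `filter_trials()` removes timeouts first, then errors, and reports both
  per task; it is idempotent;
* `rm_anova_2x2()` / `simple_effects()` implement the within-subject
  sums-of-squares decomposition with partial $\eta^2$, each effect tested
  against its own effect-by-subject interaction. Sphericity is moot for
  2×2 (one-df effects). Accuracy is analysed untransformed;
* `paired_t_fdr()` applies Benjamini–Hochberg across the declared family;
* `required_sample_size()` follows the G*Power within-factors convention
  ($\lambda = f^2 n m / (1-\rho)$, $df_1 = (m-1)\varepsilon$,
  $df_2 = (n-1)(m-1)\varepsilon$) with defaults $m = 4$, $\rho = 0.5$,
  $\varepsilon = 1$ — the most plausible settings for a 2×2
  repeated-measures design when only test family, $\alpha$, power and $f$
  are stated. With $f = 0.25$, $\alpha = .05$, power $.85$ it returns 26.

# Problem sizes used in the tests

Unit tests run on 4–6 participant cohorts with short chains (400–1,200
draws). The acceptance suite uses: the full density grid
($v \in \{-3..3\}$, $a \in \{0.5..3\}$, $z_{rel} \in \{0.2..0.8\}$) for
normalization; six parameter sets at $n = 10^5$ for simulator–density KS
agreement; twenty random parameter sets at $n = 5 \times 10^4$ for
absorption probabilities; ten seeded 30-participant cohorts at the
3,000/500 profile for parameter recovery (mean absolute error of the twelve
group-level means, ±0.3 for $v$ and ±0.2 for $a$, plus the two monotone
orderings — the per-cell sampling SD at this design size is ≈0.15, so a
per-cell bound would be dominated by sampling noise rather than estimator
quality); twenty replicate 10-participant cohorts with $z_{rel} = 0.35$ for
DIC model selection; and 2,000 null cohorts for the ANOVA type-I error.

# Known limitations

* The sampler is single-chain (split-$\hat R$ diagnoses mixing, not
  between-chain agreement); for publication-grade fits run several seeds.
* The likelihood ignores the response deadline (a <1% right-censoring at
  the defaults) and trial-to-trial parameter variability by design.
* Correct-only fitting (the default, for fidelity to the emulated design)
  is a deliberately censored likelihood; use `include_errors = TRUE` when
  the inferential target is the generative parameters.
* The generator's emotional-task parameters are a convention, not a fitted
  claim about emotional evaluation.
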
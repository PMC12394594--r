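---
title: "Emotion transition predictions, loneliness, and internal meta-analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion transition predictions, loneliness, and internal meta-analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emotrans)
```

# The problem

In the emotion transition task, a participant rates on a 0--100% scale how
likely a target -- themselves or another person -- is to move from one
emotion state (e.g. *calm*) to another (e.g. *irritable*).  Collected over
every ordered pair of a study's emotion set, these ratings describe a
participant's mental model of emotion dynamics.  `emotrans` implements a
multi-study analysis of how such models relate to trait loneliness
(20-item scale, responses 0--3, sum score 0--60, reverse-keyed items
scored `3 - x`), and pools each analysis across studies with a
random-effects meta-analysis.  A synthetic multi-study generator with
known planted effects makes every stage testable by parameter recovery,
so no external data are required.

# The analyses

**Typicality.** For each participant, the Pearson correlation between
their transition-rating vector and the group-average vector; the
association of this index with standardized loneliness is the study-level
effect, carried as Fisher *z* with variance $1/(n-3)$.  The default mode
includes the participant in the group average, which follows the verbal
definition of the procedure literally; a leave-one-out mode is provided
because inclusion biases indices upward in small samples.  Both are
reported by the pipeline configuration.

**Anna Karenina IS-RSA.** Intersubject representational similarity
analysis: the pairwise-participant similarity matrix (Pearson
correlations of rating vectors) is compared against a loneliness-derived
model matrix in which a pair's expected similarity decreases with its
(mean, by default) loneliness -- low scorers are alike, high scorers are
idiosyncratic in their own ways.  The matrix-level statistic is the
Spearman correlation of the lower triangles.  Because matrix cells are
not independent, inference uses a Mantel permutation scheme: participant
labels of the loneliness vector are permuted, the model matrix is rebuilt
each time, and the two-sided p-value is
$(1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\}) / (1 + n_{perm})$.  The pair
minimum (`ak_min`) and a nearest-neighbour matrix (`nn`,
$-|L_i - L_j|$) are provided as sensitivity variants since the exact
operationalization is a free choice.

**Accuracy.** A "ground truth" for each transition is the mean
self-rating across all participants of the study.  A linear mixed model
predicts this ground truth from each participant's other-targeted rating,
loneliness, and their interaction; a negative interaction means lonelier
participants' predictions track the consensus less strongly.  The model
orientation (ground truth as outcome) follows the source procedure
verbatim even though the reverse orientation may feel more natural.

**Anchoring.** The same moderated model predicting other-targeted ratings
from self-targeted ratings: a negative interaction means lonelier
participants rely less on their own transitions when predicting others'.

**Valence transitions.** Each non-neutral transition is classified by its
endpoint valences (PP, PN, NP, NN); neutral-involving transitions are
excluded from this analysis only.  Same-state pairs classify by their
endpoints (a *happy -> happy* pair is PP).  Ratings are modelled from
category x loneliness, and the per-category loneliness simple slopes
($\beta_{L} + \beta_{L \times c}$, variance by the usual linear
combination of the coefficient covariance) are the study-level effects.

**Confidence.** The per-participant sample standard deviation (n-1
denominator) of transition ratings, correlated with loneliness.  A
committed rater assigns high and low likelihoods; a hedging rater stays
near the midpoint, so a lower SD is read as less confident responding.

# The mixed-model engine

All moderated analyses use a Gaussian linear mixed model with crossed
random intercepts for participant, from-state and to-state:
$y = X\beta + \sum_k Z_k u_k + e$, $u_k \sim N(0, \sigma_k^2 I)$.
Estimation is restricted maximum likelihood with the variance ratios
$\lambda_k = \sigma_k^2/\sigma_e^2$ optimized on the log scale (which
enforces nonnegativity); for fixed $\lambda$, $\beta$ and $\sigma_e^2$
have closed forms through the Woodbury identity applied to the
$q \times q$ crossproducts of the random-effect indicators, so the cost
per iteration is governed by the total number of random levels (a few
hundred) rather than the number of rows (tens of thousands).  Convergence
is declared when the REML criterion changes by less than the relative
tolerance ($10^{-8}$ by default); variance ratios below $10^{-7}$ are
reported as exactly zero with a boundary flag.

Numerical/inference conventions, chosen deliberately:

* **Wald normal inference** (`z = beta/SE`, CI = estimate +/- 1.96 SE) rather
  than Satterthwaite or Kenward-Roger degrees of freedom.  With thousands
  of observations per fit the difference is negligible, and it avoids
  reimplementing a df approximation.  This is a documented divergence
  from the mixed-model software the original analyses used.
* **Standardized coefficients** are obtained by z-scoring the outcome and
  all continuous predictors across the analysis rows before fitting
  (categorical predictors are reference-coded, never standardized).
  Whether the original analyses standardized before fitting or
  post hoc is not stated; pre-standardization is this package's
  convention and is configurable per model spec.
* Ratings enter on the 0--100 scale before standardization; no logit
  transform, mirroring the linear treatment of the original analyses.

The test suite validates the engine against three independent oracles:
ordinary least squares when the random variances are truly zero, the
closed-form ANOVA estimators on balanced one-factor designs, and a
reference implementation (`lme4`) on a simulated crossed design.

# Random-effects meta-analysis

Study effects $y_j$ with sampling variances $v_j$ follow
$y_j \sim N(\mu, v_j + \tau^2)$.  $\tau^2$ is estimated by REML with the
standard fixed-point iteration (tolerance $10^{-10}$, truncation at
zero, DerSimonian--Laird start); pooling uses inverse-variance weights
$w_j = 1/(v_j + \hat\tau^2)$.  Heterogeneity is summarized by $I^2 =
100\,\tau^2/(\tau^2 + s^2)$ with the Higgins "typical" within-study
variance $s^2 = (k-1)\sum w_j / ((\sum w_j)^2 - \sum w_j^2)$,
$w_j = 1/v_j$ -- the same convention as the reference meta-analysis
package, rather than the Q-statistic form.  Confidence intervals are
plain Wald (no Knapp--Hartung).  Correlation-type effects (typicality,
IS-RSA, confidence) are pooled on the Fisher-z scale and back-transformed
with tanh for reporting; standardized mixed-model coefficients are pooled
as they are.  Whether the original analyses Fisher-transformed
correlations is unstated; both modes exist, with Fisher-z pooling the
default because it is variance-stabilizing.

Studies that lack other-target data are simply absent from other-target
families, so those pool with `k` reduced by one -- with the default
seven-study suite, `k = 7` for self analyses and `k = 6` for other
analyses.

# The synthetic world

`generate_study()` draws, per participant with within-study loneliness
z-score $L$ (raw scores from a Normal truncated to the 0--60 scale and
rounded; defaults per study follow published study-level means/SDs):

1. a base matrix $B$ of likelihoods per valence category (defaults:
   same-state 65, PP 60, NN 50, PN 30, NP 35, neutral-involving 45 -- a
   plausible persistence-over-switching structure, free parameters rather
   than empirical claims);
2. self ratings $S = B + a\,\max(L,0)\,D\,100 + c\,L\,d_{self} + \varepsilon$,
   with $D$ a unit-norm idiosyncrasy direction drawn fresh per
   participant, $d_{self}$ = -1 for PP / +1 for PN, and Gaussian noise;
3. compression of deviations around the participant's own mean by
   $e^{-\kappa L}$ (the confidence mechanism);
4. an anchoring weight $w = \mathrm{logistic}(w_0 - w_1 L)$ and other
   ratings $O = wS + (1-w)(B + m\,L\,d_{vol}) + a\,\max(L,0)\,D'\,100 +
   \varepsilon'$, with $d_{vol}$ = +1 for cross-valence and -1 for
   same-valence transitions and $D'$ a second, independent idiosyncrasy
   direction, followed by the same compression;
5. truncation to [0, 100], with the truncated fraction recorded (below
   5% under defaults).

Atypicality enters through $\max(L, 0)$, not symmetrically: low-loneliness
participants cluster near the norm while lonely ones diverge in
participant-specific directions.  This one-sided, idiosyncratic structure
is what produces the Anna Karenina pattern (high-loneliness pairs are
dissimilar *to each other*, not clustered at an opposite pole).

Two generator choices deserve emphasis.  First, the other-target
idiosyncrasy $D'$ is applied at full weight rather than filtered through
the anchoring weight $w$.  If lonely participants' deviations reached
others' ratings only via $w \cdot a\,\max(L,0)\,D$, the very anchoring
reduction being modelled ($w$ falling with $L$) would strip their
other-models of idiosyncrasy, and the compression mechanism (which
shrinks $sd(O)$ for lonely raters, mechanically *inflating* the
ground-truth-on-rating slope) would leave the accuracy moderation near
zero or positive -- contradicting the pattern the generator exists to
emulate, in which lonely individuals hold idiosyncratic and less accurate
models of others in their own right.  Second, noise is Gaussian with
truncation rather than logit-normal, for simplicity; the truncation
fraction is monitored so that boundary pile-up stays negligible.

Default effect magnitudes (`a = 0.5`, `w0 = 1`, `w1 = 0.4`, `m = 3`,
`c = 3`, `kappa = 0.05`, `noise_sd = 10`) were fixed once after a small
design study checking that each planted mechanism dominates the
statistic it targets (in particular that idiosyncrasy outweighs the
compression artifact in the accuracy model); they produce stronger
associations than real data would and are meant for direction and
calibration checks, not effect-size realism.

What a green test does **not** establish: the generator has no real
emotion dynamics (no EMA ground truth), no item-level loneliness
structure, no missing data, no scale-use or acquiescence biases, and
planted effects are linear in $L$.  Recovery of signs and calibration
under this stated world says the estimators work; it says nothing about
the empirical magnitudes in real populations.

A fifteen-state design variant uses a **synthetic** valence assignment
(`synthetic_15_state_map()`); the authoritative assignment for those
labels is not available, so that map is this package's own choice and is
only used by the generator.  Similarly, incomplete loneliness scales are
dropped rather than prorated -- whether the original procedure prorated
is unknown, and dropping is the conservative default (a prorating flag
is deliberately not offered).

# Degenerate inputs and tie-breaks

* Ratings outside [0, 100] are validation errors, never clamped: the
  task interface bounds the scale, so out-of-range values are data
  errors.
* Zero-variance rating vectors: the participant keeps contributing to
  group means but receives no typicality index and is excluded from
  similarity matrices (with a warning, and `n_used` recorded).
* A perfect correlation (|r| = 1) in an effect computation is an error,
  not an infinite Fisher z.
* Exactly zero residual variance in a mixed model (outcome explained
  exactly) is an error; downstream pooling refuses non-converged fits.
* Permutation p-values use the add-one convention, so the smallest
  attainable p is $1/(n_{perm}+1)$ and `n_perm < 100` is rejected.

# Reproducibility

Every stochastic stage takes a seed; per-study and per-stage seeds are
derived deterministically from one master seed (kept below $2^{31}$).
Identical configuration and master seed produce byte-identical effects
tables and pooled-results JSON, which the test suite asserts literally.
No multiple-testing adjustment is applied anywhere: each pooled analysis
is reported with its own p-value, and this is stated rather than
corrected.

# Known limitations

* No random slopes, crossed covariance structures, or non-Gaussian
  outcomes in the mixed model; no Satterthwaite/Kenward-Roger df.
* No meta-regression (study-level moderators) or publication-bias
  diagnostics -- with seven internal studies these are out of scope.
* The accuracy model's orientation makes its interaction sensitive to
  any mechanism that rescales rating spread (see the generator notes);
  interpret it jointly with the confidence analysis.
* Scale-use differences and genuine confidence are not separable from
  rating SD alone.
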
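---
title: "Estimating the positivity offset and negativity bias from trial-level ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the positivity offset and negativity bias from trial-level ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The Evaluative Space Model treats positivity and negativity as partially
separable systems whose activation varies with arousal. `evalspace`
estimates each system's *activation function* — a linear regression of the
rating on rated arousal $a$ (kept on its raw 0–8 coding, so intercepts are
interpretable at "no arousal") — inside one linear mixed model:

$$y_{ij} = \beta_0 + \beta_1\,\text{fn}_{ij} + \beta_2\,a_{ij}
         + \beta_3\,\text{fn}_{ij} a_{ij}
         + u_{1i}\,\text{fn}_{ij} + u_{2i}\,\text{fn}_{ij} a_{ij}
         + s_j + \varepsilon_{ij},$$

where $y$ is *emotional activation* (positivity ratings on pleasant and
half the neutral stimuli; negativity ratings on unpleasant and the other
half), $\text{fn}$ is the activation-function indicator (negativity is the
reference level), $s_j$ is a by-stimulus random intercept, and
$u_{1i}, u_{2i}$ are by-subject random slopes. With this coding,
$\beta_1$ *is* the positivity offset ($p_0 - n_0$) and $-\beta_3$ *is* the
negativity bias ($n_1 - p_1$); `offset_bias_estimates()` also reports the
identities explicitly (they hold to numerical precision within any fit).
The between-subject SDs of offset and bias are the SDs of $u_1$ and
$u_2$.

Two modelling choices deserve comment.

*No by-subject random intercept.* Subject-level variation in this design is
variation in the *function contrast*: a subject with a large offset has
elevated positivity-side responses relative to their negativity side. A
separate subject intercept would model variation shared by both sides,
which the stacked outcome does not identify separately once the function
slopes are present; the declared structure follows the estimation model
this package targets.

*Unstructured covariance for the two function slopes.* $u_1$ and $u_2$
describe one latent object — the subject's positivity function (its level
and its arousal response) — and are correlated whenever anything (e.g.
symptom severity) moves offset and bias together. Forcing them independent
pushes their covariance into the wrong components: in simulation the
offset-slope SD collapses (0.5–0.6 instead of 0.92) and the offset CI
undercovers (≈0.83 instead of ≈0.95). The category-difference models keep
independent (diagonal) by-subject terms, where the slope set is larger and
correlation parameters are weakly identified on discretized outcomes; both
choices can be overridden through `random_structure()`.

The companion analyses use the same machinery: category-difference models
for positivity, negativity, arousal, and the per-stimulus ambivalence
index $A = (P+N)/2 - |P-N|$ (total affect minus polarity; range $-4$ to
$8$ on 0–8 scales), each with by-subject intercept + category slopes and a
by-stimulus intercept. Symptom moderators are unit-rescaled (divided by
the scale maximum), sample-centered, and enter one at a time with full
interactions; age, a male-gender indicator, years of education, and the
other two symptom areas are centered main-effect covariates, so level-1
coefficients stay interpretable at covariate means. Conditional (simple)
effects within factor levels are computed when the omnibus interaction
reaches trend level ($p < 0.10$), mirroring two-step reporting practice;
`force = TRUE` bypasses the gate. Bonferroni correction is applied within
the family of the four moderator interaction tests per response variable
(the family definition is configurable via `bonferroni_adjust()`).

Estimation is REML through `lme4`, with Satterthwaite degrees of freedom,
type-III F tests and single-contrast inference through `lmerTest`.
Standardized effects are $\beta = b \cdot SD(x)/SD(y)$ with
observation-level SDs on the analysis dataset — one documented choice
among several possible standardization bases. Cohen's d for comparing
rating moments against published norms uses the unweighted
root-mean-square of the two SDs (an n-weighted option exists), because
norm-study sample sizes are often unavailable.

## What the generator emulates

`esm_sim_params()` defines the synthetic world; its defaults are the
conditions of the motivating study design:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 261 | community-sample size |
| stimuli | 16/16/16 | pleasant/neutral/unpleasant, half social each |
| `arousal_mean`, `arousal_sd` | 3.80/2.40, 2.87/1.93, 5.02/2.40 | category arousal moments on 0–8; the unpleasant mean is set so the unpleasant−pleasant contrast is 1.22 |
| `pos_intercept`, `pos_slope` | 5.29, 0.01 | positivity activation function |
| `neg_intercept`, `neg_slope` | 2.89, 0.42 | negativity activation function |
| `offset_sd`, `bias_sd` | 0.92, 0.17 | between-subject SDs of offset ($2.40$) and bias ($0.41$) |
| `offset_mod`, `bias_mod` | −0.8, −0.15 | change per +1 SD latent severity |
| `symptom_loading` | $\sqrt{0.75}$ | loading of each scale on one severity factor → pairwise CAPE correlations ≈ 0.75 |
| `stimulus_sd` | 0.85 | by-stimulus intercept SD; reproduces the precision of the offset and the intercepts at full study size, where standard errors are stimulus-dominated |
| `residual_sd` | 1.6 | trial noise; puts the activation outcome's SD near 2.4, the value implied by the ratio of raw to standardized arousal-slope effects |

Symptom scores come from a one-factor latent Gaussian (scale mean + SD ×
(loading × severity + unique part)), discretized to each instrument's
granularity (CAPE item-mean steps by scale item counts 14/8/20; integer
CAS sums) and clipped to the valid range. Moderation acts through the
*latent severity factor*, not through each observed scale separately:
fitting four separate moderator models to scales that are themselves
generated from one factor is exactly the situation the analysis faces,
and per-scale moderation coefficients of four strongly correlated scales
would not be simultaneously identifiable as generating quantities. The
implied per-observed-moderator effect is `offset_mod × symptom_loading`
(≈ −0.69 per moderator SD at defaults), in the range of the moderated
offsets the design targets.

Subject heterogeneity is placed on offset and bias directly and carried by
the positivity function (subject-specific $p_{0i}, p_{1i}$; common
negativity function). This is the exact generative inverse of the analysis
model above — the model's only by-subject terms are the function contrast
and its arousal interaction, so a generator that also spread variation
onto the negativity side would put variance where the model has no term
for it. It is one defensible allocation among several; the reported
between-subject SDs constrain only the offset/bias differences.

Ratings are produced by evaluating the subject's activation functions at
the *discretized* arousal rating (so the analysed regressor is exactly the
generative one — no errors-in-variables attenuation), adding the stimulus
deviation, category shifts, and Gaussian noise, then rounding to integers
and clipping to $[0, 8]$. Category shifts suppress positivity toward
unpleasant scenes (−3.5) and negativity toward pleasant scenes (−2.0)
but leave the categories entering each activation function unshifted, so
the activation structure remains exactly the analysed one. A consequence
worth knowing: with a near-zero positivity slope, mean positivity for
pleasant and neutral scenes is nearly identical in this world — a
strictly decreasing positivity gradient across categories cannot coexist
with the fitted activation structure.

**What the generator does not emulate:** endpoint piling beyond what
rounding/clipping produces, individual differences in scale use,
category-specific residual variance, stimulus content effects
(everything about a stimulus is one intercept), temporal or order
effects, and any non-linearity of the true activation functions. Passing
recovery tests therefore show that the *estimator* is sound for the
declared data-generating process, not that real rating data satisfy it.

## Discretization distortion — quantified, not hidden

With `discretize = FALSE` (continuous, unclipped ratings) the pipeline
recovers every activation parameter within simulation error; this
generative/estimation consistency is asserted by the test suite (30
replicates at 60 subjects × 24 stimuli: offset and intercept biases below
0.1, slope biases below 0.02–0.03, offset coverage ≈ 0.95).

With the study's 0–8 integer scale, clipping at the ends is material at
realistic dispersion: positivity (latent level 5.29, subject SD 0.92,
stimulus SD 0.85, noise 1.6) loses upper tail mass, depressing its
intercept; negativity approaches the ceiling at high arousal (latent
6.25 at arousal 8), which bends the fitted line and raises its intercept.
Both compress the estimated offset — by about −0.12 on average across 100
replicates at 60 × 24 in the acceptance suite, with the bias parameter
and CI coverage unaffected. `parameter_recovery()` reports bias, RMSE and
coverage per parameter so this distortion is visible in any
configuration; shrinking the noise components would shrink it, but at the
cost of contradicting the dispersion the defaults are calibrated to.

## Numerical and procedural choices

* Optimizer: `bobyqa` with a 10^5 evaluation budget; singular fits are
  reported (boundary SDs as 0), not suppressed. If a fit fails to
  converge, an unstructured covariance is first reduced to diagonal, then
  by-subject slopes are dropped smallest-variance-first; every step is
  logged in `$simplifications` and surfaced in the fit object.
* Neutral split: simple seeded per-participant partition; with an odd
  neutral count the positivity side receives the larger half. The split is
  not stratified by sociality (an optional refinement that the estimand
  does not require); split-to-split variation of the offset is
  Monte-Carlo noise, asserted small in the tests.
* The anhedonia moderator controls for the CAPE positive and depression
  areas (the CAPE negative scale overlaps conceptually with anhedonia);
  each CAPE moderator controls for the other two CAPE areas.
* Gender enters as a male indicator (the sampling frame recorded no
  third-category responses); the coding is centered like all covariates.
* Satterthwaite df fall back to the residual rule $n - p$ (with a
  warning) if the gradient computation fails.
* Validation is strict and non-imputing: ratings must be integers in
  $[0, 8]$ (the continuous generator option is exempted), questionnaire
  items must be complete and in range, duplicate participant × stimulus
  pairs are errors naming the row.
* Test-suite problem sizes: most properties run at 24 participants × 12
  stimuli; recovery and calibration checks use 100–150 replicates at
  48–60 participants × 24 stimuli — small enough to iterate on, large
  enough that generating values are recovered well inside the asserted
  tolerances.

## Known limitations

* The activation functions are linear by construction; curvature in real
  arousal–affect coupling is absorbed into slopes and residuals.
* Benchmark comparison against the original deposited dataset requires a
  download and is therefore not part of the test suite; the pipeline
  accepts any trial/participant tables with the documented schema.
* The standardization basis for β and the Bonferroni family definition are
  documented conventions, not uniquely determined by the estimand; both
  are configurable.
* Reported degrees of freedom depend on the random structure; under the
  unstructured activation-design default they can differ noticeably from
  software that fits other covariance structures.
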
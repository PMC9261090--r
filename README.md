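# evalspace

Analysis of trial-level emotional ratings under the Evaluative Space Model
(ESM), for researchers studying hedonic responding along the psychosis
continuum (and affective science more broadly). Participants rate
emotionally evocative pictures — pleasant, neutral, unpleasant — on three
0–8 scales (positivity, negativity, arousal); symptom questionnaires (the
three CAPE scales, the Chapman anhedonia scales) are scored at the
participant level. The package turns such data into the ESM's summary
quantities and their symptom moderation, and ships a synthetic-data
generator so the whole pipeline is testable without any real dataset.

## The model

The ESM posits two partially separable response systems whose activation
varies with arousal. Each is modelled as a linear *activation function* of
the rated arousal $a$:

$$\text{positivity} = p_0 + p_1 a, \qquad \text{negativity} = n_0 + n_1 a .$$

Two derived quantities carry the theory:

* **positivity offset** $= p_0 - n_0$: the surplus of positive over
  negative activation in low-arousing contexts ($a = 0$);
* **negativity bias** $= n_1 - p_1$: the steeper rise of negativity with
  arousal.

Both are estimated in a single linear mixed model on a stacked outcome
*emotional activation*: positivity ratings of pleasant + half the neutral
stimuli, negativity ratings of unpleasant + the other half (the neutral set
is split randomly per participant so no stimulus enters twice and a
crossed by-stimulus random intercept stays meaningful). Fixed effects are
the activation-function factor, arousal (raw 0–8 coding), and their
interaction; by-subject random slopes for the function contrast and its
arousal interaction give the between-subject SDs of offset and bias.
Symptom scales (unit-rescaled, sample-centered) enter one at a time as
level-2 moderators with full interactions, age/gender/education and the
other symptom areas as covariates; the offset and bias are then reported
at −1 SD / mean / +1 SD of the moderator.

The package also provides the per-stimulus **ambivalence** index
$A = (P + N)/2 - |P - N|$ (total affect minus polarity, range −4 to 8 on
0–8 scales), category-difference models for the raw responses, careless-
responding screens (long-string rule, task-completion eligibility), and a
parameter-recovery harness for the estimator.

## Worked example

```r
library(evalspace)

params <- esm_sim_params(n_participants = 80, n_pleasant = 8, n_neutral = 8,
                         n_unpleasant = 8)
study <- simulate_esm_study(params, seed = 42)
res <- run_offset_bias_analysis(study$trials, study$participants,
                                moderators = c("cape_negative", "cas_anhedonia"),
                                seed = 42)
res
#> <esm_estimates>
#>   positivity offset 2.15 (subject SD 0.57), 95% CI [1.82, 2.49], t(267.9) = 12.76
#>   negativity bias   0.37 (subject SD 0.07), 95% CI [0.30, 0.44], t(225.9) = 10.48
#>   offset/bias by symptom level:
#>       moderator level offset  bias
#> 1 cape_negative -1 SD   2.57 0.454
#> 2 cape_negative  Mean   2.15 0.376
#> 3 cape_negative +1 SD   1.73 0.297
#> 4 cas_anhedonia -1 SD   2.53 0.443
#> 5 cas_anhedonia  Mean   2.15 0.376
#> 6 cas_anhedonia +1 SD   1.77 0.310
```

The generating world here has a positivity offset of 2.40 (between-subject
SD 0.92), a negativity bias of 0.41 (SD 0.17), and symptom moderation that
diminishes both at higher severity. The fitted offset (2.15) and bias
(0.37) sit below their generating values because the 0–8 integer scale
clips the tails of the latent responses — a distortion the recovery
harness (`parameter_recovery()`) quantifies, and which disappears with the
continuous-scale generator option (`discretize = FALSE`). The moderated
grid shows the offset falling from −1 SD to +1 SD of each (normalized)
symptom score, the pattern of a diminished positivity offset at higher
symptom load.

The ambivalence index behaves as the worked rating pairs suggest —
a strong polarized response scores negative, strong co-activation scores
high:

```r
ambivalence(c(8, 5, 6), c(2, 5, 0))
#> [1] -1  5 -3
```

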
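# infrachoice

Do wandering albatrosses head toward regions of loud microbarom infrasound
when they set off on a bout of sustained flight? `infrachoice` implements the
full analysis pipeline needed to ask that question of GPS tracking data — and
a synthetic-data generator with known selection coefficients so every stage
can be validated without any external data. It is aimed at movement
ecologists working on step-selection / discrete-choice habitat analysis and
at anyone studying environmental sensory cues (infrasound, wind) in
wide-ranging seabirds.

## The analysis

1. **Behavioural segmentation.** A three-state hidden Markov model on step
   length (gamma) and turning angle (von Mises) labels each 15-min GPS fix
   as directed *travel*, *search* or *rest* (forward algorithm, direct
   likelihood maximisation, Viterbi decoding).
2. **Decision points.** Trips start at the first departure ≥ 10 km from the
   colony and end at the first fix after return; fixes within 10 km of the
   shelf at trip ends are trimmed. Each travel bout ≥ 20 km that follows
   search/rest yields a *decision point*: its first fix, with the bird's
   bearing there.
3. **Choice sets.** The 2,000 km disc around the bird is tiled into six 60°
   sectors, the *focal* sector centred on the bearing (±30°). Microbarom
   sound pressure (Pa) is integrated over each sector on a spherical polar
   grid from a modelled source field (geometric spreading + dB/1,000 km
   absorption) and z-standardised within the choice set; relative wind
   direction (0° = tailwind, 180° = headwind) is computed per sector and
   wind speed at the bird.
4. **Conditional-logit fit.** With one chosen sector per decision point
   (stratum *s*), the matched conditional-logit likelihood is

   log L(β) = Σₛ [ x_chosen·β − log Σⱼ₌₁⁶ exp(xⱼ·β) ],

   i.e. a softmax over each choice set that cancels all stratum-level
   effects. Scores are clustered on bird identity for a sandwich
   (robust) covariance; competing models (`windDir * windSp` vs
   `SP * windDir + SP:windSp + windDir:windSp`) are ranked by
   QIC = −2 log L + 2 tr(Î V̂ᵣ) and its Akaike-type weights QICω, with
   likelihood-ratio tests against the null (−n log 6) and a concordance
   index over the 5 within-stratum pairs per decision point.

## Worked example

Simulate 60 birds × 30 decision points from the known coefficient vector
β = (SP 0.3, windDir −0.4, SP:windDir −0.2, SP:windSp 0.15,
windDir:windSp −0.25) and fit the two competing models:

```r
library(infrachoice)
rows     <- simulate_choice_data(n_birds = 60, dp_per_bird = 30, seed = 1)
fit_full <- choice_fit(rows, "wind_sp")
fit_wind <- choice_fit(rows, "wind")
summary(fit_full)
qic_table(list(wind_sp = fit_full, wind = fit_wind))
```

```
Matched conditional-logit choice model
strata: 1800  clusters: 60  logLik: -2947.743 (null -3225.167)
QIC: 5906.24  LRT X2(5) = 554.85 (p = 1.15e-117)  C-index: 0.649
                  coef se_naive se_robust        z p_value odds_ratio or_lo95 or_hi95
SP              0.2783   0.0264    0.0298   9.3472   0e+00     1.3209  1.2460  1.4002
windDir        -0.3694   0.0262    0.0315 -11.7166   0e+00     0.6912  0.6498  0.7352
SP:windDir     -0.1697   0.0299    0.0266  -6.3880   0e+00     0.8439  0.8011  0.8890
SP:windSp       0.1021   0.0269    0.0260   3.9339   1e-04     1.1075  1.0526  1.1654
windDir:windSp -0.2657   0.0284    0.0291  -9.1275   0e+00     0.7667  0.7242  0.8117

    model                                              variables K      QIC         QICw       X2         C
1 wind_sp SP + windDir + SP:windDir + SP:windSp + windDir:windSp 5 5906.240 1.000000e+00 554.8476 0.6494444
2    wind                               windDir + windDir:windSp 2 6118.876 6.709257e-47 336.1467 0.6244444
```

Every estimate sits within two robust standard errors of its generating
value; the positive `SP` odds ratio (1.32 per within-choice-set standard
deviation of sector sound pressure) is the "birds prefer loud sectors"
effect, `windDir < 1` the tailwind preference, and the model containing
sound pressure takes essentially all the QIC weight. `run_pipeline()` runs
the same analysis end-to-end from simulated GPS tracks (HMM segmentation →
decision points → sector covariates → sex-stratified fits), writing CSV
outputs and a manifest.

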
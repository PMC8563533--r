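# sdqmix

Latent score profiles from multi-informant Strengths and Difficulties
Questionnaire (SDQ) data, and classification-error-corrected profile
prevalences across groups.

`sdqmix` is for researchers and methodologists working with screening
questionnaires rated by several informants (here: adolescent self-report and
parent report). Instead of interpreting subscales one at a time or collapsing
them into a total score, it implements a three-step profile analysis:

1. **Identify profiles.** A two-level finite mixture — informant records at
   level 1 nested in subjects at level 2 — treats the five SDQ subscale
   scores (integers 0–10) of both informants as ordinal indicators of a
   subject-level latent profile. The response model per (profile, informant,
   scale) is an adjacent-category logit,
   `P(X = k | c) ∝ exp(α_jsk + β_cjs·k)`, estimated by multi-start EM;
   the number of profiles is selected by BIC
   (`BIC = −2ℓ + p·log n_subjects`). Missing informant records are handled
   by MAR marginalization.
2. **Score subjects.** Posterior profile-membership probabilities follow by
   Bayes' rule, for the estimation sample and for new cases with any subset
   of observed scores (`score_cases()`, with models shipped as JSON).
3. **Relate profiles to groups.** Modal assignments carry a known
   classification error `D[c,w] = P(assigned w | true c)`; per group
   (care setting, diagnosis category, gender cell) the profile distribution
   θ is re-estimated by maximizing `Σ_i log Σ_c θ_c D[c, w_i]`, which undoes
   the attenuation bias of naive assignment counting. Reporting follows the
   conventional rules: per-gender breakdowns only for gaps ≥ 20 percentage
   points, small diagnosis groups suppressed.

Profiles are interpreted against normal/borderline/abnormal cutoff bands of
their expected subscale scores and labelled automatically from the band
pattern ("no difficulties", "borderline hyperactivity difficulties", ...),
with paired self/parent t tests per profile. Because the underlying clinical
datasets of this kind are not public, the package includes a first-class
synthetic-data generator (`sim_preset()`, `sim_generate()`, `truth_report()`)
with known ground truth, which the tests and the acceptance script use to
validate the whole pipeline.

## Worked example

The scripts under `analysis/` run the whole workflow on a synthetic sample
of 2000 adolescents with three true profiles — a "no difficulties" class, a
parent-reported externalizing class invisible in self-report, and a
pervasive-difficulties class:

```sh
Rscript analysis/01_simulate.R      # generate sample + ground truth
Rscript analysis/02_select_model.R  # fit K = 1..5, select by BIC
Rscript analysis/03_profiles.R      # bands, labels, informant tests
Rscript analysis/04_threestep.R     # corrected prevalence by group
Rscript analysis/05_comparisons.R   # total-score bands; self-only refit
```

Model selection recovers the three-profile structure:

```
<sdqmix_selection> best K = 3 by BIC
 K    loglik n_free_params      bic converged error
 1 -38387.35           100 77534.79      TRUE  <NA>
 2 -34963.42           111 70770.53      TRUE  <NA>
 3 -34165.06           122 69257.43      TRUE  <NA>
 4 -34153.94           133 69318.81      TRUE  <NA>
 5 -34143.32           144 69381.18      TRUE  <NA>

Selected K = 3; entropy R2 = 0.869
```

The profiles get their labels from the cutoff bands of their mean scores,
ordered by expected total difficulties:

```
  1. 'no difficulties'                             pi = 0.490
  2. 'conduct and hyperactivity difficulties'      pi = 0.319
  3. 'overall difficulties'                        pi = 0.191
```

and the corrected prevalences separate the settings sharply — 76% of
community adolescents sit in the "no difficulties" profile against 18% in
mental healthcare (CAMH), with per-gender columns appearing only where the
gap reaches 20 points:

```
     group    n no difficulties conduct and hyperactivity difficulties overall difficulties
      CAMH  742              18                                     43                   39
      CASC  200              22                                     52                   27
 community 1058              76                                     20                    4
```

Against the known simulation truth, the correction reduces the
total-variation error of the naive modal proportions by roughly an order of
magnitude (e.g. CAMH: 0.076 → 0.003). The final script shows the
multi-informant point directly: refit on self-report alone, the
parent-reported externalizing profile merges into "no difficulties"
(`full profiles {1, 2} map to one single-informant profile`).

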
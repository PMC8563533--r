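---
title: "Multilevel mixture modelling of multi-informant SDQ profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel mixture modelling of multi-informant SDQ profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdqmix)
```

# The problem

Screening instruments such as the Strengths and Difficulties Questionnaire
(SDQ) are usually interpreted one scale and one informant at a time, or
collapsed into a single total-difficulties score. Both habits discard
information: an adolescent with problems in one domain only may look
unremarkable on the total score, and self- and parent reports frequently
disagree in informative ways. `sdqmix` implements a profile-based
alternative: treat the five subscale scores from both informants as joint
indicators of a small number of latent *score profiles*, estimate those
profiles from data, and then relate profile membership to external variables
(care setting, diagnosis category, gender) while correcting for the error
that profile assignment necessarily carries.

# The measurement model

The data are two-level: informant records (adolescent self-report, parent
report) are nested in subjects. Each record carries five ordinal subscale
scores, each an integer $0,\dots,10$. Subjects belong to one of $K$ latent
profiles with mixing proportions $\pi_1,\dots,\pi_K$; given the profile,
all observed scores are conditionally independent with

$$P(X_{js} = k \mid c) \;\propto\; \exp\{\alpha_{jsk} + \beta_{cjs}\, k\},
\qquad k = 0,\dots,m-1,$$

for informant $j$ and scale $s$: an adjacent-category (linear-by-linear)
logit with equidistant category scores. The category intercepts
$\alpha_{js\cdot}$ (with $\alpha_{js0}=0$) are shared across profiles and
shape the common marginal form of each scale; the single location parameter
$\beta_{cjs}$ shifts profile $c$ up or down that scale for that informant.
This is the standard parsimonious way latent-class software treats ordinal
indicators: it respects the ordering of scores, uses one parameter per
(profile, informant, scale), and still lets every scale have an arbitrary
baseline shape. A saturated per-category multinomial parameterization is
available behind `parameterization = "multinomial"` for users who want to
check sensitivity to this choice.

**Identification.** Adding $d\cdot k$ to $\alpha_{js\cdot}$ while
subtracting $d$ from every $\beta_{\cdot js}$ leaves all probabilities
unchanged, so one linear direction per (informant, scale) block is
unidentified. Fitted parameters are reported in the gauge where each
$\alpha_{js\cdot}$ is orthogonal to the centred category scores; the free
parameter count, $(K-1) + JS(m-2+K)$, removes this degeneracy. With $K=1$
the block is saturated and the one-class fit reproduces observed category
frequencies exactly — a useful self-check that the tests exercise.

**Missing data.** Whole informant records (and individual scores) may be
absent. They simply contribute no factors to the likelihood, which is the
maximum-likelihood treatment under missingness at random at the informant
level. A subject with no observed records contributes a constant and ends up
at the prior.

# Estimation and model selection

`em_fit()` maximizes the observed-data likelihood by EM. The E-step is
Bayes' rule per subject. The M-step updates $\pi$ in closed form and the
$(\alpha, \beta)$ blocks by coordinate Newton steps with step-halving:
each accepted step cannot decrease the expected complete-data
log-likelihood, so the observed log-likelihood is non-decreasing at every
iteration (a generalized EM). This property is asserted on every seeded
trajectory in the test suite rather than assumed.

Mixtures have local maxima, so estimation is multi-start: `n_starts`
random initializations (Dirichlet(1) mixing, standard normal locations,
zero intercepts) each run for a short burn-in (30 iterations), after which
the best few are continued to convergence (relative log-likelihood change
below `tol = 1e-8`, at most 500 iterations) and the best final
log-likelihood wins, with ties broken by start index. Everything is
deterministic given the seed. Category probabilities are computed on the
log scale throughout, so likelihoods cannot underflow to $-\infty$; a
$10^{-10}$ floor additionally guards the saturated multinomial M-step.

The number of profiles is chosen by BIC,
$-2\ell + p\,\log n$, computed over a candidate range (1–8 by default) with
$n$ the number of *subjects* — the level at which the classes live. The
selection table records log-likelihood, parameter counts and BIC per
candidate so alternative sample-size conventions can be audited. Ties and
failed candidates resolve to the smallest K and are recorded in the table.

For deterministic reporting, profiles are ordered by ascending expected
total difficulties (sum of the four difficulties-subscale means, averaged
over informants), so "profile 1" is always the least severe.

# Scoring, profiling and the three-step correction

`posterior()` / `score_cases()` score any case — any subset of observed
informants and scales — by Bayes' rule under a fitted (or saved) model;
with nothing observed the prior is returned. Fitted models serialize to a
versioned JSON file at full precision, so shipped models reproduce in-sample
posteriors bit-exactly.

Profiles are interpreted by classifying their *expected* subscale scores
(per informant) into normal / borderline / abnormal bands from a cutoff
configuration, and labels are derived mechanically from the band pattern: a
domain counts as affected when *either* informant's profile mean leaves the
normal band — deliberately, because profiles that only one informant can see
are precisely the ones a multi-informant analysis exists to find. Boundary
convention: a score exactly on a boundary falls in the band on its lower
side; strengths scales (prosocial) run reversed. The shipped cutoff file is
illustrative only; it is config, not code, and substantive use requires
normed values.

Relating profiles to external groups uses the three-step approach with
modal assignment and maximum-likelihood correction. Modal assignment
misclassifies at a rate captured by
$D_{cw} = P(\text{assigned } w \mid \text{true } c)$, estimated by the
posterior-weighted cross-classification on the full estimation sample and
held fixed across groups. Within each group the profile distribution
$\theta_g$ maximizes $\sum_{i \in g} \log \sum_c \theta_{gc} D_{c w_i}$
over the simplex, again by a small EM; with $D = I$ this reduces *exactly*
to counting modal assignments, and for $K=2$ the tests check the maximizer
against a grid-search oracle. Among the three-step flavours (modal vs
proportional assignment, with or without correction) this ML-modal variant
is the standard recommendation and the one whose bias-reduction claim the
simulations here verify directly. Gender interactions repeat the estimate
within group × gender cells; reporting follows two rules — per-gender
columns appear only when the male/female gap is at least 20 percentage
points, and diagnosis groups with fewer than 100 subjects are suppressed —
both configurable.

`entropy_r2()` summarizes assignment quality as one minus the normalized
mean posterior entropy; it is the dial that decides how much the correction
matters (at values near 1, corrected and naive estimates coincide).

# The synthetic-data generator

The package ships a generator rather than data. It emulates exactly the
structure the model assumes: subject-level classes, class- and
informant-specific ordinal response distributions, whole-record
missingness, and class-conditional group composition
(class → setting/gender cells, with diagnosis label sets drawn inside the
clinical setting). Group covariates are generated *conditional on class* so
that the implied $P(\text{class} \mid \text{group})$ — reported by
`truth_report()` both as realized in the sample and analytically by Bayes
inversion — is a known recovery target for the three-step stage. The design
distributions factor as setting × gender (independent within class); the
class-conditional association between setting and gender that a joint table
could encode is not needed for any of the checks here.

Missingness is whole-informant-record and completely at random by default —
the simplest mechanism consistent with informant-level MAR. Default rates
(6% self, 15% parent) echo the record availability seen in screening
samples, where parent reports are the scarcer. A `missing_model` hook
accepts covariate-dependent (still MAR) probabilities for robustness
experiments.

Three presets share one qualitative design — a low-difficulties class
(50%), an externalizing class (30%), a pervasive-difficulties class with
weak prosocial behaviour (20%) — at three separations:

* `well_separated` (location spread ±0.5, entropy R² ≈ 0.93): parameter
  recovery and selection checks;
* `moderate` (spread scaled by 0.53, calibrated once so the true-model
  entropy R² is ≈ 0.70): the regime where naive modal proportions are
  visibly biased and the correction earns its keep;
* `near_deterministic` (spread doubled, complete records): assignment error
  essentially zero — complete records matter here because a subject with a
  missing informant record retains posterior uncertainty no matter how
  separated the classes are.

No claim is made that any preset matches the population behind any
particular screening study; the published analyses' non-public samples
cannot be reproduced at desk scale, which is why all acceptance checking is
property-based (recovery, selection consistency, correction benefit,
robustness) rather than number-matching.

**What passing these simulations does and does not show.** The generator
draws from the fitted model's own family, with conditional independence
given class, unimodal ordinal responses and MCAR records. Real
questionnaire data violate all three to some degree (local dependence
between scales, informant-specific response styles, structured
missingness). Green simulations therefore certify the *machinery* —
likelihood, EM, selection, correction — not the substantive adequacy of the
model for any given dataset.

# Numerical and design choices, in brief

* Convergence: relative log-likelihood tolerance $10^{-8}$, max 500
  iterations, 20 random starts by default (burn-in 30, top 3 continued).
* Ties: modal assignment and BIC selection break ties to the lowest index /
  smallest K; class order is fixed by expected severity.
* Paired informant tests per profile use the closed-form paired t statistic
  with a Bonferroni multiplier equal to the number of scales actually tested
  in that cluster, at $\alpha = 0.01$; zero-variance differences return
  $t = 0, p = 1$ (all equal) rather than an error. Cells with fewer than two
  complete pairs are skipped and flagged.
* The total-difficulties crosstab merges the borderline and abnormal bands,
  mirroring how such tables are conventionally presented, and bands
  *individual* totals (requiring all four difficulties scores from the
  chosen informant), while profile labels band *class means* — the two
  deliberately operate at different levels.
* Bootstrap standard errors for corrected prevalences are optional
  (`boot > 0`, seeded, resampling subjects within group); point estimates
  never depend on them.
* Problem sizes in the tests and acceptance script (n = 2000 for recovery
  and robustness, n = 1000 × 10 replicates for selection consistency,
  n = 2000 × 10 for the correction benefit) were chosen as the smallest
  sizes at which the binomial/simulation noise is comfortably below the
  tolerances being asserted.

# Known limitations

* Covariates cannot enter the measurement model (no measurement
  non-invariance by group); the three-step stage is the only place external
  variables appear.
* The step-3 estimator here is the marginal ML correction per group; a
  multinomial-logistic step-3 regression with continuous covariates is out
  of scope.
* At most two-level hierarchies (records in subjects) are supported.
* Equivalence with estimates from commercial latent-class software is not
  claimed: the exact ordinal link and intercept-sharing conventions used
  there are not public, and the adjacent-category choice here is a design
  decision, not a reverse-engineering.
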
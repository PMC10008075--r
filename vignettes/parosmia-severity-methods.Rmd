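---
title: "Scoring parosmia severity from odor-descriptor classifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring parosmia severity from odor-descriptor classifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parosmia — the qualitative distortion of odor and flavor perception — has
long been recorded in the clinic as simply present or absent, which makes it
impossible to track its course or evaluate treatment. `parosim` implements a
survey-based severity measure: patients classify a fixed list of named odors
(e.g. *coffee*, *fish*, *rose*) as smelling **normal**, **qualitatively
different** (QD), **odorless** (OL), or **unknown**, and a per-patient score
in $[0, 1]$ is derived from those classifications alone, with no odor
exposure required. Unknown responses are treated as missing throughout.

Each descriptor also carries six semantic variables from lexical resources:
the corpus-derived Olfactory Association Index (OAI) and Olfactory
Specificity Index (OSI), affective valence and arousal norms (1–9 Likert),
and olfactory/gustatory modality ratings (0–5 Likert). The package relates
the descriptor-level response pattern to these variables, and uses them —
together with the response percentages — to weight the severity score.

## The severity index

Let $qd_d$ and $ol_d$ be the percentage of participants classifying
descriptor $d$ as QD or OL (computed over observed, i.e. non-unknown,
responses). A PCA is run on the descriptor matrix of the six semantic
variables plus $qd$ and $ol$ (eight columns, z-standardized; missing
semantic cells are mean-imputed for this step only). With descriptor scores
$s_{p,d}$ on component $p$ and variance fractions $v_p$ (computed over all
components), the first $P$ components (default $P = 3$) are retained and

$$\mathrm{OLs}_{p,d} = s_{p,d}\,\rho_{s_p,\,ol}, \qquad
  \mathrm{QDs}_{p,d} = s_{p,d}\,\rho_{s_p,\,qd},$$

where $\rho$ are Pearson correlations of the score columns with the
percentage vectors. Each weighted-score column is min–max normalized across
descriptors within its component, inverted, scaled by $v_p$, and summed:

$$\mathrm{OLw}_d = \sum_{p=1}^{P}
  \left(1 - \frac{\mathrm{OLs}_{p,d} - \min_d \mathrm{OLs}_{p,d}}
  {\max_d \mathrm{OLs}_{p,d} - \min_d \mathrm{OLs}_{p,d}}\right) v_p,$$

and analogously for $\mathrm{QDw}_d$. A descriptor that is *least*
associated with affectedness therefore gets the *largest* weight: reporting
it affected signals severe disease, on the reasoning that rarely-affected
odors are the last to go. The per-participant score over the set $D_i$ of
descriptors participant $i$ classified is

$$ps_i = \frac{\sum_{d \in D_i} \mathrm{OL}_{i,d}\,\mathrm{OLw}_d +
  \mathrm{QD}_{i,d}\,\mathrm{QDw}_d}
  {\sum_{d \in D_i} \max\{\mathrm{OLw}_d, \mathrm{QDw}_d\}} \in [0, 1].$$

Design choices where the defining equations are ambiguous:

* **Summation index.** The weight equations sum over components (the
  normalized score varies with $p$ and is weighted by $v_p$); the sum is
  taken over $p = 1 \dots P$.
* **Min–max scope.** Normalization is per component by default, so every
  retained component contributes on a common $[0, 1]$ scale before variance
  weighting; a single global min/max over all retained components is
  available via `compute_weights(..., normalization = "global")`.
* **Numerator.** The OL and QD products are added; since a cell is never
  both OL and QD, each classified descriptor contributes at most one term.
* **Variance fractions** are fractions of the *total* variance (all eight
  components), not renormalized over the retained ones.
* **Degenerate components.** If a component's weighted scores are constant,
  min–max normalization is undefined; that component contributes a neutral
  $0.5\,v_p$ to every descriptor and a message is emitted.
* **Sign indeterminacy.** PCA scores are defined up to column sign; the
  weights are invariant because $\rho$ flips with the scores. This is
  asserted to $10^{-12}$ in the test suite, together with the $[0,1]$
  bounds, monotonicity under normal→affected flips, and invariance of
  $ps$ under rescaling of all weights.

Participants who classified nothing, or whose classified descriptors all
have zero weight, get a missing score with a warning rather than an error.

## Descriptor statistics and association models

* `descriptor_percentages()` computes $qd_d$, $ol_d$ with Wald
  (normal-approximation) binomial CIs, clipped to $[0, 100]$; a degenerate
  $\hat p \in \{0, 1\}$ yields a zero-width interval at the boundary, a
  choice made here (the approximation is simply reported, not replaced by an
  exact interval).
* `pearson_with_p()` uses pairwise-complete pairs and the exact $t$
  reference $t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df, two-sided. Descriptor
  rows missing a semantic rating are dropped per variable (pairwise
  deletion), so each correlation row carries its own $n$.
* `fit_glmm()` fits a logistic mixed model per outcome indicator (QD vs
  rest; OL vs rest) with a random participant intercept, via `lme4::glmer`
  (Laplace approximation, `bobyqa` optimizer). Wald $z$ and normal-tail
  $p$ values are reported per term, matching the conventional presentation
  of such model tables; likelihood-ratio tests are not used. Non-convergence
  is flagged on the result, never thrown.
* `semantic_model_suite()` fits, per outcome, one baseline model with the
  ten participant predictors and one model per semantic variable (added
  individually to avoid the collinearity among semantic variables), 14 fits
  in all. No multiple-testing correction is applied by default, mirroring
  standard practice for this design; `semantic_correlation_table(adjust =
  "BH")` offers one.

Continuous predictors are standardized by **two** standard deviations
(Gelman–Hill scaling), so their coefficients are comparable to the ±1
effect-coded sex term; the transform records (center, 2·SD) make the scaling
invertible. The parosmia degree is the weighted sum of parosmia intensity
(0–10 VAS), daily frequency (0/1), and significant consequences (0/1), with
weights defaulting to $(1,1,1)$ since no other weighting is established; the
weights are an argument of `compute_parosmia_degree()`.

## Imputation

Participant covariates are incomplete in realistic cohorts (here: ~30%
missing subjective impairment, 12.5% BMI, ≲5% elsewhere).
`impute_missing()` fits, for each incomplete variable, an additive
regression on the other numeric covariates — natural cubic splines (3 df)
on continuous predictors, fixed knots from the full data — on each of 10
bootstrap resamples of the rows observed for that variable, and imputes the
mean of the 10 predictions, clipped to the variable's declared range.
Observed cells are never modified. Predictor missingness is mean-filled
for the imputation models only. If the spline basis would have more columns
than observed rows — which happens at study size (n = 48) for heavily
missing variables — all predictors enter linearly instead; only when even
the linear design is degenerate does the variable fall back to mean
imputation with a warning. A variable under 60% observed imputes with a
warning; only an all-missing variable is an error. Single mean-of-predictions values are
used downstream — between-imputation variance is reported per cell in the
imputation report but not propagated into model standard errors, which is a
known limitation of the single-imputation design.

## The synthetic cohort generator

Since the clinical data cannot ship with the package, `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes, and
its defaults are fixed at the study's reported conditions: 48 participants
(30 F/18 M; age truncated-normal with mean 45, SD 12, range 21–70), 38
descriptors, the published 6×6 semantic correlation matrix as the
multivariate-normal target (latent draws are mapped affinely onto each
rating scale and clipped at its bounds), 2% unknown responses, and the
missingness rates above, applied completely at random after the complete
latent table is stored for recovery tests.

Responses are drawn from a trinomial logit: for cell $(i, d)$ the category
is sampled from the softmax of $(0, \eta_{QD}, \eta_{OL})$ with
$\eta_c = \alpha_c + x_{id}'\beta_c + u_i$, over 2-SD-standardized semantic
and participant predictors and a shared random intercept
$u_i \sim N(0, \sigma_u^2)$, $\sigma_u = 0.8$ by default. The default
$\beta$ maps are the published binary-model point estimates (e.g.
olfactory→QD 0.95, gustatory→QD −0.79, olfactory→OL −1.03, TDI→OL −3.13)
and the default intercepts the published model intercepts (0.12, −1.90).
Using binary-logit estimates inside a trinomial mechanism is an
approximation — the two analyses coincide only when the other category's
predictor is flat — so recovery tests assert signs and approximate
magnitudes, not exact equality. Covariates whose distributions are not
reported (BMI, TDI, threshold, VAS items, questionnaire sums) use
truncated normals over clinical ranges, all exposed in `sim_config()`.

One deliberate coupling: a latent severity factor $z_i \sim N(0,1)$ both
scales the random intercept ($u_i = \sigma_u z_i$) and feeds subjective
impairment ($5 + 2 z_i$ + unit noise, clipped to the VAS range). Marginally
$u_i$ keeps its declared normal distribution, but severely affected
simulated patients also report higher impairment — giving the severity
index's external validation something real to find. Features of real data
the generator does **not** emulate include non-random missingness,
descriptor-specific random effects, response styles, and any longitudinal
structure; passing tests therefore validate the *machinery*, not clinical
performance.

Stage sub-seeds are derived from the master seed by a fixed Lehmer step, so
each stage is independently reproducible; identical (config, seed) pairs
give bit-identical cohorts.

## Descriptor subset selection

`select_dispersed()` reproduces the "evenly dispersed descriptors" endpoint
as a greedy farthest-point (maximin) selection in an embedding space:
seed with the farthest pair, then repeatedly add the point with maximal
minimum distance to the selected set, ties broken by input order. This is
the classical 2-approximation to the exhaustive maximin optimum (verified
by brute force on small instances in the tests). Cosine distance on
unit-normalized vectors is the default, as is standard for word embeddings.
The original descriptor list involved manual curation, so no claim is made
that this surrogate reproduces any particular published set.

## Numerical and testing choices

Oracle tests transcribe the four severity equations as plain loops and
require agreement to $10^{-12}$; `pearson_with_p` is checked against both a
textbook formula and `cor.test`; PCA variance fractions against a direct
eigendecomposition of the correlation matrix. Simulation suites use fixed
seeds and sizes chosen for stable calibration at desk scale: Wald test size
is estimated from 200 null cohorts of 200 participants (per-term rejection
required within [0.03, 0.08] at $\alpha = .05$), effect recovery from 20
cohorts of 500 participants, generator correlation calibration at 5,000
descriptors (±0.05 of the target matrix), and the index property sweep over
10,000 randomized instances. The worked examples pinned in the tests: 12/48
affected gives 25% with 95% CI [12.75, 37.25] by the normal approximation,
and $r = 0.54$ at $n = 37$ gives a two-sided $p$ that rounds to 0.001.

## Known limitations

* The severity index's clinical validity is established elsewhere; this
  package validates computation, not diagnosis.
* Binary mixed models applied to trinomially generated data recover signs
  and approximate magnitudes; exact coefficient recovery is not expected
  and not asserted.
* Imputation uncertainty is not propagated (single imputation by design).
* Interpretation of the principal components is left to the analyst; the
  package emits loadings and variance fractions only.
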
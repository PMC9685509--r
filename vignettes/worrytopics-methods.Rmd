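---
title: "Methods: topic models of therapy diaries and topic-moderated symptom change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic models of therapy diaries and topic-moderated symptom change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Internet-delivered cognitive behavioral therapy (iCBT) for generalized
anxiety disorder produces, as a side effect of treatment, a large corpus of
short free-text documents: worry-diary task sheets that patients fill in
between sessions, under three task assignments (plain worry diary, worry
postponement, problem solving). Alongside the texts, each completed session
yields a GAD-7 anxiety sum score (0–21). Two questions drive the analysis
this package implements:

1. What latent topics do patients write about, and how many topics should a
   topic model have when the answer cannot be predetermined?
2. Do topics *moderate* treatment response — that is, does writing about a
   particular topic predict a faster or slower per-session decline in
   standardized GAD-7 scores?

The pipeline is: preprocessing → latent Dirichlet allocation (LDA) fitted by
collapsed Gibbs sampling → Bayesian selection of the topic number by marginal
likelihood → per-patient topic occupancy → a ladder of linear mixed-effects
growth models with topic-by-session interactions. Because the underlying
routine-care hospital data are not public, the package ships a first-class
synthetic-data module that generates corpora and symptom trajectories with
*planted* structure, so every stage is validated by parameter recovery.

## The topic model and its sampler

LDA represents document $i$ as a mixture $\theta_i$ over $K$ topics, each
topic $k$ a distribution $\phi_k$ over the $V$-word vocabulary, with
symmetric Dirichlet priors $\theta_i \sim \mathrm{Dir}(\alpha)$ and
$\phi_k \sim \mathrm{Dir}(\beta)$. We integrate $\theta, \phi$ out and sample
token-topic assignments $z$ by collapsed Gibbs:

$$p(z_{di} = k \mid z_{-di}, w) \propto (n_{dk}^- + \alpha)\,
  \frac{n_{kv}^- + \beta}{n_{k}^- + V\beta}.$$

Estimates are smoothed count ratios,
$\hat\theta_{dk} = (n_{dk}+\alpha)/(n_d+K\alpha)$ and
$\hat\phi_{kv} = (n_{kv}+\beta)/(n_k+V\beta)$, averaged over post-burn-in
sweeps by default (`estimate_average = "post-burnin-mean"`); a `last-sample`
mode exists for exactness comparisons against enumeration. Multiple chains
are kept separate and never averaged, because topic labels are not
identified across chains; downstream stages use the designated first chain.

Defaults $\alpha = 0.1$, $\beta = 0.05$ follow common practice for short
documents with sparse topics; the source analysis did not publish its
values, so these are package defaults, not reproductions. Sweep order is
doc-major/token-minor with a fixed RNG stream, which makes chains
byte-reproducible under a seed.

## Choosing the number of topics

The package treats topic-number selection as Bayesian model comparison: pick
the $K$ maximizing the marginal likelihood $p(w \mid K)$, which integrates
over all parameters and hence penalizes overfitting automatically. Two
routes are implemented:

* `exact_log_marginal()` enumerates all $K^N$ assignments and is the oracle;
  it refuses (never silently approximates) beyond an enumeration budget, and
  uses the Dirichlet-multinomial closed form at $K = 1$.
* `estimate_log_marginal()` uses power-posterior thermodynamic integration:
  along a temperature ladder $0 = t_0 < \dots < t_J = 1$ the tempered
  collapsed sampler targets $p(z)\,p(w\mid z)^{t}$, and
  $\log p(w) = \int_0^1 E_t[\log p(w \mid z)]\,dt$ is computed by
  trapezoidal quadrature, warm-starting each rung from the previous one.
  By default the ladder is walked *downward* from $t = 1$, after racing two
  short posterior chains and keeping the better mode: the high-temperature
  rungs are where the tempered posterior is most multimodal and a chain
  annealed up from the prior can freeze into a poor topic configuration,
  which we observed to inflate the between-run spread of the estimate by
  hundreds of nats on corpus-scale problems (occasionally flipping the
  7-vs-9 topic ranking). Annealing down from a converged fit removed those
  excursions entirely in our replicate studies; the ascending variant
  remains available (`direction = "up"`).

The default ladder has 16 rungs at $t_j = (j/15)^5$, dense near $t = 0$
where the integrand moves fastest, with 200 sweeps per rung and the first
20% discarded. The tempering exponent applies only to integer count ratios,
so the powered terms are precomputed as lookup tables and a tempered sweep
costs the same as an ordinary one. The Monte-Carlo SE combines per-rung
batch-means variances through the quadrature weights; it ignores the (small)
cross-rung correlation introduced by warm starts, which we state rather than
hide. The original analysis used a serial-tempering style estimator from the
topic-model selection literature whose exact configuration is not public;
thermodynamic integration was chosen here because it is simple, validated
against enumeration at small sizes, and pluggable.

Ties in the selection break toward the smaller $K$ (parsimony). A UMass
coherence diagnostic (`coherence()`) is provided as plumbing for the
human-judgment route to topic numbers, which is itself out of scope.

At the reference corpus scale (1000 documents × 50 tokens, $V = 200$,
7 planted topics), the marginal-likelihood curve peaks at the planted
number; at much smaller corpus sizes (say 150 documents of 30 tokens) the
peak can genuinely sit above the planted $K$ — small-sample selection is
noisy, which is why the recovery criterion is framed over replicates at the
stated scale.

## From topics to exposures

Per-patient topic occupancy is the unweighted mean of $\hat\theta$ rows over
the patient's entries; patients with no (surviving) entries stay in the
cohort with occupancy zero — writing activity itself is a correlate, so
non-writers must not be dropped. Entry counts are tallied per task
assignment (entries 1–3) and in total. Documents emptied by preprocessing
count as "no entry" downstream, a policy choice: the model cannot score an
empty document, and the alternative (counting raw entries) is not
distinguishable from the published description.

GAD-7 scores are standardized as z-scores against the *baseline* (session-0)
sample mean and SD; session indices run from 0 so the model intercept is
anxiety at treatment start. Inclusion requires a baseline score of at least
8 and complete age/sex.

One self-consistency subtlety is worth stating. The published
variance components (intercept SD 0.90, residual variance 0.64) imply a
model baseline variance of about 1.45 on the standardized scale, although
exact z-scoring forces the empirical baseline variance to 1 — a mild
model–data discrepancy inherited from the source estimates. The synthetic
generator therefore plants the coefficients directly on the standardized
scale and recovery fits use that continuous channel (`y_std`); re-running
`standardize_gad7()` on the generator's raw channel would rescale all
coefficients by the sample baseline SD (≈1.2) and is deliberately not part
of the recovery path. The raw GAD-7 channel is still emitted, both as a
continuous value and as an integer clipped to 0–21, for realism and for
testing the standardization operation on its own contract.

## The growth-model ladder

All models regress the standardized score $y_{it}$ on session $t$, age and
sex, with patient-level random effects; estimation is REML for reported
estimates with an ML refit stored for likelihood-ratio tests (lme4 is the
engine behind the module's own interface). The ladder mirrors the analysis
design:

* **Model 0**: random intercept. **Model 1**: adds a random slope with an
  unstructured 2×2 covariance (the published table reports an
  intercept–slope correlation, so a free covariance is assumed). The base
  model is chosen by a likelihood-ratio test with the naive $\chi^2_2$
  reference — no boundary correction, matching the source's reporting; the
  known conservatism is verified by a null simulation in the tests.
* **Model 2**: total entries as a correlate; **model 3**: the three
  per-assignment entry counts. Every correlate enters with a baseline term
  and a correlate-by-session interaction; the interaction coefficient is
  the *treatment moderation effect*.
* **Model 4**: each topic separately; **model 5**: each topic adjusted for
  the entry counts; **model 6**: all topics whose model-5 moderation CI
  excludes zero, jointly, still entry-adjusted (skipped with a note when
  none qualifies).

Wald 95% CIs ($\pm 1.96\,\mathrm{SE}$) and two-sided normal p-values are
used; the source's CI construction is unstated but its intervals are
symmetric, and with ~13,000 observations the normal reference is adequate.
No multiplicity adjustment is applied across per-topic fits (none was
applied in the source); p-values are labeled unadjusted. Singular fits
(slope variance collapsing to zero) are flagged and returned, not
silently re-parameterized.

## The synthetic world

The generator's defaults are the reference cohort: 1686 patients, 12
sessions, baseline GAD-7 13.1 (SD 3.6), fixed session effect −0.147
SD/session, random intercept SD 0.90, random slope SD 0.10, intercept–slope
correlation −0.15, residual variance 0.64, age ≈ N(33, 12²) truncated at 16,
22% male, and per-assignment entry counts with means (SDs) 4.7 (5.3),
1.6 (4.2), 0.7 (1.6).

Choices where the published moments underdetermine a distribution:

* **Entry counts**: zero-inflated negative binomials per assignment,
  moment-matched by `calibrate_zinb()` given chosen structural-zero
  probabilities (0.14, 0.50, 0.40 — later-phase assignments are reached by
  fewer patients). The implied fraction of patients with no entries at all
  (~12%) is close to the reported 239/1686 ≈ 14%. Counts are independent
  across assignments, so the *total*-entries SD (~7.0) undershoots the
  reported 8.7, which would require cross-assignment correlation; this is a
  known, accepted simplification.
* **Dropout**: the number of completed sessions is the maximum-entropy
  distribution on 1..12 subject to mean 7.8 and P(complete) = 0.43
  (`calibrate_dropout()`), an exponential-family shape with one pinned cell
  — the least-assuming distribution matching the two published moments.
* **Tokens per entry**: Poisson(50) truncated at 1; recovery corpora use a
  fixed 50 tokens per document.
* **Moderation**: topic-by-session coefficients are planted per unit
  occupancy (range 0–1), matching the "SD/session per Δθ" units of the
  reported effects; occupancy enters the trajectory model as the *true*
  per-patient mean mixture, so estimation error is attributable stage by
  stage.

What a green recovery test does **not** establish: the generator writes
synthetic words over a synthetic vocabulary — no morphology, spelling
errors, language mixing, or the document-length/vocabulary skews of real
clinical text; entry counts are uncorrelated across assignments and
occupancy is time-invariant. Recovery results validate the *estimators*,
not the original substantive findings.

### Worlds used by the acceptance targets

The model-1 recovery criterion uses a generator whose data-generating
process *is* model 1 (entry effects and topic effects zero): planting the
entry effects as well would let model 1 absorb them into its random effects
and shift the recovered components by ~0.5–1% — quantified, but excluded by
design from the 3-MC-SE check. The model-3 target (session effect) plants
the full coefficient set, because the fitted model then matches the
generative one. Moderation targets plant a single nonzero topic effect:
with two planted effects, occupancy columns are negatively correlated on
the simplex and a single-topic model-4 fit would suffer omitted-variable
bias by construction (an expected −0.045 shift for the reported pair) —
that bias belongs to the joint-adjustment stage (models 5–6), not to the
single-topic recovery check.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage derives its own 32-bit seed from a master
  seed (`derive_seed()`); identical config + seed gives byte-identical
  output.
* Enumeration: the oracle iterates assignments in base-$K$ counting order
  with lgamma lookup tables; the default budget (2^18 terms) keeps it in
  oracle territory.
* Empty corpus, all-stopword documents, zero-entry cohorts, baseline SD 0,
  non-PSD random-effect covariances, non-monotone temperature ladders, and
  more-topics-than-tokens all raise explicit errors or warnings rather than
  propagating silently.
* The tokenizer keeps unicode-letter runs only (digits and punctuation are
  separators); stemming is injected, identity by default — real-language
  stemmers (e.g. Finnish) are out of scope, and the synthetic vocabulary
  needs none.

## Known limitations

* The selection estimator's MC SE is slightly optimistic (warm-start
  correlation across rungs is ignored).
* The heuristic, interpretability-based route to the topic number is human
  judgment and is supported only by the coherence diagnostic, not
  reproduced.
* Occupancy is time-invariant per patient; session-varying exposure is a
  non-goal.
* Missing sessions are not imputed; the growth models use all available
  rows under the usual MAR-given-model assumptions.
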
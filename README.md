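# worrytopics

Topic modeling of iCBT worry-diary texts and topic-moderated growth models
of anxiety-symptom change — as a tested, reusable R pipeline with a
synthetic-data module for end-to-end parameter-recovery validation.

## What it does

Internet-delivered cognitive behavioral therapy (iCBT) for generalized
anxiety disorder yields two linked data streams: free-text worry-diary
entries written between sessions (under three task assignments), and a
GAD-7 anxiety score (0–21) at every completed session. This package
implements the full analysis chain connecting them:

1. **Preprocess** — tokenize (unicode-letter runs, lowercased), remove stop
   words, apply a pluggable stemmer, and build a sparse document-term
   matrix (Matrix Market I/O).
2. **LDA** — latent Dirichlet allocation fitted by collapsed Gibbs sampling
   (Rcpp). With counts `n` and symmetric priors α, β the sampler draws
   token assignments from
   `p(z=k|·) ∝ (n_dk + α)(n_kv + β)/(n_k + Vβ)` and reports smoothed
   posterior-mean `θ` (doc–topic) and `φ` (topic–word).
3. **Topic-number selection** — Bayesian: choose K maximizing the marginal
   likelihood `p(w|K)`, estimated by power-posterior thermodynamic
   integration along a temperature ladder, with an exact enumeration oracle
   for validation and a UMass coherence diagnostic.
4. **Exposures** — per-patient mean topic occupancy (zero for non-writers,
   who stay in the cohort), entry counts per assignment, baseline-anchored
   z-scores of GAD-7, inclusion filtering (baseline ≥ 8, complete
   demographics) and Table-style descriptives.
5. **Growth models** — a ladder of linear mixed-effects models (lme4
   engine): random intercept vs random slope chosen by likelihood-ratio
   test, then writing-activity and per-topic correlates, each entering with
   a baseline term and a correlate×session interaction — the *treatment
   moderation effect*, in SD/session per unit topic occupancy.
6. **Synthetic data** — a generator that plants LDA topics, a diary-writing
   process (zero-inflated negative-binomial entry counts, max-entropy
   dropout over 12 sessions) and a growth model with topic moderation, so
   every estimator above is checked by recovering what was planted.

## Worked example

```r
library(worrytopics)

# a synthetic cohort: 300 patients, 7 planted topics, topic 1 planted to
# moderate treatment response by -0.3 SD/session per unit occupancy
cfg <- simulation_config(n_patients = 300, vocab_size = 200, k_true = 7,
                         gamma = c(-0.3, rep(0, 6)), seed = 42)
sim <- simulate_dataset(cfg)

dtm <- build_dtm(sim$entries)
dtm
#> document-term matrix: 2130 docs x 187 words, 106729 tokens

sel <- select_k(dtm, grid = c(3, 5, 7, 9), sweeps = 200, seed = 1)
sel
#> Bayesian topic-number selection
#>   k log_marginal    mc_se coherence
#> 1 3    -420516.7 36.54922        NA
#> 2 5    -394195.8 63.39370        NA
#> 3 7    -369546.9 74.10024        NA
#> 4 9    -369910.0 64.85085        NA
#> selected k = 7

fit <- fit_lda(dtm, lda_config(k = sel$selected_k, n_iter = 500,
                               burnin = 200, seed = 1))
expos <- build_exposures(fit, dtm, patients = sim$demographics$patient_id)
records <- build_records(sim$sessions, sim$demographics)

ladder <- run_model_ladder(records, expos, n_topics = sel$selected_k)
ladder$base_lrt
#> $statistic
#> [1] 219.3297
#> $df
#> [1] 2
#> $p
#> [1] 2.361389e-48
subset(ladder$forest, model == "model4", c(topic, estimate, ci_lo, ci_hi))
#>      topic estimate  ci_lo   ci_hi
#> 6  theta_1 -0.09050 -0.241  0.0598
#> 61 theta_2 -0.00437 -0.155  0.1458
#> 62 theta_3 -0.11591 -0.253  0.0210
#> 63 theta_4 -0.06451 -0.204  0.0745
#> 64 theta_5 -0.25562 -0.384 -0.1274
#> 65 theta_6  0.01233 -0.128  0.1527
#> 66 theta_7  0.00430 -0.145  0.1536
```

Reading the output: the marginal likelihood peaks at the planted K = 7; the
likelihood-ratio test (χ²₂ = 219.3) confirms patient-to-patient
heterogeneity in symptom slopes, so the random-slope model is the base; and
exactly one fitted topic has a moderation CI excluding zero: fitted topic 5,
which is the planted topic 1 (cosine similarity 1.00 between its word
distribution and the planted one — topic labels are arbitrary across fits).
Its effect, −0.26 SD/session per unit occupancy against a planted −0.30,
says patients who write about that topic improve faster than average.
At this corpus size the moderation estimate is attenuated slightly toward
zero because estimated occupancy is a noisy version of the true mixture.

## Command line

```sh
Rscript inst/cli/worrytopics.R simulate   --config cfg.yaml --out sim/ --seed 1
Rscript inst/cli/worrytopics.R preprocess --entries sim/entries.csv --out dtm
Rscript inst/cli/worrytopics.R select-k   --dtm dtm --grid 3,5,7,10 --seed 1 --out sel.json
Rscript inst/cli/worrytopics.R fit-lda    --dtm dtm --k 7 --iters 2000 --burnin 500 --seed 1 --out lda
Rscript inst/cli/worrytopics.R run-all    --config pipeline.yaml
```

`run-all` writes immutable per-stage artifacts plus a `manifest.json` with
seeds, hashes and paths.

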
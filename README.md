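# gatedtab

Gated tabular Transformers for clinical risk prediction in R.

`gatedtab` is for biostatisticians and clinical data scientists who need to
predict rare adverse outcomes — major adverse cardiovascular events and
related complications in acute coronary syndrome cohorts — from structured
electronic health record tables with mixed categorical, continuous and
datetime columns. The central difficulty is class imbalance: the event
class is a small minority, and the informative structure includes
interactions between features that linear risk scores miss.

## The model

The backbone is a TabTransformer: each categorical column owns an
*N* × *D* embedding matrix, the looked-up rows of one record form a token
sequence, and stacked self-attention blocks turn them into contextual
embeddings,

```
Attention(Q, K, V) = softmax(QKᵀ / √d_k) V.
```

Two learned sigmoid gates are added per block to regulate information
flow. The attention branch is modulated by

```
G  = σ(X W_g + b_g),          A′ = G ⊙ A,
```

and the feed-forward branch by

```
F  = ReLU(X₁ F₁ + b₁),  G_F = σ(X₁ F_g + b_gF),  F′ = F ⊙ G_F,
```

followed by the usual output projections and post-norm residual
connections `LayerNorm(x + branch)`. Contextual embeddings are flattened,
concatenated with the scaled continuous features, and classified by a
two-layer MLP head with a sigmoid output per adverse event. Setting
`gate_enabled = FALSE` bypasses both gates exactly, recovering the plain
TabTransformer — the ablation axis for judging what gating contributes.

Around the model the package provides leakage-safe preprocessing
(z-score + min-max scaling, categorical coding with a reserved
unknown slot, calendar features, sliding-window aggregates, imputation,
outlier masking), autoencoder pre-training of the column embeddings, a
reproducible Adam training loop with early stopping, an evaluation suite
for imbalanced classification (confusion matrices, precision/recall/F1,
ROC/AUC, PR/AP with exact tie handling), and a synthetic EHR cohort
generator with planted, ground-truth-known signal for testing everything
without access to private hospital data.

## Worked example

```r
library(gatedtab)

# 1. a synthetic six-group cohort with planted signal
spec <- cohort_spec(n_records = 1200,
                    group_sizes = c(basic = 2, history = 4, lab = 6,
                                    followup = 2, echo = 4, angio = 2),
                    events = "mace", prevalence = 0.13,
                    n_main = 10, beta_sd = 1.2, n_interactions = 6,
                    gamma_sd = 1.0, seed = 2024)
cohort <- generate_cohort(spec)
cohort
#> <synthetic_cohort> n=1200, 20 feature columns, events: mace
planted_signal_check(cohort)$auc     # Bayes-oracle ceiling
#> [1] 0.9684539

# 2. stratified split + leakage-safe preprocessing
idx <- split_dataset(cohort$data$mace, c(0.7, 0.15, 0.15), seed = 1)
state <- preprocess_fit(cohort$data[idx$train, ], cohort$schema)
train <- preprocess_transform(state, cohort$data[idx$train, ])
val   <- preprocess_transform(state, cohort$data[idx$val, ])
test  <- preprocess_transform(state, cohort$data[idx$test, ])
train
#> <encoded_dataset> 840 rows, 11 categorical + 13 continuous columns, events: mace

# 3. a small gated model with pre-trained column embeddings
emb <- pretrain_embeddings(train, dim = 16, epochs = 200, lr = 0.05,
                           seed = 1)$embeddings
cfg <- block_config(n_blocks = 2, n_heads = 4, embed_dim = 16,
                    ffn_mult = 2, embed_dropout = 0.4,
                    attention_dropout = 0, addnorm_dropout = 0,
                    head_hidden = 32)
model <- init_model(train, cfg, seed = 1, embeddings = emb)
fit <- train_model(model, train, val,
                   train_config(learning_rate = 1e-3, batch_size = 32,
                                max_epochs = 30, patience = 10, seed = 1,
                                weight_decay = 0.5))
fit$report
#> <train_report> 29 epochs, best epoch 19
#>   final: train loss 0.2752, val loss 0.3356, val AUC 0.7962

# 4. held-out evaluation
evaluate_events(fit$model, test)
#> <metrics_report>
#>   mace               AUC 0.781  AP 0.311  P 0.333  R 0.208  F1 0.256
```

The oracle AUC (0.97) is the ceiling set by the generating model; the
small Transformer trained on 840 records recovers a test AUC of 0.78 at
the default 0.5 call threshold. The low recall at that threshold is the
classic imbalanced-data picture — the ROC and PR curves returned in the
report are the threshold-free view. The package-scale reference
experiment (`run_benchmark()`, n = 4000, stronger planted signal) reaches
mean test AUC ≈ 0.87 across seeds; see the vignette.

A command-line interface wrapping the same pipeline lives in
`inst/cli/gatedtab.R`:

```sh
Rscript inst/cli/gatedtab.R simulate   --out sim --seed 42
Rscript inst/cli/gatedtab.R preprocess --data sim/cohort.csv \
        --schema sim/schema.json --out enc --seed 42
Rscript inst/cli/gatedtab.R train      --encoded enc --out fit --seed 42
Rscript inst/cli/gatedtab.R evaluate   --encoded enc \
        --checkpoint fit/checkpoint --out eval
```

Every stage writes a `manifest.json` (input hashes, config hash, seed), so
each artifact is reproducible from its manifest.

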
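# Shared fixtures: tiny models and datasets built in code.

tiny_meta <- function() {
  list(cat_cols = c("a", "b", "c"),
       vocab_sizes = c(a = 3L, b = 4L, c = 2L),
       cont_cols = c("x", "y"),
       events = "ev",
       schema_hash = "tiny")
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_blocks = 2L, n_heads = 2L, embed_dim = 4L, ffn_mult = 2L,
         dropout = 0, attention_dropout = 0, addnorm_dropout = 0,
         embed_dropout = 0, head_hidden = 3L),
    list(...))
  do.call(block_config, args)
}

tiny_batch <- function(B = 5L, seed = 42L) {
  set.seed(seed)
  list(cat_codes = matrix(sample(0:1, B * 3L, TRUE), B, 3L,
                          dimnames = list(NULL, c("a", "b", "c"))),
       cont_values = matrix(rnorm(B * 2L), B, 2L,
                            dimnames = list(NULL, c("x", "y"))),
       y = rep_len(c(1, 0), B))
}

# small raw cohort + encoded splits for pipeline-level tests
tiny_cohort <- function(n = 400L, seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_records = n,
         group_sizes = c(basic = 2L, history = 2L, lab = 3L,
                         followup = 1L, echo = 2L, angio = 1L),
         events = "mace", prevalence = 0.2,
         n_main = 5L, beta_sd = 1, n_interactions = 3L,
         gamma_sd = 1, missing_rate = 0.02,
         outlier_rate = 0.005, seed = seed),
    list(...))
  generate_cohort(do.call(cohort_spec, args))
}

encode_cohort <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  idx <- split_dataset(cohort$data[[cohort$spec$events[1]]], fractions, seed)
  state <- preprocess_fit(cohort$data[idx$train, , drop = FALSE],
                          cohort$schema)
  splits <- lapply(idx, function(rows)
    preprocess_transform(state, cohort$data[rows, , drop = FALSE]))
  list(state = state, splits = splits, idx = idx)
}

# recursive leaf access for gradient checking
get_leaf <- function(tree, path) {
  for (k in path) tree <- tree[[k]]
  tree
}
set_leaf <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path[[1L]]]] <- value
  } else {
    tree[[path[[1L]]]] <- set_leaf(tree[[path[[1L]]]], path[-1L], value)
  }
  tree
}

# reference ungated TabTransformer block, written independently with
# explicit per-position loops (no code shared with the package internals)
reference_ungated_block <- function(X, p, n_heads) {
  D <- ncol(X); dh <- D / n_heads; s <- nrow(X)
  ln <- function(M, g, b) {
    t(apply(M, 1, function(r) {
      mu <- mean(r); v <- mean((r - mu)^2)
      g * (r - mu) / sqrt(v + 1e-5) + b
    }))
  }
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  C <- matrix(0, s, D)
  for (hh in seq_len(n_heads)) {
    cols <- ((hh - 1) * dh + 1):(hh * dh)
    for (i in seq_len(s)) {
      sc <- numeric(s)
      for (j in seq_len(s)) sc[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      for (j in seq_len(s)) C[i, cols] <- C[i, cols] + w[j] * V[j, cols]
    }
  }
  A <- C %*% p$Wo + matrix(p$bo, s, D, byrow = TRUE)
  X1 <- ln(X + A, p$ln1_g, p$ln1_b)
  Fo <- pmax(X1 %*% p$F1 + matrix(p$b1, s, length(p$b1), byrow = TRUE), 0)
  Fo <- Fo %*% p$F2 + matrix(p$b2, s, D, byrow = TRUE)
  ln(X1 + Fo, p$ln2_g, p$ln2_b)
}

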
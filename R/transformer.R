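# Gated Transformer blocks for tabular data.
#
# The backbone follows the TabTransformer: the embeddings of the
# categorical columns of one record form a length-s sequence of
# D-dimensional tokens that passes through stacked self-attention blocks;
# continuous features bypass attention and join the classifier head.
# Two sigmoid gates are added per block:
#   * attention gate   G   = sigmoid(src %*% W_g + b_g),  A' = G * A
#     where src is the block input X (default) or the attention output A;
#   * feed-forward gate G_F = sigmoid(X1 %*% F_g + b_gF) applied to the
#     ReLU activations of the first FFN layer, F' = F * G_F,
#     followed by the output projection F2/b2.
# Residual connections use post-norm order: LayerNorm(x + branch).

#' Configuration of the gated Transformer backbone
#'
#' Defaults correspond to the full-size clinical model: 6 blocks of
#' 8-head attention on 128-dimensional embeddings with 0.1 dropout
#' everywhere.
#'
#' @param n_blocks number of Transformer blocks.
#' @param n_heads attention heads; must divide `embed_dim`.
#' @param embed_dim token dimension D.
#' @param ffn_mult hidden width of the feed-forward layer as a multiple of
#'   D.
#' @param dropout dropout probability on the classifier head.
#' @param attention_dropout dropout on attention probabilities.
#' @param addnorm_dropout dropout on residual branches before the add.
#' @param embed_dropout dropout on the flattened contextual embeddings
#'   entering the classifier head (continuous features are not dropped);
#'   regularizes the high-dimensional embedding pathway so it cannot crowd
#'   out the continuous features.
#' @param gate_enabled logical; `FALSE` bypasses both gates entirely,
#'   recovering the plain ungated block.
#' @param gate_input_source "layer_input" (gate computed from the block
#'   input) or "attention_output" (gate computed from the attention
#'   output).
#' @param head_hidden hidden width of the classifier head MLP.
#' @return list of class `block_config`.
#' @export
block_config <- function(n_blocks = 6L, n_heads = 8L, embed_dim = 128L,
                         ffn_mult = 4L, dropout = 0.1,
                         attention_dropout = 0.1, addnorm_dropout = 0.1,
                         embed_dropout = 0.1,
                         gate_enabled = TRUE,
                         gate_input_source = c("layer_input",
                                               "attention_output"),
                         head_hidden = embed_dim) {
  gate_input_source <- match.arg(gate_input_source)
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim (", embed_dim, ") must be divisible by n_heads (",
         n_heads, ")")
  }
  stopifnot(n_blocks >= 1, dropout >= 0, dropout < 1,
            attention_dropout >= 0, attention_dropout < 1,
            addnorm_dropout >= 0, addnorm_dropout < 1,
            embed_dropout >= 0, embed_dropout < 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim),
                 ffn_mult = as.integer(ffn_mult),
                 dropout = dropout, attention_dropout = attention_dropout,
                 addnorm_dropout = addnorm_dropout,
                 embed_dropout = embed_dropout,
                 gate_enabled = isTRUE(gate_enabled),
                 gate_input_source = gate_input_source,
                 head_hidden = as.integer(head_hidden)),
            class = "block_config")
}

# ---- public single-sequence operations ---------------------------------
# These operate on one record's token matrix (s x D) and are the reference
# semantics; the batched training engine in model.R must agree with their
# composition (asserted in the test suite).

#' Scaled dot-product attention
#'
#' `A = softmax(Q K^T / sqrt(d_k)) V`; every softmax row sums to 1.
#'
#' @param Q,K,V numeric matrices (rows = positions).
#' @param d_k key dimensionality used in the scaling; defaults to
#'   `ncol(K)`.
#' @return matrix of attended values, same rows as `Q`.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (d_k <= 0) stop("d_k must be positive")
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) stop("shape mismatch")
  P <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  P %*% V
}

#' Sigmoid gating coefficients
#'
#' `G = sigmoid(source %*% W_g + b_g)`, elementwise, with entries strictly
#' inside (0, 1).
#'
#' @param source numeric matrix (block input or attention output).
#' @param W_g gating weight matrix.
#' @param b_g gating bias vector.
#' @return matrix of gate coefficients, same shape as `source %*% W_g`.
#' @export
gate_coefficients <- function(source, W_g, b_g) {
  G <- sigmoid(sweep(source %*% W_g, 2, b_g, `+`))
  pmin(pmax(G, 1e-12), 1 - 1e-12)
}

#' Apply gating coefficients to an attention output
#'
#' `A' = G * A` elementwise.
#'
#' @param A attention output matrix.
#' @param G gate coefficient matrix of identical shape.
#' @return gated matrix.
#' @export
gated_attention <- function(A, G) {
  if (!all(dim(A) == dim(G))) stop("shape mismatch between A and G")
  G * A
}

#' Gated position-wise feed-forward network
#'
#' `F = ReLU(X F1 + b1)`, `G_F = sigmoid(X F_g + b_gF)`, `F' = F * G_F`,
#' then the output projection `F' F2 + b2` restores the model dimension.
#'
#' @param X input matrix (s x D).
#' @param params list with `F1`, `b1`, `F_g`, `b_gF`, `F2`, `b2`.
#' @param gate_enabled if `FALSE` the gate is bypassed (`F' = F`).
#' @return output matrix (s x D).
#' @export
gated_ffn <- function(X, params, gate_enabled = TRUE) {
  F_ <- relu(sweep(X %*% params$F1, 2, params$b1, `+`))
  if (gate_enabled) {
    G_F <- sigmoid(sweep(X %*% params$F_g, 2, params$b_gF, `+`))
    F_ <- F_ * G_F
  }
  sweep(F_ %*% params$F2, 2, params$b2, `+`)
}

#' Layer normalization over the feature dimension
#'
#' @param X matrix (rows normalized independently).
#' @param gamma,beta scale and shift vectors of length `ncol(X)`.
#' @param eps variance floor.
#' @return normalized matrix.
#' @export
layer_norm <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sig <- sqrt(rowMeans(xc^2) + eps)
  sweep(xc / sig, 2, gamma, `*`) |> sweep(2, beta, `+`)
}

#' Forward pass of one gated Transformer block (single sequence)
#'
#' Post-norm composition without dropout (the deterministic inference
#' path): multi-head gated attention with residual + LayerNorm, then the
#' gated feed-forward network with residual + LayerNorm. With
#' `gate_enabled = FALSE` both gates are bypassed entirely, recovering the
#' plain TabTransformer block.
#'
#' @param X token matrix (s x D).
#' @param params one block's parameter list (see [init_model()]).
#' @param config a `block_config`.
#' @return matrix of the same shape as `X`.
#' @export
block_forward <- function(X, params, config) {
  D <- config$embed_dim
  h <- config$n_heads
  dh <- D %/% h
  stopifnot(ncol(X) == D)
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  C <- matrix(0, nrow(X), D)
  for (hh in seq_len(h)) {
    cols <- ((hh - 1L) * dh + 1L):(hh * dh)
    C[, cols] <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE],
                                      V[, cols, drop = FALSE], d_k = dh)
  }
  A <- sweep(C %*% params$Wo, 2, params$bo, `+`)
  if (config$gate_enabled) {
    src <- if (config$gate_input_source == "layer_input") X else A
    G <- gate_coefficients(src, params$Wg, params$bg)
    A <- gated_attention(A, G)
  }
  X1 <- layer_norm(X + A, params$ln1_g, params$ln1_b)
  Fo <- gated_ffn(X1, params, gate_enabled = config$gate_enabled)
  layer_norm(X1 + Fo, params$ln2_g, params$ln2_b)
}

# ---- parameter initialization ------------------------------------------

.glorot <- function(fin, fout) {
  matrix(stats::rnorm(fin * fout, sd = sqrt(2 / (fin + fout))), fin, fout)
}

#' Initialize a gated Transformer model
#'
#' @param meta the `meta` element of an `encoded_dataset` (categorical
#'   column names and vocabulary sizes, continuous column names, events,
#'   schema hash), or an encoded dataset itself.
#' @param config a [block_config()].
#' @param seed RNG seed for the initialization.
#' @param event name of the outcome the model predicts; defaults to the
#'   first event in `meta`.
#' @param embeddings optional pre-trained `column_embedding` (from
#'   [pretrain_embeddings()]) used instead of random embedding tables.
#' @return object of class `gated_tab_model`.
#' @export
init_model <- function(meta, config = block_config(), seed = 1L,
                       event = NULL, embeddings = NULL) {
  if (inherits(meta, "encoded_dataset")) meta <- meta$meta
  event <- event %||% meta$events[1]
  stopifnot(event %in% meta$events)
  D <- config$embed_dim
  H <- config$ffn_mult * D
  s <- length(meta$cat_cols)
  m <- length(meta$cont_cols)
  stopifnot(s >= 1)
  with_seed(seed, {
    if (!is.null(embeddings)) {
      stopifnot(all(meta$cat_cols %in% names(embeddings)))
    }
    emb <- lapply(meta$cat_cols, function(nm) {
      n <- meta$vocab_sizes[[nm]]
      if (!is.null(embeddings)) {
        E <- embeddings[[nm]]
        stopifnot(nrow(E) == n, ncol(E) == D)
        E
      } else {
        matrix(stats::rnorm(n * D, sd = 0.1), n, D)
      }
    })
    names(emb) <- meta$cat_cols
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      list(Wq = .glorot(D, D), Wk = .glorot(D, D), Wv = .glorot(D, D),
           Wo = .glorot(D, D), bo = rep(0, D),
           # gate biases start at +1 so gates open ~0.73 at initialization
           # and gating does not throttle early learning
           Wg = .glorot(D, D), bg = rep(1, D),
           F1 = .glorot(D, H), b1 = rep(0, H),
           F_g = .glorot(D, H), b_gF = rep(1, H),
           F2 = .glorot(H, D), b2 = rep(0, D),
           ln1_g = rep(1, D), ln1_b = rep(0, D),
           ln2_g = rep(1, D), ln2_b = rep(0, D))
    })
    head <- list(W1 = .glorot(s * D + m, config$head_hidden),
                 b1 = rep(0, config$head_hidden),
                 W2 = .glorot(config$head_hidden, 1L),
                 b2 = 0)
    structure(list(params = list(emb = emb, blocks = blocks, head = head),
                   config = config, meta = meta, event = event,
                   seed = as.integer(seed)),
              class = "gated_tab_model")
  })
}

#' @export
print.gated_tab_model <- function(x, ...) {
  cfg <- x$config
  cat("<gated_tab_model> event '", x$event, "': ", cfg$n_blocks,
      " blocks, D=", cfg$embed_dim, ", ", cfg$n_heads, " heads, gates ",
      if (cfg$gate_enabled) "on" else "off", "\n", sep = "")
  cat("  inputs: ", length(x$meta$cat_cols), " categorical + ",
      length(x$meta$cont_cols), " continuous columns\n", sep = "")
  invisible(x)
}
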
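# Column embeddings for categorical features and their unsupervised
# autoencoder pre-training.
#
# Each categorical column c with N categories (including the reserved
# unknown slot) owns an N x D embedding matrix E_c; looking up code j
# returns row E_c[j]. Pre-training fits, per column, a one-hidden-layer
# autoencoder that reconstructs the column's one-hot indicator vectors
# under mean squared error; the encoder image f(W_e e_j + b_e) of each
# category indicator then initializes embedding row j.

#' Randomly initialize column embeddings
#'
#' @param vocab_sizes named integer vector of vocabulary sizes per
#'   categorical column, including the unknown slot.
#' @param dim embedding dimension D (all columns share it).
#' @param seed RNG seed.
#' @param scale standard deviation of the normal initializer.
#' @return named list of N x D matrices, class `column_embedding`.
#' @export
init_embeddings <- function(vocab_sizes, dim = 128L, seed = 1L,
                            scale = 0.1) {
  stopifnot(all(vocab_sizes >= 2L), dim >= 1L)
  with_seed(seed, {
    emb <- lapply(vocab_sizes, function(n) {
      matrix(stats::rnorm(n * dim, sd = scale), nrow = n, ncol = dim)
    })
    structure(emb, class = "column_embedding", embed_dim = as.integer(dim))
  })
}

#' Look up the embedding vector of a category code
#'
#' @param embeddings a `column_embedding` list.
#' @param col column name or index.
#' @param code 0-based integer category code.
#' @return numeric vector of length D.
#' @export
embedding_lookup <- function(embeddings, col, code) {
  e <- embeddings[[col]]
  if (is.null(e)) stop("unknown embedding column: ", col)
  if (length(code) != 1 || is.na(code) || code < 0 || code >= nrow(e)) {
    stop("code ", code, " out of range [0, ", nrow(e) - 1,
         "] for column '", col, "'")
  }
  e[code + 1L, ]
}

.ae_act <- function(name) {
  switch(name,
         relu = list(f = relu, df = function(pre) (pre > 0) * 1),
         identity = list(f = identity, df = function(pre) pre * 0 + 1),
         stop("unsupported activation: ", name))
}

#' Forward pass of a one-hidden-layer autoencoder
#'
#' Computes `h = f(W_e x + b_e)` and `x_hat = g(W_d h + b_d)`.
#'
#' @param x numeric vector (one sample) or matrix with samples in rows.
#' @param params list with `W_e` (D x N), `b_e` (D), `W_d` (N x D),
#'   `b_d` (N), and activation names `f`, `g`.
#' @return list with `h` and `x_hat` (same sample layout as `x`).
#' @export
autoencoder_forward <- function(x, params) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(X) != ncol(params$W_e)) {
    stop("input dimension ", ncol(X), " does not match encoder width ",
         ncol(params$W_e))
  }
  f <- .ae_act(params$f %||% "relu")$f
  g <- .ae_act(params$g %||% "identity")$f
  H <- f(sweep(X %*% t(params$W_e), 2, params$b_e, `+`))
  Xhat <- g(sweep(H %*% t(params$W_d), 2, params$b_d, `+`))
  if (vec) list(h = drop(H), x_hat = drop(Xhat))
  else list(h = H, x_hat = Xhat)
}

#' Mean squared reconstruction loss
#'
#' `Loss = (1/N) * sum_i ||x_i - x_hat_i||^2` over the N samples (rows).
#'
#' @param x,x_hat matrices (samples in rows) or vectors of equal shape.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else x
  Xh <- if (is.null(dim(x_hat))) matrix(x_hat, nrow = 1) else x_hat
  if (!all(dim(X) == dim(Xh))) stop("shape mismatch")
  if (nrow(X) == 0) stop("empty batch")
  sum((X - Xh)^2) / nrow(X)
}

# Fit one autoencoder by full-batch Adam on weighted one-hot targets.
# X: n_distinct x N indicator matrix, w: sample weights summing to 1
# (category frequencies), so the loss equals the per-sample MSE over the
# underlying dataset rows.
.fit_autoencoder <- function(X, w, dim, epochs, lr, f_name, g_name) {
  N <- ncol(X)
  params <- list(
    W_e = matrix(stats::rnorm(dim * N, sd = 0.1), dim, N),
    b_e = rep(0, dim),
    W_d = matrix(stats::rnorm(N * dim, sd = 0.1), N, dim),
    b_d = rep(0, N),
    f = f_name, g = g_name)
  act_f <- .ae_act(f_name)
  act_g <- .ae_act(g_name)
  opt_params <- params[c("W_e", "b_e", "W_d", "b_d")]
  opt <- adam_init(opt_params)
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    pre_h <- sweep(X %*% t(opt_params$W_e), 2, opt_params$b_e, `+`)
    H <- act_f$f(pre_h)
    pre_o <- sweep(H %*% t(opt_params$W_d), 2, opt_params$b_d, `+`)
    Xhat <- act_g$f(pre_o)
    R <- Xhat - X
    loss <- sum(w * rowSums(R^2))
    if (!is.finite(loss)) {
      stop("autoencoder loss diverged (non-finite) at epoch ", ep,
           "; last loss = ", loss)
    }
    d_pre_o <- (2 * w * R) * act_g$df(pre_o)
    grads <- list(
      W_e = NULL, b_e = NULL,
      W_d = t(d_pre_o) %*% H,
      b_d = colSums(d_pre_o))
    dH <- d_pre_o %*% opt_params$W_d
    d_pre_h <- dH * act_f$df(pre_h)
    grads$W_e <- t(d_pre_h) %*% X
    grads$b_e <- colSums(d_pre_h)
    st <- adam_step(opt_params, grads, opt, lr)
    opt_params <- st$params
    opt <- st$state
  }
  params[c("W_e", "b_e", "W_d", "b_d")] <- opt_params
  list(params = params, final_loss = loss)
}

#' Pre-train column embeddings with per-column autoencoders
#'
#' For every categorical column of an encoded dataset, fits an autoencoder
#' on the column's one-hot indicator vectors (weighted by how often each
#' category occurs) and initializes the column's embedding rows with the
#' encoder images of the category indicators. With `epochs = 0` the
#' embeddings equal the seeded random initialization of the encoder images.
#'
#' @param encoded an `encoded_dataset` (training split).
#' @param dim embedding dimension D.
#' @param epochs full-batch training iterations per column.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @param f,g encoder / decoder activation names ("relu" or "identity").
#' @return list with `embeddings` (a `column_embedding`), `autoencoders`
#'   (per-column parameter lists) and `losses` (final per-column MSE).
#' @export
pretrain_embeddings <- function(encoded, dim = 128L, epochs = 200L,
                                lr = 0.01, seed = 1L,
                                f = "relu", g = "identity") {
  stopifnot(inherits(encoded, "encoded_dataset"))
  if (nrow(encoded$cat_codes) == 0) stop("empty dataset")
  with_seed(seed, {
    emb <- list(); aes <- list(); losses <- numeric(0)
    for (nm in encoded$meta$cat_cols) {
      N <- encoded$meta$vocab_sizes[[nm]]
      codes <- encoded$cat_codes[, nm]
      counts <- tabulate(codes + 1L, nbins = N)
      X <- diag(N)                     # one indicator per category
      w <- counts / sum(counts)
      # categories never observed still get an embedding row; give them a
      # vanishing weight so they do not influence the fit
      w[w == 0] <- 1e-12
      w <- w / sum(w)
      fit <- .fit_autoencoder(X, w, dim, epochs, lr, f, g)
      img <- autoencoder_forward(X, fit$params)$h     # N x D encoder images
      emb[[nm]] <- img
      aes[[nm]] <- fit$params
      losses[nm] <- fit$final_loss
    }
    list(embeddings = structure(emb, class = "column_embedding",
                                embed_dim = as.integer(dim)),
         autoencoders = aes, losses = losses)
  })
}
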
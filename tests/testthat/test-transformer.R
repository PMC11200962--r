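# Gated Transformer blocks: attention, gating, feed-forward, full model.

test_that("scaled dot-product attention matches hand arithmetic", {
  # sequence length 1: softmax of a scalar is 1, so A = V
  Q <- matrix(c(1, 2), 1); K <- matrix(c(0.3, -1), 1)
  V <- matrix(c(5, 7), 1)
  expect_equal(scaled_dot_attention(Q, K, V, 2), V)

  # all key rows identical: uniform attention, every row = colMeans(V)
  Q2 <- matrix(rnorm(6), 3); K2 <- matrix(1, 3, 2)
  V2 <- matrix(rnorm(6), 3)
  A2 <- scaled_dot_attention(Q2, K2, V2, 2)
  for (i in 1:3) expect_equal(A2[i, ], colMeans(V2))

  # 2-position example with Q = K, against direct softmax arithmetic
  Q3 <- matrix(c(1, 0, 0, 1), 2)
  V3 <- matrix(c(1, 2, 3, 4), 2)
  S <- Q3 %*% t(Q3) / sqrt(2)
  P <- exp(S) / rowSums(exp(S))
  expect_equal(scaled_dot_attention(Q3, Q3, V3, 2), P %*% V3,
               tolerance = 1e-12)

  expect_error(scaled_dot_attention(Q3, Q3, V3, 0), "positive")
})

test_that("gate coefficients are sigmoid responses strictly inside (0,1)", {
  X <- matrix(rnorm(8), 2)
  G0 <- gate_coefficients(X, matrix(0, 4, 4), rep(0, 4))
  expect_true(all(G0 == 0.5))
  G1 <- gate_coefficients(X, matrix(0, 4, 4), rep(20, 4))
  expect_true(all(G1 > 0.999 & G1 < 1))
  # scalar case: pre-activation 2 -> sigmoid(2)
  expect_equal(gate_coefficients(matrix(1), matrix(2), 0)[1, 1],
               1 / (1 + exp(-2)), tolerance = 1e-6)
  expect_equal(round(gate_coefficients(matrix(1), matrix(2), 0)[1, 1], 4),
               0.8808)
})

test_that("gated attention is the elementwise product G * A", {
  A <- matrix(c(1, -2, 3, 4), 2)
  expect_equal(gated_attention(A, matrix(1, 2, 2)), A)
  expect_equal(gated_attention(A, matrix(0, 2, 2)), matrix(0, 2, 2))
  G <- matrix(c(0.5, 0.25, 1, 0.1), 2)
  expect_equal(gated_attention(A, G), A * G)
  expect_error(gated_attention(A, matrix(1, 3, 2)), "shape")
})

test_that("gated FFN composes ReLU, sigmoid gate and output projection", {
  p <- list(F1 = matrix(c(1, 0, 0, 1), 2), b1 = c(0, 0),
            F_g = matrix(c(0.5, 0, 0, -0.5), 2), b_gF = c(0, 0),
            F2 = diag(2), b2 = c(0, 0))
  # all first-layer pre-activations negative: ReLU annihilates the branch
  Xneg <- matrix(c(-1, -2, -3, -4), 2)
  expect_equal(gated_ffn(Xneg, p), matrix(0, 2, 2))

  # gate bypassed equals the plain two-layer FFN
  X <- matrix(c(1, 2, -1, 0.5), 2)
  plain <- pmax(X %*% p$F1, 0) %*% p$F2
  expect_equal(gated_ffn(X, p, gate_enabled = FALSE), plain)

  # scalar chain ReLU -> sigmoid -> product
  ps <- list(F1 = matrix(2), b1 = 0.5, F_g = matrix(1), b_gF = -1,
             F2 = matrix(3), b2 = 0.25)
  x <- matrix(0.7)
  f <- max(2 * 0.7 + 0.5, 0)
  g <- 1 / (1 + exp(-(0.7 - 1)))
  expect_equal(gated_ffn(x, ps)[1, 1], f * g * 3 + 0.25, tolerance = 1e-12)
})

test_that("gate_enabled = FALSE reproduces an independent ungated block", {
  cfg <- tiny_config(n_blocks = 1L, gate_enabled = FALSE)
  m <- init_model(tiny_meta(), cfg, seed = 2L)
  p <- m$params$blocks[[1]]
  set.seed(10)
  X <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(block_forward(X, p, cfg),
               reference_ungated_block(X, p, cfg$n_heads),
               tolerance = 1e-6)
})

test_that("block forward respects shape, determinism and softmax rows", {
  cfg <- tiny_config(n_blocks = 1L)
  m <- init_model(tiny_meta(), cfg, seed = 4L)
  X <- matrix(rnorm(12), 3, 4)
  out1 <- block_forward(X, m$params$blocks[[1]], cfg)
  out2 <- block_forward(X, m$params$blocks[[1]], cfg)
  expect_identical(dim(out1), dim(X))
  expect_identical(out1, out2)

  fb <- gatedtab:::.block_forward_batch(X, m$params$blocks[[1]], cfg,
                                        B = 1L, s = 3L, keep_cache = TRUE)
  for (P in fb$cache$P) {
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  }
  if (!is.null(fb$G)) expect_true(all(fb$G > 0 & fb$G < 1))
})

test_that("batched model forward equals composing the public single-record ops", {
  cfg <- tiny_config()
  m <- init_model(tiny_meta(), cfg, seed = 7L)
  b <- tiny_batch()
  fwd <- model_forward(m, b)
  for (r in seq_len(nrow(b$cat_codes))) {
    X <- t(vapply(seq_along(m$meta$cat_cols), function(i)
      m$params$emb[[i]][b$cat_codes[r, i] + 1L, ], numeric(cfg$embed_dim)))
    for (k in seq_len(cfg$n_blocks)) {
      X <- block_forward(X, m$params$blocks[[k]], cfg)
    }
    z <- c(as.vector(X), b$cont_values[r, ])
    hid <- pmax(drop(z %*% m$params$head$W1) + m$params$head$b1, 0)
    logit <- drop(hid %*% m$params$head$W2) + m$params$head$b2
    expect_equal(fwd$logit[r], logit, tolerance = 1e-10)
  }
  expect_true(all(fwd$prob > 0 & fwd$prob < 1))
})

test_that("permuting the batch permutes outputs identically", {
  m <- init_model(tiny_meta(), tiny_config(), seed = 7L)
  b <- tiny_batch(B = 8L)
  perm <- c(3L, 1L, 8L, 5L, 2L, 7L, 4L, 6L)
  f1 <- model_forward(m, b)
  f2 <- model_forward(m, list(cat_codes = b$cat_codes[perm, ],
                              cont_values = b$cont_values[perm, ]))
  expect_equal(f2$logit, f1$logit[perm], tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  m <- init_model(tiny_meta(), cfg, seed = 7L)
  b <- tiny_batch()
  fwd <- gatedtab:::.forward_batch(m, b$cat_codes, b$cont_values,
                                   keep_cache = TRUE)
  ls <- gatedtab:::.bce_loss(fwd$logit, b$y)
  gr <- gatedtab:::.backward_batch(m, b$cat_codes, fwd, ls$dlogit)
  loss_at <- function(params) {
    mm <- m; mm$params <- params
    f <- gatedtab:::.forward_batch(mm, b$cat_codes, b$cont_values)
    gatedtab:::.bce_loss(f$logit, b$y)$loss
  }
  paths <- list(list("emb", "a"), list("emb", "c"),
                list("blocks", 1L, "Wq"), list("blocks", 1L, "Wk"),
                list("blocks", 1L, "Wv"), list("blocks", 1L, "Wo"),
                list("blocks", 1L, "Wg"), list("blocks", 1L, "bg"),
                list("blocks", 1L, "F1"), list("blocks", 1L, "F_g"),
                list("blocks", 1L, "b_gF"), list("blocks", 1L, "F2"),
                list("blocks", 1L, "ln1_g"), list("blocks", 2L, "ln2_b"),
                list("blocks", 2L, "Wg"), list("head", "W1"),
                list("head", "W2"), list("head", "b2"))
  set.seed(99)
  eps <- 1e-5
  for (path in paths) {
    leaf <- get_leaf(m$params, path)
    g <- get_leaf(gr, path)
    for (k in sample(seq_along(leaf), min(3L, length(leaf)))) {
      up <- leaf; up[k] <- up[k] + eps
      dn <- leaf; dn[k] <- dn[k] - eps
      num <- (loss_at(set_leaf(m$params, path, up)) -
                loss_at(set_leaf(m$params, path, dn))) / (2 * eps)
      expect_lt(abs(g[k] - num), 1e-6 * max(1, abs(num)),
                label = paste0("gradient mismatch at ",
                               paste(unlist(path), collapse = "/"),
                               "[", k, "]"))
    }
  }
})

test_that("near-closed gates suppress the attention branch's contribution", {
  cfg_open <- tiny_config(n_blocks = 1L)
  m <- init_model(tiny_meta(), cfg_open, seed = 5L)
  X <- matrix(rnorm(12), 3, 4)
  p_open <- m$params$blocks[[1]]
  p_open$bg <- rep(20, 4)
  p_closed <- m$params$blocks[[1]]
  p_closed$bg <- rep(-20, 4)
  # reference path with the attention output forced to zero
  p_zero <- p_open
  p_zero$Wo <- p_zero$Wo * 0
  p_zero$bo <- p_zero$bo * 0
  base <- block_forward(X, p_zero, cfg_open)
  contrib_open <- norm(block_forward(X, p_open, cfg_open) - base, "F")
  contrib_closed <- norm(block_forward(X, p_closed, cfg_open) - base, "F")
  expect_lte(contrib_closed, 1e-6 * contrib_open)
})

test_that("checkpoints reload bit-stably and guard the schema", {
  cohort <- tiny_cohort(n = 150L)
  enc <- encode_cohort(cohort)
  cfg <- tiny_config()
  m <- init_model(enc$splits$train, cfg, seed = 3L)
  dir <- file.path(tempdir(), "ckpt-test")
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  f1 <- model_forward(m, enc$splits$test)
  f2 <- model_forward(m2, enc$splits$test)
  expect_identical(f1$logit, f2$logit)

  other <- tiny_cohort(n = 150L, seed = 99L,
                       group_sizes = c(basic = 1L, history = 3L, lab = 2L,
                                       followup = 1L, echo = 1L,
                                       angio = 1L))
  enc_other <- encode_cohort(other)
  expect_error(predict_risk(m2, enc_other$splits$test), "schema")
  unlink(dir, recursive = TRUE)
})
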
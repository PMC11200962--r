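# Small numeric and bookkeeping helpers shared across the package.

#' Numerically safe logistic function
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with values in \[0, 1\].
#' @keywords internal
sigmoid <- function(x) {
  out <- 1 / (1 + exp(-x))
  out
}

# log(1 + exp(x)) without overflow for large |x|
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

relu <- function(x) {
  pmax(x, 0)
}

# Row-wise softmax of a matrix; each output row sums to 1.
# (max.col is C-level; much faster than apply(m, 1, max) on hot paths)
softmax_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

# add a row vector to every row of a matrix (fast sweep(M, 2, b, `+`))
add_row <- function(M, b) {
  M + rep(b, each = nrow(M))
}

#' Population standard deviation (ddof = 0)
#' @keywords internal
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Content hash of an arbitrary R object
#'
#' Serializes the object to a temporary file (uncompressed, serialization
#' version 3) and returns its MD5 digest. Used for reproducibility checks,
#' leakage guards and artifact manifests.
#'
#' @param x any serializable R object.
#' @return length-1 character MD5 hash.
#' @export
hash_object <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 3L, compress = FALSE)
  unname(tools::md5sum(f))
}

#' MD5 hash of a file on disk
#' @param path file path.
#' @return length-1 character MD5 hash.
#' @export
hash_file <- function(path) {
  stopifnot(file.exists(path))
  unname(tools::md5sum(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- nested-list ("tree") parameter utilities --------------------------
# Model parameters live in nested lists with numeric arrays at the leaves.

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

# ---- Adam optimizer over parameter trees -------------------------------

adam_init <- function(params) {
  list(
    m = tree_map(function(p) p * 0, params),
    v = tree_map(function(p) p * 0, params),
    t = 0L
  )
}

# One Adam update; returns list(params, state). Operates leaf-by-leaf on
# the parameter tree so any architecture shares the same optimizer code.
# weight_decay is decoupled (AdamW) and applied to matrix-shaped leaves
# only — biases and LayerNorm vectors are never decayed.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step_leaf <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    if (weight_decay > 0 && !is.null(dim(p))) p <- p * (1 - lr * weight_decay)
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      ps <- p; ms <- m; vs <- v
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        ps[[i]] <- r$p; ms[[i]] <- r$m; vs[[i]] <- r$v
      }
      list(p = ps, m = ms, v = vs)
    } else {
      step_leaf(p, g, m, v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
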
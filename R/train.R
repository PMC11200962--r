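# Training loop: stratified splitting, minibatch Adam optimization of the
# binary cross-entropy, validation-based early stopping, reproducible
# seeding.

#' Training configuration
#'
#' Defaults are the full-size settings used for the clinical model
#' (learning rate 5e-6, batch 256, up to 200 epochs); scale them down for
#' small synthetic studies.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs (on validation loss);
#'   `Inf` disables early stopping.
#' @param seed RNG seed controlling shuffling, dropout and initialization
#'   order inside [train_model()].
#' @param class_weight `NULL` for unweighted loss, "inverse_prevalence"
#'   for minority upweighting, or a positive number used as the weight of
#'   positive samples.
#' @param weight_decay decoupled (AdamW-style) weight decay applied to
#'   matrix-shaped parameters; 0 disables it.
#' @param lr_schedule "constant", or "cosine" for cosine decay of the
#'   learning rate from its initial value to (near) zero over
#'   `max_epochs`.
#' @param split_fractions length-3 train/validation/test fractions summing
#'   to 1.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-6, batch_size = 256L,
                         max_epochs = 200L, patience = 20L, seed = 1L,
                         class_weight = NULL, weight_decay = 0,
                         lr_schedule = c("constant", "cosine"),
                         split_fractions = c(0.7, 0.15, 0.15)) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 0,
            weight_decay >= 0,
            length(split_fractions) == 3,
            abs(sum(split_fractions) - 1) < 1e-8)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = patience, seed = as.integer(seed),
                 class_weight = class_weight,
                 weight_decay = weight_decay,
                 lr_schedule = lr_schedule,
                 split_fractions = split_fractions),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Splits row indices into disjoint, exhaustive subsets whose class
#' proportions match the full data (largest-remainder allocation within
#' each class).
#'
#' @param y binary outcome vector, or an `encoded_dataset` (its first
#'   event column is used).
#' @param fractions length-3 non-negative fractions summing to 1.
#' @param seed RNG seed; identical seeds give identical splits.
#' @param event event name when `y` is an `encoded_dataset`.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(y, fractions = c(0.7, 0.15, 0.15), seed = 1L,
                          event = NULL) {
  if (inherits(y, "encoded_dataset")) {
    ev <- event %||% colnames(y$outcomes)[1]
    y <- y$outcomes[, ev]
  }
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, all(y %in% c(0, 1)))
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      rows <- sample(which(y == cls))
      k <- length(rows)
      base <- floor(fractions * k)
      rem <- k - sum(base)
      # largest remainder, ties resolved in train/val/test order
      frac_part <- fractions * k - base
      add <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
      base[add] <- base[add] + 1L
      cuts <- cumsum(base)
      idx$train <- c(idx$train, rows[seq_len(base[1])])
      if (base[2] > 0) idx$val <- c(idx$val, rows[(cuts[1] + 1):cuts[2]])
      if (base[3] > 0) idx$test <- c(idx$test, rows[(cuts[2] + 1):cuts[3]])
    }
  })
  idx <- lapply(idx, sort)
  n_min <- min(sum(y == 1), sum(y == 0))
  for (part in names(idx)) {
    rows <- idx[[part]]
    if (length(rows) > 0 && n_min > 0 &&
        (sum(y[rows] == 1) == 0 || sum(y[rows] == 0) == 0)) {
      stop("split '", part, "' received zero samples of one class; ",
           "use larger fractions or more data")
    }
  }
  idx
}

#' Train a gated tabular Transformer
#'
#' Minibatch Adam on the (optionally class-weighted) binary cross-entropy.
#' All parameters are updated, including the gate weights. After every
#' epoch the model is evaluated on the validation split; training stops
#' early when validation loss has not improved for `patience` epochs, and
#' the best-epoch weights are restored.
#'
#' @param model an initialized `gated_tab_model`.
#' @param train_set,val_set `encoded_dataset`s.
#' @param config a [train_config()].
#' @return list with `model` (trained, best-epoch weights) and `report`
#'   (class `train_report`: per-epoch train/validation loss and validation
#'   AUC, `best_epoch`, `checksum` of the final parameters).
#' @export
train_model <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "gated_tab_model"),
            inherits(train_set, "encoded_dataset"))
  ev <- model$event
  y_tr <- train_set$outcomes[, ev]
  y_va <- if (!is.null(val_set)) val_set$outcomes[, ev] else NULL
  w_tr <- .class_weights(y_tr, config$class_weight)
  cat_tr <- train_set$cat_codes[, model$meta$cat_cols, drop = FALSE]
  cont_tr <- train_set$cont_values[, model$meta$cont_cols, drop = FALSE]
  n <- length(y_tr)

  report <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), val_auc = numeric(0))
  best <- list(loss = Inf, epoch = 0L, params = model$params)
  opt <- adam_init(model$params)
  stale <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr_epoch <- if (identical(config$lr_schedule, "cosine")) {
        config$learning_rate * 0.5 *
          (1 + cos(pi * (epoch - 1) / max(config$max_epochs, 1L)))
      } else {
        config$learning_rate
      }
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, n)]
        if (length(rows) == 0L) {
          warning("empty minibatch skipped")
          next
        }
        fwd <- .forward_batch(model, cat_tr[rows, , drop = FALSE],
                              cont_tr[rows, , drop = FALSE],
                              training = TRUE, keep_cache = TRUE)
        ls <- .bce_loss(fwd$logit, y_tr[rows], w_tr[rows])
        if (!is.finite(ls$loss)) {
          stop("training loss became non-finite at epoch ", epoch,
               " (batch starting ", start, "); last loss = ", ls$loss)
        }
        if (config$learning_rate > 0) {
          grads <- .backward_batch(model, cat_tr[rows, , drop = FALSE],
                                   fwd, ls$dlogit)
          st <- adam_step(model$params, grads, opt, lr_epoch,
                          weight_decay = config$weight_decay %||% 0)
          model$params <- st$params
          opt <- st$state
        }
        ep_loss <- ep_loss + ls$loss * length(rows)
        ep_n <- ep_n + length(rows)
      }
      val_loss <- NA_real_; val_auc <- NA_real_
      if (!is.null(val_set) && length(y_va) > 0) {
        pv <- .forward_batch(model, val_set$cat_codes[, model$meta$cat_cols,
                                                      drop = FALSE],
                             val_set$cont_values[, model$meta$cont_cols,
                                                 drop = FALSE])
        val_loss <- .bce_loss(pv$logit, y_va)$loss
        val_auc <- if (length(unique(y_va)) == 2) {
          roc_auc(y_va, pv$prob)$auc
        } else NA_real_
      }
      report <- rbind(report, data.frame(
        epoch = epoch, train_loss = ep_loss / max(ep_n, 1L),
        val_loss = val_loss, val_auc = val_auc))
      track <- if (!is.na(val_loss)) val_loss else ep_loss / max(ep_n, 1L)
      if (track < best$loss - 1e-12) {
        best <- list(loss = track, epoch = epoch, params = model$params)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (is.finite(config$patience) && stale >= config$patience) break
      }
    }
  })
  if (best$epoch > 0L) model$params <- best$params
  rep <- structure(list(epochs = report,
                        best_epoch = best$epoch,
                        checksum = hash_object(model$params),
                        config = config),
                   class = "train_report")
  list(model = model, report = rep)
}

.class_weights <- function(y, class_weight) {
  if (is.null(class_weight)) return(rep(1, length(y)))
  w_pos <- if (identical(class_weight, "inverse_prevalence")) {
    mean(y == 0) / max(mean(y == 1), 1e-12)
  } else {
    stopifnot(is.numeric(class_weight), class_weight > 0)
    class_weight
  }
  ifelse(y == 1, w_pos, 1)
}

#' @export
print.train_report <- function(x, ...) {
  cat("<train_report> ", nrow(x$epochs), " epochs, best epoch ",
      x$best_epoch, "\n", sep = "")
  if (nrow(x$epochs)) {
    last <- x$epochs[nrow(x$epochs), ]
    cat(sprintf("  final: train loss %.4f, val loss %.4f, val AUC %.4f\n",
                last$train_loss, last$val_loss, last$val_auc))
  }
  invisible(x)
}

#' Predict adverse-event risk for a batch of records
#'
#' @param model a trained `gated_tab_model`.
#' @param records an `encoded_dataset` (or list with `cat_codes`,
#'   `cont_values`) conforming to the model's schema.
#' @param threshold probability cutoff; a record is called positive when
#'   its probability is greater than or equal to the threshold.
#' @return data.frame with `row_id`, `prob` and binary `call`.
#' @export
predict_risk <- function(model, records, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (inherits(records, "encoded_dataset") &&
      !is.null(model$meta$schema_hash) &&
      !identical(records$meta$schema_hash, model$meta$schema_hash)) {
    stop("schema mismatch: the model was trained under a different ",
         "feature schema than these records were encoded with")
  }
  out <- model_forward(model, records)
  data.frame(
    row_id = if (!is.null(records$row_ids)) records$row_ids
             else as.character(seq_along(out$prob)),
    prob = out$prob,
    call = as.integer(out$prob >= threshold))
}
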
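# End-to-end pipeline glue: merged YAML configuration with strict key
# validation, subcommand dispatch, and JSON manifests recording input
# hashes, configuration hash and seed for every artifact.

.default_config <- function() {
  list(
    cohort = list(n_records = 2000L,
                  group_sizes = c(basic = 8L, history = 31L, lab = 30L,
                                  followup = 25L, echo = 20L, angio = 20L),
                  events = c("ischemic", "bleeding", "infectious",
                             "febrile", "revascularization"),
                  prevalence = 0.13, n_main = 20L, beta_sd = 0.3,
                  n_interactions = 10L, gamma_sd = 0.3,
                  missing_rate = 0.03, outlier_rate = 0.005),
    preprocess = list(impute_numeric = "mean",
                      impute_categorical = "mode",
                      outlier_rule = "zscore", outlier_k = 3,
                      outlier_m = 1.5, holidays = character(0),
                      max_drop_fraction = 0.05),
    model = list(n_blocks = 6L, n_heads = 8L, embed_dim = 128L,
                 ffn_mult = 4L, dropout = 0.1, attention_dropout = 0.1,
                 addnorm_dropout = 0.1, embed_dropout = 0.1,
                 gate_enabled = TRUE,
                 gate_input_source = "layer_input", head_hidden = 128L),
    pretrain = list(enabled = FALSE, epochs = 200L, lr = 0.01),
    train = list(learning_rate = 5e-6, batch_size = 256L,
                 max_epochs = 200L, patience = 20L,
                 class_weight = NULL, weight_decay = 0,
                 lr_schedule = "constant",
                 split_fractions = c(0.7, 0.15, 0.15),
                 event = NULL),
    evaluate = list(threshold = 0.5),
    seed = 1L)
}

# strict recursive merge: keys absent from the defaults are rejected
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a pipeline run configuration
#'
#' Merges a YAML file over the package defaults; unknown keys are
#' rejected. With `path = NULL` the defaults are returned.
#'
#' @param path YAML file path or `NULL`.
#' @return nested configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

.write_manifest <- function(dir, subcommand, cfg, seed, inputs, outputs) {
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    config_hash = hash_object(unclass(cfg)),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (synthetic cohort), `preprocess` (stratified
#' split + fit/transform), `pretrain` (autoencoder embedding
#' pre-training), `train`, `evaluate`, `predict`. Each stage writes its
#' artifacts plus a `manifest.json` with input hashes, the configuration
#' hash and the seed, so every artifact is reproducible from its manifest.
#'
#' @param subcommand one of simulate, preprocess, pretrain, train,
#'   evaluate, predict.
#' @param config a `run_config` (see [read_run_config()]).
#' @param out output directory for the stage's artifacts.
#' @param data,schema paths to the raw cohort CSV and schema JSON
#'   (preprocess).
#' @param encoded directory produced by the preprocess stage (pretrain /
#'   train / evaluate / predict).
#' @param checkpoint checkpoint directory (evaluate / predict).
#' @param pretrained optional pretrain-stage directory consumed by train.
#' @param seed integer seed overriding `config$seed`.
#' @return invisibly, a list of the stage's main in-memory artifacts.
#' @export
run_pipeline <- function(subcommand = c("simulate", "preprocess",
                                        "pretrain", "train", "evaluate",
                                        "predict"),
                         config = read_run_config(), out,
                         data = NULL, schema = NULL, encoded = NULL,
                         checkpoint = NULL, pretrained = NULL,
                         seed = NULL) {
  subcommand <- match.arg(subcommand)
  seed <- as.integer(seed %||% config$seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      stop(subcommand, " requires ", what,
           if (!is.null(path)) paste0(" (not found: ", path, ")"))
    }
    path
  }

  if (subcommand == "simulate") {
    cc <- config$cohort
    spec <- cohort_spec(n_records = cc$n_records,
                        group_sizes = unlist(cc$group_sizes),
                        events = cc$events, prevalence = cc$prevalence,
                        n_main = cc$n_main, beta_sd = cc$beta_sd,
                        n_interactions = cc$n_interactions,
                        gamma_sd = cc$gamma_sd,
                        missing_rate = cc$missing_rate,
                        outlier_rate = cc$outlier_rate, seed = seed)
    cohort <- generate_cohort(spec, seed)
    paths <- write_cohort(cohort, out)
    .write_manifest(out, subcommand, config, seed, list(), paths)
    return(invisible(list(cohort = cohort)))
  }

  if (subcommand == "preprocess") {
    data <- need(data, "--data (cohort CSV)")
    schema_path <- need(schema, "--schema (schema JSON)")
    sc <- read_schema_json(schema_path)
    raw <- utils::read.csv(data, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "")
    for (nm in schema_columns(sc, "continuous")) {
      raw[[nm]] <- as.numeric(raw[[nm]])
    }
    for (ev in schema_columns(sc, "outcome")) {
      raw[[ev]] <- as.integer(raw[[ev]])
    }
    pc <- do.call(preprocess_config, config$preprocess)
    ev1 <- config$train$event %||% schema_columns(sc, "outcome")[1]
    idx <- split_dataset(raw[[ev1]], config$train$split_fractions, seed)
    state <- preprocess_fit(raw[idx$train, , drop = FALSE], sc, pc)
    outputs <- character(0)
    splits <- list()
    for (part in names(idx)) {
      if (length(idx[[part]]) == 0) next
      ed <- preprocess_transform(state, raw[idx[[part]], , drop = FALSE])
      splits[[part]] <- ed
      outputs <- c(outputs,
                   write_encoded_dataset(ed, file.path(out, part)))
    }
    st_path <- file.path(out, "preprocess_state.json")
    write_preprocess_state(state, st_path)
    saveRDS(splits, file.path(out, "splits.rds"), version = 3L)
    log_path <- file.path(out, "run_log.txt")
    writeLines(c(
      sprintf("train rows: %d", length(idx$train)),
      sprintf("val rows: %d", length(idx$val)),
      sprintf("test rows: %d", length(idx$test)),
      sprintf("outliers masked at fit: %d", state$n_outliers_fit),
      sprintf("cells imputed (train): %d", splits$train$log$n_imputed),
      sprintf("unknown categories (train): %d", splits$train$log$n_unknown)),
      log_path)
    .write_manifest(out, subcommand, config, seed,
                    list(data, schema_path),
                    c(outputs, st_path, log_path))
    return(invisible(list(state = state, splits = splits)))
  }

  if (subcommand == "pretrain") {
    enc_dir <- need(file.path(encoded %||% "", "splits.rds"),
                    "--encoded (preprocess output dir)")
    splits <- readRDS(enc_dir)
    pt <- pretrain_embeddings(splits$train,
                              dim = config$model$embed_dim,
                              epochs = config$pretrain$epochs,
                              lr = config$pretrain$lr, seed = seed)
    saveRDS(pt, file.path(out, "pretrained.rds"), version = 3L)
    jsonlite::write_json(as.list(pt$losses),
                         file.path(out, "pretrain_losses.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_manifest(out, subcommand, config, seed, list(enc_dir),
                    file.path(out, "pretrained.rds"))
    return(invisible(list(pretrained = pt)))
  }

  if (subcommand == "train") {
    enc_dir <- need(file.path(encoded %||% "", "splits.rds"),
                    "--encoded (preprocess output dir)")
    splits <- readRDS(enc_dir)
    cfg_m <- do.call(block_config, config$model)
    cfg_t <- do.call(train_config,
                     c(config$train[setdiff(names(config$train), "event")],
                       list(seed = seed)))
    emb <- NULL
    if (!is.null(pretrained)) {
      emb <- readRDS(need(file.path(pretrained, "pretrained.rds"),
                          "--pretrained dir"))$embeddings
    }
    ev <- config$train$event %||% splits$train$meta$events[1]
    model <- init_model(splits$train, cfg_m, seed = seed, event = ev,
                        embeddings = emb)
    fit <- train_model(model, splits$train, splits$val, cfg_t)
    save_checkpoint(fit$model, file.path(out, "checkpoint"))
    rep_path <- file.path(out, "train_report.jsonl")
    writeLines(vapply(seq_len(nrow(fit$report$epochs)), function(i) {
      jsonlite::toJSON(as.list(fit$report$epochs[i, ]), auto_unbox = TRUE,
                       digits = NA, na = "null")
    }, character(1)), rep_path)
    .write_manifest(out, subcommand, config, seed, list(enc_dir),
                    c(file.path(out, "checkpoint"), rep_path))
    return(invisible(fit))
  }

  if (subcommand == "evaluate") {
    enc_dir <- need(file.path(encoded %||% "", "splits.rds"),
                    "--encoded (preprocess output dir)")
    ckpt <- need(file.path(checkpoint %||% "", "manifest.json"),
                 "--checkpoint dir")
    splits <- readRDS(enc_dir)
    model <- load_checkpoint(dirname(ckpt))
    test <- splits$test %||% splits$train
    if (!identical(test$meta$schema_hash, model$meta$schema_hash)) {
      stop("schema mismatch between checkpoint and encoded data")
    }
    report <- evaluate_events(model, test,
                              threshold = config$evaluate$threshold)
    paths <- write_metrics_report(report, out)
    .write_manifest(out, subcommand, config, seed,
                    list(enc_dir, ckpt), paths)
    return(invisible(list(report = report)))
  }

  # predict
  enc_dir <- need(file.path(encoded %||% "", "splits.rds"),
                  "--encoded (preprocess output dir)")
  ckpt <- need(file.path(checkpoint %||% "", "manifest.json"),
               "--checkpoint dir")
  splits <- readRDS(enc_dir)
  model <- load_checkpoint(dirname(ckpt))
  test <- splits$test %||% splits$train
  preds <- predict_risk(model, test, config$evaluate$threshold)
  p_path <- file.path(out, "predictions.csv")
  utils::write.csv(preds, p_path, row.names = FALSE)
  .write_manifest(out, "predict", config, seed, list(enc_dir, ckpt),
                  p_path)
  invisible(list(predictions = preds))
}
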
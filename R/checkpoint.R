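# Model checkpointing: an archive of named numeric arrays (RDS) plus a
# JSON manifest describing configuration, schema fingerprint, seed and
# parameter shapes. Reloading reproduces forward outputs bit-for-bit.

#' Save a model checkpoint
#'
#' @param model a `gated_tab_model`.
#' @param dir checkpoint directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "gated_tab_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"), version = 3L)
  shapes <- tree_map(function(p) dim(p) %||% length(p), model$params)
  manifest <- list(
    format = "gatedtab-checkpoint-1",
    event = model$event,
    seed = model$seed,
    config = unclass(model$config),
    meta = list(cat_cols = model$meta$cat_cols,
                vocab_sizes = as.list(model$meta$vocab_sizes),
                cont_cols = model$meta$cont_cols,
                events = model$meta$events,
                schema_hash = model$meta$schema_hash),
    param_hash = hash_object(model$params),
    shapes = shapes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Load a model checkpoint
#'
#' Verifies the stored parameter hash before returning the model.
#'
#' @param dir directory written by [save_checkpoint()].
#' @return a `gated_tab_model`.
#' @export
load_checkpoint <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  w_path <- file.path(dir, "weights.rds")
  if (!file.exists(man_path) || !file.exists(w_path)) {
    stop("not a checkpoint directory: ", dir)
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  params <- readRDS(w_path)
  if (!identical(unname(hash_object(params)), unname(man$param_hash))) {
    stop("checkpoint weights do not match the manifest hash")
  }
  cfg <- do.call(block_config, man$config[names(man$config) %in%
                                            names(formals(block_config))])
  meta <- list(cat_cols = man$meta$cat_cols,
               vocab_sizes = unlist(man$meta$vocab_sizes),
               cont_cols = man$meta$cont_cols %||% character(0),
               events = man$meta$events,
               schema_hash = man$meta$schema_hash)
  structure(list(params = params, config = cfg, meta = meta,
                 event = man$event, seed = man$seed),
            class = "gated_tab_model")
}
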
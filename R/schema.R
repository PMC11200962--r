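# Feature schema: the typed description of an EHR feature table.

.roles <- c("categorical", "continuous", "datetime", "outcome")
.groups <- c("basic", "history", "lab", "followup", "echo", "angio")

#' Construct a feature schema
#'
#' A feature schema describes every column of a structured clinical feature
#' table: its name, its role (categorical, continuous, datetime or binary
#' outcome), the clinical category group it belongs to (basic information,
#' medical history, laboratory results, follow-up, echocardiography,
#' angiography), and — for categorical columns — the ordered category
#' vocabulary. Every categorical column additionally carries one reserved
#' "unknown" slot used for categories unseen at fit time.
#'
#' @param columns data.frame with character columns `name`, `role`, `group`.
#'   `group` may be `NA` for outcome columns.
#' @param vocabulary named list mapping each categorical column name to a
#'   non-empty character vector of categories (excluding the unknown slot).
#' @return object of class `feature_schema`.
#' @export
feature_schema <- function(columns, vocabulary = list()) {
  stopifnot(is.data.frame(columns),
            all(c("name", "role", "group") %in% names(columns)))
  columns <- data.frame(name = as.character(columns$name),
                        role = as.character(columns$role),
                        group = as.character(columns$group),
                        stringsAsFactors = FALSE)
  schema <- structure(list(columns = columns, vocabulary = vocabulary),
                      class = "feature_schema")
  validate_schema(schema)
  schema
}

#' Validate a feature schema
#'
#' Checks column-name uniqueness, role and group values, and that every
#' categorical column has a non-empty vocabulary.
#'
#' @param schema a `feature_schema`.
#' @return the schema, invisibly; errors on violation.
#' @export
validate_schema <- function(schema) {
  cols <- schema$columns
  if (anyDuplicated(cols$name)) {
    stop("duplicate column names in schema: ",
         paste(unique(cols$name[duplicated(cols$name)]), collapse = ", "))
  }
  if (!all(cols$role %in% .roles)) {
    stop("invalid roles: ",
         paste(setdiff(unique(cols$role), .roles), collapse = ", "))
  }
  feat <- cols[cols$role != "outcome", ]
  if (!all(feat$group %in% .groups)) {
    stop("invalid groups: ",
         paste(setdiff(unique(feat$group), .groups), collapse = ", "))
  }
  cat_cols <- cols$name[cols$role == "categorical"]
  for (nm in cat_cols) {
    v <- schema$vocabulary[[nm]]
    if (is.null(v) || length(v) == 0) {
      stop("categorical column '", nm, "' has no vocabulary")
    }
    if (anyDuplicated(v)) stop("duplicate vocabulary entries in '", nm, "'")
  }
  invisible(schema)
}

#' @export
print.feature_schema <- function(x, ...) {
  cols <- x$columns
  feat <- cols[cols$role != "outcome", ]
  cat("<feature_schema> ", nrow(feat), " feature columns, ",
      sum(cols$role == "outcome"), " outcome column(s)\n", sep = "")
  tab <- table(factor(feat$group, levels = .groups))
  cat("  groups: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  cat("  roles:  ", paste(sprintf("%s=%d", names(table(feat$role)),
                                  table(feat$role)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Convenience accessors ---------------------------------------------------

#' Names of schema columns with a given role
#' @param schema a `feature_schema`.
#' @param role one of "categorical", "continuous", "datetime", "outcome".
#' @return character vector of column names, in schema order.
#' @export
schema_columns <- function(schema, role) {
  stopifnot(role %in% .roles)
  schema$columns$name[schema$columns$role == role]
}

# vocabulary size including the reserved unknown slot
vocab_size <- function(schema, name) {
  length(schema$vocabulary[[name]]) + 1L
}

#' Fingerprint of the model-facing part of a schema
#'
#' Hash over feature names, roles and vocabulary sizes; checkpoints store it
#' so that a model is never applied to data encoded under a different schema.
#'
#' @param schema a `feature_schema`.
#' @return MD5 character hash.
#' @export
schema_fingerprint <- function(schema) {
  hash_object(list(schema$columns$name, schema$columns$role,
                   lapply(schema$vocabulary, length)))
}

# JSON persistence ---------------------------------------------------------

#' Write a schema to JSON
#' @param schema a `feature_schema`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schema_json <- function(schema, path) {
  obj <- list(columns = schema$columns, vocabulary = schema$vocabulary)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a schema from JSON
#' @param path JSON file written by [write_schema_json()].
#' @return a `feature_schema`.
#' @export
read_schema_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cols <- as.data.frame(obj$columns, stringsAsFactors = FALSE)
  vocab <- lapply(obj$vocabulary, as.character)
  feature_schema(cols, vocab)
}
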
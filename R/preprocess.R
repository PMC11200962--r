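# Leakage-safe preprocessing of mixed-type clinical feature tables.
#
# All statistics (means, standard deviations, min/max after z-scoring,
# imputation values, category code maps, outlier thresholds) are fitted on
# the training split only and frozen into a `preprocess_state`; transforming
# any other split reuses that state untouched.

#' Preprocessing configuration
#'
#' @param impute_numeric "mean" or "median" for continuous columns.
#' @param impute_categorical imputation for categorical columns; only
#'   "mode" is supported.
#' @param outlier_rule "zscore" or "iqr".
#' @param outlier_k z-score threshold (used when `outlier_rule = "zscore"`).
#' @param outlier_m IQR multiplier (used when `outlier_rule = "iqr"`).
#' @param holidays character vector of ISO dates flagged as holidays when
#'   expanding datetime columns.
#' @param max_drop_fraction largest missing fraction at which the
#'   `drop_rows` / `drop_column` imputation strategies are permitted.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(impute_numeric = "mean",
                              impute_categorical = "mode",
                              outlier_rule = "zscore",
                              outlier_k = 3,
                              outlier_m = 1.5,
                              holidays = character(0),
                              max_drop_fraction = 0.05) {
  stopifnot(impute_numeric %in% c("mean", "median"),
            impute_categorical == "mode",
            outlier_rule %in% c("zscore", "iqr"))
  structure(list(impute_numeric = impute_numeric,
                 impute_categorical = impute_categorical,
                 outlier_rule = outlier_rule, outlier_k = outlier_k,
                 outlier_m = outlier_m, holidays = as.character(holidays),
                 max_drop_fraction = max_drop_fraction),
            class = "preprocess_config")
}

# ---- single-column operations ------------------------------------------

#' Fit and apply continuous-column scaling
#'
#' Standardizes by subtracting the mean and dividing by the (population)
#' standard deviation, then min-max rescales the z-scores to \[0, 1\] using
#' the fitted split's extremes. Constant columns are flagged degenerate and
#' mapped to 0.5 everywhere.
#'
#' @param x numeric vector (the fitting split); may contain `NA`.
#' @return list with `values` (scaled column, `NA` preserved) and `state`
#'   (`mean`, `sd`, `post_z_min`, `post_z_max`, `degenerate`).
#' @export
fit_transform_numeric <- function(x) {
  if (length(x) == 0) stop("empty column")
  obs <- x[!is.na(x)]
  if (length(obs) == 0) stop("all-missing column")
  m <- mean(obs)
  s <- sd_pop(obs)
  if (s == 0) {
    warning("degenerate continuous column (sd = 0); mapped to 0.5")
    state <- list(mean = m, sd = 0, post_z_min = 0, post_z_max = 0,
                  degenerate = TRUE)
    values <- ifelse(is.na(x), NA_real_, 0.5)
    return(list(values = values, state = state))
  }
  z <- (x - m) / s
  zmin <- min(z, na.rm = TRUE)
  zmax <- max(z, na.rm = TRUE)
  state <- list(mean = m, sd = s, post_z_min = zmin, post_z_max = zmax,
                degenerate = FALSE)
  list(values = (z - zmin) / (zmax - zmin), state = state)
}

#' Apply a fitted continuous scaling to new data
#'
#' Uses the frozen statistics; values outside the fitting split's range map
#' outside \[0, 1\] (no clipping), which keeps the transform affine.
#'
#' @param x numeric vector.
#' @param state state from [fit_transform_numeric()].
#' @return scaled numeric vector.
#' @export
transform_numeric <- function(x, state) {
  if (isTRUE(state$degenerate)) return(ifelse(is.na(x), NA_real_, 0.5))
  z <- (x - state$mean) / state$sd
  (z - state$post_z_min) / (state$post_z_max - state$post_z_min)
}

#' Encode a categorical column against a fitted vocabulary
#'
#' Each category receives the 0-based integer position of its vocabulary
#' entry; values not in the vocabulary (including `NA`) receive the reserved
#' unknown code `length(vocab)`. Indicator rows carry exactly one 1 for
#' in-vocabulary values and all zeros for unknowns.
#'
#' @param x character vector of category values.
#' @param vocab ordered character vocabulary (without the unknown slot).
#' @return list with `codes` (integer, 0-based), `indicators`
#'   (length(x) x length(vocab) 0/1 matrix) and `n_unknown`.
#' @export
encode_categorical <- function(x, vocab) {
  stopifnot(length(vocab) >= 1)
  pos <- match(as.character(x), vocab)
  codes <- ifelse(is.na(pos), length(vocab), pos - 1L)
  ind <- matrix(0L, nrow = length(x), ncol = length(vocab),
                dimnames = list(NULL, vocab))
  inv <- which(!is.na(pos))
  ind[cbind(inv, pos[inv])] <- 1L
  list(codes = as.integer(codes), indicators = ind,
       n_unknown = sum(is.na(pos)))
}

#' Decode integer category codes back to labels
#'
#' @param codes 0-based integer codes from [encode_categorical()].
#' @param vocab the vocabulary used at encoding.
#' @return character vector; the unknown code decodes to `NA`.
#' @export
decode_categorical <- function(codes, vocab) {
  out <- rep(NA_character_, length(codes))
  inv <- codes >= 0 & codes < length(vocab)
  out[inv] <- vocab[codes[inv] + 1L]
  out
}

#' Extract calendar features from a datetime column
#'
#' @param x character or Date vector of ISO-8601 dates; unparseable entries
#'   become missing in every derived column.
#' @param holidays character vector of ISO dates to flag.
#' @return data.frame with columns `year`, `month`, `day`, `day_of_week`
#'   (0 = Monday ... 6 = Sunday) and `is_holiday` (0/1).
#' @export
extract_time_features <- function(x, holidays = character(0)) {
  d <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  lt <- as.POSIXlt(d)
  hol <- as.character(suppressWarnings(as.Date(as.character(holidays))))
  data.frame(
    year = lt$year + 1900L,
    month = lt$mon + 1L,
    day = lt$mday,
    day_of_week = (lt$wday + 6L) %% 7L,
    is_holiday = ifelse(is.na(d), NA_integer_,
                        as.integer(as.character(d) %in% hol))
  )
}

#' Trailing sliding-window aggregates of a time-ordered series
#'
#' The window includes the current observation and shrinks at the start of
#' the series, so every position produces an output.
#'
#' @param x numeric vector ordered in time.
#' @param window positive integer window length (default 3).
#' @param stats subset of `c("mean", "min", "max", "count")`; `count` is
#'   the number of non-missing values in the window.
#' @return data.frame with one column per statistic, named
#'   `roll_<stat>_<window>`.
#' @export
window_aggregate <- function(x, window = 3L,
                             stats = c("mean", "min", "max", "count")) {
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    stop("window must be a positive integer")
  }
  window <- as.integer(window)
  stats <- match.arg(stats, several.ok = TRUE)
  fns <- list(
    mean = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
    min = function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE),
    max = function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
    count = function(v) sum(!is.na(v))
  )
  out <- lapply(stats, function(s) {
    zoo::rollapplyr(x, width = window, FUN = fns[[s]], partial = TRUE)
  })
  names(out) <- paste0("roll_", stats, "_", window)
  as.data.frame(out)
}

#' Impute missing values in a single column
#'
#' The imputation value is computed from the supplied (fitting) data and
#' returned so it can be frozen into a preprocessing state.
#'
#' @param x vector with possible `NA`s.
#' @param strategy one of "mean", "median" (numeric only), "mode",
#'   "drop_rows", "drop_column". "model" (imputation by model
#'   predictions) is a reserved extension point and errors if selected.
#' @param vocab optional category vocabulary; mode ties on categorical data
#'   are broken by vocabulary order, numeric ties by sort order.
#' @param max_missing largest missing fraction at which the drop strategies
#'   are permitted.
#' @return list with `values` (imputed column; for `drop_rows` the retained
#'   entries plus a `kept` index; for `drop_column` `NULL`), `fill` (the
#'   frozen imputation value, if any) and `strategy`.
#' @export
impute_missing <- function(x, strategy = c("mean", "median", "mode",
                                           "drop_rows", "drop_column",
                                           "model"),
                           vocab = NULL, max_missing = 0.05) {
  strategy <- match.arg(strategy)
  if (strategy == "model") {
    stop("model-based imputation is an extension point and is not ",
         "implemented")
  }
  miss <- is.na(x)
  frac <- mean(miss)
  if (strategy %in% c("mean", "median") && !is.numeric(x)) {
    stop(strategy, " imputation requires a numeric column")
  }
  if (strategy %in% c("drop_rows", "drop_column") && frac > max_missing) {
    stop("missing fraction ", signif(frac, 3), " exceeds max_missing ",
         max_missing, " for strategy ", strategy)
  }
  if (strategy == "drop_rows") {
    return(list(values = x[!miss], kept = which(!miss), fill = NULL,
                strategy = strategy))
  }
  if (strategy == "drop_column") {
    return(list(values = NULL, fill = NULL, strategy = strategy))
  }
  obs <- x[!miss]
  if (length(obs) == 0) stop("all-missing column cannot be imputed")
  fill <- switch(strategy,
    mean = mean(obs),
    median = stats::median(obs),
    mode = {
      if (!is.null(vocab)) {
        counts <- vapply(vocab, function(v) sum(obs == v), integer(1))
        vocab[which.max(counts)]        # ties: first in vocabulary order
      } else {
        tab <- table(obs)
        u <- names(tab)[tab == max(tab)]
        if (is.numeric(x)) as.numeric(u)[1] else u[1]
      }
    })
  x[miss] <- fill
  list(values = x, fill = fill, strategy = strategy)
}

#' Flag outlying values in a continuous column
#'
#' @param x numeric vector.
#' @param rule "zscore" (|z| > k, population sd) or "iqr" (outside
#'   \[Q1 - m*IQR, Q3 + m*IQR\]).
#' @param k z-score threshold.
#' @param m IQR multiplier.
#' @return logical mask, `TRUE` for flagged values (`NA`s are never
#'   flagged). Constant columns flag nothing.
#' @export
flag_outliers <- function(x, rule = c("zscore", "iqr"), k = 3, m = 1.5) {
  rule <- match.arg(rule)
  mask <- rep(FALSE, length(x))
  obs <- !is.na(x)
  if (!any(obs)) return(mask)
  if (rule == "zscore") {
    mu <- mean(x[obs]); s <- sd_pop(x[obs])
    if (s == 0) return(mask)
    mask[obs] <- abs(x[obs] - mu) / s > k
  } else {
    q <- stats::quantile(x[obs], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - m * iqr; hi <- q[2] + m * iqr
    mask[obs] <- x[obs] < lo | x[obs] > hi
  }
  mask
}

# raw-unit acceptance interval of the outlier rule on the fitting data;
# frozen into the state so fit and transform mask exactly the same cells
.outlier_bounds <- function(x, rule, k, m) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0) return(c(-Inf, Inf))
  if (rule == "zscore") {
    s <- sd_pop(obs)
    if (s == 0) return(c(-Inf, Inf))
    mu <- mean(obs)
    c(mu - k * s, mu + k * s)
  } else {
    q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    c(q[1] - m * iqr, q[2] + m * iqr)
  }
}

# ---- pipeline: fit on the training split, transform any split ----------

# Expand datetime columns into derived feature columns and return the
# widened data plus the derived schema entries. Derived year/month/day are
# continuous; day-of-week and holiday flags are categorical.
.expand_datetime <- function(data, schema, holidays) {
  dt_cols <- schema_columns(schema, "datetime")
  cols <- schema$columns
  vocab <- schema$vocabulary
  for (nm in dt_cols) {
    tf <- extract_time_features(data[[nm]], holidays)
    base <- paste0(nm, "_", c("year", "month", "day"))
    for (i in 1:3) data[[base[i]]] <- as.numeric(tf[[i]])
    dow_nm <- paste0(nm, "_day_of_week")
    hol_nm <- paste0(nm, "_is_holiday")
    data[[dow_nm]] <- ifelse(is.na(tf$day_of_week), NA_character_,
                             as.character(tf$day_of_week))
    data[[hol_nm]] <- ifelse(is.na(tf$is_holiday), NA_character_,
                             as.character(tf$is_holiday))
    grp <- cols$group[cols$name == nm]
    add <- data.frame(
      name = c(base, dow_nm, hol_nm),
      role = c(rep("continuous", 3), "categorical", "categorical"),
      group = grp, stringsAsFactors = FALSE)
    cols <- rbind(cols, add)
    vocab[[dow_nm]] <- as.character(0:6)
    vocab[[hol_nm]] <- c("0", "1")
  }
  cols <- cols[!(cols$name %in% dt_cols), ]
  list(data = data, schema = feature_schema(cols, vocab))
}

#' Fit the preprocessing pipeline on training data
#'
#' Expands datetime columns into calendar features, masks outliers in
#' continuous columns (set missing, then imputed), freezes imputation
#' values, category code maps and scaling statistics. Outcome columns must
#' be complete 0/1.
#'
#' @param data raw feature data.frame (training split only).
#' @param schema the `feature_schema` describing `data`.
#' @param config a [preprocess_config()].
#' @return object of class `preprocess_state`.
#' @export
preprocess_fit <- function(data, schema, config = preprocess_config()) {
  validate_schema(schema)
  ex <- .expand_datetime(data, schema, config$holidays)
  wdata <- ex$data; wschema <- ex$schema
  cont_cols <- schema_columns(wschema, "continuous")
  cat_cols <- schema_columns(wschema, "categorical")

  cont_state <- list()
  n_flagged <- 0L
  for (nm in cont_cols) {
    x <- as.numeric(wdata[[nm]])
    bounds <- .outlier_bounds(x, config$outlier_rule,
                              config$outlier_k, config$outlier_m)
    mask <- !is.na(x) & (x < bounds[1] | x > bounds[2])
    x[mask] <- NA
    n_flagged <- n_flagged + sum(mask)
    imp <- impute_missing(x, config$impute_numeric)
    ft <- fit_transform_numeric(imp$values)
    cont_state[[nm]] <- c(ft$state,
                          list(fill = imp$fill,
                               accept_lo = bounds[1], accept_hi = bounds[2]))
  }
  cat_state <- list()
  for (nm in cat_cols) {
    x <- as.character(wdata[[nm]])
    imp <- impute_missing(x, "mode", vocab = wschema$vocabulary[[nm]],
                          max_missing = 1)
    cat_state[[nm]] <- list(fill = imp$fill,
                            vocab = wschema$vocabulary[[nm]])
  }
  for (ev in schema_columns(schema, "outcome")) {
    y <- wdata[[ev]]
    if (anyNA(y) || !all(y %in% c(0, 1))) {
      stop("outcome column '", ev, "' must be complete 0/1")
    }
  }
  structure(list(schema = schema, expanded_schema = wschema,
                 config = config,
                 continuous = cont_state, categorical = cat_state,
                 n_train_rows = nrow(data), n_outliers_fit = n_flagged),
            class = "preprocess_state")
}

#' Transform a feature table with a fitted preprocessing state
#'
#' Applies the frozen statistics from [preprocess_fit()] to any split; the
#' state is never updated. The result has no missing values.
#'
#' @param state a `preprocess_state`.
#' @param data raw feature data.frame conforming to the fitted schema.
#' @return object of class `encoded_dataset`: `cat_codes` (0-based integer
#'   matrix), `cont_values` (numeric matrix, in \[0,1\] on the fitting
#'   split), `outcomes` (0/1 matrix), `row_ids`, `meta` (column names and
#'   vocabulary sizes including the unknown slot) and a `log` of imputed /
#'   flagged / unknown cell counts.
#' @export
preprocess_transform <- function(state, data) {
  stopifnot(inherits(state, "preprocess_state"))
  schema <- state$schema
  missing_cols <- setdiff(
    schema$columns$name[schema$columns$role != "outcome"], names(data))
  if (length(missing_cols)) {
    stop("data lacks schema columns: ", paste(missing_cols, collapse = ", "))
  }
  ex <- .expand_datetime(data, schema, state$config$holidays)
  wdata <- ex$data
  cont_cols <- names(state$continuous)
  cat_cols <- names(state$categorical)
  n <- nrow(wdata)

  log <- list(n_imputed = 0L, n_outliers = 0L, n_unknown = 0L)
  cont <- matrix(NA_real_, n, length(cont_cols),
                 dimnames = list(NULL, cont_cols))
  for (nm in cont_cols) {
    st <- state$continuous[[nm]]
    x <- as.numeric(wdata[[nm]])
    # frozen acceptance interval from the fitting split
    mask <- !is.na(x) & (x < st$accept_lo | x > st$accept_hi)
    x[mask] <- NA
    log$n_outliers <- log$n_outliers + sum(mask)
    nmiss <- sum(is.na(x))
    x[is.na(x)] <- st$fill
    log$n_imputed <- log$n_imputed + nmiss
    cont[, nm] <- transform_numeric(x, st)
  }
  cat_codes <- matrix(NA_integer_, n, length(cat_cols),
                      dimnames = list(NULL, cat_cols))
  for (nm in cat_cols) {
    st <- state$categorical[[nm]]
    x <- as.character(wdata[[nm]])
    nmiss <- sum(is.na(x))
    x[is.na(x)] <- st$fill
    log$n_imputed <- log$n_imputed + nmiss
    enc <- encode_categorical(x, st$vocab)
    log$n_unknown <- log$n_unknown + enc$n_unknown
    cat_codes[, nm] <- enc$codes
  }
  events <- schema_columns(schema, "outcome")
  outcomes <- matrix(NA_real_, n, length(events),
                     dimnames = list(NULL, events))
  for (ev in events) outcomes[, ev] <- as.numeric(wdata[[ev]])

  structure(list(
    cat_codes = cat_codes, cont_values = cont, outcomes = outcomes,
    row_ids = if ("record_id" %in% names(data)) as.character(data$record_id)
              else as.character(seq_len(n)),
    meta = list(cat_cols = cat_cols,
                vocab_sizes = vapply(state$categorical,
                                     function(s) length(s$vocab) + 1L,
                                     integer(1)),
                vocabs = lapply(state$categorical, function(s) s$vocab),
                cont_cols = cont_cols, events = events,
                schema_hash = schema_fingerprint(state$expanded_schema)),
    log = log), class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("<encoded_dataset> ", nrow(x$cat_codes), " rows, ",
      ncol(x$cat_codes), " categorical + ", ncol(x$cont_values),
      " continuous columns, events: ",
      paste(colnames(x$outcomes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset an encoded dataset by row index
#' @param ed an `encoded_dataset`.
#' @param idx integer row indices.
#' @return an `encoded_dataset` restricted to `idx`.
#' @export
encoded_subset <- function(ed, idx) {
  out <- ed
  out$cat_codes <- ed$cat_codes[idx, , drop = FALSE]
  out$cont_values <- ed$cont_values[idx, , drop = FALSE]
  out$outcomes <- ed$outcomes[idx, , drop = FALSE]
  out$row_ids <- ed$row_ids[idx]
  out
}

#' Persist an encoded dataset as a CSV pair plus outcomes
#' @param ed an `encoded_dataset`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_encoded_dataset <- function(ed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cat = file.path(dir, "cat_codes.csv"),
             cont = file.path(dir, "cont_values.csv"),
             out = file.path(dir, "outcomes.csv"))
  utils::write.csv(data.frame(row_id = ed$row_ids, ed$cat_codes,
                              check.names = FALSE),
                   paths[["cat"]], row.names = FALSE)
  utils::write.csv(data.frame(row_id = ed$row_ids, ed$cont_values,
                              check.names = FALSE),
                   paths[["cont"]], row.names = FALSE)
  utils::write.csv(data.frame(row_id = ed$row_ids, ed$outcomes,
                              check.names = FALSE),
                   paths[["out"]], row.names = FALSE)
  invisible(paths)
}

#' Write a fitted preprocessing state to JSON
#' @param state a `preprocess_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_state <- function(state, path) {
  obj <- list(
    config = unclass(state$config),
    continuous = state$continuous,
    categorical = state$categorical,
    n_train_rows = state$n_train_rows,
    n_outliers_fit = state$n_outliers_fit,
    schema = list(columns = state$schema$columns,
                  vocabulary = state$schema$vocabulary))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
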
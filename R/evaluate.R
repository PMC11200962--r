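# Imbalanced-classification evaluation: confusion matrices,
# precision/recall/F1, ROC/AUC and PR/AP, per adverse event.
#
# Conventions (fixed across the package): a record is called positive when
# its probability is >= the threshold; tied scores receive half credit in
# the AUC (Mann-Whitney estimator), which the trapezoidal ROC area matches
# exactly; average precision is the step-wise, non-interpolated sum.

#' Confusion matrix at a probability threshold
#'
#' @param y_true binary 0/1 vector.
#' @param y_prob probability (or score) vector of equal length.
#' @param threshold cutoff in \[0, 1\]; positive call iff
#'   `y_prob >= threshold`.
#' @return list of class `confusion_matrix` with integer `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) == 0) stop("empty input")
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% c(0, 1)),
            threshold >= 0, threshold <= 1)
  call <- y_prob >= threshold
  structure(list(TP = sum(call & y_true == 1),
                 FP = sum(call & y_true == 0),
                 FN = sum(!call & y_true == 1),
                 TN = sum(!call & y_true == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP=", x$TP, " FP=", x$FP,
      " FN=", x$FN, " TN=", x$TN, "\n", sep = "")
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2*precision*recall/(precision+recall)`. A zero denominator yields
#' 0 with a warning, so batch evaluation never aborts.
#'
#' @param cm a `confusion_matrix` (or list with TP/FP/FN/TN).
#' @return named list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm) {
  stopifnot(all(c("TP", "FP", "FN") %in% names(cm)))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator in ", what, "; returning 0")
      0
    } else num / den
  }
  precision <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  recall <- safe_div(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- if (precision + recall == 0) {
    warning("zero denominator in F1; returning 0")
    0
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' ROC curve and area under it
#'
#' The curve is traced over all distinct score thresholds; the area is
#' computed by the trapezoidal rule, which equals the
#' probability-of-correct-ranking (Mann-Whitney) estimator with ties
#' counted half.
#'
#' @param y_true binary 0/1 vector containing both classes.
#' @param y_prob score vector.
#' @return list of class `curve_report` with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% c(0, 1)))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes in y_true")
  }
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_prob[ord]
  # cumulative counts at the boundary after each distinct-score group
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  points <- data.frame(threshold = c(Inf, s[last_of_group]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, kind = "roc"),
            class = "curve_report")
}

#' Precision-recall curve and average precision
#'
#' Points are produced at every distinct score threshold; average
#' precision is the step-wise estimator
#' `AP = sum_k (R_k - R_{k-1}) * P_k` with no interpolation.
#'
#' @param y_true binary 0/1 vector with at least one positive.
#' @param y_prob score vector.
#' @return list of class `curve_report` with `points` (data.frame
#'   `threshold`, `recall`, `precision`) and `ap`.
#' @export
pr_ap <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% c(0, 1)))
  n_pos <- sum(y_true == 1)
  if (n_pos == 0) stop("PR curve requires at least one positive sample")
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_prob[ord]
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last_of_group]
  k <- last_of_group            # predictions called positive at threshold
  precision <- tp / k
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  points <- data.frame(threshold = s[last_of_group],
                       recall = recall, precision = precision)
  structure(list(points = points, ap = ap, kind = "pr"),
            class = "curve_report")
}

#' @export
print.curve_report <- function(x, ...) {
  if (x$kind == "roc") {
    cat("<curve_report> ROC, ", nrow(x$points), " points, AUC = ",
        sprintf("%.4f", x$auc), "\n", sep = "")
  } else {
    cat("<curve_report> PR, ", nrow(x$points), " points, AP = ",
        sprintf("%.4f", x$ap), "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate trained models on a test split, per adverse event
#'
#' @param models a single `gated_tab_model` or a named list of models, one
#'   per event.
#' @param test_set an `encoded_dataset`.
#' @param events event names to evaluate; defaults to the events the
#'   models were trained for.
#' @param threshold probability cutoff for the confusion matrix.
#' @return object of class `metrics_report`: per event a list with
#'   `confusion`, `precision`, `recall`, `f1`, `auc`, `ap`, `roc`
#'   (curve), `pr` (curve), `n`.
#' @export
evaluate_events <- function(models, test_set, events = NULL,
                            threshold = 0.5) {
  if (inherits(models, "gated_tab_model")) {
    models <- stats::setNames(list(models), models$event)
  }
  events <- events %||% names(models)
  missing_ev <- setdiff(events, colnames(test_set$outcomes))
  if (length(missing_ev)) {
    stop("events absent from outcomes: ", paste(missing_ev, collapse = ", "))
  }
  out <- list()
  for (ev in events) {
    model <- models[[ev]]
    if (is.null(model)) stop("no model supplied for event '", ev, "'")
    y <- test_set$outcomes[, ev]
    p <- model_forward(model, test_set)$prob
    cm <- confusion(y, p, threshold)
    prf <- precision_recall_f1(cm)
    roc <- roc_auc(y, p)
    pr <- pr_ap(y, p)
    out[[ev]] <- list(confusion = cm, precision = prf$precision,
                      recall = prf$recall, f1 = prf$f1,
                      auc = roc$auc, ap = pr$ap, roc = roc, pr = pr,
                      n = length(y))
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (ev in names(x)) {
    m <- x[[ev]]
    cat(sprintf("  %-18s AUC %.3f  AP %.3f  P %.3f  R %.3f  F1 %.3f\n",
                ev, m$auc, m$ap, m$precision, m$recall, m$f1))
  }
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the scalar metrics and confusion matrices as JSON, and each
#' event's ROC and PR curves as 2-column TSV files.
#'
#' @param report a `metrics_report`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- lapply(report, function(m) {
    list(confusion = unclass(m$confusion), precision = m$precision,
         recall = m$recall, f1 = m$f1, auc = m$auc, ap = m$ap, n = m$n)
  })
  paths <- file.path(dir, "metrics.json")
  jsonlite::write_json(scalars, paths, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (ev in names(report)) {
    roc_p <- file.path(dir, paste0("roc_", ev, ".tsv"))
    pr_p <- file.path(dir, paste0("pr_", ev, ".tsv"))
    utils::write.table(report[[ev]]$roc$points[, c("fpr", "tpr")], roc_p,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(report[[ev]]$pr$points[, c("recall", "precision")],
                       pr_p, sep = "\t", row.names = FALSE, quote = FALSE)
    cm <- report[[ev]]$confusion
    utils::write.csv(data.frame(TP = cm$TP, FP = cm$FP, FN = cm$FN,
                                TN = cm$TN),
                     file.path(dir, paste0("confusion_", ev, ".csv")),
                     row.names = FALSE)
    paths <- c(paths, roc_p, pr_p)
  }
  invisible(paths)
}
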
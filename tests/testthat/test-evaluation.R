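# Imbalanced-classification metrics: confusion, P/R/F1, ROC/AUC, PR/AP.

# brute-force rank-statistic AUC: share of correctly ordered
# positive/negative pairs, ties counted half
auc_rank_oracle <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# brute-force stepwise average precision over descending distinct scores
ap_oracle <- function(y, p) {
  ths <- sort(unique(p), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (t in ths) {
    call <- p >= t
    prec <- sum(y[call]) / sum(call)
    rec <- sum(y[call]) / sum(y)
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

test_that("confusion counts follow the prob >= threshold convention", {
  cm <- confusion(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1), 0.5)
  expect_equal(unclass(cm)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion(c(1, 0, 1), c(0.99, 0.01, 0.98), 0.5)
  expect_equal(perfect$FP + perfect$FN, 0L)
  expect_error(confusion(numeric(0), numeric(0)), "empty")

  # a probability exactly at the threshold is called positive
  expect_equal(confusion(1, 0.5, 0.5)$TP, 1L)
})

test_that("precision, recall and F1 match direct arithmetic", {
  # the reported test-cohort confusion counts of the ungated model
  cm <- list(TP = 1099, FP = 49, FN = 164, TN = 140)
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 1452)
  out <- precision_recall_f1(cm)
  p <- 1099 / (1099 + 49)
  r <- 1099 / (1099 + 164)
  expect_equal(out$precision, p, tolerance = 1e-12)
  expect_equal(out$recall, r, tolerance = 1e-12)
  expect_equal(out$f1, 2 * p * r / (p + r), tolerance = 1e-12)

  w <- capture_warnings(z <- precision_recall_f1(list(TP = 0, FP = 0,
                                                      FN = 3, TN = 5)))
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
  ideal <- precision_recall_f1(list(TP = 10, FP = 0, FN = 0, TN = 5))
  expect_equal(unlist(ideal), c(precision = 1, recall = 1, f1 = 1))
})

test_that("F1 obeys its harmonic-mean bounds on random confusion matrices", {
  set.seed(31)
  for (i in 1:50) {
    cm <- list(TP = sample(1:50, 1), FP = sample(1:50, 1),
               FN = sample(1:50, 1), TN = sample(1:50, 1))
    out <- precision_recall_f1(cm)
    lo <- min(out$precision, out$recall)
    expect_lte(out$f1, 2 * lo / (1 + lo) + 1e-12)
    expect_lte(out$f1, sqrt(out$precision * out$recall) + 1e-12)
    expect_gte(out$f1, 0)
  }
})

test_that("trapezoidal AUC equals the tie-aware rank statistic exactly", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(17)
  for (i in 1:20) {
    n <- 200
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)          # rounding forces ties
    r <- roc_auc(y, p)
    expect_equal(r$auc, auc_rank_oracle(y, p), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- rbinom(150, 1, 0.4)
  p <- runif(150)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, p, direction = "<", levels = c(0, 1),
                        quiet = TRUE))))
  expect_equal(roc_auc(y, p)$auc, ref, tolerance = 1e-10)
})

test_that("average precision is the stepwise sum over thresholds", {
  expect_equal(pr_ap(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$ap, 1)
  # 4-point hand enumeration: thresholds 0.9, 0.8, 0.7, 0.6
  r <- pr_ap(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(r$ap, 0.5 * 1 + 0 + 0.5 * (2 / 3) + 0, tolerance = 1e-12)
  # reversed perfect ranking, against the enumeration oracle
  yrev <- c(0, 0, 1, 1); prev_ <- c(0.9, 0.8, 0.2, 0.1)
  expect_equal(pr_ap(yrev, prev_)$ap, ap_oracle(yrev, prev_),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    y <- rbinom(80, 1, 0.25)
    if (sum(y) == 0) next
    p <- round(runif(80), 2)
    expect_equal(pr_ap(y, p)$ap, ap_oracle(y, p), tolerance = 1e-12)
  }
  expect_error(pr_ap(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("raising the threshold never increases TP or FP", {
  set.seed(53)
  y <- rbinom(100, 1, 0.3)
  p <- runif(100)
  prev_cm <- confusion(y, p, 0)
  for (t in seq(0.1, 1, by = 0.1)) {
    cm <- confusion(y, p, t)
    expect_lte(cm$TP, prev_cm$TP)
    expect_lte(cm$FP, prev_cm$FP)
    prev_cm <- cm
  }
})

test_that("event evaluation reports one consistent block per event", {
  cohort <- tiny_cohort(n = 250L)
  enc <- encode_cohort(cohort)
  m <- init_model(enc$splits$train, tiny_config(), seed = 6L)
  rep <- suppressWarnings(evaluate_events(m, enc$splits$test,
                                          threshold = 0.5))
  expect_s3_class(rep, "metrics_report")
  expect_named(rep, "mace")
  blk <- rep$mace
  for (v in c("precision", "recall", "f1", "auc", "ap")) {
    expect_gte(blk[[v]], 0); expect_lte(blk[[v]], 1)
  }
  # metrics recomputed from the exported confusion matrix agree
  back <- suppressWarnings(precision_recall_f1(blk$confusion))
  expect_equal(back$precision, blk$precision)
  expect_equal(back$recall, blk$recall)
  expect_equal(back$f1, blk$f1)
  expect_error(evaluate_events(m, enc$splits$test, events = "nope"),
               "absent")

  dir <- file.path(tempdir(), "metrics-test")
  write_metrics_report(rep, dir)
  expect_true(file.exists(file.path(dir, "metrics.json")))
  expect_true(file.exists(file.path(dir, "roc_mace.tsv")))
  unlink(dir, recursive = TRUE)
})

test_that("multi-event evaluation produces one block per requested event", {
  cohort <- tiny_cohort(n = 220L, events = c("ischemic", "bleeding"),
                        prevalence = c(0.2, 0.3))
  enc <- encode_cohort(cohort)
  models <- list(
    ischemic = init_model(enc$splits$train, tiny_config(), seed = 1L,
                          event = "ischemic"),
    bleeding = init_model(enc$splits$train, tiny_config(), seed = 2L,
                          event = "bleeding"))
  rep <- suppressWarnings(evaluate_events(models, enc$splits$test))
  expect_named(rep, c("ischemic", "bleeding"))
  expect_error(suppressWarnings(
    evaluate_events(models["ischemic"], enc$splits$test,
                    events = c("ischemic", "bleeding"))), "no model")
})

test_that("the generating risk score dominates a permutation null", {
  cohort <- tiny_cohort(n = 600L, seed = 13L)
  y <- cohort$data$mace
  score <- cohort$truth$mace$eta
  obs <- roc_auc(y, stats::plogis(score))$auc
  set.seed(77)
  null_auc <- replicate(200, roc_auc(sample(y), stats::plogis(score))$auc)
  # planted-signal AUC beyond the null distribution at p < 0.01
  expect_gt(obs, quantile(null_auc, 0.99))
})
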
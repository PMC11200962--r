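# Synthetic EHR cohort generator.

test_that("the default schema reproduces the six-group clinical layout", {
  schema <- make_schema(cohort_spec())
  feat <- schema$columns[schema$columns$role != "outcome", ]
  expect_equal(nrow(feat), 134L)
  counts <- table(factor(feat$group, levels = c("basic", "history", "lab",
                                                "followup", "echo",
                                                "angio")))
  expect_equal(unname(c(counts)), c(8L, 31L, 30L, 25L, 20L, 20L))
  # exactly one admission-date column, in the basic group
  expect_equal(schema$columns$name[schema$columns$role == "datetime"],
               "basic_1")
  # categorical cardinalities stay within 2..10
  sizes <- lengths(schema$vocabulary)
  expect_true(all(sizes >= 2 & sizes <= 10))

  small <- make_schema(cohort_spec(group_sizes = stats::setNames(
    rep(1L, 6), c("basic", "history", "lab", "followup", "echo", "angio"))))
  expect_equal(sum(small$columns$role != "outcome"), 6L)

  expect_identical(hash_object(make_schema(cohort_spec())),
                   hash_object(schema))
})

test_that("cohorts are reproducible and empty cohorts keep their schema", {
  spec <- cohort_spec(n_records = 80L, seed = 5L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(hash_object(a), hash_object(b))
  c2 <- generate_cohort(spec, seed = 6L)
  expect_false(identical(hash_object(a), hash_object(c2)))

  e <- generate_cohort(cohort_spec(n_records = 0L))
  expect_equal(nrow(e$data), 0L)
  expect_equal(sum(e$schema$columns$role != "outcome"), 134L)
})

test_that("marginal prevalence and missingness match their targets", {
  spec <- cohort_spec(n_records = 6000L, events = "mace", prevalence = 0.13,
                      group_sizes = c(basic = 2L, history = 4L, lab = 4L,
                                      followup = 2L, echo = 2L, angio = 2L),
                      missing_rate = 0.03, outlier_rate = 0, seed = 11L)
  cohort <- generate_cohort(spec)
  # exact binomial 99% band around the target prevalence
  n <- spec$n_records
  band <- qbinom(c(0.005, 0.995), n, 0.13) / n
  expect_gte(mean(cohort$data$mace), band[1])
  expect_lte(mean(cohort$data$mace), band[2])

  feat <- cohort$schema$columns$name[cohort$schema$columns$role != "outcome"]
  miss <- mean(is.na(as.matrix(cohort$data[, feat])))
  expect_lt(abs(miss - 0.03), 0.005)
})

test_that("null-signal cohorts carry no discriminative information", {
  spec <- cohort_spec(n_records = 1500L, events = "mace",
                      group_sizes = c(basic = 1L, history = 2L, lab = 2L,
                                      followup = 1L, echo = 1L, angio = 1L),
                      n_main = 0L, n_interactions = 0L,
                      missing_rate = 0, outlier_rate = 0, seed = 17L)
  cohort <- generate_cohort(spec)
  chk <- planted_signal_check(cohort)
  # rank-statistic standard error (Hanley-McNeil at AUC = 0.5)
  n1 <- sum(cohort$data$mace); n0 <- nrow(cohort$data) - n1
  se <- sqrt((n0 + n1 + 1) / (12 * n0 * n1))
  expect_lt(abs(chk$auc - 0.5), 2.58 * se)
})

test_that("strong planted signal yields a high oracle AUC", {
  spec <- cohort_spec(n_records = 2500L, events = "mace",
                      group_sizes = c(basic = 2L, history = 4L, lab = 6L,
                                      followup = 2L, echo = 4L, angio = 2L),
                      n_main = 12L, beta_sd = 1.5, n_interactions = 8L,
                      gamma_sd = 1.2, missing_rate = 0, outlier_rate = 0,
                      seed = 19L)
  cohort <- generate_cohort(spec)
  expect_gt(planted_signal_check(cohort)$auc, 0.9)
})

test_that("interaction-bearing cohorts defeat a main-effects-only model", {
  # across seeds, a logistic fit on main effects only scores strictly
  # below the full generating risk score
  for (seed in c(31L, 32L, 33L)) {
    spec <- cohort_spec(n_records = 2000L, events = "mace",
                        group_sizes = c(basic = 1L, history = 4L, lab = 4L,
                                        followup = 1L, echo = 2L,
                                        angio = 2L),
                        n_main = 5L, beta_sd = 0.6, n_interactions = 8L,
                        gamma_sd = 1.5, missing_rate = 0, outlier_rate = 0,
                        seed = seed)
    cohort <- generate_cohort(spec)
    enc <- encode_cohort(cohort, fractions = c(0.7, 0, 0.3), seed = seed)
    tr <- enc$splits$train; te <- enc$splits$test
    design <- function(ed) {
      X <- ed$cont_values
      for (nm in ed$meta$cat_cols) {
        f <- factor(ed$cat_codes[, nm],
                    levels = 0:(ed$meta$vocab_sizes[[nm]] - 1L))
        X <- cbind(X, stats::model.matrix(~f)[, -1, drop = FALSE])
      }
      X
    }
    Xtr <- design(tr); Xte <- design(te)
    keep <- apply(Xtr, 2, stats::sd) > 0
    fit <- suppressWarnings(stats::glm.fit(cbind(1, Xtr[, keep]),
                                           tr$outcomes[, 1],
                                           family = stats::binomial()))
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
    auc_main <- roc_auc(te$outcomes[, 1],
                        drop(cbind(1, Xte[, keep]) %*% coef))$auc
    auc_oracle <- roc_auc(cohort$data$mace[enc$idx$test],
                          cohort$truth$mace$eta[enc$idx$test])$auc
    expect_lt(auc_main, auc_oracle)
  }
})

test_that("cohort files round-trip through the plain-text formats", {
  cohort <- tiny_cohort(n = 60L)
  dir <- file.path(tempdir(), "cohort-out")
  paths <- write_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["data"]], stringsAsFactors = FALSE,
                          na.strings = "")
  expect_equal(nrow(back), 60L)
  schema2 <- read_schema_json(paths[["schema"]])
  expect_identical(schema2$columns, cohort$schema$columns)
  unlink(dir, recursive = TRUE)
})
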
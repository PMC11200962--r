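# Leakage-safe preprocessing of mixed-type clinical tables.

test_that("continuous scaling z-scores then min-max rescales to [0,1]", {
  r <- fit_transform_numeric(c(1, 2, 3))
  expect_equal(r$values, c(0, 0.5, 1))
  expect_equal(r$state$mean, 2)
  expect_equal(r$state$sd, sqrt(2 / 3))   # population sd

  # a value equal to the column mean has z-score 0, which lands inside [0,1]
  mid <- (0 - r$state$post_z_min) / (r$state$post_z_max - r$state$post_z_min)
  expect_equal(r$values[2], mid)

  expect_warning(rc <- fit_transform_numeric(c(5, 5, 5)), "degenerate")
  expect_equal(rc$values, c(0.5, 0.5, 0.5))
  expect_true(rc$state$degenerate)

  expect_error(fit_transform_numeric(numeric(0)), "empty")
  expect_error(fit_transform_numeric(c(NA_real_, NA_real_)), "all-missing")
})

test_that("frozen scaling state transforms new data affinely, no refit", {
  r <- fit_transform_numeric(c(10, 20, 30, 40))
  out <- transform_numeric(c(25, 50), r$state)
  z <- (c(25, 50) - r$state$mean) / r$state$sd
  expect_equal(out, (z - r$state$post_z_min) /
                 (r$state$post_z_max - r$state$post_z_min))
  expect_gt(out[2], 1)   # out-of-range values are not clipped
})

test_that("categorical encoding maps categories to codes with unknown slot", {
  enc <- encode_categorical(c("A"), c("A", "B"))
  expect_equal(enc$codes, 0L)
  expect_equal(unname(enc$indicators[1, ]), c(1L, 0L))

  enc2 <- encode_categorical(c("C"), c("A", "B"))
  expect_equal(enc2$codes, 2L)                 # reserved unknown slot
  expect_equal(unname(enc2$indicators[1, ]), c(0L, 0L))
  expect_equal(enc2$n_unknown, 1L)

  set.seed(1)
  vocab <- c("p", "q", "r")
  x <- sample(vocab, 50, TRUE)
  enc3 <- encode_categorical(x, vocab)
  expect_true(all(rowSums(enc3$indicators) == 1L))
  expect_true(all(enc3$codes < length(vocab) + 1L))
  # round-trip for in-vocabulary values
  expect_equal(decode_categorical(enc3$codes, vocab), x)
})

test_that("calendar features follow the Monday=0 convention", {
  tf <- extract_time_features("2019-12-31")   # a Tuesday
  expect_equal(tf$year, 2019L)
  expect_equal(tf$month, 12L)
  expect_equal(tf$day, 31L)
  expect_equal(tf$day_of_week, 1L)
  expect_equal(tf$is_holiday, 0L)

  tf2 <- extract_time_features("2016-02-29")  # leap day parses
  expect_equal(tf2$day, 29L)

  tf3 <- extract_time_features("2019-01-01", holidays = "2019-01-01")
  expect_equal(tf3$is_holiday, 1L)

  tf4 <- extract_time_features("not-a-date")
  expect_true(all(is.na(tf4)))
})

test_that("trailing window aggregates shrink at the series start", {
  expect_equal(window_aggregate(c(3, 1, 4), 1, "mean")$roll_mean_1,
               c(3, 1, 4))
  expect_equal(window_aggregate(c(1, 2, 3, 4), 2, "mean")$roll_mean_2,
               c(1, 1.5, 2.5, 3.5))
  w <- window_aggregate(rep(7, 5), 3)
  expect_true(all(w$roll_mean_3 == 7) && all(w$roll_min_3 == 7) &&
                all(w$roll_max_3 == 7))
  expect_equal(w$roll_count_3, c(1, 2, 3, 3, 3))
  expect_error(window_aggregate(1:3, 0), "positive")
})

test_that("imputation freezes fill values and respects roles", {
  expect_equal(impute_missing(c(1, NA, 3), "mean")$values, c(1, 2, 3))
  expect_equal(impute_missing(c("A", "A", "B", NA), "mode",
                              vocab = c("A", "B"))$values,
               c("A", "A", "B", "A"))
  # mode ties broken by vocabulary order
  expect_equal(impute_missing(c("A", "B", NA), "mode",
                              vocab = c("B", "A"))$fill, "B")
  expect_equal(impute_missing(c(1, 2, 3), "median")$values, c(1, 2, 3))
  expect_error(impute_missing(c("A", NA), "mean"), "numeric")
  expect_error(impute_missing(c(1, NA, NA, 4), "drop_rows",
                              max_missing = 0.05), "exceeds")
  dr <- impute_missing(c(1, NA, 4), "drop_rows", max_missing = 0.5)
  expect_equal(dr$values, c(1, 4))
  expect_equal(dr$kept, c(1L, 3L))
})

test_that("outlier rules flag gross values and spare constant columns", {
  x <- c(0, 0, 0, 0, 100)   # population z of 100 is exactly 2
  expect_equal(which(flag_outliers(x, "zscore", k = 1.5)), 5L)
  expect_equal(sum(flag_outliers(x, "zscore", k = 3)), 0L)
  expect_equal(sum(flag_outliers(rep(4, 6), "zscore", k = 1)), 0L)
  expect_equal(which(flag_outliers(c(1, 2, 3, 4, 100), "iqr", m = 1.5)), 5L)
})

test_that("pipeline fit/transform is leakage-safe, complete and deterministic", {
  cohort <- tiny_cohort()
  enc <- encode_cohort(cohort)
  tr <- enc$splits$train

  # fitting split lands in [0,1]; nothing missing anywhere
  expect_true(all(tr$cont_values >= 0 & tr$cont_values <= 1))
  expect_false(anyNA(tr$cont_values))
  expect_false(anyNA(tr$cat_codes))
  for (nm in tr$meta$cat_cols) {
    expect_true(all(tr$cat_codes[, nm] < tr$meta$vocab_sizes[[nm]]))
  }

  # transforming another split never updates the fitted state
  h_before <- hash_object(enc$state)
  invisible(preprocess_transform(enc$state,
                                 cohort$data[enc$idx$test, , drop = FALSE]))
  expect_identical(hash_object(enc$state), h_before)

  # byte-identical reruns
  enc2 <- encode_cohort(cohort)
  expect_identical(hash_object(enc2$splits$train),
                   hash_object(enc$splits$train))
})

test_that("schema persists through JSON round-trips", {
  cohort <- tiny_cohort(n = 50L)
  p <- file.path(tempdir(), "schema-roundtrip.json")
  write_schema_json(cohort$schema, p)
  back <- read_schema_json(p)
  expect_identical(back$columns, cohort$schema$columns)
  expect_identical(lapply(back$vocabulary, as.character),
                   lapply(cohort$schema$vocabulary, as.character))
  unlink(p)
})
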
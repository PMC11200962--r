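# Synthetic EHR cohort generator.
#
# Real ACS inpatient registries are rarely shareable, so the package ships a
# generator that reproduces the *shape* of such data — six clinical variable
# groups totalling 134 columns by default, mixed categorical / continuous /
# datetime types, missing cells, occasional gross outliers, and rare binary
# adverse-event outcomes (~13% prevalence) driven by a logistic model with
# main effects and pairwise feature interactions. The generating
# coefficients are returned so tests can compare trained models against the
# Bayes-optimal score.

#' Specification of a synthetic cohort
#'
#' @param n_records number of patient records to generate.
#' @param group_sizes named integer vector of feature counts for the six
#'   clinical groups, in order basic/history/lab/followup/echo/angio.
#'   Default 8/31/30/25/20/20 (134 variables).
#' @param events character vector of adverse-event outcome names.
#' @param prevalence marginal event prevalence in (0,1); recycled over
#'   events. Default 0.13.
#' @param n_main number of feature columns with non-zero main effects.
#' @param beta_sd standard deviation of main-effect coefficients.
#' @param n_interactions number of feature pairs with product interactions.
#' @param gamma_sd standard deviation of interaction coefficients.
#' @param interaction_pool "categorical" (default) draws interaction pairs
#'   among categorical columns — the between-feature dependency structure
#'   self-attention over column embeddings is designed to capture — or
#'   "all" to draw pairs from every non-datetime feature column.
#' @param missing_rate fraction of feature cells set missing completely at
#'   random.
#' @param outlier_rate fraction of continuous cells inflated tenfold to
#'   emulate unit-entry errors.
#' @param seed default RNG seed used by [generate_cohort()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_records = 8000L,
                        group_sizes = c(basic = 8L, history = 31L, lab = 30L,
                                        followup = 25L, echo = 20L,
                                        angio = 20L),
                        events = c("ischemic", "bleeding", "infectious",
                                   "febrile", "revascularization"),
                        prevalence = 0.13,
                        n_main = 20L,
                        beta_sd = 0.3,
                        n_interactions = 10L,
                        gamma_sd = 0.3,
                        interaction_pool = c("categorical", "all"),
                        missing_rate = 0.03,
                        outlier_rate = 0.005,
                        seed = 20140601L) {
  stopifnot(n_records >= 0, length(group_sizes) == 6L, all(group_sizes >= 1L),
            length(events) >= 1L, all(prevalence > 0), all(prevalence < 1),
            n_main >= 0L, n_interactions >= 0L,
            missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1)
  names(group_sizes) <- .groups
  prevalence <- rep_len(prevalence, length(events))
  structure(list(n_records = as.integer(n_records),
                 group_sizes = as.integer(group_sizes) |>
                   stats::setNames(.groups),
                 events = events, prevalence = prevalence,
                 n_main = as.integer(n_main), beta_sd = beta_sd,
                 n_interactions = as.integer(n_interactions),
                 gamma_sd = gamma_sd,
                 interaction_pool = match.arg(interaction_pool),
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n=", x$n_records, ", ",
      sum(x$group_sizes), " feature columns, events: ",
      paste(x$events, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the feature schema implied by a cohort specification
#'
#' Column naming is deterministic (`<group>_<k>`). Types are assigned by a
#' fixed within-group pattern: medical history and angiography are mostly
#' categorical, laboratory and echocardiography mostly continuous, basic
#' information is mixed and includes one admission-date column, follow-up
#' alternates. Categorical cardinalities cycle over 2..10.
#'
#' @param spec a `cohort_spec`.
#' @return a `feature_schema` with the spec's feature and outcome columns.
#' @export
make_schema <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  name <- character(0); role <- character(0); group <- character(0)
  n_cat_so_far <- 0L
  vocab <- list()
  add_col <- function(nm, rl, gp) {
    name <<- c(name, nm); role <<- c(role, rl); group <<- c(group, gp)
    if (rl == "categorical") {
      n_cat_so_far <<- n_cat_so_far + 1L
      k <- 2L + (n_cat_so_far %% 9L)        # cardinalities cycle 2..10
      vocab[[nm]] <<- paste0("lvl", seq_len(k))
    }
  }
  for (g in .groups) {
    k <- spec$group_sizes[[g]]
    for (i in seq_len(k)) {
      nm <- paste0(g, "_", i)
      rl <- switch(g,
        basic = if (i == 1L) "datetime"
                else if (i %% 2L == 0L) "categorical" else "continuous",
        history = if (i %% 5L == 0L) "continuous" else "categorical",
        lab = if (i %% 5L == 0L) "categorical" else "continuous",
        followup = if (i %% 2L == 0L) "continuous" else "categorical",
        echo = if (i %% 5L == 0L) "categorical" else "continuous",
        angio = if (i %% 5L == 0L) "continuous" else "categorical")
      add_col(nm, rl, g)
    }
  }
  cols <- data.frame(name = name, role = role, group = group,
                     stringsAsFactors = FALSE)
  out <- data.frame(name = spec$events, role = "outcome", group = NA_character_,
                    stringsAsFactors = FALSE)
  feature_schema(rbind(cols, out), vocab)
}

# Level scores for a categorical column: centered N(0,1) draws, one per level.
.level_scores <- function(k) {
  u <- stats::rnorm(k)
  u - mean(u)
}

#' Generate a synthetic cohort
#'
#' Continuous features are drawn from normal or log-normal marginals,
#' categorical features from Dirichlet-categorical distributions, and the
#' admission-date column uniformly over 2014-2019. For each adverse event a
#' logistic outcome model is built on standardized feature scores: `n_main`
#' main effects plus `n_interactions` pairwise product terms; the intercept
#' is solved numerically so the marginal prevalence matches the spec.
#' Missing cells (MCAR) and tenfold-inflated outlier cells are injected
#' afterwards, so the stored ground truth refers to the clean data.
#'
#' @param spec a `cohort_spec`.
#' @param seed RNG seed; defaults to `spec$seed`. Identical (spec, seed)
#'   pairs yield byte-identical cohorts.
#' @return object of class `synthetic_cohort`: list with `data` (raw
#'   feature data.frame with a `record_id` column), `schema`, `spec`, and
#'   `truth` (per event: intercept `alpha`, linear predictor `eta`, effect
#'   tables).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  schema <- make_schema(spec)
  n <- spec$n_records
  feat_cols <- schema$columns[schema$columns$role != "outcome", ]

  with_seed(seed, {
    dat <- list()
    scores <- list()  # standardized per-column scores driving the outcome
    cont_idx <- 0L
    for (r in seq_len(nrow(feat_cols))) {
      nm <- feat_cols$name[r]
      rl <- feat_cols$role[r]
      if (rl == "datetime") {
        days <- sample.int(as.integer(as.Date("2019-12-31") -
                                        as.Date("2014-01-01")) + 1L,
                           n, replace = TRUE) - 1L
        d <- as.Date("2014-01-01") + days
        dat[[nm]] <- as.character(d)
        scores[[nm]] <- rep(0, n)   # admission date carries no planted signal
      } else if (rl == "continuous") {
        cont_idx <- cont_idx + 1L
        mu <- stats::runif(1, -2, 2)
        sdv <- stats::runif(1, 0.5, 2)
        if (cont_idx %% 4L == 0L) {
          x <- stats::rlnorm(n, meanlog = mu / 4, sdlog = sdv / 2)
        } else {
          x <- stats::rnorm(n, mu, sdv)
        }
        dat[[nm]] <- x
        scores[[nm]] <- if (n > 1 && sd_pop(x) > 0) (x - mean(x)) / sd_pop(x)
                        else rep(0, n)
      } else {
        voc <- schema$vocabulary[[nm]]
        g <- stats::rgamma(length(voc), 1)
        p <- g / sum(g)
        lev <- sample.int(length(voc), n, replace = TRUE, prob = p)
        dat[[nm]] <- voc[lev]
        ls <- .level_scores(length(voc))
        scores[[nm]] <- if (n > 0) ls[lev] else numeric(0)
      }
    }
    data <- as.data.frame(dat, stringsAsFactors = FALSE,
                          optional = TRUE)
    if (n == 0) {
      data <- as.data.frame(stats::setNames(
        replicate(nrow(feat_cols), character(0), simplify = FALSE),
        feat_cols$name), stringsAsFactors = FALSE)
    }

    # per-event logistic outcome model on the standardized scores
    signal_cols <- setdiff(feat_cols$name,
                           feat_cols$name[feat_cols$role == "datetime"])
    truth <- list()
    for (e in seq_along(spec$events)) {
      ev <- spec$events[e]
      beta <- data.frame(column = character(0), beta = numeric(0))
      gamma <- data.frame(col_i = character(0), col_j = character(0),
                          gamma = numeric(0))
      eta <- rep(0, n)
      if (spec$n_main > 0) {
        main_cols <- sample(signal_cols, min(spec$n_main, length(signal_cols)))
        b <- stats::rnorm(length(main_cols), 0, spec$beta_sd)
        beta <- data.frame(column = main_cols, beta = b,
                           stringsAsFactors = FALSE)
        for (i in seq_along(main_cols)) {
          eta <- eta + b[i] * scores[[main_cols[i]]]
        }
      }
      if (spec$n_interactions > 0) {
        pool <- if (identical(spec$interaction_pool, "categorical")) {
          intersect(signal_cols,
                    feat_cols$name[feat_cols$role == "categorical"])
        } else {
          signal_cols
        }
        if (length(pool) < 2) pool <- signal_cols
        ci <- sample(pool, spec$n_interactions, replace = TRUE)
        cj <- sample(pool, spec$n_interactions, replace = TRUE)
        keep <- ci != cj
        ci <- ci[keep]; cj <- cj[keep]
        gm <- stats::rnorm(length(ci), 0, spec$gamma_sd)
        gamma <- data.frame(col_i = ci, col_j = cj, gamma = gm,
                            stringsAsFactors = FALSE)
        for (i in seq_along(ci)) {
          eta <- eta + gm[i] * scores[[ci[i]]] * scores[[cj[i]]]
        }
      }
      alpha <- .solve_intercept(eta, spec$prevalence[e])
      y <- if (n > 0) stats::rbinom(n, 1L, sigmoid(alpha + eta)) else integer(0)
      data[[ev]] <- y
      truth[[ev]] <- list(alpha = alpha, eta = eta, beta = beta, gamma = gamma,
                          prevalence = spec$prevalence[e])
    }

    # MCAR missingness over feature cells
    if (spec$missing_rate > 0 && n > 0) {
      for (nm in feat_cols$name) {
        miss <- stats::runif(n) < spec$missing_rate
        data[[nm]][miss] <- NA
      }
    }
    # gross outliers: inflate a random subset of continuous cells tenfold
    if (spec$outlier_rate > 0 && n > 0) {
      cont_cols <- feat_cols$name[feat_cols$role == "continuous"]
      for (nm in cont_cols) {
        hit <- stats::runif(n) < spec$outlier_rate
        hit <- hit & !is.na(data[[nm]])
        data[[nm]][hit] <- data[[nm]][hit] * 10
      }
    }
    data <- cbind(record_id = if (n > 0) sprintf("rec%06d", seq_len(n))
                              else character(0),
                  data, stringsAsFactors = FALSE)

    structure(list(data = data, schema = schema, spec = spec, seed = seed,
                   truth = truth),
              class = "synthetic_cohort")
  })
}

# Solve the logistic intercept so mean(sigmoid(alpha + eta)) = prevalence.
.solve_intercept <- function(eta, prevalence) {
  if (length(eta) == 0) return(stats::qlogis(prevalence))
  f <- function(a) mean(sigmoid(a + eta)) - prevalence
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence unattainable for this signal")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n=", nrow(x$data), ", ",
      sum(x$schema$columns$role != "outcome"), " feature columns, events: ",
      paste(x$spec$events, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bayes-oracle discrimination of the planted signal
#'
#' Computes the AUC of the true generating risk score
#' `sigmoid(alpha + eta)` against the realized labels. No trained model can
#' beat this score in expectation, so it serves as the upper reference in
#' learnability tests.
#'
#' @param cohort a `synthetic_cohort`.
#' @param event event name; defaults to the first event.
#' @return list with `auc` and the number of records used.
#' @export
planted_signal_check <- function(cohort, event = cohort$spec$events[1]) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            event %in% cohort$spec$events)
  tr <- cohort$truth[[event]]
  y <- cohort$data[[event]]
  p <- sigmoid(tr$alpha + tr$eta)
  list(auc = roc_auc(y, p)$auc, n = length(y))
}

#' Write a synthetic cohort to disk
#'
#' Writes the raw feature table as CSV, the schema as JSON and the
#' generating ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(data = file.path(dir, "cohort.csv"),
             schema = file.path(dir, "schema.json"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$data, paths[["data"]], row.names = FALSE, na = "")
  write_schema_json(cohort$schema, paths[["schema"]])
  jsonlite::write_json(
    list(seed = cohort$seed,
         spec = unclass(cohort$spec),
         truth = lapply(cohort$truth, function(t)
           list(alpha = t$alpha, beta = t$beta, gamma = t$gamma,
                prevalence = t$prevalence))),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
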
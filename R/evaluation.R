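#' @title Model evaluation
#' @description
#' Stratified 80/20 derivation/validation splits, stratified k-fold
#' cross-validation, AUC by the Mann-Whitney pair-counting convention (ties
#' count one half) with stratified-bootstrap percentile confidence intervals
#' and a Youden-optimal threshold, paired-bootstrap AUC comparison between
#' two models, and rare-pattern ("N of 1") subset evaluation.
#' @name evaluation
NULL

# Scalar-safe draws: sample `size` elements of the vector `v` (never the
# 1:v expansion R's sample() applies to length-one numeric input).
draw <- function(v, size, replace = FALSE) {
  v[sample.int(length(v), size, replace = replace)]
}

# AUC as the scaled Mann-Whitney U statistic; labels are 0/1.
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

labels_01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- labels == "present"
  as.integer(labels)
}

#' Stratified derivation/validation split
#'
#' The validation side receives `round((1 - fraction) * n)` records per
#' outcome class, so the event rate is preserved to within one record per
#' side; the split is an exact partition and deterministic given the seed.
#'
#' @param x A `cohort` with both outcome classes present.
#' @param fraction Derivation fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with `derivation` and `validation` cohorts and the
#'   validation row indices in `validation_idx`.
#' @export
split_cohort <- function(x, fraction = 0.8, seed = 1) {
  stopifnot(inherits(x, "cohort"), fraction > 0, fraction < 1)
  y <- as.character(x$records[[x$outcome]])
  classes <- unique(y)
  if (length(classes) < 2) stop("both outcome classes must be present")
  if (any(table(y) < 5)) {
    warning("an outcome class has fewer than 5 members", call. = FALSE)
  }
  val_idx <- integer(0)
  with_seed(seed, {
    for (cl in sort(classes)) {
      rows <- which(y == cl)
      n_val <- round((1 - fraction) * length(rows))
      val_idx <- c(val_idx, draw(rows, n_val))
    }
  })
  val_idx <- sort(val_idx)
  subset_c <- function(idx) {
    cohort(x$records[idx, , drop = FALSE], x$outcome, x$specs)
  }
  list(derivation = subset_c(setdiff(seq_along(y), val_idx)),
       validation = subset_c(val_idx),
       validation_idx = val_idx)
}

# Stratified fold assignment: per class, fold sizes differ by at most one.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      rows <- which(y == cl)
      assign_f <- rep_len(seq_len(k), length(rows))
      fold[rows] <- draw(assign_f, length(assign_f))
    }
  })
  fold
}

#' Model builder for a logistic regression baseline
#'
#' Returns a builder suitable for [cross_validate()]: fits
#' `outcome ~ features` (binary columns coded present = 1) on the training
#' cohort and scores new cohorts with predicted probabilities.
#'
#' @param features Character vector of binary predictor columns.
#' @return Function `(train_cohort) -> (test_cohort) -> scores`.
#' @export
logistic_builder <- function(features) {
  force(features)
  function(train) {
    df <- as.data.frame(lapply(train$records[features], function(col) {
      as.integer(col == "present")
    }))
    names(df) <- features
    df$.y <- labels_01(train$records[[train$outcome]])
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                       family = stats::binomial()))
    function(test) {
      nd <- as.data.frame(lapply(test$records[features], function(col) {
        as.integer(col == "present")
      }))
      names(nd) <- features
      as.vector(stats::predict(fit, nd, type = "response"))
    }
  }
}

#' Model builder for the Bayesian-network model
#'
#' Learns a structure (BIC hill-climbing with the supplied blacklist) and
#' fits parameters on the training cohort; scores new cohorts with
#' [predict_risk()].
#'
#' @param blacklist Forbidden edges, e.g. [blacklist_from_families()].
#' @param restarts,seed Structure-search settings.
#' @param method,alpha Parameter-fitting settings.
#' @param d Optional fixed `net_dag`; when supplied the structure search is
#'   skipped and only parameters are refitted.
#' @return Function `(train_cohort) -> (test_cohort) -> scores`.
#' @export
pgm_builder <- function(blacklist = NULL, restarts = 2, seed = 1,
                        method = "bayes", alpha = 1, d = NULL) {
  function(train) {
    dd <- if (is.null(d)) {
      learn_structure(train, blacklist = blacklist, seed = seed,
                      restarts = restarts)
    } else d
    net <- fit_parameters(dd, train, method = method, alpha = alpha)
    function(test) predict_risk(net, test, target = train$outcome)
  }
}

#' Stratified k-fold cross-validation
#'
#' Class-stratified folds; for each fold the model is built on the remaining
#' folds and scored on the held-out fold by AUC. A fold lacking both classes
#' triggers one refold with a new seed (logged via a message).
#'
#' @param x A `cohort`.
#' @param folds Number of folds (>= 2).
#' @param builder A model builder, e.g. [logistic_builder()] or
#'   [pgm_builder()].
#' @param seed Fold-assignment seed.
#' @return List with per-fold `auc`, their `mean`, and `fold` assignments.
#' @export
cross_validate <- function(x, folds = 5, builder, seed = 1) {
  stopifnot(inherits(x, "cohort"), folds >= 2)
  y <- labels_01(x$records[[x$outcome]])
  fold <- stratified_folds(y, folds, seed)
  for (attempt in 1:2) {
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[fold == f])) == 2
    }, logical(1)))
    if (ok) break
    message("a fold lacked both outcome classes; refolding with a new seed")
    fold <- stratified_folds(y, folds, seed + 1)
  }
  subset_c <- function(idx) cohort(x$records[idx, , drop = FALSE],
                                   x$outcome, x$specs)
  aucs <- vapply(seq_len(folds), function(f) {
    predictor <- builder(subset_c(which(fold != f)))
    scores <- predictor(subset_c(which(fold == f)))
    auc_mann_whitney(scores, y[fold == f])
  }, numeric(1))
  list(auc = aucs, mean = mean(aucs), fold = fold)
}

#' AUC with a stratified-bootstrap confidence interval
#'
#' AUC is the scaled Mann-Whitney U (ties count one half). The CI is the
#' percentile interval over `b` stratified bootstrap resamples of the
#' (score, label) pairs (resampling within each class); the optimal
#' threshold maximizes Youden's J over the observed scores.
#'
#' @param scores Numeric model scores.
#' @param labels Binary labels (`"present"`/`"absent"`, logical, or 0/1).
#' @param b Bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List of class `eval_report`: `auc`, `ci_low`, `ci_high`,
#'   `threshold`, `n`, `n_events`, `b`.
#' @export
auc_with_ci <- function(scores, labels, b = 1000, seed = 1, level = 0.95) {
  y <- labels_01(labels)
  stopifnot(length(scores) == length(y), b >= 2)
  point <- auc_mann_whitney(scores, y)
  i1 <- which(y == 1); i0 <- which(y == 0)
  reps <- numeric(b)
  with_seed(seed, {
    for (i in seq_len(b)) {
      idx <- c(draw(i1, length(i1), replace = TRUE),
               draw(i0, length(i0), replace = TRUE))
      reps[i] <- auc_mann_whitney(scores[idx], y[idx])
    }
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  thr <- if (length(unique(scores)) >= 2) {
    derive_threshold(scores, y)$cutpoint
  } else NA_real_
  structure(list(auc = point, ci_low = qs[1], ci_high = qs[2],
                 threshold = thr, n = length(y), n_events = length(i1), b = b),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUC %.3f (%.3f-%.3f), n = %d (%d events)\n",
              x$auc, x$ci_low, x$ci_high, x$n, x$n_events))
  invisible(x)
}

#' Compare two models' AUCs by paired bootstrap
#'
#' Both score vectors are resampled on the same stratified index draws; the
#' two-sided p-value is twice the smaller tail fraction of the bootstrap
#' distribution of the AUC difference around zero, capped at 1.
#'
#' @param scores_a,scores_b Scores of the two models on the same records.
#' @param labels Binary labels.
#' @param b Bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `auc_a`, `auc_b`, `delta`, `p_value`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, b = 1000, seed = 1) {
  y <- labels_01(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  auc_a <- auc_mann_whitney(scores_a, y)
  auc_b <- auc_mann_whitney(scores_b, y)
  i1 <- which(y == 1); i0 <- which(y == 0)
  deltas <- numeric(b)
  with_seed(seed, {
    for (i in seq_len(b)) {
      idx <- c(draw(i1, length(i1), replace = TRUE),
               draw(i0, length(i0), replace = TRUE))
      deltas[i] <- auc_mann_whitney(scores_a[idx], y[idx]) -
                   auc_mann_whitney(scores_b[idx], y[idx])
    }
  })
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b, p_value = p)
}

#' Rare-pattern ("N of 1") subset evaluation
#'
#' A record's pattern is its full tuple of non-outcome states (including
#' `"unknown"`). Pattern frequencies are counted over the entire cohort;
#' validation records whose pattern occurs at most `max_frequency` times are
#' returned (frequency 1 = "N of 1" scenarios), with an AUC report when
#' scores are supplied and both classes are present in the subset.
#'
#' @param x The full `cohort` (frequency reference).
#' @param validation The validation `cohort`.
#' @param max_frequency Pattern frequency cutoff (default 1).
#' @param scores Optional model scores aligned with the validation rows.
#' @param b,seed Passed to [auc_with_ci()].
#' @return List with `idx` (validation row indices in the subset), `n`,
#'   `fraction_pct` (percent of validation records), `report` (an
#'   `eval_report` or NULL with `reason`).
#' @export
unique_scenarios <- function(x, validation, max_frequency = 1, scores = NULL,
                             b = 1000, seed = 1) {
  stopifnot(inherits(x, "cohort"), inherits(validation, "cohort"))
  vars <- cohort_variables(x, include_outcome = FALSE)
  pat <- function(records) {
    do.call(paste, c(lapply(records[vars], as.character), list(sep = "\r")))
  }
  freq <- table(pat(x$records))
  vpat <- pat(validation$records)
  idx <- which(as.vector(freq[vpat]) <= max_frequency)
  n <- length(idx)
  report <- NULL
  reason <- NULL
  if (n == 0) {
    reason <- "no records at or below the frequency cutoff"
  } else {
    y <- labels_01(validation$records[[validation$outcome]][idx])
    if (length(unique(y)) < 2) {
      reason <- "subset lacks both outcome classes; AUC omitted"
    } else if (!is.null(scores)) {
      report <- auc_with_ci(scores[idx], y, b = b, seed = seed)
    }
  }
  list(idx = idx, n = n,
       fraction_pct = round(100 * n / n_records(validation), 1),
       report = report, reason = reason)
}
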
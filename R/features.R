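#' @title Categorical feature selection
#' @description
#' Candidate predictors (binary, post one-hot) are ranked against the outcome
#' by Pearson chi-square and plug-in mutual information, combined by rank
#' sum; redundant variables are pruned by Jaccard similarity of their
#' "present" sets, favoring variables with standard clinical definitions;
#' continuous variables get empirical ROC (Youden) thresholds; the final
#' model feature set comes from a best-AUC search over k-variable logistic
#' models plus forced clinical includes.
#' @name feature-selection
NULL

# Pairwise-complete 2x2 table of a binary predictor vs the binary outcome
# ("unknown" cells excluded pairwise).
binary_table <- function(pred, out) {
  keep <- pred != UNKNOWN_STATE & out != UNKNOWN_STATE
  table(factor(as.character(pred[keep]), levels = c("absent", "present")),
        factor(as.character(out[keep]), levels = c("absent", "present")))
}

pearson_chi2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  ok <- e > 0
  sum((tab[ok] - e[ok])^2 / e[ok])
}

# Plug-in mutual information in bits.
plugin_mi <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  ind <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ind[nz]))
}

#' Rank binary features against the outcome
#'
#' Per variable: Pearson chi-square statistic and p-value (1 df, no
#' continuity correction) and plug-in mutual information in bits, computed on
#' pairwise-complete records. The combined rank is the rank sum of the two
#' per-metric rankings (larger statistic = better rank), ties broken
#' lexicographically by variable name. Variables with a single observed state
#' are flagged degenerate and assigned zero statistics.
#'
#' @param x A `cohort` whose non-outcome columns are binary.
#' @param outcome Outcome column (defaults to the cohort outcome).
#' @param variables Candidate columns (default: all non-outcome binaries).
#' @return Data frame of class `feature_ranking` with `variable`,
#'   `chi2_stat`, `chi2_p`, `mi`, `degenerate`, `combined_rank`, sorted by
#'   combined rank.
#' @export
rank_features <- function(x, outcome = x$outcome,
                          variables = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(variables)) {
    variables <- Filter(function(v) is_binary_spec(x$specs[[v]]),
                        setdiff(cohort_variables(x), outcome))
  }
  out <- x$records[[outcome]]
  rows <- lapply(variables, function(v) {
    tab <- binary_table(x$records[[v]], out)
    degenerate <- sum(rowSums(tab) > 0) < 2 || sum(colSums(tab) > 0) < 2
    if (degenerate) {
      data.frame(variable = v, chi2_stat = 0, chi2_p = 1, mi = 0,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      stat <- pearson_chi2(tab)
      data.frame(variable = v, chi2_stat = stat,
                 chi2_p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 mi = plugin_mi(tab), degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  rk <- do.call(rbind, rows)
  ord_chi <- rank(-rk$chi2_stat, ties.method = "min")
  ord_mi <- rank(-rk$mi, ties.method = "min")
  rank_sum <- ord_chi + ord_mi
  rk <- rk[order(rank_sum, rk$variable), , drop = FALSE]
  rk$combined_rank <- seq_len(nrow(rk))
  rownames(rk) <- NULL
  class(rk) <- c("feature_ranking", "data.frame")
  rk
}

# Jaccard similarity of the "present" sets of two binary columns; both-empty
# pairs are defined as 0.
jaccard_present <- function(a, b) {
  pa <- a == "present"; pb <- b == "present"
  u <- sum(pa | pb)
  if (u == 0) return(0)
  sum(pa & pb) / u
}

#' Prune redundant binary features by Jaccard similarity
#'
#' For every pair with Jaccard similarity of "present" sets at or above the
#' threshold, the variable with the worse (larger) `clinical_rank` is
#' dropped; when unranked, the worse `combined_rank` is dropped. Pairs are
#' processed in a deterministic order (similarity descending, then names), so
#' the result does not depend on input ordering.
#'
#' @param ranking A `feature_ranking` (provides the fallback ordering).
#' @param x The `cohort` the ranking came from.
#' @param threshold Similarity threshold in (0, 1\]; default 0.8.
#' @return Character vector of retained variable names (ranking order).
#' @export
prune_redundant <- function(ranking, x, threshold = 0.8) {
  stopifnot(inherits(ranking, "feature_ranking"), inherits(x, "cohort"),
            threshold > 0, threshold <= 1)
  vars <- sort(ranking$variable)
  if (length(vars) < 2) return(ranking$variable)
  cols <- lapply(vars, function(v) as.character(x$records[[v]]))
  names(cols) <- vars
  pairs <- utils::combn(vars, 2)
  sims <- apply(pairs, 2, function(pr) jaccard_present(cols[[pr[1]]],
                                                       cols[[pr[2]]]))
  ord <- order(-sims, pairs[1, ], pairs[2, ])
  dropped <- character(0)
  crank <- vapply(vars, function(v) x$specs[[v]]$clinical_rank, integer(1))
  mrank <- ranking$combined_rank[match(vars, ranking$variable)]
  names(mrank) <- vars
  worse <- function(a, b) {
    # TRUE if a should be dropped in favor of b
    ca <- crank[[a]]; cb <- crank[[b]]
    if (!is.na(ca) && !is.na(cb) && ca != cb) return(ca > cb)
    if (is.na(ca) != is.na(cb)) return(is.na(ca))
    if (mrank[[a]] != mrank[[b]]) return(mrank[[a]] > mrank[[b]])
    a > b
  }
  for (j in ord) {
    if (sims[j] < threshold) break
    a <- pairs[1, j]; b <- pairs[2, j]
    if (a %in% dropped || b %in% dropped) next
    dropped <- c(dropped, if (worse(a, b)) a else b)
  }
  keep <- setdiff(ranking$variable, dropped)
  keep[order(match(keep, ranking$variable))]
}

#' Empirical ROC threshold by Youden's J
#'
#' Scans every observed value as a candidate cutpoint (positive when
#' `value >= cutpoint`) and returns the one maximizing sensitivity +
#' specificity - 1; ties break toward the smaller cutpoint.
#'
#' @param values Numeric vector (>= 2 distinct values).
#' @param outcome Binary vector (`"present"`/`"absent"`, logical, or 0/1).
#' @return List with `cutpoint`, `j`, `sensitivity`, `specificity`.
#' @export
derive_threshold <- function(values, outcome) {
  if (is.logical(outcome)) outcome <- ifelse(outcome, "present", "absent")
  if (is.numeric(outcome)) outcome <- ifelse(outcome > 0, "present", "absent")
  pos <- outcome == "present"
  if (!any(pos) || all(pos)) stop("both outcome classes must be present")
  cand <- sort(unique(values))
  if (length(cand) < 2) stop("need at least two distinct values")
  best <- NULL
  for (cut in cand) {
    pred <- values >= cut
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(cutpoint = cut, j = j, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

# In-sample AUC of a logistic model on the given binary feature columns.
# Returns list(auc, fit, separated).
fit_logistic_auc <- function(x, features, outcome = x$outcome) {
  df <- as.data.frame(lapply(x$records[features], function(col) {
    as.integer(col == "present")
  }))
  names(df) <- features
  df$.y <- as.integer(x$records[[outcome]] == "present")
  separated <- FALSE
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  probs <- fit$fitted.values
  if (any(probs > 1 - 1e-10) || any(probs < 1e-10) || !fit$converged) {
    separated <- TRUE
    if (requireNamespace("glmnet", quietly = TRUE)) {
      mm <- as.matrix(df[features])
      rfit <- glmnet::glmnet(mm, df$.y, family = "binomial", alpha = 0,
                             lambda = 1e-4)
      probs <- as.vector(stats::predict(rfit, mm, type = "response"))
    }
  }
  list(auc = auc_mann_whitney(probs, df$.y), fit = fit, separated = separated)
}

#' Search feature subsets by logistic-model AUC
#'
#' Fits a maximum-likelihood logistic model for each k-subset of the top-m
#' candidate features and returns the subset with the best in-sample AUC.
#' Exhaustive mode refuses (reporting the exact subset count) when
#' `choose(m, k)` exceeds the budget; `sampled` draws distinct random
#' subsets; `greedy` performs forward selection. Deterministic given
#' mode and seed. Fits with complete separation fall back to a ridge fit and
#' are flagged.
#'
#' @param x A `cohort` with binary candidate columns.
#' @param top_features Character vector of m candidate variables (ranked).
#' @param k Subset size (k <= m).
#' @param mode `"exhaustive"`, `"sampled"` or `"greedy"`.
#' @param n_subsets Number of subsets for `sampled` mode.
#' @param seed Seed for `sampled` mode.
#' @param budget Maximum subsets exhaustive mode will fit.
#' @param cv_folds If > 0, score subsets by stratified k-fold
#'   cross-validated AUC instead of in-sample AUC.
#' @return List of class `combination_result`: `feature_set`, `auc`,
#'   `n_evaluated`, `separated`.
#' @export
search_combinations <- function(x, top_features, k,
                                mode = c("exhaustive", "sampled", "greedy"),
                                n_subsets = 200, seed = 1, budget = 20000,
                                cv_folds = 0) {
  mode <- match.arg(mode)
  m <- length(top_features)
  stopifnot(k >= 1, k <= m)
  score_subset <- function(set) {
    if (cv_folds > 0) {
      mean(cross_validate(x, folds = cv_folds,
                          builder = logistic_builder(set), seed = seed)$auc)
    } else {
      fit_logistic_auc(x, set)$auc
    }
  }
  n_eval <- 0L
  separated <- FALSE
  best <- list(feature_set = NULL, auc = -Inf)
  consider <- function(set) {
    res <- fit_logistic_auc(x, set)
    a <- if (cv_folds > 0) score_subset(set) else res$auc
    n_eval <<- n_eval + 1L
    if (res$separated) separated <<- TRUE
    if (a > best$auc + 1e-12) best <<- list(feature_set = set, auc = a)
  }
  if (mode == "exhaustive") {
    count <- choose(m, k)
    if (count > budget) {
      stop("exhaustive search over ", format(count, big.mark = ",", scientific = FALSE),
           " subsets exceeds the budget (", budget,
           "); use mode = \"sampled\" or \"greedy\"")
    }
    subsets <- utils::combn(top_features, k, simplify = FALSE)
    for (s in subsets) consider(s)
  } else if (mode == "sampled") {
    with_seed(seed, {
      seen <- new.env(parent = emptyenv())
      tries <- 0L
      while (n_eval < n_subsets && tries < 50L * n_subsets) {
        tries <- tries + 1L
        s <- sort(sample(top_features, k))
        key <- paste(s, collapse = "\r")
        if (exists(key, envir = seen, inherits = FALSE)) next
        assign(key, TRUE, envir = seen)
        consider(s)
      }
    })
  } else {
    set <- character(0)
    for (step in seq_len(k)) {
      cand <- setdiff(top_features, set)
      scores <- vapply(cand, function(v) {
        res <- fit_logistic_auc(x, c(set, v))
        n_eval <<- n_eval + 1L
        if (res$separated) separated <<- TRUE
        res$auc
      }, numeric(1))
      set <- c(set, cand[order(-scores, cand)][1])
    }
    best <- list(feature_set = set, auc = score_subset(set))
  }
  structure(list(feature_set = sort(best$feature_set), auc = best$auc,
                 n_evaluated = n_eval, separated = separated),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat("<combination_result> AUC ", round(x$auc, 4), " with {",
      paste(x$feature_set, collapse = ", "), "} (", x$n_evaluated,
      " subsets fitted)\n", sep = "")
  invisible(x)
}

#' Assemble the final model feature list
#'
#' Refits the best subset's logistic model and keeps its significant features
#' (two-sided Wald p < `p_cutoff`), then unions the forced clinical includes,
#' de-duplicated with stable order (significant features first). Exact
#' discrete models are limited to fewer than 20 variables.
#'
#' @param x The derivation `cohort`.
#' @param best_set Feature set from [search_combinations()].
#' @param forced_includes Clinical variables always retained.
#' @param p_cutoff Wald significance threshold (default 0.05).
#' @return Character vector of model features.
#' @export
assemble_pgm_features <- function(x, best_set, forced_includes = character(0),
                                  p_cutoff = 0.05) {
  sig <- best_set
  if (length(best_set)) {
    res <- fit_logistic_auc(x, best_set)
    if (!res$separated) {
      coefs <- summary(res$fit)$coefficients
      pvals <- coefs[match(best_set, rownames(coefs)), "Pr(>|z|)"]
      sig <- best_set[!is.na(pvals) & pvals < p_cutoff]
    }
  }
  out <- unique(c(sig, forced_includes))
  if (length(out) >= 20) {
    stop("final feature list has ", length(out),
         " variables; exact discrete models require fewer than 20")
  }
  out
}
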
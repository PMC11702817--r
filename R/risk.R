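#' @title Scenario risk estimation
#' @description
#' Turns exact network inference into clinical outputs: absolute risk (AR)
#' of an outcome under a scenario (a partial assignment of variable states
#' used as query evidence), relative risk (RR) against the model background
#' or an explicit reference scenario, bootstrap percentile confidence
#' intervals (resampling records, refitting parameters on the fixed learned
#' structure, re-running the query), cumulative scenario sequences,
#' alternate-target panels, and an effect-modification scanner that flags
#' strata whose RR confidence intervals do not overlap.
#'
#' Point estimates come from the network fitted to the full cohort, not from
#' the mean of bootstrap replicates, so they need not sit in the center of
#' the interval.
#' @name risk-analysis
NULL

#' Define a scenario
#'
#' @param label Human-readable description.
#' @param evidence Named list of variable -> state assignments (states may
#'   include `"unknown"`).
#' @return Object of class `scenario`.
#' @export
scenario <- function(label, evidence = list()) {
  stopifnot(is.character(label), is.list(evidence))
  structure(list(label = label, evidence = evidence), class = "scenario")
}

as_evidence <- function(s) {
  if (inherits(s, "scenario")) s$evidence else as.list(s)
}

#' @export
print.scenario <- function(x, ...) {
  ev <- if (length(x$evidence)) {
    paste(names(x$evidence), unlist(x$evidence), sep = "=", collapse = ", ")
  } else "(background)"
  cat("<scenario> ", x$label, ": ", ev, "\n", sep = "")
  invisible(x)
}

#' Absolute risk of an outcome under a scenario
#'
#' `P(target = present | scenario evidence)` by exact query. The background
#' (empty) scenario gives the model's marginal outcome risk.
#'
#' @param net A `bayes_net`.
#' @param s A [scenario()] or plain evidence list.
#' @param target Target node (default `"morbidity"` when present).
#' @return Probability in \[0, 1\].
#' @export
absolute_risk <- function(net, s = list(),
                          target = intersect("morbidity", net$dag$nodes)[1]) {
  ev <- as_evidence(s)
  if (!"present" %in% net$specs[[target]]$states) {
    stop("target '", target, "' has no state \"present\"; ",
         "absolute risk needs a binary target")
  }
  q <- query_net(net, target, ev)
  unname(q$distribution[["present"]])
}

#' Relative risk of a scenario against a reference
#'
#' `AR(scenario) / AR(reference)`; the default reference is the background
#' (empty evidence), i.e. the fitted model's marginal outcome risk.
#'
#' @inheritParams absolute_risk
#' @param reference Reference scenario (default: background).
#' @return Positive ratio.
#' @export
relative_risk <- function(net, s, reference = list(),
                          target = intersect("morbidity", net$dag$nodes)[1]) {
  ar <- absolute_risk(net, s, target)
  ar_ref <- absolute_risk(net, reference, target)
  if (ar_ref <= 0) stop("reference scenario has zero absolute risk")
  ar / ar_ref
}

#' Bootstrap percentile confidence interval for a network query
#'
#' Resamples the cohort rows with replacement, refits the CPT parameters on
#' the fixed structure, and recomputes an arbitrary query for each replicate;
#' returns the 2.5th/97.5th percentile bounds (for `level = 0.95`) per
#' component of the query. The structure is never re-learned per replicate.
#' Replicates in which the query is inconsistent (zero evidence mass) are
#' dropped and counted.
#'
#' @param x The `cohort` to resample.
#' @param d The fixed `net_dag`.
#' @param query_fn Function taking a fitted `bayes_net` and returning a named
#'   numeric vector (e.g. an AR or RR).
#' @param b Number of replicates (>= 2); the study default is 1000.
#' @param seed Integer seed; the same seed reproduces the same interval.
#' @param method,alpha Parameter-fitting method for the refits (and the point
#'   estimate), see [fit_parameters()].
#' @param level Confidence level.
#' @return List of class `bootstrap_ci`: `point`, `ci_low`, `ci_high`, `b`,
#'   `n_failed`, and the replicate matrix in `replicates`.
#' @export
bootstrap_ci <- function(x, d, query_fn, b = 1000, seed = 1,
                         method = "mle", alpha = 1, level = 0.95) {
  stopifnot(inherits(x, "cohort"), inherits(d, "net_dag"), b >= 2)
  specs <- x$specs[d$nodes]
  code <- encode_records(x$records, x$specs, d$nodes)
  n <- nrow(code)
  cards <- lapply(specs, function(s) length(s$states))
  fam <- lapply(d$nodes, function(v) {
    list(node = v, parents = d$parents[[v]],
         code = family_code(code, v, d$parents[[v]], cards),
         r = cards[[v]],
         q = prod(unlist(cards[d$parents[[v]]], use.names = FALSE), 1))
  })
  names(fam) <- d$nodes
  refit <- function(idx) {
    cpts <- lapply(fam, function(f) {
      counts <- matrix(tabulate(f$code[idx], nbins = f$r * f$q),
                       nrow = f$r, ncol = f$q)
      list(node = f$node, parents = unname(f$parents),
           prob = normalize_counts(counts, method, alpha))
    })
    bayes_net(d, cpts, specs, validate = FALSE)
  }
  point <- query_fn(refit(seq_len(n)))
  k <- length(point)
  reps <- matrix(NA_real_, nrow = b, ncol = k)
  colnames(reps) <- names(point)
  with_seed(seed, {
    for (i in seq_len(b)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(query_fn(refit(idx)), error = function(e) rep(NA_real_, k))
      reps[i, ] <- val
    }
  })
  ok <- stats::complete.cases(reps)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = qs,
              names = FALSE)
  structure(list(point = point,
                 ci_low = stats::setNames(ci[1, ], names(point)),
                 ci_high = stats::setNames(ci[2, ], names(point)),
                 b = b, n_failed = sum(!ok), replicates = reps),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat("<bootstrap_ci> B = ", x$b,
      if (x$n_failed) paste0(" (", x$n_failed, " failed)"), "\n", sep = "")
  print(round(rbind(point = x$point, low = x$ci_low, high = x$ci_high), 4))
  invisible(x)
}

# Count cohort records consistent with a scenario's evidence.
n_matching <- function(x, evidence) {
  if (!length(evidence)) return(n_records(x))
  keep <- rep(TRUE, n_records(x))
  for (v in names(evidence)) {
    keep <- keep & as.character(x$records[[v]]) == evidence[[v]]
  }
  sum(keep)
}

#' Cumulative scenario sequence risk table
#'
#' Starting from a base scenario, clinical factors are introduced one at a
#' time; each cumulative scenario is reported with its AR (percent), RR vs
#' the model background, RR vs the base scenario, a bootstrap CI for the AR,
#' and the number of derivation-cohort records matching the scenario
#' (reported even when 0 — the model can still be queried there).
#'
#' @param net Fitted `bayes_net`.
#' @param base A [scenario()].
#' @param added_factors Named list of variable -> state, added in order.
#' @param x Derivation `cohort` (for `n_matching` and the bootstrap).
#' @param b Bootstrap replicates for the AR interval (0 skips the bootstrap).
#' @param seed Bootstrap seed.
#' @param target Outcome node.
#' @return Data frame, one row per cumulative scenario.
#' @export
scenario_sequence <- function(net, base, added_factors = list(), x = NULL,
                              b = 0, seed = 1,
                              target = intersect("morbidity", net$dag$nodes)[1]) {
  evs <- list(as_evidence(base))
  labels <- if (inherits(base, "scenario")) base$label else "base"
  acc <- as_evidence(base)
  for (v in names(added_factors)) {
    acc[[v]] <- added_factors[[v]]
    evs <- c(evs, list(acc))
    labels <- c(labels, paste0(labels[length(labels)], " + ", v, "=",
                               added_factors[[v]]))
  }
  ar_base <- absolute_risk(net, evs[[1]], target)
  ar_bg <- absolute_risk(net, list(), target)
  rows <- lapply(seq_along(evs), function(i) {
    ar <- absolute_risk(net, evs[[i]], target)
    ci <- c(NA_real_, NA_real_)
    if (b > 0 && !is.null(x)) {
      bs <- bootstrap_ci(x, net$dag, function(fit) {
        c(ar = absolute_risk(fit, evs[[i]], target))
      }, b = b, seed = seed)
      ci <- c(bs$ci_low[["ar"]], bs$ci_high[["ar"]])
    }
    data.frame(
      label = labels[i],
      ar_pct = 100 * ar,
      rr_background = ar / ar_bg,
      rr_base = ar / ar_base,
      ar_ci_low_pct = 100 * ci[1],
      ar_ci_high_pct = 100 * ci[2],
      n_matching = if (is.null(x)) NA_integer_ else n_matching(x, evs[[i]]),
      b = b,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Risk panel for alternate targets
#'
#' Any network variable can serve as the query target without refitting: for
#' each requested target the panel reports AR, RR vs the background, and
#' (optionally) RR vs a comparator scenario, under the same evidence.
#'
#' @param net Fitted `bayes_net`.
#' @param evidence Scenario evidence (named list).
#' @param targets Character vector of target nodes (not in the evidence).
#' @param comparator Optional comparator scenario for the second RR column.
#' @return Data frame, one row per target.
#' @export
alternate_target_panel <- function(net, evidence, targets, comparator = NULL) {
  evidence <- as_evidence(evidence)
  stopifnot(!any(targets %in% names(evidence)))
  rows <- lapply(targets, function(tg) {
    ar <- absolute_risk(net, evidence, target = tg)
    bg <- absolute_risk(net, list(), target = tg)
    rr_cmp <- if (is.null(comparator)) NA_real_ else {
      ar / absolute_risk(net, comparator, target = tg)
    }
    data.frame(target = tg, ar_pct = 100 * ar, rr_background = ar / bg,
               rr_comparator = rr_cmp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Joint distribution over a handful of nodes (all other variables summed
# out), as a named-dimension array.
joint_over <- function(net, keep) {
  pots <- lapply(net$dag$nodes, function(v) cpt_potential(net, v))
  for (v in min_fill_order(net, setdiff(net$dag$nodes, keep))) {
    inv <- vapply(pots, function(f) v %in% f$vars, logical(1))
    if (!any(inv)) next
    prod_f <- Reduce(potential_product, pots[inv])
    pots <- c(pots[!inv], list(potential_marginalize(prod_f, v)))
  }
  res <- Reduce(potential_product, pots)
  val <- res$val[index_map(keep, res$cards[keep], res$vars)]
  array(val, dim = res$cards[keep],
        dimnames = lapply(net$specs[keep], `[[`, "states"))
}

#' Scan for effect modification (interactions)
#'
#' For a binary effect variable, computes the stratum-specific RR of the
#' target (effect present vs absent) within each level of each context
#' variable, with bootstrap percentile CIs sharing replicates across strata.
#' A context is flagged when two of its strata have non-overlapping CIs;
#' the flag is `"reversal"` when the point RRs additionally sit on opposite
#' sides of 1, else `"magnitude"`. Strata with zero evidence mass are
#' skipped and reported.
#'
#' @param net Fitted `bayes_net` (point estimates).
#' @param x The `cohort` (bootstrap resampling).
#' @param effect_var Binary variable whose effect is examined.
#' @param context_vars Variables whose levels define the strata.
#' @param target Outcome node.
#' @param b Bootstrap replicates per scan.
#' @param seed Bootstrap seed.
#' @param method Parameter fitting for refits (`"mle"` or `"bayes"`).
#' @return List with `strata` (per-stratum RR + CI data frame) and
#'   `findings` (flagged contexts data frame).
#' @export
scan_interactions <- function(net, x, effect_var, context_vars,
                              target = x$outcome, b = 200, seed = 1,
                              method = "mle") {
  stopifnot(inherits(net, "bayes_net"), inherits(x, "cohort"))
  strata_rr <- function(fit, ctx) {
    jt <- joint_over(fit, c(target, effect_var, ctx))
    states <- setdiff(net$specs[[ctx]]$states, UNKNOWN_STATE)
    out <- c()
    for (s in states) {
      num_mass <- sum(jt[, "present", s])
      den_mass <- sum(jt[, "absent", s])
      if (num_mass <= 0 || den_mass <= 0) {
        out[s] <- NA_real_
        next
      }
      ar1 <- jt["present", "present", s] / num_mass
      ar0 <- jt["present", "absent", s] / den_mass
      out[s] <- ar1 / ar0
    }
    out
  }
  strata_list <- list()
  findings <- list()
  for (ctx in context_vars) {
    bs <- bootstrap_ci(x, net$dag, function(fit) strata_rr(fit, ctx),
                       b = b, seed = seed, method = method)
    point <- strata_rr(net, ctx)
    skipped <- names(point)[is.na(point)]
    df <- data.frame(
      context_var = ctx, stratum = names(point), rr = unname(point),
      ci_low = unname(bs$ci_low[names(point)]),
      ci_high = unname(bs$ci_high[names(point)]),
      stringsAsFactors = FALSE
    )
    strata_list[[ctx]] <- df
    ok <- df[!is.na(df$rr), , drop = FALSE]
    if (nrow(ok) >= 2) {
      for (i in seq_len(nrow(ok) - 1)) for (j in (i + 1):nrow(ok)) {
        no_overlap <- ok$ci_low[i] > ok$ci_high[j] ||
                      ok$ci_low[j] > ok$ci_high[i]
        if (isTRUE(no_overlap)) {
          reversal <- sign(ok$rr[i] - 1) * sign(ok$rr[j] - 1) < 0
          findings[[length(findings) + 1]] <- data.frame(
            effect_var = effect_var, context_var = ctx,
            stratum_a = ok$stratum[i], stratum_b = ok$stratum[j],
            rr_a = ok$rr[i], rr_b = ok$rr[j],
            flag = if (reversal) "reversal" else "magnitude",
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (length(skipped)) {
      attr(strata_list[[ctx]], "skipped") <- skipped
    }
  }
  list(
    strata = do.call(rbind, c(strata_list, list(make.row.names = FALSE))),
    findings = if (length(findings)) {
      do.call(rbind, findings)
    } else data.frame(effect_var = character(0), context_var = character(0),
                      stratum_a = character(0), stratum_b = character(0),
                      rr_a = numeric(0), rr_b = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE)
  )
}
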
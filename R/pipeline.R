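#' @title Configuration-driven pipeline
#' @description
#' Sequences the full analysis — simulate, encode, select, learn, evaluate,
#' query — from a single YAML-able configuration with per-stage seeds. Every
#' artifact is stamped with the configuration hash and seeds; a rerun with
#' the same configuration reproduces identical outputs.
#' @name pipeline
NULL

# FNV-1a over the serialized object (no external hashing dependency).
# State is kept as a double below 2^32; the multiply is split into 16-bit
# halves to stay within exact double-precision integer range.
fnv1a <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * prime + ((hi16 * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' Defaults run the full synthetic study: a calibrated truth network, a
#' sampled cohort with injected missingness, one-hot encoding of the
#' gestational-age and EFW categories, chi-square/MI ranking with Jaccard
#' pruning, a k-subset logistic search, structure learning with one-hot
#' family blacklists, stratified evaluation and the scenario/interaction
#' queries.
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @param ... Named overrides applied after the file.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    out_dir = "contextrisk-artifacts",
    n = 20000,
    seeds = list(simulate = 101, missingness = 102, split = 103,
                 structure = 104, bootstrap = 105, subsets = 106, folds = 107),
    selection = list(top_m = 12, k = 8, mode = "greedy", n_subsets = 200,
                     jaccard_threshold = 0.8,
                     forced_includes = c("hdp", "ga_term", "efw_lt3",
                                         "efw_p3to9")),
    network = list(restarts = 5, method = "bayes", alpha = 1),
    bootstrap_b = 200,
    folds = 5,
    scenarios = list(
      list(label = "EFW 3-9th percentile",
           evidence = list(efw_p3to9 = "present")),
      list(label = "EFW 3-9th + diabetes",
           evidence = list(efw_p3to9 = "present", diabetes = "present"))
    ),
    interaction = list(effect_var = "female_sex",
                       context_vars = "diabetes")
  )
  # top-level entries are replaced wholesale (modifyList would merge nested
  # lists and skip unnamed elements such as the scenario list)
  apply_overrides <- function(base, over) {
    for (i in seq_along(over)) base[[names(over)[i]]] <- over[[i]]
    base
  }
  if (!is.null(path)) cfg <- apply_overrides(cfg, yaml::read_yaml(path))
  cfg <- apply_overrides(cfg, list(...))
  stopifnot(cfg$bootstrap_b >= 2,
            all(vapply(cfg$seeds, is.numeric, logical(1))))
  class(cfg) <- "pipeline_config"
  cfg
}

artifact_path <- function(cfg, name) file.path(cfg$out_dir, name)

stamp <- function(cfg) {
  list(config_hash = fnv1a(unclass(cfg)), seeds = cfg$seeds)
}

write_stamped_json <- function(obj, cfg, path) {
  obj$provenance <- stamp(cfg)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline stages
#'
#' Each stage reads its upstream artifacts from `config$out_dir` and writes
#' its own, so stages can be run in isolation; [run_pipeline()] chains them.
#' `stage_simulate` writes the cohort CSV/schema and the truth network;
#' `stage_select` the feature ranking and final feature list; `stage_learn`
#' the learned network (JSON + DOT); `stage_evaluate` the evaluation report
#' (validation AUC, cross-validation, rare-pattern subsets); `stage_query`
#' the scenario risk table and interaction scan.
#'
#' @param cfg A [pipeline_config()].
#' @return Each stage returns its main artifact invisibly.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_truth_network(truth_config(n = cfg$n))
  write_network(truth, artifact_path(cfg, "truth_network.json"))
  x <- sample_cohort(truth, cfg$n, seed = cfg$seeds$simulate)
  x <- inject_missingness(x, attr(truth, "config")$missingness,
                          seed = cfg$seeds$missingness)
  write_cohort(x, artifact_path(cfg, "cohort.csv"))
  summary_df <- summarize_cohort(x)
  utils::write.csv(summary_df, artifact_path(cfg, "cohort_summary.csv"),
                   row.names = FALSE)
  write_stamped_json(list(n = n_records(x)), cfg,
                     artifact_path(cfg, "simulate.json"))
  invisible(x)
}

encoded_cohort <- function(cfg) {
  x <- read_cohort(artifact_path(cfg, "cohort.csv"))
  for (v in intersect(c("ga", "efw"), names(x$records))) x <- one_hot(x, v)
  x
}

#' @rdname pipeline-stages
#' @export
stage_select <- function(cfg) {
  x <- encoded_cohort(cfg)
  ranking <- rank_features(x)
  utils::write.csv(ranking, artifact_path(cfg, "feature_ranking.csv"),
                   row.names = FALSE)
  kept <- prune_redundant(ranking, x, cfg$selection$jaccard_threshold)
  top <- utils::head(kept, cfg$selection$top_m)
  combo <- search_combinations(x, top, min(cfg$selection$k, length(top)),
                               mode = cfg$selection$mode,
                               n_subsets = cfg$selection$n_subsets,
                               seed = cfg$seeds$subsets)
  features <- assemble_pgm_features(x, combo$feature_set,
                                    cfg$selection$forced_includes)
  write_stamped_json(list(top_candidates = top,
                          best_subset = combo$feature_set,
                          best_subset_auc = combo$auc,
                          n_evaluated = combo$n_evaluated,
                          features = features),
                     cfg, artifact_path(cfg, "features.json"))
  invisible(features)
}

#' @rdname pipeline-stages
#' @export
stage_learn <- function(cfg) {
  x <- encoded_cohort(cfg)
  sel <- jsonlite::read_json(artifact_path(cfg, "features.json"),
                             simplifyVector = TRUE)
  check_stamp(sel, cfg, "features.json")
  vars <- unique(c(unlist(sel$features), x$outcome))
  sub <- cohort(x$records[vars], x$outcome, x$specs[vars])
  bl <- blacklist_from_families(sub$specs)
  d <- learn_structure(sub, blacklist = bl, seed = cfg$seeds$structure,
                       restarts = cfg$network$restarts)
  net <- fit_parameters(d, sub, method = cfg$network$method,
                        alpha = cfg$network$alpha)
  write_network(net, artifact_path(cfg, "network.json"))
  write_dot(d, artifact_path(cfg, "network.dot"))
  write_stamped_json(list(nodes = d$nodes,
                          edges = apply(d$edges, 1, paste, collapse = " -> "),
                          bic = attr(d, "score")),
                     cfg, artifact_path(cfg, "learn.json"))
  invisible(net)
}

#' @rdname pipeline-stages
#' @export
stage_evaluate <- function(cfg) {
  x <- encoded_cohort(cfg)
  net <- read_network(artifact_path(cfg, "network.json"))
  vars <- setdiff(net$dag$nodes, x$outcome)
  sub <- cohort(x$records[c(vars, x$outcome)], x$outcome, x$specs[c(vars, x$outcome)])
  sp <- split_cohort(sub, fraction = 0.8, seed = cfg$seeds$split)
  refit <- fit_parameters(net$dag, sp$derivation,
                          method = cfg$network$method,
                          alpha = cfg$network$alpha)
  scores <- predict_risk(refit, sp$validation)
  y <- sp$validation$records[[sub$outcome]]
  report <- auc_with_ci(scores, y, b = cfg$bootstrap_b,
                        seed = cfg$seeds$bootstrap)
  cv <- cross_validate(sp$derivation, folds = cfg$folds,
                       builder = pgm_builder(d = net$dag,
                                             method = cfg$network$method,
                                             alpha = cfg$network$alpha),
                       seed = cfg$seeds$folds)
  nof1 <- unique_scenarios(sub, sp$validation, max_frequency = 1,
                           scores = scores, b = cfg$bootstrap_b,
                           seed = cfg$seeds$bootstrap)
  out <- list(
    validation = unclass(report),
    cv_auc = cv$auc, cv_mean_auc = cv$mean,
    nof1 = list(n = nof1$n, fraction_pct = nof1$fraction_pct,
                report = if (!is.null(nof1$report)) unclass(nof1$report),
                reason = nof1$reason)
  )
  write_stamped_json(out, cfg, artifact_path(cfg, "evaluation.json"))
  invisible(out)
}

#' @rdname pipeline-stages
#' @export
stage_query <- function(cfg) {
  x <- encoded_cohort(cfg)
  net <- read_network(artifact_path(cfg, "network.json"))
  vars <- setdiff(net$dag$nodes, x$outcome)
  sub <- cohort(x$records[c(vars, x$outcome)], x$outcome, x$specs[c(vars, x$outcome)])
  rows <- lapply(cfg$scenarios, function(sc) {
    miss <- setdiff(names(sc$evidence), net$dag$nodes)
    if (length(miss)) {
      stop("scenario '", sc$label, "' references unknown variable(s): ",
           paste(miss, collapse = ", "))
    }
    ar <- absolute_risk(net, sc$evidence, target = sub$outcome)
    bs <- bootstrap_ci(sub, net$dag, function(fit) {
      c(ar = absolute_risk(fit, sc$evidence, target = sub$outcome))
    }, b = cfg$bootstrap_b, seed = cfg$seeds$bootstrap,
    method = cfg$network$method, alpha = cfg$network$alpha)
    data.frame(label = sc$label, ar_pct = 100 * ar,
               rr_background = ar / absolute_risk(net, list(),
                                                  target = sub$outcome),
               ar_ci_low_pct = 100 * bs$ci_low[["ar"]],
               ar_ci_high_pct = 100 * bs$ci_high[["ar"]],
               n_matching = n_matching(sub, sc$evidence),
               b = cfg$bootstrap_b, stringsAsFactors = FALSE)
  })
  risks <- do.call(rbind, rows)
  utils::write.csv(risks, artifact_path(cfg, "scenario_risks.csv"),
                   row.names = FALSE)
  scan <- NULL
  if (!is.null(cfg$interaction) &&
      all(c(cfg$interaction$effect_var, cfg$interaction$context_vars) %in%
            net$dag$nodes)) {
    scan <- scan_interactions(net, sub, cfg$interaction$effect_var,
                              cfg$interaction$context_vars,
                              b = cfg$bootstrap_b,
                              seed = cfg$seeds$bootstrap)
    utils::write.csv(scan$strata, artifact_path(cfg, "interaction_strata.csv"),
                     row.names = FALSE)
    utils::write.csv(scan$findings,
                     artifact_path(cfg, "interaction_findings.csv"),
                     row.names = FALSE)
  }
  invisible(list(risks = risks, scan = scan))
}

check_stamp <- function(artifact, cfg, name) {
  got <- artifact$provenance$config_hash
  if (!is.null(got) && !identical(got, fnv1a(unclass(cfg)))) {
    warning("artifact '", name, "' was produced under a different ",
            "configuration (hash mismatch)", call. = FALSE)
  }
}

#' Run the full pipeline
#'
#' Chains simulate, select, learn, evaluate and query; any stage failure
#' aborts with the stage name and cause. Outputs land in `config$out_dir`;
#' a rerun with the same configuration is byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list with the evaluation report and query tables.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stages <- list(simulate = stage_simulate, select = stage_select,
                 learn = stage_learn, evaluate = stage_evaluate,
                 query = stage_query)
  out <- list()
  for (nm in names(stages)) {
    out[[nm]] <- tryCatch(stages[[nm]](cfg), error = function(e) {
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  invisible(out)
}
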
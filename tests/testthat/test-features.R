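bin_cohort <- function(df, outcome = "y") cohort(df, outcome)

test_that("chi-square and mutual information behave at the association extremes", {
  set.seed(21)
  y <- sample(c("absent", "present"), 4000, replace = TRUE, prob = c(0.7, 0.3))
  x <- bin_cohort(data.frame(same = y, indep = sample(c("absent", "present"),
                                                      4000, replace = TRUE),
                             y = y))
  rk <- rank_features(x)
  same <- rk[rk$variable == "same", ]
  p1 <- mean(y == "present")
  entropy <- -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
  expect_equal(same$mi, entropy, tolerance = 1e-12)
  expect_lt(same$chi2_p, 1e-100)
  expect_equal(same$combined_rank, 1)
  expect_gt(rk[rk$variable == "indep", "chi2_p"], 1e-6)
})

test_that("the Pearson statistic matches the standard implementation on a 2x2 table", {
  # cells (a=30, b=10, c=10, d=50): a/c = exposed rows, b/d = unexposed
  pred <- c(rep("present", 40), rep("absent", 60))
  out <- c(rep("present", 30), rep("absent", 10),
           rep("present", 10), rep("absent", 50))
  x <- bin_cohort(data.frame(v = pred, y = out))
  rk <- rank_features(x)
  ref <- stats::chisq.test(table(pred, out), correct = FALSE)
  expect_equal(rk$chi2_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(rk$chi2_p, unname(ref$p.value), tolerance = 1e-12)
})

test_that("independent predictors carry almost no plug-in information at large n", {
  set.seed(33)
  n <- 50000
  x <- bin_cohort(data.frame(
    v = sample(c("absent", "present"), n, replace = TRUE),
    y = sample(c("absent", "present"), n, replace = TRUE, prob = c(0.9, 0.1))))
  rk <- rank_features(x)
  expect_lt(rk$mi, 0.001)
})

test_that("degenerate single-state variables are flagged with zero statistics", {
  x <- bin_cohort(data.frame(flat = rep("absent", 50),
                             y = rep(c("absent", "present"), 25)))
  rk <- rank_features(x)
  expect_true(rk$degenerate)
  expect_equal(rk$chi2_stat, 0)
  expect_equal(rk$mi, 0)
})

test_that("Jaccard pruning keeps the clinically ranked twin and spares disjoint pairs", {
  n <- 200
  base <- c(rep("present", 50), rep("absent", n - 50))
  df <- data.frame(std_def = base, dup = base,
                   other = c(rep("absent", 50), rep("present", 30),
                             rep("absent", n - 80)),
                   y = sample(c(rep("present", 40), rep("absent", n - 40))))
  specs <- list(std_def = binary_spec("std_def", clinical_rank = 1L),
                dup = binary_spec("dup", clinical_rank = 5L),
                other = binary_spec("other"), y = binary_spec("y"))
  x <- cohort(df, "y", specs)
  rk <- rank_features(x)
  kept <- prune_redundant(rk, x, threshold = 0.8)
  expect_true("std_def" %in% kept)
  expect_false("dup" %in% kept)
  expect_true("other" %in% kept)  # disjoint from both: Jaccard 0

  # A subset of B with |A| = 50, |B| = 100 has Jaccard exactly 0.5
  df2 <- data.frame(a = c(rep("present", 50), rep("absent", 150)),
                    b = c(rep("present", 100), rep("absent", 100)),
                    y = rep(c("absent", "present"), 100))
  x2 <- bin_cohort(df2)
  expect_equal(contextrisk:::jaccard_present(df2$a, df2$b), 0.5)
  rk2 <- rank_features(x2)
  expect_length(prune_redundant(rk2, x2, threshold = 0.51), 2)
  expect_length(prune_redundant(rk2, x2, threshold = 0.5), 1)

  # both-all-absent pairs are defined as similarity 0
  expect_equal(contextrisk:::jaccard_present(rep("absent", 5),
                                             rep("absent", 5)), 0)
})

test_that("pruning is invariant to the cohort's column order", {
  x <- get_cohort(2000, seed = 41, missing = TRUE)
  xe <- one_hot(one_hot(x, "ga"), "efw")
  rk <- rank_features(xe)
  kept1 <- prune_redundant(rk, xe, 0.8)
  shuffled <- xe$records[, rev(names(xe$records))]
  xs <- cohort(shuffled, xe$outcome, xe$specs[rev(names(xe$records))])
  kept2 <- prune_redundant(rk, xs, 0.8)
  expect_identical(sort(kept1), sort(kept2))
})

test_that("ROC thresholds maximize Youden's J, ties toward the smaller cutpoint", {
  perfect <- derive_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(perfect$cutpoint, 3)
  expect_equal(perfect$j, 1)

  # worked 6-point set checked against an exhaustive scan oracle
  v <- c(1, 2, 3, 4, 5, 6); y <- c(0, 0, 1, 0, 1, 1)
  oracle <- sapply(v, function(cut) {
    pred <- v >= cut
    sum(pred & y == 1) / sum(y) + sum(!pred & y == 0) / sum(y == 0) - 1
  })
  best_j <- max(oracle)
  best_cut <- min(v[abs(oracle - best_j) < 1e-12])
  got <- derive_threshold(v, y)
  expect_equal(got$cutpoint, best_cut)
  expect_equal(got$j, best_j)

  set.seed(5)
  null <- derive_threshold(stats::runif(2000), sample(0:1, 2000, replace = TRUE))
  expect_lt(null$j, 0.1)
  expect_error(derive_threshold(c(1, 2), c(1, 1)), "both")
  expect_error(derive_threshold(c(2, 2), c(0, 1)), "distinct")
})

test_that("subset search finds the planted drivers and respects its budget", {
  set.seed(55)
  n <- 8000
  a <- sample(c("absent", "present"), n, replace = TRUE)
  b <- sample(c("absent", "present"), n, replace = TRUE)
  lp <- -2.2 + 1.4 * (a == "present") + 1.1 * (b == "present")
  y <- ifelse(stats::runif(n) < stats::plogis(lp), "present", "absent")
  df <- data.frame(a = a, b = b,
                   n1 = sample(c("absent", "present"), n, replace = TRUE),
                   n2 = sample(c("absent", "present"), n, replace = TRUE),
                   y = y)
  x <- bin_cohort(df)
  res <- search_combinations(x, c("a", "b", "n1", "n2"), k = 2,
                             mode = "exhaustive")
  expect_equal(res$feature_set, c("a", "b"))
  expect_equal(res$n_evaluated, 6)

  # k = m: single subset
  res_all <- search_combinations(x, c("a", "b"), k = 2, mode = "exhaustive")
  expect_equal(res_all$n_evaluated, 1)
  expect_equal(res_all$feature_set, c("a", "b"))

  # exhaustive best is at least as good as any single subset refit
  standalone <- contextrisk:::fit_logistic_auc(x, c("n1", "n2"))$auc
  expect_gte(res$auc, standalone - 1e-12)

  # C(30, 12) is refused with the exact count
  expect_error(
    search_combinations(x, sprintf("f%02d", 1:30), k = 12, mode = "exhaustive"),
    "86,493,225")

  # sampled mode is seed-deterministic
  s1 <- search_combinations(x, c("a", "b", "n1", "n2"), 2, mode = "sampled",
                            n_subsets = 4, seed = 9)
  s2 <- search_combinations(x, c("a", "b", "n1", "n2"), 2, mode = "sampled",
                            n_subsets = 4, seed = 9)
  expect_identical(s1$feature_set, s2$feature_set)

  greedy <- search_combinations(x, c("a", "b", "n1", "n2"), 2, mode = "greedy")
  expect_equal(greedy$feature_set, c("a", "b"))
})

test_that("final feature assembly unions significant and forced variables under the node cap", {
  set.seed(66)
  n <- 6000
  a <- sample(c("absent", "present"), n, replace = TRUE)
  noise <- sample(c("absent", "present"), n, replace = TRUE)
  y <- ifelse(stats::runif(n) < stats::plogis(-2 + 1.5 * (a == "present")),
              "present", "absent")
  x <- bin_cohort(data.frame(a = a, noise = noise,
                             forced1 = sample(c("absent", "present"), n,
                                              replace = TRUE),
                             y = y))
  out <- assemble_pgm_features(x, c("a", "noise"), c("noise", "forced1"))
  expect_equal(out, c("a", "noise", "forced1"))  # noise forced in, not duplicated
  expect_equal(assemble_pgm_features(x, character(0), c("forced1")),
               "forced1")
  expect_error(assemble_pgm_features(x, character(0), sprintf("f%02d", 1:20)),
               "fewer than 20")
})
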
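label_cohort <- function(n, events, seed = 1) {
  set.seed(seed)
  y <- c(rep("present", events), rep("absent", n - events))
  cohort(data.frame(v = sample(c("absent", "present"), n, replace = TRUE),
                    y = y), outcome = "y")
}

test_that("stratified splits round per class and partition losslessly", {
  x <- label_cohort(9558, 783)
  sp <- split_cohort(x, fraction = 0.8, seed = 4)
  # round(0.2 * 783) + round(0.2 * 8775) = 157 + 1755
  expect_equal(n_records(sp$validation), 1912)
  expect_equal(n_records(sp$derivation) + n_records(sp$validation), 9558)
  expect_length(intersect(sp$validation_idx,
                          setdiff(seq_len(9558), sp$validation_idx)), 0)
  ev_val <- sum(sp$validation$records$y == "present")
  expect_equal(ev_val, 157)
  sp2 <- split_cohort(x, fraction = 0.8, seed = 4)
  expect_identical(sp$validation_idx, sp2$validation_idx)

  single <- cohort(data.frame(v = rep("absent", 10),
                              y = rep("present", 10)), "y")
  expect_error(split_cohort(single), "both outcome classes")
  expect_warning(split_cohort(label_cohort(40, 3)), "fewer than 5")
})

test_that("cross-validation is stratified and calibrated at the extremes", {
  # perfectly separable: predictor identical to outcome
  n <- 600
  y <- rep(c("absent", "present"), c(480, 120))
  x <- cohort(data.frame(v = y, y = y), "y")
  cv <- cross_validate(x, folds = 5, builder = logistic_builder("v"), seed = 2)
  expect_true(all(cv$auc == 1))
  # fold sizes differ by at most one per class
  tab <- table(cv$fold, x$records$y)
  expect_lte(max(tab[, "present"]) - min(tab[, "present"]), 1)
  expect_lte(max(tab[, "absent"]) - min(tab[, "absent"]), 1)

  # permuted labels: mean AUC near 1/2
  set.seed(3)
  n <- 10000
  xr <- cohort(data.frame(v = sample(c("absent", "present"), n, replace = TRUE),
                          y = sample(rep(c("absent", "present"),
                                         c(n - 800, 800)))), "y")
  cvr <- cross_validate(xr, folds = 5, builder = logistic_builder("v"),
                        seed = 4)
  expect_lt(abs(cvr$mean - 0.5), 0.05)
})

test_that("AUC matches exhaustive pair counting and the reference implementation", {
  expect_equal(auc_with_ci(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), b = 10)$auc, 1)
  expect_equal(auc_with_ci(rep(0.5, 10), rep(c(0, 1), 5), b = 10)$auc, 0.5)

  # worked 6-score set with one discordant pair and one tie
  scores <- c(0.9, 0.7, 0.4, 0.8, 0.4, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  pairs <- expand.grid(e = which(labels == 1), ne = which(labels == 0))
  oracle <- mean(ifelse(scores[pairs$e] > scores[pairs$ne], 1,
                        ifelse(scores[pairs$e] == scores[pairs$ne], 0.5, 0)))
  expect_equal(auc_with_ci(scores, labels, b = 10)$auc, oracle)

  # property: pair-counting oracle on random small inputs
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    sc <- round(stats::runif(n), 2)  # ties likely
    lb <- sample(0:1, n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    pr <- expand.grid(e = which(lb == 1), ne = which(lb == 0))
    oracle <- mean(ifelse(sc[pr$e] > sc[pr$ne], 1,
                          ifelse(sc[pr$e] == sc[pr$ne], 0.5, 0)))
    expect_equal(contextrisk:::auc_mann_whitney(sc, lb), oracle,
                 tolerance = 1e-12)
  }

  # cross-check against an independent implementation
  set.seed(9)
  sc <- stats::runif(500); lb <- sample(0:1, 500, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(contextrisk:::auc_mann_whitney(sc, lb), ref, tolerance = 1e-12)
})

test_that("AUC confidence intervals bracket the point estimate and stay seed-stable", {
  set.seed(10)
  n <- 1000
  lb <- rep(c(0, 1), c(850, 150))
  sc <- stats::rnorm(n, mean = lb)
  r1 <- auc_with_ci(sc, lb, b = 200, seed = 5)
  r2 <- auc_with_ci(sc, lb, b = 200, seed = 5)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_lte(r1$ci_low, r1$auc)
  expect_gte(r1$ci_high, r1$auc)
  expect_true(is.finite(r1$threshold))
  expect_error(auc_with_ci(sc, rep(1, n), b = 10), "both classes")
})

test_that("paired-bootstrap AUC comparison separates distinct models only", {
  set.seed(11)
  n <- 2000
  lb <- rep(c(0, 1), c(1700, 300))
  identical_scores <- stats::runif(n)
  same <- compare_auc(identical_scores, identical_scores, lb, b = 100, seed = 1)
  expect_equal(same$p_value, 1)

  perfect <- as.numeric(lb) + stats::runif(n) * 0.01
  random <- stats::runif(n)
  res <- compare_auc(perfect, random, lb, b = 200, seed = 2)
  expect_lt(res$p_value, 0.01)
  res2 <- compare_auc(perfect, random, lb, b = 200, seed = 2)
  expect_identical(res$p_value, res2$p_value)
})

test_that("rare-pattern subsets follow the frequency cutoff and nest", {
  # all rows identical -> no unique scenarios
  same <- cohort(data.frame(v = rep("present", 30),
                            y = rep(c("absent", "present"), 15)), "y")
  u0 <- unique_scenarios(same, same, max_frequency = 1)
  expect_equal(u0$n, 0)

  # all rows distinct -> every validation row unique
  n <- 40
  distinct <- cohort(data.frame(v1 = sprintf("s%02d", 1:n),
                                y = rep(c("absent", "present"), n / 2)),
                     "y",
                     list(v1 = variable_spec("v1", sprintf("s%02d", 1:n)),
                          y = binary_spec("y")))
  u1 <- unique_scenarios(distinct, distinct, max_frequency = 1)
  expect_equal(u1$n, n)
  expect_equal(u1$fraction_pct, 100)

  # planted duplicate blocks vs a direct grouping oracle
  x <- get_cohort(4000, seed = 71, missing = TRUE)
  sp <- split_cohort(x, seed = 7)
  vars <- setdiff(names(x$records), "morbidity")
  key <- function(df) do.call(paste, c(lapply(df[vars], as.character),
                                       list(sep = "|")))
  full_counts <- table(key(x$records))
  val_keys <- key(sp$validation$records)
  for (f in c(1, 5, 10)) {
    u <- unique_scenarios(x, sp$validation, max_frequency = f)
    expect_equal(u$n, sum(full_counts[val_keys] <= f))
  }
  n1 <- unique_scenarios(x, sp$validation, 1)$idx
  n5 <- unique_scenarios(x, sp$validation, 5)$idx
  n10 <- unique_scenarios(x, sp$validation, 10)$idx
  expect_true(all(n1 %in% n5) && all(n5 %in% n10))
})
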
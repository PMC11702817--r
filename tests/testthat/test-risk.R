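test_that("absolute and relative risks reduce to exact queries", {
  net <- get_truth_net()
  expect_equal(absolute_risk(net, list()), 0.082, tolerance = 1e-6)
  # evidence on a node d-separated from the target leaves the risk unchanged
  ind <- two_node_net()
  expect_equal(absolute_risk(ind, list(a = "present"), target = "b"),
               absolute_risk(ind, list(), target = "b"), tolerance = 1e-12)
  # planted scenario equals the enumeration oracle
  ev <- list(efw = "p3to9", diabetes = "present", female_sex = "present")
  bf <- brute_force_query(net, "morbidity", ev)$distribution[["present"]]
  expect_equal(absolute_risk(net, ev), unname(bf), tolerance = 1e-10)

  s <- scenario("EFW 3-9th", list(efw = "p3to9"))
  expect_equal(relative_risk(net, s, reference = s), 1)
  # ratio algebra: RR(s | background) = RR(s | ref) * RR(ref | background)
  ref <- scenario("diabetes", list(diabetes = "present"))
  expect_equal(relative_risk(net, s),
               relative_risk(net, s, reference = ref) * relative_risk(net, ref),
               tolerance = 1e-12)
})

test_that("relative risk follows constructed CPTs", {
  # outcome depends only on s: P(m | s) = 0.2, P(m | not s) = 0.0889,
  # P(s) = 0.1 -> background 0.1 and RR(s) = 2
  specs <- list(s = binary_spec("s"), m = binary_spec("m"))
  d <- dag(c("s", "m"), rbind(c("s", "m")))
  p0 <- (0.1 - 0.1 * 0.2) / 0.9
  cpts <- list(
    s = list(node = "s", parents = character(0),
             prob = matrix(c(0.9, 0.1, 0), ncol = 1)),
    m = list(node = "m", parents = "s",
             prob = matrix(c(1 - p0, p0, 0, 0.8, 0.2, 0, 1 / 3, 1 / 3, 1 / 3),
                           ncol = 3))
  )
  net <- bayes_net(d, cpts, specs)
  expect_equal(absolute_risk(net, list(), target = "m"), 0.1,
               tolerance = 1e-12)
  expect_equal(relative_risk(net, list(s = "present"), target = "m"), 2,
               tolerance = 1e-12)
})

test_that("bootstrap intervals are deterministic, degenerate-safe, and shrink with n", {
  net <- get_truth_net()
  # degenerate cohort: identical rows -> zero-width interval
  one <- sample_cohort(net, 1, seed = 2)
  rows <- one$records[rep(1, 60), , drop = FALSE]
  x0 <- cohort(rows, "morbidity", one$specs)
  d2 <- dag(c("female_sex", "morbidity"),
            rbind(c("female_sex", "morbidity")))
  bs0 <- bootstrap_ci(x0, d2, function(fit) {
    c(p = absolute_risk(fit, list(), target = "morbidity"))
  }, b = 25, seed = 1)
  expect_equal(unname(bs0$ci_low), unname(bs0$ci_high))

  query <- function(fit) c(ar = absolute_risk(fit, list(female_sex = "present")))
  x_small <- get_cohort(2000, seed = 51)
  x_big <- get_cohort(20000, seed = 52)
  b1 <- bootstrap_ci(x_small, net$dag, query, b = 100, seed = 3)
  b2 <- bootstrap_ci(x_small, net$dag, query, b = 100, seed = 3)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_ci(x_big, net$dag, query, b = 100, seed = 3)
  w1 <- b1$ci_high[["ar"]] - b1$ci_low[["ar"]]
  w3 <- b3$ci_high[["ar"]] - b3$ci_low[["ar"]]
  expect_lt(w3, w1)
  expect_equal(bs0$n_failed, 0)
})

test_that("scenario sequences accumulate risk factors monotonically on the truth network", {
  net <- get_truth_net()
  x <- get_cohort(2000, seed = 51)
  base <- scenario("EFW 3-9th percentile", list(efw = "p3to9"))
  tab <- scenario_sequence(net, base,
                          list(diabetes = "present", anomaly = "present",
                               ga = "early_ptb"), x = x)
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$ar_pct) > -1e-12))
  expect_equal(tab$rr_base[1], 1)
  # n_matching equals a direct row filter
  manual <- sum(x$records$efw == "p3to9" & x$records$diabetes == "present")
  expect_equal(tab$n_matching[2], manual)
  # matching counts are reported even when zero
  expect_true(all(tab$n_matching >= 0))

  single <- scenario_sequence(net, base, list(), x = x)
  expect_equal(nrow(single), 1)
})

test_that("alternate targets reuse the same joint distribution", {
  net <- get_truth_net()
  panel <- alternate_target_panel(net, list(efw = "p3to9"),
                                  c("apgar_low", "urgent_cesarean",
                                    "progesterone"))
  expect_equal(nrow(panel), 3)
  # progesterone is d-separated from efw: RR exactly 1
  expect_equal(panel$rr_background[panel$target == "progesterone"], 1,
               tolerance = 1e-9)
  # each row equals its standalone query
  q <- query_net(net, "urgent_cesarean", list(efw = "p3to9"))
  expect_equal(panel$ar_pct[panel$target == "urgent_cesarean"],
               100 * unname(q$distribution[["present"]]), tolerance = 1e-9)
  # swapped roles: outcome as evidence, former predictor as target
  swap <- query_net(net, "diabetes", list(morbidity = "present"))
  bf <- brute_force_query(net, "diabetes", list(morbidity = "present"))
  expect_equal(swap$distribution, bf$distribution, tolerance = 1e-10)
  expect_error(alternate_target_panel(net, list(efw = "p3to9"), "efw"))
})

test_that("the interaction scanner flags the planted reversal and stays quiet without it", {
  x <- get_cohort(50000, seed = 61)
  net <- fit_parameters(get_truth_net()$dag, x, method = "mle")
  scan <- scan_interactions(net, x, "female_sex", "diabetes",
                            b = 80, seed = 5)
  expect_equal(nrow(scan$findings), 1)
  expect_equal(scan$findings$flag, "reversal")
  expect_lt(scan$strata$rr[scan$strata$stratum == "absent"], 1)
  expect_gt(scan$strata$rr[scan$strata$stratum == "present"], 1)

  flat <- get_flat_net()
  xf <- sample_cohort(flat, 50000, seed = 62)
  netf <- fit_parameters(flat$dag, xf, method = "mle")
  scanf <- scan_interactions(netf, xf, "female_sex", "diabetes",
                             b = 80, seed = 5)
  expect_equal(nrow(scanf$findings), 0)
})

test_that("identical stratum CPT rows give identical RRs and no flag", {
  # outcome depends on the effect only; context is independent
  specs <- list(e = binary_spec("e"), c = binary_spec("c"),
                m = binary_spec("m"))
  d <- dag(c("e", "c", "m"), rbind(c("e", "m")))
  cpts <- list(
    e = list(node = "e", parents = character(0),
             prob = matrix(c(0.5, 0.5, 0), ncol = 1)),
    c = list(node = "c", parents = character(0),
             prob = matrix(c(0.6, 0.4, 0), ncol = 1)),
    m = list(node = "m", parents = "e",
             prob = matrix(c(0.9, 0.1, 0, 0.7, 0.3, 0, 1 / 3, 1 / 3, 1 / 3),
                           ncol = 3))
  )
  net <- bayes_net(d, cpts, specs)
  x <- sample_cohort(net, 4000, seed = 9, outcome = "m")
  scan <- scan_interactions(net, x, "e", "c", target = "m", b = 40, seed = 2)
  rr <- scan$strata$rr
  expect_equal(rr[1], rr[2], tolerance = 1e-9)
  expect_equal(nrow(scan$findings), 0)
})
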
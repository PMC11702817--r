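mk_cohort <- function(df, outcome = names(df)[ncol(df)]) {
  cohort(df, outcome)
}

test_that("DAG construction rejects cycles, self-edges and duplicates", {
  expect_error(dag(c("a", "b"), rbind(c("a", "b"), c("b", "a"))), "cycle")
  expect_error(dag("a", rbind(c("a", "a"))), "self-edges")
  expect_error(dag(c("a", "b"), rbind(c("a", "b"), c("a", "b"))), "duplicate")
  d <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(topo_sort(d), c("a", "b", "c"))
})

test_that("BIC matches the closed form for a single binary node", {
  y <- c(rep("present", 6), rep("absent", 4))
  x <- mk_cohort(data.frame(y = y))
  d <- dag("y")
  expect_equal(bic_score(d, x),
               6 * log(0.6) + 4 * log(0.4) - 0.5 * log(10),
               tolerance = 1e-12)
})

test_that("BIC equals an independent log-likelihood oracle plus penalty", {
  set.seed(42)
  n <- 400
  a <- sample(c("absent", "present"), n, replace = TRUE, prob = c(0.4, 0.6))
  b <- ifelse(stats::runif(n) < ifelse(a == "present", 0.8, 0.3),
              "present", "absent")
  x <- mk_cohort(data.frame(a = a, b = b), outcome = "b")
  for (edges in list(matrix(character(0), ncol = 2), rbind(c("a", "b")))) {
    d <- dag(c("a", "b"), edges)
    fit <- fit_parameters(d, x, method = "mle")
    ll <- sum(log(vapply(seq_len(n), function(i) {
      joint_probability(fit, list(a = a[i], b = b[i]))
    }, numeric(1))))
    # penalty: one free parameter per observed parent configuration
    d_free <- if (nrow(edges)) 1 + 2 else 1 + 1
    expect_equal(bic_score(d, x), ll - d_free / 2 * log(n), tolerance = 1e-8)
  }
})

test_that("likelihood-equivalent structures score equally; edges never hurt the likelihood", {
  set.seed(7)
  n <- 1000
  a <- sample(c("absent", "present"), n, replace = TRUE)
  b <- ifelse(stats::runif(n) < ifelse(a == "present", 0.7, 0.4),
              "present", "absent")
  x <- mk_cohort(data.frame(a = a, b = b), outcome = "b")
  s_ab <- bic_score(dag(c("a", "b"), rbind(c("a", "b"))), x)
  s_ba <- bic_score(dag(c("a", "b"), rbind(c("b", "a"))), x)
  expect_equal(s_ab, s_ba, tolerance = 1e-9)
  # likelihood term (score + penalty) never decreases when adding an edge
  s_empty <- bic_score(dag(c("a", "b")), x)
  ll_edge <- s_ab + (1 + 2) / 2 * log(n)
  ll_empty <- s_empty + (1 + 1) / 2 * log(n)
  expect_gte(ll_edge + 1e-9, ll_empty)
})

test_that("hill-climbing recovers a strong planted dependency and prunes noise", {
  set.seed(11)
  n <- 5000
  a <- sample(c("absent", "present"), n, replace = TRUE)
  b <- ifelse(stats::runif(n) < ifelse(a == "present", 0.9, 0.1),
              "present", "absent")
  noise <- sample(c("absent", "present"), n, replace = TRUE)
  x <- mk_cohort(data.frame(a = a, b = b, noise = noise), outcome = "b")
  d <- learn_structure(x, seed = 1, restarts = 2)
  expect_true("a~b" %in% skeleton(d$edges))
  expect_false(any(grepl("noise", skeleton(d$edges))))

  # fully independent variables: empty graph
  set.seed(12)
  ind <- as.data.frame(replicate(4, sample(c("absent", "present"), 2000,
                                           replace = TRUE)))
  names(ind) <- letters[1:4]
  d0 <- learn_structure(mk_cohort(ind, outcome = "a"), seed = 1, restarts = 2)
  expect_equal(nrow(d0$edges), 0)
})

test_that("blacklisted edges never appear, even under deterministic dependence", {
  set.seed(13)
  n <- 2000
  early <- sample(c("absent", "present"), n, replace = TRUE, prob = c(0.7, 0.3))
  term <- ifelse(early == "present", "absent", "present")  # deterministic
  x <- mk_cohort(data.frame(early_ptb = early, term = term), outcome = "term")
  bl <- rbind(c("early_ptb", "term"), c("term", "early_ptb"))
  d <- learn_structure(x, blacklist = bl, seed = 1, restarts = 3)
  expect_equal(nrow(d$edges), 0)
})

test_that("family blacklists forbid both directions within each family", {
  specs <- list(
    a = binary_spec("a", family = "ga"), b = binary_spec("b", family = "ga"),
    c = binary_spec("c", family = "ga"),
    d = binary_spec("d", family = "efw"), e = binary_spec("e", family = "efw"),
    f = binary_spec("f", family = "efw"), g = binary_spec("g", family = "efw"),
    h = binary_spec("h")
  )
  bl <- blacklist_from_families(specs)
  expect_equal(nrow(bl), 6 + 12)
  expect_true(all(c("a", "b") %in% bl[, 1]))
  expect_equal(nrow(blacklist_from_families(list(h = binary_spec("h")))), 0)
  ga_pairs <- bl[bl[, 1] %in% c("a", "b", "c"), , drop = FALSE]
  expect_equal(nrow(ga_pairs), 6)
})

test_that("learned structures are always acyclic and blacklist-respecting", {
  bl <- rbind(c("v1", "v2"), c("v2", "v1"))
  for (s in 1:5) {
    set.seed(100 + s)
    df <- as.data.frame(replicate(5, {
      z <- sample(c("absent", "present", "unknown"), 800, replace = TRUE,
                  prob = c(0.5, 0.4, 0.1))
      z
    }))
    names(df) <- paste0("v", 1:5)
    df$v2 <- ifelse(df$v1 == "present" & stats::runif(800) < 0.8,
                    "present", df$v2)
    df$v2[df$v2 == "unknown"] <- "absent"
    df$v5 <- sample(c("absent", "present"), 800, replace = TRUE)
    x <- cohort(df, outcome = "v5")
    d <- learn_structure(x, blacklist = bl, seed = s, restarts = 3)
    expect_false(is.null(topo_sort(d)))
    if (nrow(d$edges)) {
      expect_false(any(paste(d$edges[, 1], d$edges[, 2]) %in%
                         paste(bl[, 1], bl[, 2])))
    }
    expect_gte(attr(d, "score"), bic_score(dag(d$nodes), x) - 1e-9)
  }
})

test_that("parameter estimation follows the MLE and Laplace closed forms", {
  y <- c(rep("present", 6), rep("absent", 4))
  x <- mk_cohort(data.frame(y = y))
  d <- dag("y")
  mle <- fit_parameters(d, x, method = "mle")
  expect_equal(as.vector(mle$cpts$y$prob),
               c(0.4, 0.6, 0))  # states: absent, present, unknown
  bay <- fit_parameters(d, x, method = "bayes", alpha = 1)
  expect_equal(as.vector(bay$cpts$y$prob), c(5, 7, 1) / 13)

  # unobserved parent configuration -> uniform fallback, flagged
  df <- data.frame(p = rep("absent", 10),
                   ch = rep(c("absent", "present"), 5))
  x2 <- mk_cohort(df, outcome = "ch")
  d2 <- dag(c("p", "ch"), rbind(c("p", "ch")))
  fit2 <- fit_parameters(d2, x2, method = "mle")
  expect_equal(unname(attr(fit2, "fallback_configs")["ch"]), 2)
  expect_equal(fit2$cpts$ch$prob[, 2], rep(1 / 3, 3), ignore_attr = TRUE)
  expect_lt(max(abs(colSums(fit2$cpts$ch$prob) - 1)), 1e-12)
})

test_that("networks survive a JSON round trip", {
  net <- get_truth_net()
  path <- file.path(tempdir(), "net-roundtrip.json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(sort(back$dag$nodes), sort(net$dag$nodes))
  expect_equal(skeleton(back$dag$edges), skeleton(net$dag$edges))
  q1 <- query_net(net, "morbidity", list(efw = "p3to9", diabetes = "present"))
  q2 <- query_net(back, "morbidity", list(efw = "p3to9", diabetes = "present"))
  expect_equal(q1$distribution, q2$distribution, tolerance = 1e-12)
  dot <- file.path(tempdir(), "net.dot")
  write_dot(net$dag, dot)
  expect_true(any(grepl("->", readLines(dot))))
})
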
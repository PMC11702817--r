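# Shared fixtures, memoized per test run (the truth network involves a
# root-finding calibration; building it once keeps the suite fast).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  got <- .fixture_env[[key]]
  if (is.null(got)) {
    got <- force(expr)
    .fixture_env[[key]] <- got
  }
  got
}

get_truth_net <- function() memo("truth", make_truth_network())

get_flat_net <- function() {
  memo("flat", make_truth_network(truth_config(interaction = FALSE)))
}

get_cohort <- function(n, seed = 7, missing = FALSE) {
  memo(paste0("cohort", n, "_", seed, "_", missing), {
    x <- sample_cohort(get_truth_net(), n, seed = seed)
    if (missing) {
      x <- inject_missingness(x, list(efw = 0.064, bp_high = 0.049),
                              seed = seed + 1)
    }
    x
  })
}

# Two independent binary nodes with P(present) = 0.3 and 0.5.
two_node_net <- function() {
  specs <- list(a = binary_spec("a"), b = binary_spec("b"))
  d <- dag(c("a", "b"))
  cpts <- list(
    a = list(node = "a", parents = character(0),
             prob = matrix(c(0.7, 0.3, 0), ncol = 1)),
    b = list(node = "b", parents = character(0),
             prob = matrix(c(0.5, 0.5, 0), ncol = 1))
  )
  bayes_net(d, cpts, specs)
}

# Chain a -> b with P(a=present)=0.4, P(b=present|a) = 0.9 / 0.2.
chain_net <- function() {
  specs <- list(a = binary_spec("a"), b = binary_spec("b"))
  d <- dag(c("a", "b"), rbind(c("a", "b")))
  cpts <- list(
    a = list(node = "a", parents = character(0),
             prob = matrix(c(0.6, 0.4, 0), ncol = 1)),
    b = list(node = "b", parents = "a",
             # parent configs: a = absent, present, unknown
             prob = matrix(c(0.8, 0.2, 0,
                             0.1, 0.9, 0,
                             1 / 3, 1 / 3, 1 / 3), ncol = 3))
  )
  bayes_net(d, cpts, specs)
}

# Collider a -> c <- b, all binary, with fixed CPTs.
collider_net <- function() {
  specs <- list(a = binary_spec("a"), b = binary_spec("b"),
                c = binary_spec("c"))
  d <- dag(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
  p_c <- function(a, b) 0.05 + 0.6 * a + 0.3 * b  # P(c = present | a, b)
  # config order: first parent (a) fastest; states absent, present, unknown
  cfg <- expand.grid(a = c(0, 1, NA), b = c(0, 1, NA))
  prob <- sapply(seq_len(nrow(cfg)), function(i) {
    if (is.na(cfg$a[i]) || is.na(cfg$b[i])) return(c(1 / 3, 1 / 3, 1 / 3))
    p <- p_c(cfg$a[i], cfg$b[i])
    c(1 - p, p, 0)
  })
  cpts <- list(
    a = list(node = "a", parents = character(0),
             prob = matrix(c(0.55, 0.45, 0), ncol = 1)),
    b = list(node = "b", parents = character(0),
             prob = matrix(c(0.35, 0.65, 0), ncol = 1)),
    c = list(node = "c", parents = c("a", "b"), prob = prob)
  )
  bayes_net(d, cpts, specs)
}

# Random DAG + random Dirichlet CPTs over n_nodes variables with 2-3
# observable states each (plus "unknown", which receives probability mass so
# that queries exercise it as an ordinary state).
random_net <- function(n_nodes, seed, max_parents = 3) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  specs <- lapply(nodes, function(v) {
    k <- sample(2:3, 1)
    variable_spec(v, paste0("s", seq_len(k)))
  })
  names(specs) <- nodes
  edges <- NULL
  for (j in seq_along(nodes)[-1]) {
    k <- min(j - 1, sample(0:max_parents, 1))
    if (k > 0) {
      pa <- sample(nodes[seq_len(j - 1)], k)
      edges <- rbind(edges, cbind(pa, nodes[j]))
    }
  }
  d <- dag(nodes, if (is.null(edges)) matrix(character(0), ncol = 2) else edges)
  cards <- vapply(specs, function(s) length(s$states), integer(1))
  cpts <- lapply(nodes, function(v) {
    q <- prod(cards[d$parents[[v]]], 1)
    r <- cards[[v]]
    raw <- matrix(stats::rgamma(r * q, shape = 1) + 0.05, nrow = r)
    list(node = v, parents = unname(d$parents[[v]]),
         prob = sweep(raw, 2, colSums(raw), "/"))
  })
  names(cpts) <- nodes
  bayes_net(d, cpts, specs)
}

# Undirected skeleton of an edge matrix, as sorted "a~b" strings.
skeleton <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(character(0))
  unique(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
               sep = "~"))
}

skeleton_f1 <- function(learned, truth) {
  ls <- skeleton(learned); ts <- skeleton(truth)
  tp <- length(intersect(ls, ts))
  if (tp == 0) return(0)
  prec <- tp / length(ls); rec <- tp / length(ts)
  2 * prec * rec / (prec + rec)
}
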
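#' @title Discrete Bayesian network core
#' @description
#' A `bayes_net` couples a DAG over categorical variables with one conditional
#' probability table (CPT) per node. Structure is learned by greedy BIC
#' hill-climbing over add/delete/reverse moves, honoring edge blacklists
#' (mutually exclusive one-hot siblings must not predict each other);
#' parameters by maximum likelihood or Dirichlet-smoothed (Bayesian)
#' estimation. The `"unknown"` state is scored and fitted as an ordinary
#' category: missingness is modeled, never dropped.
#' @name bayesnet
NULL

#' Construct a DAG
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column character matrix (parent, child); may have 0 rows.
#' @return Object of class `net_dag` with `nodes`, `edges`, and `parents`
#'   (named list of parent vectors, in stable order).
#' @export
dag <- function(nodes, edges = matrix(character(0), ncol = 2)) {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes))
  edges <- matrix(as.character(edges), ncol = 2)
  colnames(edges) <- c("parent", "child")
  if (nrow(edges)) {
    if (!all(edges %in% nodes)) stop("edge endpoints must be nodes")
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  }
  parents <- lapply(nodes, function(v) edges[edges[, 2] == v, 1])
  names(parents) <- nodes
  d <- structure(list(nodes = nodes, edges = edges, parents = parents),
                 class = "net_dag")
  if (is.null(topo_sort(d))) stop("edges contain a cycle")
  d
}

#' Topological order of a DAG (NULL if cyclic)
#' @param d A `net_dag`.
#' @return Character vector of nodes in topological order, or NULL.
#' @export
topo_sort <- function(d) {
  indeg <- vapply(d$parents, length, integer(1))
  order <- character(0)
  avail <- names(indeg)[indeg == 0]
  children <- lapply(d$nodes, function(v) d$edges[d$edges[, 1] == v, 2])
  names(children) <- d$nodes
  while (length(avail)) {
    v <- sort(avail)[1]
    avail <- setdiff(avail, v)
    order <- c(order, v)
    for (c in children[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) avail <- c(avail, c)
    }
  }
  if (length(order) != length(d$nodes)) NULL else order
}

#' @export
print.net_dag <- function(x, ...) {
  cat("<dag> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Assemble a Bayesian network
#'
#' @param d A `net_dag`.
#' @param cpts Named list, one per node:
#'   `list(parents = <chr>, prob = <matrix states x parent-configs>)`.
#'   Column j of `prob` is the distribution of the node's states given the
#'   j-th parent configuration (first parent varying fastest); each column
#'   sums to 1.
#' @param specs Named list of [variable_spec()] per node; `spec$states` fixes
#'   the row order of each CPT.
#' @param validate Check CPT consistency (set FALSE in hot loops).
#' @return Object of class `bayes_net`.
#' @export
bayes_net <- function(d, cpts, specs, validate = TRUE) {
  net <- structure(list(dag = d, cpts = cpts, specs = specs), class = "bayes_net")
  if (validate) validate_net(net)
  net
}

validate_net <- function(net) {
  d <- net$dag
  stopifnot(setequal(names(net$cpts), d$nodes), setequal(names(net$specs), d$nodes))
  for (v in d$nodes) {
    cpt <- net$cpts[[v]]
    if (!identical(sort(cpt$parents), sort(unname(d$parents[[v]])))) {
      stop("CPT parents of '", v, "' do not match the DAG")
    }
    r <- length(net$specs[[v]]$states)
    q <- prod(vapply(cpt$parents, function(p) length(net$specs[[p]]$states),
                     numeric(1)))
    if (!is.matrix(cpt$prob) || nrow(cpt$prob) != r || ncol(cpt$prob) != q) {
      stop("CPT of '", v, "' has wrong dimensions")
    }
    if (any(abs(colSums(cpt$prob) - 1) > 1e-12)) {
      stop("CPT columns of '", v, "' must sum to 1")
    }
  }
  invisible(net)
}

#' @export
print.bayes_net <- function(x, ...) {
  cat("<bayes_net> ", length(x$dag$nodes), " nodes, ", nrow(x$dag$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Number of states of each node
#' @param net A `bayes_net`.
#' @return Named integer vector.
#' @export
node_cards <- function(net) {
  vapply(net$specs, function(s) length(s$states), integer(1))[net$dag$nodes]
}

# Integer-code a cohort's records against a spec list: matrix n x p of
# 1-based state indices.
encode_records <- function(records, specs, nodes = names(specs)) {
  m <- vapply(nodes, function(v) {
    f <- records[[v]]
    if (is.null(f)) stop("cohort lacks column '", v, "'")
    if (is.factor(f) && identical(levels(f), specs[[v]]$states)) {
      as.integer(f)
    } else {
      match(as.character(f), specs[[v]]$states)
    }
  }, integer(nrow(records)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(records))
  colnames(m) <- nodes
  if (anyNA(m)) stop("records contain states outside their specs")
  m
}

# Combined (child, parent-config) code per record for one node: values in
# 1..(r*q); config index uses first parent fastest.
family_code <- function(code, node, parents, cards) {
  cfg <- rep.int(1L, nrow(code))
  mult <- 1L
  for (p in parents) {
    cfg <- cfg + (code[, p] - 1L) * mult
    mult <- mult * cards[[p]]
  }
  (cfg - 1L) * cards[[node]] + code[, node]
}

family_counts <- function(code, node, parents, cards) {
  r <- cards[[node]]
  q <- prod(unlist(cards[parents], use.names = FALSE), 1)
  fc <- family_code(code, node, parents, cards)
  matrix(tabulate(fc, nbins = r * q), nrow = r, ncol = q)
}

# Per-node BIC contribution: maximized log likelihood minus penalty.
# The free-parameter count uses the states and parent configurations
# actually observed in the data: an unobserved parent configuration takes
# the uniform fallback and estimates nothing, and a never-observed state
# (e.g. "unknown" on a fully observed variable) sits at the MLE boundary 0.
node_bic <- function(code, node, parents, cards, n) {
  counts <- family_counts(code, node, parents, cards)
  tot <- colSums(counts)
  obs <- tot > 0
  ll <- 0
  if (any(obs)) {
    cc <- counts[, obs, drop = FALSE]
    p <- sweep(cc, 2, tot[obs], "/")
    nz <- cc > 0
    ll <- sum(cc[nz] * log(p[nz]))
  }
  r_obs <- sum(rowSums(counts) > 0)
  d_free <- max(r_obs - 1, 0) * sum(obs)
  ll - d_free / 2 * log(n)
}

#' BIC score of a DAG on a cohort
#'
#' `score = sum over nodes of [max log-likelihood of node given parents]
#' - (d/2) ln N`, with natural logs and `d` the number of free parameters
#' (see the methods vignette for how unobserved parent configurations are
#' counted). Higher is better; the score decomposes node-wise.
#'
#' @param d A `net_dag`.
#' @param x A `cohort` covering the DAG's nodes.
#' @return Numeric scalar.
#' @export
bic_score <- function(d, x) {
  stopifnot(inherits(x, "cohort"))
  code <- encode_records(x$records, x$specs, d$nodes)
  cards <- lapply(x$specs[d$nodes], function(s) length(s$states))
  n <- nrow(code)
  sum(vapply(d$nodes, function(v) node_bic(code, v, d$parents[[v]], cards, n),
             numeric(1)))
}

#' Blacklist within-family edges
#'
#' For every pair of one-hot siblings (variables sharing a `family`
#' identifier) both directed edges are forbidden, so that e.g. the absence of
#' term birth cannot be used to predict preterm birth.
#'
#' @param specs Named list of [variable_spec()] objects.
#' @return Two-column character matrix (parent, child) of forbidden edges.
#' @export
blacklist_from_families <- function(specs) {
  fams <- vapply(specs, function(s) s$family, character(1))
  out <- matrix(character(0), ncol = 2,
                dimnames = list(NULL, c("parent", "child")))
  for (f in unique(stats::na.omit(fams))) {
    members <- names(specs)[!is.na(fams) & fams == f]
    if (length(members) > 1) {
      pairs <- expand.grid(parent = members, child = members,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$parent != pairs$child, ]
      out <- rbind(out, as.matrix(pairs))
    }
  }
  rownames(out) <- NULL
  out
}

#' Fit CPT parameters on a fixed DAG
#'
#' `mle`: cell probability = count / row total, with a uniform fallback for
#' parent configurations never observed (flagged). `bayes`: symmetric
#' Dirichlet smoothing, `(count + alpha) / (total + alpha * r)`.
#'
#' @param d A `net_dag`.
#' @param x A `cohort`.
#' @param method `"bayes"` (default) or `"mle"`.
#' @param alpha Dirichlet strength (> 0) for `method = "bayes"`.
#' @return A `bayes_net`. Nodes with uniform-fallback columns carry their
#'   count in `attr(net, "fallback_configs")`.
#' @export
fit_parameters <- function(d, x, method = c("bayes", "mle"), alpha = 1) {
  method <- match.arg(method)
  stopifnot(inherits(x, "cohort"))
  code <- encode_records(x$records, x$specs, d$nodes)
  fit_parameters_coded(d, code, x$specs[d$nodes], method, alpha)
}

# Internal fitting path reused by the bootstrap (pre-encoded records).
fit_parameters_coded <- function(d, code, specs, method = "bayes", alpha = 1,
                                 validate = FALSE) {
  cards <- lapply(specs, function(s) length(s$states))
  fallback <- integer(0)
  cpts <- lapply(d$nodes, function(v) {
    counts <- family_counts(code, v, d$parents[[v]], cards)
    prob <- normalize_counts(counts, method, alpha)
    if (method == "mle") {
      nf <- sum(colSums(counts) == 0)
      if (nf > 0) fallback[[v]] <<- nf
    }
    list(node = v, parents = unname(d$parents[[v]]), prob = prob)
  })
  names(cpts) <- d$nodes
  net <- bayes_net(d, cpts, specs, validate = validate)
  if (length(fallback)) attr(net, "fallback_configs") <- fallback
  net
}

normalize_counts <- function(counts, method = "bayes", alpha = 1) {
  r <- nrow(counts)
  if (method == "bayes") {
    stopifnot(alpha > 0)
    sweep(counts + alpha, 2, colSums(counts) + alpha * r, "/")
  } else {
    tot <- colSums(counts)
    prob <- counts
    zero <- tot == 0
    if (any(!zero)) prob[, !zero] <- sweep(counts[, !zero, drop = FALSE], 2,
                                           tot[!zero], "/")
    if (any(zero)) prob[, zero] <- 1 / r
    prob
  }
}

# --- hill-climbing structure search ------------------------------------------

# Reachability: is there a directed path from `from` to `to` in adjacency
# list `ch` (children)?
has_path <- function(ch, from, to) {
  if (from == to) return(TRUE)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(ch[frontier], use.names = FALSE))
    if (to %in% nxt) return(TRUE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  FALSE
}

#' Learn a network structure by BIC hill-climbing
#'
#' Greedy search over single-edge add/delete/reverse moves, never creating
#' cycles or blacklisted edges. The best strictly improving move is accepted
#' (ties broken lexicographically by (parent, child)); the climb stops at a
#' local optimum. `restarts` additional climbs start from the incumbent
#' perturbed by two random feasible edge additions; the best-scoring local
#' optimum wins. Deterministic given `seed`.
#'
#' @param x A `cohort`.
#' @param blacklist Optional two-column (parent, child) matrix of forbidden
#'   edges, e.g. from [blacklist_from_families()].
#' @param seed Integer seed for the restart perturbations.
#' @param restarts Number of random-restart climbs after the first.
#' @param max_parents Cap on parents per node (Inf by default).
#' @return A `net_dag`; `attr(, "score")` holds its BIC.
#' @export
learn_structure <- function(x, blacklist = NULL, seed = 1, restarts = 10,
                            max_parents = Inf) {
  stopifnot(inherits(x, "cohort"))
  nodes <- sort(cohort_variables(x))
  if (length(nodes) >= 20) {
    stop("exact PGMs are limited to fewer than 20 variables")
  }
  code <- encode_records(x$records, x$specs, nodes)
  cards <- lapply(x$specs[nodes], function(s) length(s$states))
  n <- nrow(code)

  bl <- new.env(parent = emptyenv())
  if (!is.null(blacklist) && nrow(blacklist)) {
    stopifnot(all(blacklist %in% nodes))
    for (i in seq_len(nrow(blacklist))) {
      assign(paste(blacklist[i, 1], blacklist[i, 2], sep = "\r"), TRUE, envir = bl)
    }
  }
  blacklisted <- function(p, c) {
    exists(paste(p, c, sep = "\r"), envir = bl, inherits = FALSE)
  }

  cache <- new.env(parent = emptyenv())
  fam_score <- function(v, parents) {
    key <- paste(v, paste(sort(parents), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    s <- node_bic(code, v, parents, cards, n)
    cache[[key]] <- s
    s
  }

  climb <- function(parents) {
    children <- lapply(nodes, function(v) character(0))
    names(children) <- nodes
    for (v in nodes) for (p in parents[[v]]) {
      children[[p]] <- c(children[[p]], v)
    }
    scores <- vapply(nodes, function(v) fam_score(v, parents[[v]]), numeric(1))
    repeat {
      best <- list(delta = 0, move = NULL)
      consider <- function(delta, move) {
        # strict improvement; deterministic tie-break on (type, parent, child)
        if (delta > best$delta + 1e-9 ||
            (abs(delta - best$delta) <= 1e-9 && !is.null(best$move) &&
             paste(move, collapse = "\r") < paste(best$move, collapse = "\r"))) {
          best <<- list(delta = delta, move = move)
        }
      }
      for (p in nodes) for (v in nodes) {
        if (p == v) next
        if (p %in% parents[[v]]) {
          # delete p -> v
          d_del <- fam_score(v, setdiff(parents[[v]], p)) - scores[[v]]
          consider(d_del, c("del", p, v))
          # reverse p -> v (becomes v -> p)
          if (!blacklisted(v, p) && length(parents[[p]]) < max_parents) {
            ch_minus <- children
            ch_minus[[p]] <- setdiff(ch_minus[[p]], v)
            if (!has_path(ch_minus, p, v)) {
              d_rev <- d_del +
                fam_score(p, c(parents[[p]], v)) - scores[[p]]
              consider(d_rev, c("rev", p, v))
            }
          }
        } else if (!blacklisted(p, v) && length(parents[[v]]) < max_parents &&
                   !has_path(children, v, p)) {
          d_add <- fam_score(v, c(parents[[v]], p)) - scores[[v]]
          consider(d_add, c("add", p, v))
        }
      }
      if (is.null(best$move) || best$delta <= 1e-9) break
      m <- best$move
      p <- m[2]; v <- m[3]
      if (m[1] == "add") {
        parents[[v]] <- c(parents[[v]], p)
        children[[p]] <- c(children[[p]], v)
      } else if (m[1] == "del") {
        parents[[v]] <- setdiff(parents[[v]], p)
        children[[p]] <- setdiff(children[[p]], v)
      } else {
        parents[[v]] <- setdiff(parents[[v]], p)
        children[[p]] <- setdiff(children[[p]], v)
        parents[[p]] <- c(parents[[p]], v)
        children[[v]] <- c(children[[v]], p)
      }
      scores[[v]] <- fam_score(v, parents[[v]])
      if (m[1] == "rev") scores[[p]] <- fam_score(p, parents[[p]])
    }
    list(parents = parents, score = sum(scores))
  }

  empty <- lapply(nodes, function(v) character(0))
  names(empty) <- nodes
  best <- climb(empty)

  if (restarts > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
    for (r in seq_len(restarts)) {
      parents <- best$parents
      children <- lapply(nodes, function(v) character(0))
      names(children) <- nodes
      for (v in nodes) for (p in parents[[v]]) {
        children[[p]] <- c(children[[p]], v)
      }
      # perturb: two random feasible edge additions
      for (k in 1:2) {
        cand <- expand.grid(p = nodes, v = nodes, stringsAsFactors = FALSE)
        cand <- cand[cand$p != cand$v, ]
        cand <- cand[sample.int(nrow(cand)), ]
        for (i in seq_len(nrow(cand))) {
          p <- cand$p[i]; v <- cand$v[i]
          if (p %in% parents[[v]] || blacklisted(p, v) ||
              length(parents[[v]]) >= max_parents ||
              has_path(children, v, p)) next
          parents[[v]] <- c(parents[[v]], p)
          children[[p]] <- c(children[[p]], v)
          break
        }
      }
      run <- climb(parents)
      if (run$score > best$score + 1e-9) best <- run
    }
  }

  edges <- do.call(rbind, lapply(nodes, function(v) {
    if (length(best$parents[[v]])) cbind(best$parents[[v]], v) else NULL
  }))
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  out <- dag(nodes, edges)
  attr(out, "score") <- best$score
  out
}

# --- serialization ------------------------------------------------------------

#' Write / read a network as JSON
#'
#' Format: `{nodes: [{name, states, family}], edges: [[parent, child]],
#' cpts: {node: {parents, prob (states x configs, column-major)}}}`.
#'
#' @param net A `bayes_net`.
#' @param path Output path.
#' @return `read_network` returns a `bayes_net`.
#' @export
write_network <- function(net, path) {
  obj <- list(
    nodes = lapply(net$dag$nodes, function(v) {
      s <- net$specs[[v]]
      list(name = v, states = s$states,
           family = if (is.na(s$family)) NULL else s$family)
    }),
    edges = if (nrow(net$dag$edges)) {
      lapply(seq_len(nrow(net$dag$edges)),
             function(i) as.list(unname(net$dag$edges[i, ])))
    } else list(),
    cpts = lapply(net$cpts, function(cpt) {
      list(parents = as.list(cpt$parents), prob = as.vector(cpt$prob),
           n_states = nrow(cpt$prob))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(obj$nodes, function(v) {
    variable_spec(v$name, unlist(v$states), family = v$family)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  edges <- if (length(obj$edges)) {
    do.call(rbind, lapply(obj$edges, function(e) c(e[[1]], e[[2]])))
  } else matrix(character(0), ncol = 2)
  d <- dag(names(specs), edges)
  cpts <- lapply(names(obj$cpts), function(v) {
    cpt <- obj$cpts[[v]]
    prob <- matrix(unlist(cpt$prob), nrow = cpt$n_states)
    list(node = v, parents = unlist(cpt$parents) %||% character(0), prob = prob)
  })
  names(cpts) <- names(obj$cpts)
  bayes_net(d, cpts[d$nodes], specs[d$nodes])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a DAG in DOT format for visualization
#' @param d A `net_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(d, path) {
  lines <- c("digraph pgm {",
             paste0("  \"", d$nodes, "\";"),
             if (nrow(d$edges)) paste0("  \"", d$edges[, 1], "\" -> \"",
                                       d$edges[, 2], "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}
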
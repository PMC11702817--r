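#' @title Exact inference on a discrete Bayesian network
#' @description
#' Conditional queries are answered exactly by variable elimination with a
#' min-fill ordering; a full-enumeration oracle (`brute_force_query`) provides
#' an independent cross-check. Evidence on the `"unknown"` state is
#' conditioned on literally — it is a learned category, consistent with how
#' the network was fitted. Evidence with zero probability under the model
#' raises an error rather than silently returning a uniform answer, which
#' would corrupt downstream relative risks.
#' @name inference
NULL

# A factor (potential): list(vars, cards (named int), val (numeric, mixed
# radix over vars with the FIRST var fastest)).
new_potential <- function(vars, cards, val) {
  list(vars = vars, cards = cards, val = val)
}

cpt_potential <- function(net, v) {
  cpt <- net$cpts[[v]]
  vars <- c(v, cpt$parents)
  cards <- vapply(net$specs[vars], function(s) length(s$states), integer(1))
  new_potential(vars, cards, as.vector(cpt$prob))
}

# Map from the cells of a potential over `vars`/`cards` to the cells of a
# sub-potential over `sub` (sub must be a subset of vars, in any order).
index_map <- function(vars, cards, sub) {
  n <- prod(cards)
  idx <- rep.int(0L, n)
  mult <- 1L
  for (s in sub) {
    pos <- match(s, vars)
    stride <- if (pos == 1L) 1L else prod(cards[seq_len(pos - 1L)])
    state <- (((seq_len(n) - 1L) %/% stride) %% cards[pos])
    idx <- idx + state * mult
    mult <- mult * cards[pos]
  }
  idx + 1L
}

potential_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  cards <- c(f1$cards, f2$cards)[vars]
  val <- f1$val[index_map(vars, cards, f1$vars)] *
         f2$val[index_map(vars, cards, f2$vars)]
  new_potential(vars, cards, val)
}

potential_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (!length(keep)) {
    return(new_potential(character(0), integer(0), sum(f$val)))
  }
  cards <- f$cards[keep]
  val <- rowsum(f$val, group = index_map(f$vars, f$cards, keep), reorder = TRUE)
  new_potential(keep, cards, as.vector(val))
}

potential_reduce <- function(f, var, state_idx) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  n <- prod(f$cards)
  stride <- if (pos == 1L) 1L else prod(f$cards[seq_len(pos - 1L)])
  state <- (((seq_len(n) - 1L) %/% stride) %% f$cards[pos]) + 1L
  keep <- setdiff(f$vars, var)
  new_potential(keep, f$cards[keep], f$val[state == state_idx])
}

check_evidence <- function(net, evidence, target = NULL) {
  if (is.null(evidence)) evidence <- list()
  stopifnot(is.list(evidence))
  for (v in names(evidence)) {
    if (!v %in% net$dag$nodes) stop("evidence node '", v, "' is not in the network")
    if (!is.null(target) && v == target) stop("target may not appear in evidence")
    if (!evidence[[v]] %in% net$specs[[v]]$states) {
      stop("'", evidence[[v]], "' is not a state of '", v, "'")
    }
  }
  evidence
}

#' Joint probability of a full assignment
#'
#' The product of the matching CPT entries — the factorization the network
#' defines.
#'
#' @param net A `bayes_net`.
#' @param assignment Named list/vector of states covering all nodes.
#' @return Numeric probability.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- as.list(assignment)
  if (!setequal(names(assignment), net$dag$nodes)) {
    stop("assignment must cover all nodes")
  }
  check_evidence(net, assignment)
  p <- 1
  for (v in net$dag$nodes) {
    cpt <- net$cpts[[v]]
    r <- match(assignment[[v]], net$specs[[v]]$states)
    cfg <- 1L
    mult <- 1L
    for (pa in cpt$parents) {
      cfg <- cfg + (match(assignment[[pa]], net$specs[[pa]]$states) - 1L) * mult
      mult <- mult * length(net$specs[[pa]]$states)
    }
    p <- p * cpt$prob[r, cfg]
  }
  p
}

min_fill_order <- function(net, elim) {
  # neighbors in the moralized-and-reduced factor graph
  nbrs <- lapply(net$dag$nodes, function(v) character(0))
  names(nbrs) <- net$dag$nodes
  scopes <- lapply(net$dag$nodes, function(v) {
    intersect(c(v, net$cpts[[v]]$parents), elim)
  })
  for (sc in scopes) {
    for (v in sc) nbrs[[v]] <- union(nbrs[[v]], setdiff(sc, v))
  }
  order <- character(0)
  remaining <- elim
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(nbrs[[v]], remaining)
      if (length(nb) < 2) return(0L)
      cnt <- 0L
      for (i in seq_along(nb)[-length(nb)]) {
        cnt <- cnt + sum(!nb[(i + 1):length(nb)] %in% nbrs[[nb[i]]])
      }
      cnt
    }, integer(1))
    v <- remaining[order(fill, remaining)][1]
    nb <- intersect(nbrs[[v]], remaining)
    for (a in nb) nbrs[[a]] <- union(nbrs[[a]], setdiff(nb, a))
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

#' Exact conditional query by variable elimination
#'
#' @param net A `bayes_net`.
#' @param target Node whose conditional distribution is requested.
#' @param evidence Named list of observed states (may include `"unknown"`).
#' @return List of class `query_result`: `target`, `distribution` (named
#'   probabilities summing to 1), `evidence_mass` (probability of the evidence
#'   under the model).
#' @export
query_net <- function(net, target, evidence = list()) {
  stopifnot(inherits(net, "bayes_net"), target %in% net$dag$nodes)
  evidence <- check_evidence(net, evidence, target)
  pots <- lapply(net$dag$nodes, function(v) cpt_potential(net, v))
  for (v in names(evidence)) {
    s <- match(evidence[[v]], net$specs[[v]]$states)
    pots <- lapply(pots, potential_reduce, var = v, state_idx = s)
  }
  elim <- setdiff(net$dag$nodes, c(target, names(evidence)))
  for (v in min_fill_order(net, elim)) {
    inv <- vapply(pots, function(f) v %in% f$vars, logical(1))
    if (!any(inv)) next
    prod_f <- Reduce(potential_product, pots[inv])
    pots <- c(pots[!inv], list(potential_marginalize(prod_f, v)))
  }
  res <- Reduce(potential_product, pots)
  # collapse any residual empty-scope constants
  if (!identical(res$vars, target)) {
    res <- new_potential(target, res$cards[target],
                         as.vector(rowsum(res$val,
                                          index_map(res$vars, res$cards, target),
                                          reorder = TRUE)))
  }
  mass <- sum(res$val)
  if (!is.finite(mass) || mass <= 0) {
    stop("evidence {", paste(names(evidence), unlist(evidence), sep = "=",
                             collapse = ", "),
         "} has zero probability under the model")
  }
  dist <- res$val / mass
  names(dist) <- net$specs[[target]]$states
  structure(list(target = target, distribution = dist, evidence_mass = mass),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat("P(", x$target, " | evidence), evidence mass ",
      format(x$evidence_mass, digits = 4), "\n", sep = "")
  print(round(x$distribution, 4))
  invisible(x)
}

#' Brute-force conditional query by full enumeration
#'
#' Independent oracle: enumerates every joint configuration, multiplies CPT
#' entries row-wise, filters on the evidence and sums by target state.
#' Refuses when the state space exceeds `max_states`.
#'
#' @inheritParams query_net
#' @param max_states Enumeration budget (default 1e7 configurations).
#' @return A `query_result`.
#' @export
brute_force_query <- function(net, target, evidence = list(), max_states = 1e7) {
  stopifnot(inherits(net, "bayes_net"), target %in% net$dag$nodes)
  evidence <- check_evidence(net, evidence, target)
  nodes <- net$dag$nodes
  cards <- node_cards(net)
  if (prod(cards) > max_states) {
    stop("state space (", format(prod(cards), big.mark = ","),
         ") exceeds the enumeration budget")
  }
  grid <- do.call(expand.grid, c(lapply(cards, seq_len),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  names(grid) <- nodes
  p <- rep.int(1, nrow(grid))
  for (v in nodes) {
    cpt <- net$cpts[[v]]
    cfg <- rep.int(1L, nrow(grid))
    mult <- 1L
    for (pa in cpt$parents) {
      cfg <- cfg + (grid[[pa]] - 1L) * mult
      mult <- mult * cards[[pa]]
    }
    p <- p * cpt$prob[cbind(grid[[v]], cfg)]
  }
  keep <- rep.int(TRUE, nrow(grid))
  for (v in names(evidence)) {
    keep <- keep & grid[[v]] == match(evidence[[v]], net$specs[[v]]$states)
  }
  mass <- sum(p[keep])
  if (mass <= 0) {
    stop("evidence has zero probability under the model")
  }
  dist <- vapply(seq_len(cards[[target]]), function(s) {
    sum(p[keep & grid[[target]] == s])
  }, numeric(1)) / mass
  names(dist) <- net$specs[[target]]$states
  structure(list(target = target, distribution = dist, evidence_mass = mass),
            class = "query_result")
}

#' Per-record outcome prediction
#'
#' For each record, conditions on every non-target column (including
#' `"unknown"` cells, which are evidence on the learned missing-data state)
#' and returns the probability that the target is `"present"`. Because the
#' evidence covers the whole Markov blanket, the computation reduces to the
#' target's own CPT row times the CPT entries of its children, normalized
#' over target states — vectorized over records.
#'
#' @param net A `bayes_net`.
#' @param x A `cohort` (its target column, if present, is ignored as
#'   evidence).
#' @param target Target node; defaults to the cohort outcome.
#' @return Numeric vector of probabilities.
#' @export
predict_risk <- function(net, x, target = x$outcome) {
  stopifnot(inherits(net, "bayes_net"), inherits(x, "cohort"),
            target %in% net$dag$nodes)
  others <- setdiff(net$dag$nodes, target)
  code <- encode_records(x$records, net$specs, others)
  n <- nrow(code)
  cards <- lapply(net$specs, function(s) length(s$states))
  r_t <- cards[[target]]
  children <- net$dag$edges[net$dag$edges[, 1] == target, 2]
  logp <- matrix(0, nrow = n, ncol = r_t)
  fam_entry <- function(v, v_state) {
    # log CPT entry of node v per record, with target fixed at v_state when
    # target occurs in the family
    cpt <- net$cpts[[v]]
    cfg <- rep.int(1L, n)
    mult <- 1L
    for (pa in cpt$parents) {
      st <- if (pa == target) rep.int(v_state, n) else code[, pa]
      cfg <- cfg + (st - 1L) * mult
      mult <- mult * cards[[pa]]
    }
    row <- if (v == target) rep.int(v_state, n) else code[, v]
    log(cpt$prob[cbind(row, cfg)])
  }
  for (s in seq_len(r_t)) {
    acc <- fam_entry(target, s)
    for (ch in children) acc <- acc + fam_entry(ch, s)
    logp[, s] <- acc
  }
  m <- logp[, 1]
  for (s in seq_len(r_t)[-1]) m <- pmax(m, logp[, s])
  w <- exp(logp - m)
  tot <- rowSums(w)
  if (any(!is.finite(tot) | tot <= 0)) {
    stop("some records have zero probability under the model")
  }
  present <- match("present", net$specs[[target]]$states)
  if (is.na(present)) stop("target '", target, "' has no state \"present\"")
  w[, present] / tot
}
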
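#' @title Synthetic nulliparous obstetric cohort generator
#' @description
#' Builds a fully parameterized ground-truth Bayesian network over the twelve
#' clinical variables of the risk model (preexisting diabetes, progesterone
#' use, fetal sex, congenital anomaly, PPROM, HDP, visit-3 EFW category,
#' visit-2 BP > 140/90, gestational-age category, urgent cesarean, 5-minute
#' Apgar < 7, composite perinatal morbidity), calibrated so that every exact
#' marginal matches its configured prevalence, with a planted fetal-sex by
#' preexisting-diabetes effect reversal on the outcome: female sex is
#' protective without diabetes and harmful with it. Cohorts are drawn by
#' ancestral sampling; missingness is injected afterwards, completely at
#' random, as the `"unknown"` state.
#' @name synthetic-cohort
NULL

#' Ground-truth generator configuration
#'
#' Defaults encode the published cohort's prevalences and missingness; the
#' interaction block fixes the planted effect-reversal magnitudes (within-
#' stratum odds ratios for female vs male sex). Effect sizes for the
#' remaining edges are design constants chosen to be clinically plausible
#' (see the methods vignette).
#'
#' @param n Default cohort size for the pipeline.
#' @param seed Integer seed.
#' @param marginals Named list of target prevalences; for `efw` and `ga`,
#'   named vectors of the non-reference category probabilities.
#' @param missingness Named list of per-variable missing-completely-at-random
#'   rates (the outcome may not appear).
#' @param interaction `TRUE` plants the sex-by-diabetes reversal;
#'   `FALSE` keeps the female effect constant across diabetes strata
#'   (negative control).
#' @param or_female Odds ratio for female vs male sex on morbidity without
#'   diabetes (< 1: protective).
#' @param or_female_dm Same, within the diabetes stratum (> 1 under the
#'   planted reversal).
#' @return List of class `truth_config`.
#' @export
truth_config <- function(n = 20000,
                         seed = 1,
                         marginals = list(
                           diabetes = 0.016,
                           progesterone = 0.026,
                           female_sex = 0.509,
                           anomaly = 0.059,
                           pprom = 0.026,
                           hdp = 0.100,
                           bp_high = 0.008,
                           urgent_cesarean = 0.091,
                           apgar_low = 0.040,
                           efw = c(lt3 = 0.010, p3to9 = 0.043, gt90 = 0.073),
                           ga = c(early_ptb = 0.028, late_ptb = 0.058),
                           morbidity = 0.082
                         ),
                         missingness = list(efw = 0.064, bp_high = 0.049),
                         interaction = TRUE,
                         or_female = 0.70,
                         or_female_dm = 1.80) {
  scal <- unlist(marginals[setdiff(names(marginals), c("efw", "ga"))])
  stopifnot(all(scal > 0 & scal < 1),
            all(marginals$efw > 0), sum(marginals$efw) < 1,
            all(marginals$ga > 0), sum(marginals$ga) < 1,
            all(unlist(missingness) >= 0 & unlist(missingness) < 1))
  if ("morbidity" %in% names(missingness)) {
    stop("the outcome may not be assigned a missingness rate")
  }
  structure(list(
    n = n, seed = seed, marginals = marginals, missingness = missingness,
    interaction = isTRUE(interaction),
    or_female = or_female, or_female_dm = or_female_dm,
    # design constants for the remaining dependencies
    rr_hdp_dm = 3.0,
    efw_given_dm = c(lt3 = 0.030, p3to9 = 0.100, p10to90 = 0.640, gt90 = 0.230),
    p_bp_hdp = 0.050,
    p_ces_hdp = 0.250,
    ga_mult_early = c(hdp = 3.5, progesterone = 3.5, pprom = 10),
    ga_mult_late = c(hdp = 2.0, progesterone = 2.5, pprom = 4),
    apgar_mult = c(early_ptb = 8, late_ptb = 3, term = 1),
    or_dm = 3.0, or_anomaly = 3.5,
    lor_early = 2.75, lor_late = 1.23,
    truth_dag = truth_edges()
  ), class = "truth_config")
}

truth_edges <- function() {
  rbind(
    c("diabetes", "efw"), c("diabetes", "hdp"), c("diabetes", "morbidity"),
    c("female_sex", "morbidity"),
    c("hdp", "ga"), c("hdp", "urgent_cesarean"), c("hdp", "bp_high"),
    c("progesterone", "ga"), c("pprom", "ga"),
    c("ga", "morbidity"), c("ga", "apgar_low"),
    c("anomaly", "morbidity")
  )
}

truth_specs <- function() {
  specs <- list(
    diabetes = binary_spec("diabetes", clinical_rank = 1L),
    progesterone = binary_spec("progesterone", clinical_rank = 2L),
    female_sex = binary_spec("female_sex", clinical_rank = 1L),
    anomaly = binary_spec("anomaly", clinical_rank = 2L),
    pprom = binary_spec("pprom", clinical_rank = 2L),
    hdp = binary_spec("hdp", clinical_rank = 1L),
    efw = variable_spec("efw", c("lt3", "p3to9", "p10to90", "gt90"),
                        clinical_rank = 1L),
    bp_high = binary_spec("bp_high", clinical_rank = 3L),
    ga = variable_spec("ga", c("early_ptb", "late_ptb", "term"),
                       clinical_rank = 1L),
    urgent_cesarean = binary_spec("urgent_cesarean", clinical_rank = 2L),
    apgar_low = binary_spec("apgar_low", clinical_rank = 2L),
    morbidity = binary_spec("morbidity", clinical_rank = 1L)
  )
  specs
}

# CPT for a binary child: p_present given each parent configuration.
# `p_fun(cfg_df)` returns the present-probability per configuration row;
# configurations containing "unknown" parent states get a uniform row.
binary_cpt <- function(node, parents, specs, p_fun) {
  states <- lapply(specs[parents], `[[`, "states")
  grid <- if (length(parents)) {
    do.call(expand.grid, c(states, list(stringsAsFactors = FALSE,
                                        KEEP.OUT.ATTRS = FALSE)))
  } else data.frame(row.names = 1)
  names(grid) <- parents
  q <- max(nrow(grid), 1L)
  r <- length(specs[[node]]$states)
  prob <- matrix(1 / r, nrow = r, ncol = q)
  has_unknown <- if (length(parents)) {
    Reduce(`|`, lapply(grid, function(col) col == UNKNOWN_STATE))
  } else rep(FALSE, q)
  p <- p_fun(grid)
  ok <- !has_unknown
  prob[, ok] <- 0
  present <- match("present", specs[[node]]$states)
  absent <- match("absent", specs[[node]]$states)
  prob[present, ok] <- p[ok]
  prob[absent, ok] <- 1 - p[ok]
  list(node = node, parents = parents, prob = prob)
}

# CPT for a categorical child (no "unknown" mass on observed configs).
categorical_cpt <- function(node, parents, specs, dist_fun) {
  states <- lapply(specs[parents], `[[`, "states")
  grid <- if (length(parents)) {
    do.call(expand.grid, c(states, list(stringsAsFactors = FALSE,
                                        KEEP.OUT.ATTRS = FALSE)))
  } else data.frame(row.names = 1)
  names(grid) <- parents
  q <- max(nrow(grid), 1L)
  child_states <- specs[[node]]$states
  r <- length(child_states)
  prob <- matrix(1 / r, nrow = r, ncol = q)
  has_unknown <- if (length(parents)) {
    Reduce(`|`, lapply(grid, function(col) col == UNKNOWN_STATE))
  } else rep(FALSE, q)
  d <- dist_fun(grid)  # matrix q x (r-1 observable states), named columns
  for (j in which(!has_unknown)) {
    row <- rep(0, r)
    names(row) <- child_states
    row[colnames(d)] <- d[j, ]
    if (any(row < -1e-12) || abs(sum(row) - 1) > 1e-9) {
      stop("infeasible CPT for '", node, "': a configured marginal/effect ",
           "combination yields an invalid distribution")
    }
    prob[, j] <- pmax(row, 0) / sum(pmax(row, 0))
  }
  list(node = node, parents = parents, prob = prob)
}

#' Build the calibrated ground-truth network
#'
#' Root and conditional probabilities are solved so that every node's exact
#' marginal (computed by exact inference on the finished network) matches its
#' configured target; the outcome CPT is a logistic-in-parameters table whose
#' intercept is solved by root finding against the target outcome prevalence
#' and whose sex term reverses sign across diabetes strata when the
#' interaction is planted.
#'
#' @param config A [truth_config()].
#' @return A `bayes_net` with `attr(, "config")` attached.
#' @export
make_truth_network <- function(config = truth_config()) {
  stopifnot(inherits(config, "truth_config"))
  if (!identical(config$truth_dag, truth_edges())) {
    stop("custom truth DAGs are not supported by the built-in recipe")
  }
  specs <- truth_specs()
  mg <- config$marginals
  d <- dag(names(specs), config$truth_dag)

  p_dm <- mg$diabetes
  cpts <- list()
  for (v in c("diabetes", "progesterone", "female_sex", "anomaly", "pprom")) {
    local_v <- v
    cpts[[v]] <- binary_cpt(v, character(0), specs,
                            function(g) mg[[local_v]])
  }

  # hdp | diabetes, calibrated to the hdp marginal with a fixed risk ratio
  b_hdp <- mg$hdp / ((1 - p_dm) + p_dm * config$rr_hdp_dm)
  p_hdp_dm <- b_hdp * config$rr_hdp_dm
  if (p_hdp_dm >= 1) stop("infeasible HDP marginal/effect combination")
  cpts$hdp <- binary_cpt("hdp", "diabetes", specs, function(g) {
    ifelse(g$diabetes == "present", p_hdp_dm, b_hdp)
  })

  # efw | diabetes: fixed diabetic profile, non-diabetic profile solved from
  # the marginal mixture
  v1 <- config$efw_given_dm
  targets <- c(mg$efw["lt3"], mg$efw["p3to9"],
               p10to90 = 1 - sum(mg$efw), mg$efw["gt90"])
  names(targets) <- c("lt3", "p3to9", "p10to90", "gt90")
  v0 <- (targets - p_dm * v1[names(targets)]) / (1 - p_dm)
  if (any(v0 <= 0)) stop("infeasible EFW marginals given the diabetes effect")
  cpts$efw <- categorical_cpt("efw", "diabetes", specs, function(g) {
    out <- matrix(rep(v0, each = nrow(g)), nrow = nrow(g),
                  dimnames = list(NULL, names(v0)))
    dm <- g$diabetes == "present"
    out[dm, ] <- matrix(rep(v1[names(v0)], each = sum(dm)), nrow = sum(dm))
    out
  })

  # bp_high | hdp and urgent_cesarean | hdp
  p_bp0 <- (mg$bp_high - mg$hdp * config$p_bp_hdp) / (1 - mg$hdp)
  p_ces0 <- (mg$urgent_cesarean - mg$hdp * config$p_ces_hdp) / (1 - mg$hdp)
  if (p_bp0 <= 0 || p_ces0 <= 0) stop("infeasible BP/cesarean marginals")
  cpts$bp_high <- binary_cpt("bp_high", "hdp", specs, function(g) {
    ifelse(g$hdp == "present", config$p_bp_hdp, p_bp0)
  })
  cpts$urgent_cesarean <- binary_cpt("urgent_cesarean", "hdp", specs,
                                     function(g) {
    ifelse(g$hdp == "present", config$p_ces_hdp, p_ces0)
  })

  # ga | hdp, progesterone, pprom: multiplicative category risks calibrated
  # to the marginal by fixed-point iteration (row cap at 0.9 total preterm)
  ga_parents <- c("hdp", "progesterone", "pprom")
  w_parent <- function(g) {
    w <- rep(1, nrow(g))
    for (pa in ga_parents) {
      pr <- mg[[pa]]
      w <- w * ifelse(g[[pa]] == "present", pr, 1 - pr)
    }
    w
  }
  ga_rows <- function(g, b_e, b_l) {
    m_e <- rep(1, nrow(g)); m_l <- rep(1, nrow(g))
    for (pa in ga_parents) {
      pres <- g[[pa]] == "present"
      m_e <- m_e * ifelse(pres, config$ga_mult_early[[pa]], 1)
      m_l <- m_l * ifelse(pres, config$ga_mult_late[[pa]], 1)
    }
    e <- b_e * m_e; l <- b_l * m_l
    tot <- e + l
    over <- tot > 0.9
    e[over] <- e[over] * 0.9 / tot[over]
    l[over] <- l[over] * 0.9 / tot[over]
    cbind(early_ptb = e, late_ptb = l, term = 1 - e - l)
  }
  grid3 <- expand.grid(hdp = c("absent", "present"),
                       progesterone = c("absent", "present"),
                       pprom = c("absent", "present"),
                       stringsAsFactors = FALSE)
  b_e <- mg$ga[["early_ptb"]]; b_l <- mg$ga[["late_ptb"]]
  for (i in 1:40) {
    rows <- ga_rows(grid3, b_e, b_l)
    w <- w_parent(grid3)
    cur_e <- sum(w * rows[, "early_ptb"]); cur_l <- sum(w * rows[, "late_ptb"])
    b_e <- b_e * mg$ga[["early_ptb"]] / cur_e
    b_l <- b_l * mg$ga[["late_ptb"]] / cur_l
  }
  cpts$ga <- categorical_cpt("ga", ga_parents, specs, function(g) {
    ga_rows(g, b_e, b_l)
  })

  # apgar_low | ga
  am <- config$apgar_mult
  ga_w <- c(early_ptb = mg$ga[["early_ptb"]], late_ptb = mg$ga[["late_ptb"]],
            term = 1 - sum(mg$ga))
  b_ap <- mg$apgar_low / sum(ga_w * am[names(ga_w)])
  if (b_ap * max(am) >= 1) stop("infeasible Apgar marginal/effect combination")
  cpts$apgar_low <- binary_cpt("apgar_low", "ga", specs, function(g) {
    ifelse(g$ga == UNKNOWN_STATE, 0.5, b_ap * am[g$ga])
  })

  # morbidity | female_sex, diabetes, ga, anomaly: logistic table, intercept
  # solved against the outcome prevalence on the exact parent joint
  or_f_dm <- if (config$interaction) config$or_female_dm else config$or_female
  lor <- list(female = log(config$or_female),
              female_dm = log(or_f_dm) - log(config$or_female),
              dm = log(config$or_dm), anomaly = log(config$or_anomaly),
              early = config$lor_early, late = config$lor_late)
  parent_joint <- morbidity_parent_joint(mg, b_hdp, p_hdp_dm, grid3, w_parent,
                                         ga_rows, b_e, b_l)
  lp_terms <- function(g) {
    f <- g$female_sex == "present"; dm <- g$diabetes == "present"
    lor$female * f + lor$female_dm * (f & dm) + lor$dm * dm +
      lor$anomaly * (g$anomaly == "present") +
      lor$early * (g$ga == "early_ptb") + lor$late * (g$ga == "late_ptb")
  }
  terms_j <- lp_terms(parent_joint)
  marg_fun <- function(b0) {
    sum(parent_joint$w * stats::plogis(b0 + terms_j)) - mg$morbidity
  }
  b0 <- stats::uniroot(marg_fun, c(-12, 4), tol = 1e-12)$root
  # parent order matches the DAG's (stable across refits on the same DAG)
  cpts$morbidity <- binary_cpt("morbidity", unname(d$parents[["morbidity"]]),
                               specs, function(g) {
    stats::plogis(b0 + lp_terms(g))
  })

  net <- bayes_net(d, cpts[d$nodes], specs)
  check_truth_marginals(net, config)
  attr(net, "config") <- config
  net
}

# Exact joint of the outcome's parents (sex, diabetes, ga, anomaly) under the
# partially built network: sex and anomaly are independent roots; (diabetes,
# ga) couple through HDP.
morbidity_parent_joint <- function(mg, b_hdp, p_hdp_dm, grid3, w_parent,
                                   ga_rows, b_e, b_l) {
  rows <- ga_rows(grid3, b_e, b_l)
  out <- list()
  for (dm in c("absent", "present")) {
    p_dm <- if (dm == "present") mg$diabetes else 1 - mg$diabetes
    p_h <- if (dm == "present") p_hdp_dm else b_hdp
    w3 <- ifelse(grid3$hdp == "present", p_h, 1 - p_h) *
      ifelse(grid3$progesterone == "present", mg$progesterone,
             1 - mg$progesterone) *
      ifelse(grid3$pprom == "present", mg$pprom, 1 - mg$pprom)
    p_ga <- colSums(w3 * rows)
    for (ga in names(p_ga)) {
      out[[paste(dm, ga)]] <- data.frame(diabetes = dm, ga = ga,
                                         w_dmga = p_dm * p_ga[[ga]])
    }
  }
  dmga <- do.call(rbind, out)
  full <- merge(
    merge(dmga, data.frame(female_sex = c("absent", "present"),
                           w_f = c(1 - mg$female_sex, mg$female_sex))),
    data.frame(anomaly = c("absent", "present"),
               w_a = c(1 - mg$anomaly, mg$anomaly))
  )
  full$w <- full$w_dmga * full$w_f * full$w_a
  full
}

check_truth_marginals <- function(net, config, tol = 0.001) {
  mg <- config$marginals
  for (v in names(mg)) {
    got <- query_net(net, v)$distribution
    want <- mg[[v]]
    if (is.null(names(want)) || length(want) == 1) {
      dev <- abs(got[["present"]] - want)
    } else {
      dev <- max(abs(got[names(want)] - want))
    }
    if (dev > tol) {
      stop("calibration failed for '", v, "': marginal off by ",
           format(dev, digits = 3))
    }
  }
  invisible(net)
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Draw an i.i.d. cohort from a network by ancestral sampling
#'
#' @param net A `bayes_net`.
#' @param n Number of records (>= 1).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @param outcome Outcome column name (defaults to `"morbidity"` when
#'   present).
#' @return A `cohort`.
#' @export
sample_cohort <- function(net, n, seed = 1,
                          outcome = intersect("morbidity", net$dag$nodes)[1]) {
  stopifnot(inherits(net, "bayes_net"), n >= 1)
  if (is.na(outcome)) stop("specify the outcome column")
  order <- topo_sort(net$dag)
  cards <- node_cards(net)
  code <- matrix(0L, nrow = n, ncol = length(order),
                 dimnames = list(NULL, order))
  with_seed(seed, {
    for (v in order) {
      cpt <- net$cpts[[v]]
      cfg <- rep.int(1L, n)
      mult <- 1L
      for (pa in cpt$parents) {
        cfg <- cfg + (code[, pa] - 1L) * mult
        mult <- mult * cards[[pa]]
      }
      cum <- apply(cpt$prob, 2, cumsum)
      u <- stats::runif(n)
      r <- cards[[v]]
      st <- rep.int(1L, n)
      if (r > 1) {
        th <- t(cum)[cfg, seq_len(r - 1L), drop = FALSE]
        st <- 1L + as.integer(rowSums(u > th))
      }
      code[, v] <- st
    }
  })
  records <- as.data.frame(lapply(net$dag$nodes, function(v) {
    factor(net$specs[[v]]$states[code[, v]], levels = net$specs[[v]]$states)
  }), col.names = net$dag$nodes)
  cohort(records, outcome, net$specs[net$dag$nodes])
}

#' Mask cells completely at random as "unknown"
#'
#' @param x A `cohort`.
#' @param rates Named list/vector of per-variable masking rates in \[0, 1).
#'   The outcome may not be masked.
#' @param seed Integer seed.
#' @return The masked `cohort`.
#' @export
inject_missingness <- function(x, rates, seed = 1) {
  stopifnot(inherits(x, "cohort"))
  rates <- unlist(rates)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  if (x$outcome %in% names(rates)) {
    stop("the outcome column may not be masked")
  }
  bad <- setdiff(names(rates), names(x$records))
  if (length(bad)) stop("no such variable(s): ", paste(bad, collapse = ", "))
  n <- n_records(x)
  with_seed(seed, {
    for (v in names(rates)) {
      if (rates[[v]] == 0) next
      mask <- stats::runif(n) < rates[[v]]
      lv <- x$records[[v]]
      lv[mask] <- UNKNOWN_STATE
      x$records[[v]] <- lv
    }
  })
  x
}

#' Raw-record fixture for the exclusion arithmetic
#'
#' Produces `n_total` raw records of which `n_missing_outcome` lack outcome
#' data and a disjoint `n_early_delivery` delivered before 20 weeks, shuffled
#' deterministically.
#'
#' @param n_total Total records.
#' @param n_missing_outcome Records flagged missing-outcome.
#' @param n_early_delivery Records delivered < 20 weeks (disjoint from the
#'   missing-outcome set).
#' @param seed Integer seed for the shuffle.
#' @return Data frame with `gestational_age_at_delivery` and
#'   `outcome_available`.
#' @export
make_exclusion_fixture <- function(n_total, n_missing_outcome,
                                   n_early_delivery, seed = 1) {
  if (n_missing_outcome + n_early_delivery > n_total) {
    stop("flag counts exceed the total number of records")
  }
  ga <- rep(39, n_total)
  avail <- rep(TRUE, n_total)
  if (n_missing_outcome > 0) avail[seq_len(n_missing_outcome)] <- FALSE
  if (n_early_delivery > 0) {
    ga[n_missing_outcome + seq_len(n_early_delivery)] <- 18
  }
  idx <- with_seed(seed, sample.int(n_total))
  data.frame(gestational_age_at_delivery = ga[idx],
             outcome_available = avail[idx])
}
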
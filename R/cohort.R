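#' @title Cohort data model and clinical encodings
#' @description
#' A cohort is a flat table of categorical clinical variables (one row per
#' pregnancy) with a designated binary outcome column. Every variable carries a
#' `variable_spec` describing its admissible states; missingness is represented
#' by the reserved state `"unknown"`, which downstream models treat as an
#' ordinary category rather than dropping or imputing rows.
#' @name cohort-model
NULL

UNKNOWN_STATE <- "unknown"

#' Describe a categorical cohort variable
#'
#' @param name Variable name (column name in the cohort table).
#' @param states Character vector of category labels. The reserved label
#'   `"unknown"` is appended automatically if absent; it must occur at most
#'   once. Binary clinical variables use `c("absent", "present", "unknown")`.
#' @param family Optional identifier grouping mutually exclusive one-hot
#'   siblings (e.g. the gestational-age category columns).
#' @param clinical_rank Optional integer preference used during redundancy
#'   pruning; lower values are preferred for retention (variables with standard
#'   clinical definitions get low ranks).
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, states, family = NULL, clinical_rank = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (!UNKNOWN_STATE %in% states) states <- c(states, UNKNOWN_STATE)
  if (anyDuplicated(states)) {
    stop("states of '", name, "' must be unique (\"unknown\" may appear once)")
  }
  if (sum(states == UNKNOWN_STATE) != 1L) {
    stop("state \"unknown\" must appear exactly once in '", name, "'")
  }
  family <- as.character(unlist(family))
  family <- if (length(family) == 0 || is.na(family[1])) NA_character_ else family[1]
  clinical_rank <- as.integer(unlist(clinical_rank))
  clinical_rank <- if (length(clinical_rank) == 0) NA_integer_ else clinical_rank[1]
  structure(
    list(
      name = name,
      states = states,
      family = family,
      clinical_rank = clinical_rank
    ),
    class = "variable_spec"
  )
}

#' @rdname variable_spec
#' @export
binary_spec <- function(name, family = NULL, clinical_rank = NA_integer_) {
  variable_spec(name, c("absent", "present", UNKNOWN_STATE), family, clinical_rank)
}

is_binary_spec <- function(spec) {
  setequal(spec$states, c("absent", "present", UNKNOWN_STATE))
}

#' @export
print.variable_spec <- function(x, ...) {
  fam <- if (is.na(x$family)) "" else paste0(" [family: ", x$family, "]")
  cat("<variable_spec> ", x$name, ": {", paste(x$states, collapse = ", "), "}",
      fam, "\n", sep = "")
  invisible(x)
}

#' Assemble a categorical cohort
#'
#' @param records Data frame of categorical columns (character or factor).
#' @param outcome Name of the binary outcome column; it must never take the
#'   state `"unknown"` in an analyzed cohort.
#' @param specs Optional named list of [variable_spec()] objects, one per
#'   column. When omitted, specs are inferred: columns whose observed values
#'   are a subset of absent/present/unknown become binary, others take their
#'   observed states (sorted) plus `"unknown"`.
#'
#' @return An object of class `cohort`: list with elements `records` (data
#'   frame of factors whose levels equal the spec states), `outcome`, `specs`.
#' @export
cohort <- function(records, outcome, specs = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) < 1L) stop("a cohort needs at least one record")
  if (!outcome %in% names(records)) stop("outcome column '", outcome, "' not found")
  if (is.null(specs)) {
    specs <- lapply(names(records), function(nm) {
      vals <- unique(as.character(records[[nm]]))
      vals <- vals[!is.na(vals)]
      if (all(vals %in% c("absent", "present", UNKNOWN_STATE))) {
        binary_spec(nm)
      } else {
        variable_spec(nm, sort(setdiff(vals, UNKNOWN_STATE)))
      }
    })
    names(specs) <- names(records)
  }
  if (!setequal(names(specs), names(records))) {
    stop("specs must cover exactly the cohort columns")
  }
  specs <- specs[names(records)]
  for (nm in names(records)) {
    vals <- as.character(records[[nm]])
    vals[is.na(vals)] <- UNKNOWN_STATE
    bad <- setdiff(unique(vals), specs[[nm]]$states)
    if (length(bad)) {
      stop("column '", nm, "' contains values outside its spec: ",
           paste(bad, collapse = ", "))
    }
    records[[nm]] <- factor(vals, levels = specs[[nm]]$states)
  }
  if (any(records[[outcome]] == UNKNOWN_STATE)) {
    stop("outcome column '", outcome, "' may not take state \"unknown\"")
  }
  structure(list(records = records, outcome = outcome, specs = specs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$records), " records x ", ncol(x$records),
      " variables; outcome: ", x$outcome, "\n", sep = "")
  invisible(x)
}

#' Number of records in a cohort
#' @param x A `cohort`.
#' @return Integer record count.
#' @export
n_records <- function(x) nrow(x$records)

#' Names of cohort variables
#' @param x A `cohort`.
#' @param include_outcome Keep the outcome column in the result?
#' @return Character vector of column names.
#' @export
cohort_variables <- function(x, include_outcome = TRUE) {
  nms <- names(x$records)
  if (!include_outcome) nms <- setdiff(nms, x$outcome)
  nms
}

# Names of the nine composite-morbidity components.
OUTCOME_COMPONENTS <- c(
  "stillbirth", "neonatal_death", "mech_ventilation", "rds", "nec",
  "sepsis", "ivh_grade34", "seizures", "nicu_gt7d"
)

#' Apply the cohort exclusion criteria
#'
#' Removes records with missing birth/neonatal outcome data, then records
#' delivered before 20 weeks' gestation. The order is fixed so that
#' per-criterion counts are deterministic; a record failing both criteria is
#' counted once, at the first matching criterion.
#'
#' @param raw_records Data frame with at least `gestational_age_at_delivery`
#'   (weeks, numeric) and `outcome_available` (logical).
#' @return List with `records` (the surviving rows), `removed` (named integer:
#'   `missing_outcome`, `early_delivery`) and `n_input`.
#' @export
apply_exclusions <- function(raw_records) {
  raw_records <- as.data.frame(raw_records)
  if (nrow(raw_records) == 0L) stop("cannot build a cohort from zero records")
  stopifnot(all(c("gestational_age_at_delivery", "outcome_available") %in%
                  names(raw_records)))
  ga <- raw_records$gestational_age_at_delivery
  if (any(!is.na(ga) & ga <= 0)) stop("gestational age must be positive")
  miss <- !raw_records$outcome_available
  early <- !miss & (is.na(ga) | ga < 20)
  keep <- !miss & !early
  list(
    records = raw_records[keep, , drop = FALSE],
    removed = c(missing_outcome = sum(miss), early_delivery = sum(early)),
    n_input = nrow(raw_records)
  )
}

#' Derive the composite perinatal morbidity outcome
#'
#' The composite is present when any of the nine components is present:
#' stillbirth, neonatal death, mechanical ventilation, RDS, NEC, confirmed
#' sepsis, grade 3-4 IVH, seizures, or NICU admission > 7 days.
#'
#' @param components Data frame or matrix with the nine component columns
#'   (values `"present"`/`"absent"`, logical, or NA for missing).
#' @param missing_policy `"absent"` (default) treats a missing component flag
#'   as absent with a warning; `"error"` stops.
#' @return Character vector of `"present"`/`"absent"`, one per row.
#' @export
derive_outcome <- function(components, missing_policy = c("absent", "error")) {
  missing_policy <- match.arg(missing_policy)
  components <- as.data.frame(components)
  missing_cols <- setdiff(OUTCOME_COMPONENTS, names(components))
  if (length(missing_cols)) {
    stop("missing outcome component columns: ", paste(missing_cols, collapse = ", "))
  }
  flags <- lapply(OUTCOME_COMPONENTS, function(nm) {
    v <- components[[nm]]
    if (is.logical(v)) v <- ifelse(v, "present", "absent")
    v <- as.character(v)
    if (anyNA(v) || any(v == UNKNOWN_STATE)) {
      if (missing_policy == "error") stop("component '", nm, "' has missing flags")
      warning("component '", nm, "' has missing flags; treated as absent",
              call. = FALSE)
      v[is.na(v) | v == UNKNOWN_STATE] <- "absent"
    }
    bad <- setdiff(unique(v), c("absent", "present"))
    if (length(bad)) stop("component '", nm, "' has invalid values: ",
                          paste(bad, collapse = ", "))
    v == "present"
  })
  any_present <- Reduce(`|`, flags)
  ifelse(any_present, "present", "absent")
}

#' Categorize estimated fetal weight percentile
#'
#' Boundaries: `< 3` -> `lt3`; `[3, 10)` -> `p3to9`; `[10, 90]` -> `p10to90`;
#' `> 90` -> `gt90`; missing -> `unknown`. The four observed categories
#' partition the percentile scale.
#'
#' @param percentile Numeric vector in \[0, 100\]; NA means missing.
#' @return Character vector of EFW category states.
#' @export
categorize_efw <- function(percentile) {
  ok <- is.na(percentile) | (percentile >= 0 & percentile <= 100)
  if (!all(ok)) stop("EFW percentile outside [0, 100]")
  out <- rep(UNKNOWN_STATE, length(percentile))
  obs <- !is.na(percentile)
  p <- percentile[obs]
  out[obs] <- ifelse(p < 3, "lt3",
              ifelse(p < 10, "p3to9",
              ifelse(p <= 90, "p10to90", "gt90")))
  out
}

#' Categorize gestational age at delivery
#'
#' `< 34` completed weeks -> early preterm; `[34, 37)` -> late preterm;
#' `>= 37` -> term ("34-36 weeks" is read as completed weeks). Records below
#' 20 weeks should have been excluded and raise an error.
#'
#' @param weeks Numeric gestational age in weeks; NA means unknown.
#' @return Character vector of states `early_ptb`/`late_ptb`/`term`/`unknown`.
#' @export
categorize_ga <- function(weeks) {
  if (any(!is.na(weeks) & weeks < 20)) {
    stop("gestational age < 20 weeks: such records must be excluded upstream")
  }
  out <- rep(UNKNOWN_STATE, length(weeks))
  obs <- !is.na(weeks)
  w <- weeks[obs]
  out[obs] <- ifelse(w < 34, "early_ptb", ifelse(w < 37, "late_ptb", "term"))
  out
}

HDP_QUALIFYING <- c("eclampsia", "preeclampsia_severe", "gestational_htn_prelabor")
HDP_ACCEPTED <- c(
  "none", "chronic_htn", "gestational_htn_prelabor", "gestational_htn_intrapartum",
  "preeclampsia_mild", "preeclampsia_severe", "superimposed_preeclampsia",
  "hellp", "eclampsia"
)

#' Dichotomize hypertensive disorders of pregnancy
#'
#' HDP is present when the subtype is eclampsia, preeclampsia with severe
#' features, or gestational hypertension with onset prior to labor. Mild
#' preeclampsia alone does not qualify.
#'
#' @param subtype Character vector of HDP subtype labels (see
#'   `contextrisk:::HDP_ACCEPTED`).
#' @return Character vector of `"present"`/`"absent"`.
#' @export
dichotomize_hdp <- function(subtype) {
  subtype <- as.character(subtype)
  bad <- setdiff(unique(subtype), HDP_ACCEPTED)
  if (length(bad)) {
    stop("unknown HDP subtype(s): ", paste(bad, collapse = ", "),
         "; accepted labels: ", paste(HDP_ACCEPTED, collapse = ", "))
  }
  ifelse(subtype %in% HDP_QUALIFYING, "present", "absent")
}

#' One-hot encode a multi-state variable into a family of binary columns
#'
#' Each non-unknown state becomes a binary column named `<var>_<state>`,
#' sharing `family = <var>`. For each record exactly one sibling is present
#' unless the source cell is unknown, in which case all siblings are unknown.
#'
#' @param x A `cohort`.
#' @param variable Name of a column with at least three non-unknown states.
#' @return A new `cohort` with the variable replaced by its siblings.
#' @export
one_hot <- function(x, variable) {
  stopifnot(inherits(x, "cohort"))
  spec <- x$specs[[variable]]
  if (is.null(spec)) stop("no such variable: ", variable)
  states <- setdiff(spec$states, UNKNOWN_STATE)
  if (length(states) < 3L) {
    warning("'", variable, "' is already binary; one_hot is a no-op", call. = FALSE)
    return(x)
  }
  src <- as.character(x$records[[variable]])
  records <- x$records
  specs <- x$specs
  pos <- match(variable, names(records))
  new_cols <- list()
  new_specs <- list()
  for (s in states) {
    nm <- paste(variable, s, sep = "_")
    v <- ifelse(src == UNKNOWN_STATE, UNKNOWN_STATE,
                ifelse(src == s, "present", "absent"))
    new_cols[[nm]] <- v
    new_specs[[nm]] <- binary_spec(nm, family = variable,
                                   clinical_rank = spec$clinical_rank)
  }
  records[[variable]] <- NULL
  specs[[variable]] <- NULL
  before <- seq_len(pos - 1L)
  records <- cbind(records[, intersect(before, seq_along(records)), drop = FALSE],
                   as.data.frame(new_cols, stringsAsFactors = FALSE),
                   records[, setdiff(seq_along(records), before), drop = FALSE])
  specs <- c(specs[seq_len(pos - 1L)], new_specs,
             specs[setdiff(seq_along(specs), seq_len(pos - 1L))])
  cohort(records, x$outcome, specs)
}

#' Format a count as "percent (n)"
#'
#' @param count Integer count(s).
#' @param n Denominator.
#' @return Character like `"8.2% (783)"` (one decimal place).
#' @export
format_pct <- function(count, n) {
  sprintf("%.1f%% (%d)", 100 * count / n, as.integer(count))
}

#' Summarize a cohort as per-state "percent (n)" rows
#'
#' Percentages are over the full cohort size N, to one decimal place; the
#' `"unknown"` rows double as per-variable missingness rates and are flagged
#' in the `missingness` column.
#'
#' @param x A `cohort`.
#' @return Data frame with `variable`, `state`, `count`, `pct`, `label`,
#'   `missingness`.
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  n <- n_records(x)
  rows <- lapply(names(x$records), function(nm) {
    tab <- table(x$records[[nm]])
    data.frame(
      variable = nm,
      state = names(tab),
      count = as.integer(tab),
      pct = round(100 * as.integer(tab) / n, 1),
      label = format_pct(as.integer(tab), n),
      missingness = names(tab) == UNKNOWN_STATE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a cohort as CSV plus a JSON schema sidecar
#'
#' The CSV holds state labels (reserved label `"unknown"`); the sidecar lists
#' each variable's states, one-hot family and clinical rank, plus the outcome
#' column name.
#'
#' @param path CSV path; the schema lives at `<path>.schema.json` unless
#'   `schema_path` is given.
#' @param x A `cohort` (for writing).
#' @param schema_path Optional explicit schema path.
#' @return `read_cohort` returns a `cohort`; `write_cohort` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(x, path, schema_path = paste0(path, ".schema.json")) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(lapply(x$records, as.character), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  schema <- list(
    outcome = x$outcome,
    variables = lapply(unname(x$specs), function(s) {
      list(name = s$name, states = s$states,
           family = if (is.na(s$family)) NULL else s$family,
           clinical_rank = if (is.na(s$clinical_rank)) NULL else s$clinical_rank)
    })
  )
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema_path = paste0(path, ".schema.json")) {
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  specs <- lapply(schema$variables, function(v) {
    variable_spec(v$name, unlist(v$states),
                  family = v$family,
                  clinical_rank = if (is.null(v$clinical_rank)) NA_integer_
                                  else v$clinical_rank)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  records <- utils::read.csv(path, colClasses = "character",
                             check.names = FALSE)
  cohort(records, schema$outcome, specs)
}
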
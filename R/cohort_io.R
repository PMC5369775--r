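# Cohort data model: binary risk-factor and outcome matrices, CSV I/O,
# outcome-hierarchy validation, and descriptive summaries.

#' Standard preeclampsia-related outcome names
#'
#' The default outcome set used throughout the package: total preeclampsia and
#' its severity/timing subtypes, plus gestational hypertension, small for
#' gestational age, and gestational diabetes.
#'
#' @return character vector of outcome names.
#' @export
standard_outcomes <- function() {
  c("pe", "severe_pe", "early_pe", "intermediate_pe", "term_pe",
    "preterm_pe", "gh", "sga", "gdm")
}

# Implication rules between preeclampsia subtype indicators. Each row:
# antecedent outcome, consequent outcome ("" for mutual exclusion pairs).
subtype_rules <- function() {
  list(
    list(rule = "early_pe => preterm_pe", type = "implies",
         a = "early_pe", b = "preterm_pe"),
    list(rule = "intermediate_pe => preterm_pe", type = "implies",
         a = "intermediate_pe", b = "preterm_pe"),
    list(rule = "preterm_pe => pe", type = "implies",
         a = "preterm_pe", b = "pe"),
    list(rule = "term_pe => pe", type = "implies",
         a = "term_pe", b = "pe"),
    list(rule = "severe_pe => pe", type = "implies",
         a = "severe_pe", b = "pe"),
    list(rule = "term_pe and preterm_pe mutually exclusive", type = "excl",
         a = "term_pe", b = "preterm_pe")
  )
}

check_binary_matrix <- function(values, what) {
  if (!is.matrix(values)) stop_(what, ": `values` must be a matrix")
  bad <- which(!(values %in% c(0L, 1L)) | is.na(values))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop_(what, ": non-binary cell at row ", rownames(values)[i[1L]] %||% i[1L],
          ", column '", colnames(values)[i[2L]], "' (value ",
          values[bad[1L]], ")")
  }
  invisible(values)
}

new_binary_matrix <- function(values, subject_ids, var_names, class, what) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  rownames(values) <- as.character(subject_ids)
  colnames(values) <- var_names
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_(what, ": need at least one subject and one column")
  if (anyDuplicated(rownames(values)))
    stop_(what, ": duplicate subject id '",
          rownames(values)[duplicated(rownames(values))][1L], "'")
  if (anyDuplicated(colnames(values)))
    stop_(what, ": duplicate column name")
  check_binary_matrix(values, what)
  structure(values, class = c(class, "matrix", "array"))
}

#' Construct a validated risk-factor matrix
#'
#' @param values n x J matrix of 0/1 indicators (subjects in rows).
#' @param subject_ids unique subject identifiers; defaults to existing
#'   rownames or `1:n`.
#' @param factor_names risk-factor labels; defaults to existing colnames.
#' @return an integer matrix of class `risk_factor_matrix`.
#' @export
risk_factor_matrix <- function(values,
                               subject_ids = rownames(values) %||% seq_len(nrow(as.matrix(values))),
                               factor_names = colnames(values)) {
  if (is.null(factor_names))
    factor_names <- paste0("factor", seq_len(ncol(as.matrix(values))))
  m <- new_binary_matrix(values, subject_ids, factor_names,
                         "risk_factor_matrix", "risk_factor_matrix")
  if (any(rowSums(m) == 0L))
    warning("risk_factor_matrix: ", sum(rowSums(m) == 0L),
            " subject(s) carry no risk factor", call. = FALSE)
  m
}

#' Construct a validated outcome matrix
#'
#' @param values n x M matrix of 0/1 outcome indicators.
#' @param subject_ids subject identifiers, aligned with the paired
#'   risk-factor matrix.
#' @param outcome_names outcome labels.
#' @return an integer matrix of class `outcome_matrix`.
#' @export
outcome_matrix <- function(values,
                           subject_ids = rownames(values) %||% seq_len(nrow(as.matrix(values))),
                           outcome_names = colnames(values)) {
  if (is.null(outcome_names))
    outcome_names <- paste0("outcome", seq_len(ncol(as.matrix(values))))
  new_binary_matrix(values, subject_ids, outcome_names,
                    "outcome_matrix", "outcome_matrix")
}

#' Read a cohort CSV into paired risk-factor and outcome matrices
#'
#' The CSV must have a header row; `schema` names the subject-id column and
#' which columns are risk factors vs outcomes. `schema` may also be the path
#' to a YAML file with keys `id`, `factors`, `outcomes`.
#'
#' @param path CSV file path.
#' @param schema list with elements `id` (single column name), `factors`
#'   (character vector) and `outcomes` (character vector), or a YAML path.
#' @return list with elements `factors` (risk_factor_matrix) and `outcomes`
#'   (outcome_matrix).
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop_("read_cohort: file not found: ", path)
  if (is.character(schema) && length(schema) == 1L)
    schema <- yaml::read_yaml(schema)
  stopifnot(is.list(schema))
  dat <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(schema$id, schema$factors, schema$outcomes)
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop_("read_cohort: schema column(s) not in header: ",
          paste(missing_cols, collapse = ", "))
  ids <- as.character(dat[[schema$id]])
  if (anyDuplicated(ids))
    stop_("read_cohort: duplicate subject id '", ids[duplicated(ids)][1L], "'")
  fac <- as.matrix(dat[, schema$factors, drop = FALSE])
  out <- as.matrix(dat[, schema$outcomes, drop = FALSE])
  rownames(fac) <- rownames(out) <- ids
  list(factors  = risk_factor_matrix(fac),
       outcomes = outcome_matrix(out))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes one row per subject with an id column
#' followed by the factor and outcome columns.
#'
#' @param factors risk_factor_matrix.
#' @param outcomes outcome_matrix aligned with `factors`.
#' @param path output CSV path.
#' @param id_col name of the subject-id column.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(factors, outcomes, path, id_col = "subject_id") {
  check_aligned(factors, outcomes)
  df <- data.frame(rownames(factors), unclass(factors), unclass(outcomes),
                   check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_aligned <- function(factors, outcomes) {
  if (!identical(rownames(factors), rownames(outcomes)))
    stop_("subject ids of the risk-factor and outcome matrices do not align")
  invisible(TRUE)
}

#' Check preeclampsia subtype logic in an outcome matrix
#'
#' Verifies the implication rules among subtype indicators: early and
#' intermediate imply preterm; preterm, term and severe imply total
#' preeclampsia; term and preterm are mutually exclusive. Rules involving a
#' column absent from the matrix are skipped.
#'
#' @param outcomes outcome_matrix.
#' @return data.frame of violations with columns `subject_id` and `rule`;
#'   zero rows when the hierarchy holds.
#' @export
validate_outcome_hierarchy <- function(outcomes) {
  viol <- list()
  for (r in subtype_rules()) {
    if (!all(c(r$a, r$b) %in% colnames(outcomes))) next
    bad <- if (r$type == "implies") {
      outcomes[, r$a] == 1L & outcomes[, r$b] == 0L
    } else {
      outcomes[, r$a] == 1L & outcomes[, r$b] == 1L
    }
    if (any(bad))
      viol[[length(viol) + 1L]] <- data.frame(
        subject_id = rownames(outcomes)[bad], rule = r$rule,
        stringsAsFactors = FALSE)
  }
  if (!length(viol))
    return(data.frame(subject_id = character(), rule = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

#' Summarize a cohort
#'
#' Counts and percentages per risk factor and per outcome, and the
#' complication dichotomy (subjects with zero vs at least one outcome).
#' Percentages are `100 * count / n` rounded half-up to one decimal.
#'
#' @param factors risk_factor_matrix.
#' @param outcomes outcome_matrix aligned with `factors`.
#' @return object of class `cohort_summary`: a list with `n_subjects`,
#'   `factor_table`, `outcome_table`, `n_no_complication`,
#'   `n_any_complication` and the corresponding percentages.
#' @export
summarize_cohort <- function(factors, outcomes) {
  check_aligned(factors, outcomes)
  n <- nrow(factors)
  pct <- function(k) round_half_up(100 * k / n, 1)
  ftab <- data.frame(variable = colnames(factors),
                     count = as.integer(colSums(factors)),
                     percent = pct(colSums(factors)),
                     stringsAsFactors = FALSE, row.names = NULL)
  otab <- data.frame(variable = colnames(outcomes),
                     count = as.integer(colSums(outcomes)),
                     percent = pct(colSums(outcomes)),
                     stringsAsFactors = FALSE, row.names = NULL)
  any_comp <- as.integer(sum(rowSums(outcomes) > 0L))
  structure(list(
    n_subjects = n,
    factor_table = ftab,
    outcome_table = otab,
    n_no_complication = n - any_comp,
    n_any_complication = any_comp,
    pct_no_complication = pct(n - any_comp),
    pct_any_complication = pct(any_comp)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n_subjects, "subjects\n")
  cat(sprintf("  no complication: %d (%.1f%%); any complication: %d (%.1f%%)\n",
              x$n_no_complication, x$pct_no_complication,
              x$n_any_complication, x$pct_any_complication))
  cat("Risk factors:\n")
  print(x$factor_table, row.names = FALSE)
  cat("Outcomes:\n")
  print(x$outcome_table, row.names = FALSE)
  invisible(x)
}

#' Share of cases with a sub-outcome
#'
#' Among subjects positive for `of`, the count and percentage also positive
#' for `outcome` (e.g. the share of preeclampsia cases with early onset).
#'
#' @param outcomes outcome_matrix.
#' @param outcome name of the sub-outcome column.
#' @param of name of the denominator outcome column.
#' @return list with `k`, `n` and `percent` (half-up, one decimal).
#' @export
subgroup_share <- function(outcomes, outcome, of) {
  stopifnot(outcome %in% colnames(outcomes), of %in% colnames(outcomes))
  idx <- outcomes[, of] == 1L
  n <- sum(idx)
  k <- sum(outcomes[idx, outcome] == 1L)
  list(k = k, n = n,
       percent = if (n > 0) round_half_up(100 * k / n, 1) else 0)
}

#' Write a cohort summary as CSV
#'
#' @param summary cohort_summary from [summarize_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  tab <- rbind(cbind(role = "factor", summary$factor_table),
               cbind(role = "outcome", summary$outcome_table))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
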
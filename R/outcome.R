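#' @name outcome
#' @title Composite knowledge-score outcome construction
#'
#' @description
#' A respondent is said to have *sufficient knowledge* of mother-to-child
#' transmission of HIV (MTCT) and its prevention (PMTCT) when she answers
#' "yes" to all five of the survey questions: having heard of HIV/AIDS;
#' transmission during pregnancy; during delivery; during breastfeeding;
#' and awareness of drugs that prevent transmission to the baby.  The
#' functions here score respondents, apply the complete-case rule (a
#' record missing any of the five responses is excluded), and produce the
#' descriptive tables used in reporting.
NULL

#' The five knowledge-question column names
#' @export
knowledge_questions <- function() {
  c("heard_hiv", "mtct_pregnancy", "mtct_delivery",
    "mtct_breastfeeding", "knows_pmtct_drugs")
}

check_binary_columns <- function(records, cols) {
  for (cl in cols) {
    if (!cl %in% names(records)) {
      stop("missing response column: ", cl, call. = FALSE)
    }
    v <- records[[cl]]
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad)) {
      stop("column '", cl, "' contains non-binary value(s): ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Score the five knowledge responses
#'
#' Computes the 0-5 knowledge score (sum of the five binary indicators)
#' and the binary sufficient-knowledge outcome (score equal to 5).
#' Records missing any of the five responses are flagged incomplete and
#' receive `NA` scores; they take no part in tabulation or modelling.
#'
#' @param records data frame with the five columns named by
#'   [knowledge_questions()], each 0/1 or `NA`.
#' @return `records` with columns `score` (integer 0-5 or `NA`),
#'   `sufficient` (0/1 or `NA`) and `complete` (logical) appended.
#' @examples
#' r <- data.frame(heard_hiv = 1, mtct_pregnancy = 1, mtct_delivery = 1,
#'                 mtct_breastfeeding = 1, knows_pmtct_drugs = 1)
#' score_responses(r)$sufficient  # 1
#' @export
score_responses <- function(records) {
  qs <- knowledge_questions()
  check_binary_columns(records, qs)
  m <- as.matrix(records[qs])
  complete <- rowSums(is.na(m)) == 0L
  score <- ifelse(complete, rowSums(m), NA_integer_)
  records$score <- as.integer(score)
  records$sufficient <- ifelse(complete, as.integer(score == 5L), NA_integer_)
  records$complete <- complete
  records
}

#' Drop records that fail the complete-case rule
#'
#' @param records scored or unscored record data frame.
#' @return records with all five responses present; the number dropped is
#'   stored in attribute `n_dropped` and reported via `message()`.
#' @export
filter_complete_cases <- function(records) {
  if (!"complete" %in% names(records)) records <- score_responses(records)
  n0 <- nrow(records)
  out <- records[records$complete, , drop = FALSE]
  n_dropped <- n0 - nrow(out)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped: incomplete knowledge responses")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Tabulate knowledge of MTCT and PMTCT
#'
#' Per-question yes/no counts with one-decimal percentages, plus the
#' sufficient/insufficient split, computed on complete cases.
#'
#' @param records data frame of respondent records.
#' @return data frame with columns `item`, `response`, `count`, `pct`
#'   and attribute `n` (the complete-case denominator).
#' @export
tabulate_knowledge <- function(records) {
  if (nrow(records) == 0L) stop("no records to tabulate", call. = FALSE)
  records <- filter_complete_cases(score_responses(records))
  n <- nrow(records)
  if (n == 0L) stop("no complete-case records to tabulate", call. = FALSE)
  qs <- knowledge_questions()
  rows <- lapply(qs, function(q) {
    yes <- sum(records[[q]] == 1L)
    data.frame(item = q, response = c("no", "yes"),
               count = c(n - yes, yes))
  })
  suff <- sum(records$sufficient == 1L)
  rows <- c(rows, list(data.frame(
    item = "knowledge_mtct_pmtct",
    response = c("insufficient", "sufficient"),
    count = c(n - suff, suff))))
  out <- do.call(rbind, rows)
  out$pct <- round_half_up(100 * out$count / n, 1)
  attr(out, "n") <- n
  out
}

#' Tabulate categorical covariates
#'
#' Count and one-decimal percentage per level of each requested covariate.
#' Percentages use the per-covariate non-missing denominator.
#'
#' @param records data frame of respondent records.
#' @param covariates character vector of column names to tabulate.
#' @param levels optional named list of declared level sets; any observed
#'   value outside the declared set is a validation error.
#' @return data frame with columns `covariate`, `level`, `count`, `pct`.
#' @export
tabulate_covariates <- function(records, covariates, levels = NULL) {
  if (nrow(records) == 0L) stop("no records to tabulate", call. = FALSE)
  rows <- lapply(covariates, function(cv) {
    if (!cv %in% names(records)) {
      stop("unknown covariate column: ", cv, call. = FALSE)
    }
    v <- records[[cv]]
    v <- v[!is.na(v)]
    lv <- if (!is.null(levels) && cv %in% names(levels)) {
      levels[[cv]]
    } else if (is.factor(v)) base::levels(v) else sort(unique(as.character(v)))
    v <- as.character(v)
    bad <- setdiff(unique(v), lv)
    if (length(bad) > 0) {
      stop("covariate '", cv, "' has undeclared level(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cnt <- vapply(lv, function(l) sum(v == l), integer(1))
    data.frame(covariate = cv, level = lv, count = as.integer(cnt),
               pct = round_half_up(100 * cnt / length(v), 1),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Read a women-level survey CSV
#'
#' @param path CSV path, one row per woman.
#' @param column_map optional named character vector mapping canonical
#'   names (e.g. `heard_hiv`, `region`) to the file's column names;
#'   survey dialects differ.
#' @return data frame with canonical column names.
#' @export
read_women_csv <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("mapped column '", src, "' not found in ", path, call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  df
}
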
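#' Study-table schema
#'
#' A study table is a data frame with one row per case-control study and
#' eight required columns: `study_id`, `population`, and the genotype counts
#' `case_cc`, `case_ct`, `case_tt`, `control_cc`, `control_ct`, `control_tt`.
#' `CC` is the reference-allele homozygote, `CT` the heterozygote and `TT`
#' the effect-allele homozygote. All counts are non-negative integers and
#' each arm must contain at least one individual.
#'
#' @name study_table
#' @keywords internal
NULL

STUDY_COLS <- c(
  "study_id", "population",
  "case_cc", "case_ct", "case_tt",
  "control_cc", "control_ct", "control_tt"
)
COUNT_COLS <- STUDY_COLS[3:8]

#' Validate a study table
#'
#' Checks a data frame against the study-table schema (see [study_table]):
#' required columns present, counts non-negative integers, arm totals at
#' least one, and study ids unique. Returns the table as a tibble with the
#' schema columns first, so it can be dropped into a pipe.
#'
#' @param studies A data frame of per-study genotype counts.
#' @return A tibble with the validated studies, invisibly classed as-is.
#' @examples
#' validate_study_table(rs1564282_studies())
#' @export
validate_study_table <- function(studies) {
  if (!is.data.frame(studies)) {
    abort("`studies` must be a data frame.", class = "allelemeta_format_error")
  }
  missing <- setdiff(STUDY_COLS, names(studies))
  if (length(missing) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
      class = "allelemeta_format_error"
    )
  }
  if (nrow(studies) == 0) {
    abort("No studies: the table has a header but no rows.",
          class = "allelemeta_validation_error")
  }
  out <- as_tibble(studies)
  out$study_id <- as.character(out$study_id)
  out$population <- as.character(out$population)
  for (col in COUNT_COLS) {
    x <- parse_count(out[[col]])
    bad <- which(is.na(x) | x < 0)
    if (length(bad) > 0) {
      abort(
        sprintf(
          "Invalid count in column '%s' for study '%s': counts must be non-negative integers.",
          col, out$study_id[bad[1]]
        ),
        class = "allelemeta_validation_error"
      )
    }
    out[[col]] <- x
  }
  dup <- out$study_id[duplicated(out$study_id)]
  if (length(dup) > 0) {
    abort(
      paste0("Duplicate study_id: ", paste(unique(dup), collapse = ", ")),
      class = "allelemeta_validation_error"
    )
  }
  case_total <- out$case_cc + out$case_ct + out$case_tt
  control_total <- out$control_cc + out$control_ct + out$control_tt
  empty <- which(case_total < 1 | control_total < 1)
  if (length(empty) > 0) {
    abort(
      sprintf("Study '%s' has an empty arm (zero total).", out$study_id[empty[1]]),
      class = "allelemeta_validation_error"
    )
  }
  dplyr::relocate(out, dplyr::all_of(STUDY_COLS))
}

## integer parse tolerating thousands separators and stray whitespace
parse_count <- function(x) {
  if (is.numeric(x)) {
    ok <- is.finite(x) & x == floor(x)
    return(ifelse(ok, as.integer(x), NA_integer_))
  }
  x <- gsub("[, ]", "", as.character(x))
  suppressWarnings({
    num <- as.numeric(x)
    ifelse(is.finite(num) & num == floor(num), as.integer(num), NA_integer_)
  })
}

#' Read a study table from TSV or CSV
#'
#' Reads a delimited file of per-study genotype counts and validates it
#' against the study-table schema. Columns are matched by header name, not
#' position; counts may contain thousands separators.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated study-table tibble.
#' @examples
#' path <- system.file("extdata", "rs1564282_studies.tsv", package = "allelemeta")
#' read_study_table(path)
#' @export
read_study_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "allelemeta_io_error")
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  validate_study_table(raw)
}

#' Write a study table to TSV or CSV
#'
#' The written file round-trips exactly through [read_study_table()].
#'
#' @param studies A study-table data frame.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  studies <- validate_study_table(studies)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(studies[STUDY_COLS], path, progress = FALSE)
  invisible(path)
}

#' The seven published rs1564282 case-control studies
#'
#' Genotype counts for the seven case-control studies of the GAK rs1564282
#' variant (alleles C/T) and Parkinson's disease in Chinese populations:
#' Tang 2012 (South China), Li 2011 (West China), Chen 2013 (West China),
#' Lin 2013 (Taiwan), Tseng 2013 (Taiwan and Singapore arms) and Yu 2015
#' (West China) - 4,055 cases and 3,826 controls in all. This is the worked
#' dataset used throughout the package documentation.
#'
#' @return A validated study-table tibble with 7 rows.
#' @examples
#' rs1564282_studies()
#' @export
rs1564282_studies <- function() {
  validate_study_table(tibble::tribble(
    ~study_id,     ~population,   ~case_cc, ~case_ct, ~case_tt, ~control_cc, ~control_ct, ~control_tt,
    "tang2012",    "South China", 814L,     186L,     19L,      866L,        152L,        12L,
    "li2011",      "West China",  616L,     183L,     13L,      616L,        142L,        4L,
    "chen2013",    "West China",  285L,     81L,      10L,      227L,        48L,         2L,
    "lin2013",     "Taiwan",      341L,     97L,      10L,      363L,        85L,         4L,
    "tseng2013_t", "Taiwan",      381L,     97L,      5L,       387L,        104L,        4L,
    "tseng2013_s", "Singapore",   306L,     77L,      5L,       311L,        77L,         1L,
    "yu2015",      "West China",  385L,     132L,     12L,      331L,        89L,         1L
  ))
}
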
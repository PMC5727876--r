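# Patient-record schema: the flat CSV layout every scoring function consumes.
# Flags are 0/1, sex is male|female, rockall_comorbidity is none|major|severe.

.patient_cols <- c(
  "age", "sex", "pulse", "sbp", "bun_mg_dl", "hb_g_dl",
  "melena", "syncope", "hepatic_disease", "cardiac_failure",
  "rockall_comorbidity", "endoscopy_delay_h", "intervention", "death30"
)
.flag_cols <- c("melena", "syncope", "hepatic_disease", "cardiac_failure")
.comorbidity_levels <- c("none", "major", "severe")

stop_invalid <- function(field, msg, rows = NULL) {
  where <- if (is.null(rows)) "" else
    sprintf(" (row%s %s)", if (length(rows) > 1L) "s" else "",
            paste(utils::head(rows, 5L), collapse = ", "))
  stop(sprintf("invalid patient record: field '%s' %s%s", field, msg, where),
       call. = FALSE)
}

#' Validate a cohort of patient records
#'
#' Checks a data frame of patient records against the schema the score
#' calculators require: mandatory, strictly positive vitals and labs
#' (`pulse`, `sbp`, `bun_mg_dl`, `hb_g_dl`), `age` at least 18 (the study
#' enrols adults only), `sex` one of `male`/`female`, and
#' `rockall_comorbidity` one of `none`/`major`/`severe`. The four GBS symptom
#' and comorbidity flags (`melena`, `syncope`, `hepatic_disease`,
#' `cardiac_failure`) default to 0 when their columns are absent — the scores
#' award points only for a documented "present", so absence of mention is the
#' clinical default. Outcome columns (`intervention`, `death30`) and
#' `endoscopy_delay_h` stay optional.
#'
#' @param records Data frame of patient records (one row per patient).
#' @return The validated data frame, with any absent flag columns added as 0,
#'   flags coerced to integer 0/1 and `sex`/`rockall_comorbidity` to character.
#' @examples
#' validate_patients(data.frame(
#'   age = 70, sex = "male", pulse = 88, sbp = 132,
#'   bun_mg_dl = 17, hb_g_dl = 13.5, rockall_comorbidity = "none"
#' ))
#' @export
validate_patients <- function(records) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame of patient records", call. = FALSE)
  }
  for (col in c("age", "sex", "pulse", "sbp", "bun_mg_dl", "hb_g_dl",
                "rockall_comorbidity")) {
    if (!col %in% names(records)) stop_invalid(col, "is missing")
  }
  num_check <- function(col, lower, strict = TRUE) {
    x <- records[[col]]
    if (!is.numeric(x)) stop_invalid(col, "must be numeric")
    bad <- which(!is.finite(x) | (if (strict) x <= lower else x < lower))
    if (length(bad)) {
      stop_invalid(col, sprintf("must be %s %s", if (strict) ">" else ">=", lower),
                   rows = bad)
    }
  }
  num_check("pulse", 0)
  num_check("sbp", 0)
  num_check("bun_mg_dl", 0)
  num_check("hb_g_dl", 0)
  num_check("age", 18, strict = FALSE)

  sex <- as.character(records$sex)
  bad <- which(!sex %in% c("male", "female"))
  if (length(bad)) stop_invalid("sex", "must be 'male' or 'female'", rows = bad)
  records$sex <- sex

  com <- as.character(records$rockall_comorbidity)
  bad <- which(!com %in% .comorbidity_levels)
  if (length(bad)) {
    stop_invalid("rockall_comorbidity", "must be one of none|major|severe",
                 rows = bad)
  }
  records$rockall_comorbidity <- com

  for (col in .flag_cols) {
    if (!col %in% names(records)) {
      records[[col]] <- integer(nrow(records))
      next
    }
    x <- records[[col]]
    if (is.logical(x)) x <- as.integer(x)
    bad <- which(!x %in% c(0L, 1L))
    if (length(bad)) stop_invalid(col, "must be a 0/1 flag", rows = bad)
    records[[col]] <- as.integer(x)
  }
  for (col in c("intervention", "death30")) {
    if (col %in% names(records)) {
      x <- records[[col]]
      if (is.logical(x)) x <- as.integer(x)
      bad <- which(!(x %in% c(0L, 1L) | is.na(x)))
      if (length(bad)) stop_invalid(col, "must be a 0/1 flag", rows = bad)
      records[[col]] <- as.integer(x)
    }
  }
  records
}

#' Read and write patient cohorts in the flat CSV schema
#'
#' `read_cohort()` reads a CSV of patient records, validates it with
#' [validate_patients()], and returns the validated data frame.
#' `write_cohort()` writes records back in the same schema, so a written
#' cohort round-trips through `read_cohort()` unchanged.
#'
#' @param path Path to a CSV file.
#' @param records Data frame of patient records.
#' @return `read_cohort()` returns the validated data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  validate_patients(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  records <- validate_patients(records)
  cols <- intersect(.patient_cols, names(records))
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
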
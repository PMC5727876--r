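# Score band definitions. Band edges follow the printed one-decimal tables as
# half-open intervals on the left edge: "22.4-27.9" means [22.4, 28), so values
# in the printed rounding gaps (e.g. BUN 22.35) still fall in exactly one band.

.band <- function(x, breaks, points) {
  # breaks partition (-Inf, Inf) into length(points) half-open [lo, hi) bands
  points[findInterval(x, breaks, left.open = FALSE)]
}

mgbs_component_points <- function(pulse, sbp, bun, hb, sex) {
  pulse_pts <- as.integer(pulse >= 100)
  sbp_pts <- .band(sbp, c(-Inf, 90, 100, 110), c(3L, 2L, 1L, 0L))
  bun_pts <- .band(bun, c(-Inf, 19, 22.4, 28, 70), c(0L, 2L, 3L, 4L, 6L))
  hb_pts <- ifelse(
    sex == "male",
    .band(hb, c(-Inf, 10, 12, 13), c(6L, 3L, 1L, 0L)),
    .band(hb, c(-Inf, 10, 12), c(6L, 1L, 0L))
  )
  data.frame(pulse = pulse_pts, sbp = sbp_pts, bun = bun_pts,
             hb = as.integer(hb_pts))
}

#' Compute the modified Glasgow-Blatchford score (mGBS)
#'
#' The mGBS keeps only the four quantitative factors of the GBS — pulse,
#' systolic blood pressure, blood urea nitrogen and hemoglobin — and drops the
#' symptom/comorbidity flags. Points per band:
#' pulse >= 100 beats/min scores 1; SBP 100-109 mmHg scores 1, 90-99 scores 2,
#' < 90 scores 3; BUN (mg/dL) 19-22.3 scores 2, 22.4-27.9 scores 3, 28-69.9
#' scores 4, >= 70 scores 6; hemoglobin (g/dL) for men 12-12.9 scores 1,
#' 10-11.9 scores 3, < 10 scores 6, and for women 10-11.9 scores 1, < 10
#' scores 6. Everything else scores 0, so the range is 0-16.
#'
#' @param records Data frame of patient records (see [validate_patients()]).
#' @return Integer vector of scores, one per row of `records`.
#' @examples
#' pt <- data.frame(age = 60, sex = "male", pulse = 102, sbp = 105,
#'                  bun_mg_dl = 25, hb_g_dl = 11.5,
#'                  rockall_comorbidity = "none")
#' compute_mgbs(pt)  # 1 + 1 + 3 + 3 = 8
#' @seealso [compute_gbs()], [compute_pre_e_rs()], [score_patients()]
#' @export
compute_mgbs <- function(records) {
  records <- validate_patients(records)
  pts <- mgbs_component_points(records$pulse, records$sbp,
                               records$bun_mg_dl, records$hb_g_dl,
                               records$sex)
  as.integer(rowSums(pts))
}

#' Compute the Glasgow-Blatchford score (GBS)
#'
#' The full GBS adds four categorical factors to the mGBS bands: hepatic
#' disease (2 points), cardiac failure (2), melena (1) and syncope (2), for a
#' maximum of 23. Flags absent from the data default to 0 (not present).
#'
#' @inheritParams compute_mgbs
#' @return Integer vector of scores.
#' @export
compute_gbs <- function(records) {
  records <- validate_patients(records)
  compute_mgbs(records) +
    2L * records$hepatic_disease + 2L * records$cardiac_failure +
    1L * records$melena + 2L * records$syncope
}

#' Compute the pre-endoscopy Rockall score (Pre-E RS)
#'
#' The Rockall score without its endoscopic-findings item: age (< 60 scores 0,
#' 60-79 scores 1, >= 80 scores 2), shock, and comorbidity (none 0; ischemic
#' heart disease, congestive heart failure or other major comorbidity 2; renal
#' failure, hepatic failure or malignancy 3). Shock is a single ordinal item:
#' hypotension (SBP < 100 mmHg) scores 2 and takes precedence over tachycardia
#' (pulse > 100, scoring 1); the two are never summed. Range 0-7. Note the
#' tachycardia threshold is strictly greater than 100, unlike the mGBS pulse
#' band which starts at 100.
#'
#' @inheritParams compute_mgbs
#' @return Integer vector of scores.
#' @export
compute_pre_e_rs <- function(records) {
  records <- validate_patients(records)
  age_pts <- .band(records$age, c(-Inf, 60, 80), c(0L, 1L, 2L))
  shock_pts <- ifelse(records$sbp < 100, 2L,
                      ifelse(records$pulse > 100, 1L, 0L))
  com_pts <- c(none = 0L, major = 2L, severe = 3L)[records$rockall_comorbidity]
  as.integer(age_pts + shock_pts + unname(com_pts))
}

.score_funs <- list(gbs = compute_gbs, mgbs = compute_mgbs,
                    pre_e_rs = compute_pre_e_rs)

#' Append all three risk scores to a cohort
#'
#' @inheritParams compute_mgbs
#' @return `records` with integer columns `gbs`, `mgbs` and `pre_e_rs`
#'   appended.
#' @export
score_patients <- function(records) {
  records <- validate_patients(records)
  records$gbs <- compute_gbs(records)
  records$mgbs <- compute_mgbs(records)
  records$pre_e_rs <- compute_pre_e_rs(records)
  records
}

#' Group a scored cohort into per-score outcome counts
#'
#' Collapses per-patient records into the grouped form the ROC and threshold
#' machinery consumes: one row per distinct score value with the number of
#' outcome-positive and outcome-negative patients. This is the native data
#' shape of a published score-by-outcome table.
#'
#' @inheritParams compute_mgbs
#' @param score One of `"gbs"`, `"mgbs"`, `"pre_e_rs"`.
#' @param outcome One of `"intervention"`, `"death30"`; must be present and
#'   non-missing for every record.
#' @return A [grouped_counts] data frame with columns `score`, `n_pos`,
#'   `n_neg`; row counts sum to `nrow(records)`.
#' @export
score_cohort <- function(records, score = c("gbs", "mgbs", "pre_e_rs"),
                         outcome = c("intervention", "death30")) {
  score <- match.arg(score)
  outcome <- match.arg(outcome)
  if (nrow(records) == 0L) {
    return(grouped_counts(integer(), integer(), integer()))
  }
  records <- validate_patients(records)
  if (!outcome %in% names(records) || anyNA(records[[outcome]])) {
    stop(sprintf("outcome '%s' must be present for every record", outcome),
         call. = FALSE)
  }
  s <- .score_funs[[score]](records)
  y <- records[[outcome]]
  values <- sort(unique(s))
  grouped_counts(
    score = values,
    n_pos = vapply(values, function(v) sum(y == 1L & s == v), integer(1)),
    n_neg = vapply(values, function(v) sum(y == 0L & s == v), integer(1))
  )
}
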
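#' Score immunohistochemistry cases for nuclear activation
#'
#' Computes the nuclear H-score (nuclear staining intensity, 0-3,
#' times the percentage of positive nuclei, 0-100; range 0-300) and
#' calls a case *activated* when its H-score strictly exceeds the
#' normal-tissue reference. The default reference of 90 encodes the
#' normal bronchial epithelium pattern -- strong (intensity 3)
#' nuclear staining in 30% of cells -- so a tumor indistinguishable
#' from normal is not called activated. Cases with strong,
#' exclusively cytoplasmic staining (cytoplasmic intensity 3, nuclear
#' 0) are flagged separately; they are never activated.
#'
#' @param records data.frame with case_id, nuclear_intensity,
#'   cytoplasmic_intensity and pct_positive_nuclei columns
#'   (see [read_ihc_table()]).
#' @param reference_h Reference H-score (default 90).
#' @return data.frame with case_id, h_score, activated and
#'   cytoplasmic_only columns.
#' @export
score_case <- function(records, reference_h = 90) {
  validate_ihc(records)
  h <- records$nuclear_intensity * records$pct_positive_nuclei
  data.frame(
    case_id = records$case_id,
    h_score = h,
    activated = h > reference_h,
    cytoplasmic_only = records$cytoplasmic_intensity == 3 &
      records$nuclear_intensity == 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Summarize activation calls over a cohort
#'
#' Tallies the three categories -- activated, exclusively-cytoplasmic
#' and other -- with percentages rounded to the nearest integer.
#'
#' @param calls data.frame from [score_case()].
#' @return List with n_total, per-category counts and rounded
#'   percentages.
#' @export
summarize_cohort <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stopf("no activation calls to summarize")
  n <- nrow(calls)
  n_act <- sum(calls$activated)
  n_cyt <- sum(calls$cytoplasmic_only & !calls$activated)
  n_other <- n - n_act - n_cyt
  list(
    n_total = n,
    n_activated = n_act,
    n_cytoplasmic_only = n_cyt,
    n_other = n_other,
    pct_activated = round(100 * n_act / n),
    pct_cytoplasmic_only = round(100 * n_cyt / n),
    pct_other = round(100 * n_other / n)
  )
}
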
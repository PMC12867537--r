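# Proportional recovery rule: expected recovery = beta * (66 - FMAUE_T0)
# + C, with beta = 0.7 and C = 0.4. Patients whose absolute PRR error is
# below 20 FMA-UE points are recoverers (REC); the rest are NO-REC.

#' Proportional-recovery-rule parameters
#' @param beta recovered proportion of the lost FMA-UE points.
#' @param C additive offset (FMA-UE points).
#' @param rec_threshold REC/NO-REC absolute-error threshold (strict
#'   `<`).
#' @return named list of parameters.
#' @export
prrParams <- function(beta = 0.7, C = 0.4, rec_threshold = 20) {
  stopifnot(beta > 0, beta <= 1, rec_threshold > 0)
  list(beta = beta, C = C, rec_threshold = rec_threshold)
}

#' Predicted FMA-UE recovery under the proportional recovery rule
#' @param fmaue_T0 baseline FMA-UE score(s), 0-66.
#' @param params a [prrParams()] list.
#' @return predicted score change (FMA-UE points).
#' @examples
#' prrPredict(c(66, 0, 8))  # 0.4, 46.6, 41.0
#' @export
prrPredict <- function(fmaue_T0, params = prrParams()) {
  if (any(fmaue_T0 < 0 | fmaue_T0 > 66))
    stop("fmaue_T0 outside [0, 66]")
  params$beta * (66 - fmaue_T0) + params$C
}

#' Evaluate the proportional recovery rule on a cohort
#'
#' Computes per patient the predicted and actual recovery, the absolute
#' error, and the REC/NO-REC label (REC iff error < 20 points, strict).
#' The summary median and IQR of absolute errors are taken only over
#' patients passing the configured ceiling exclusions (ceiling = score
#' 66); NO-REC counts always cover the whole cohort.
#'
#' @param cohort a patient table as from [readCohort()].
#' @param params a [prrParams()] list.
#' @param exclude_baseline_ceiling drop baseline-66 patients from the
#'   error summary.
#' @param exclude_followup_ceiling additionally drop follow-up-66
#'   patients (used for the subacute cohort).
#' @return list with `results` (per-patient `data.frame`: subject_id,
#'   predicted_delta, actual_delta, abs_error, label, tested), and the
#'   summary fields `median`, `iqr`, `n_tested`, `n_norec`.
#' @examples
#' fx <- cohortFixtures()
#' prrEvaluate(fx$fdg, exclude_followup_ceiling = TRUE)$median  # 19
#' @export
prrEvaluate <- function(cohort, params = prrParams(),
                        exclude_baseline_ceiling = TRUE,
                        exclude_followup_ceiling = FALSE) {
  stopifnot(nrow(cohort) > 0)
  pred <- prrPredict(cohort$fmaue_T0, params)
  actual <- cohort$fmaue_T1 - cohort$fmaue_T0
  err <- abs(pred - actual)
  tested <- rep(TRUE, nrow(cohort))
  if (exclude_baseline_ceiling) tested <- tested & cohort$fmaue_T0 < 66
  if (exclude_followup_ceiling) tested <- tested & cohort$fmaue_T1 < 66
  if (!any(tested)) stop("all patients excluded from PRR testing")
  res <- data.frame(
    subject_id = as.character(cohort$subject_id),
    predicted_delta = pred, actual_delta = actual, abs_error = err,
    label = ifelse(err < params$rec_threshold, "REC", "NO-REC"),
    tested = tested, stringsAsFactors = FALSE
  )
  list(results = res,
       median = median(err[tested]), iqr = IQR(err[tested]),
       n_tested = sum(tested), n_norec = sum(res$label == "NO-REC"))
}
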
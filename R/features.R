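# Feature registry and per-recording extraction. The per-epoch vector
# is 141 spectral + 80 connectivity/network EEG features, plus the
# three fixed clinical inputs (baseline FMA-UE, days since stroke,
# days to follow-up): 224 in total.

#' Canonical feature inventory
#'
#' One row per feature, in the exact order emitted by
#' [spectralBlock()], [connectivityBlock()] and the clinical triple:
#' name, family (relpow, dar, dtabr, pdbsi, dirpdbsi, iaf, net, node,
#' clinical), functional domain (spectral, brain_symmetry,
#' node_connectivity, network, clinical), band and scope.
#'
#' @return `data.frame` with 224 rows and columns `name`, `family`,
#'   `domain`, `band`, `scope`.
#' @examples
#' table(featureRegistry()$domain)
#' @export
featureRegistry <- function() {
  rows <- list()
  add <- function(name, family, domain, band, scope)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, family = family, domain = domain, band = band,
      scope = scope, stringsAsFactors = FALSE)
  for (scope in .RELPOW_SCOPES)
    for (band in .POW_BANDS)
      add(paste("relpow", band, scope, sep = "_"), "relpow", "spectral",
          band, scope)
  for (scope in .RELPOW_SCOPES)
    add(paste("dar", scope, sep = "_"), "dar", "spectral", "", scope)
  for (scope in .DTABR_SCOPES)
    add(paste("dtabr", scope, sep = "_"), "dtabr", "spectral", "", scope)
  for (fam in c("pdbsi", "dirpdbsi"))
    for (band in .SYM_BANDS)
      for (scope in .SYM_SCOPES)
        add(paste(fam, band, scope, sep = "_"), fam, "brain_symmetry",
            band, scope)
  for (scope in .RELPOW_SCOPES)
    add(paste("iaf", scope, sep = "_"), "iaf", "spectral", "", scope)
  for (band in .POW_BANDS) {
    for (m in c("degree", "strength", "pathlen", "clustering", "omega",
                "richclub"))
      add(paste("net", m, band, sep = "_"), "net", "network", band,
          "global")
    for (lab in c("AH", "UH"))
      for (m in c("degree", "strength", "pathlen", "clustering",
                  "localeff"))
        add(paste("node", m, lab, band, sep = "_"), "node",
            "node_connectivity", band, lab)
  }
  add("fmaue_t0", "clinical", "clinical", "", "")
  add("days_since_stroke", "clinical", "clinical", "", "")
  add("days_to_followup", "clinical", "clinical", "", "")
  do.call(rbind, rows)
}

#' Names of the 221 candidate EEG features
#' @return character vector (registry order, clinical triple removed).
#' @export
eegFeatureNames <- function() {
  reg <- featureRegistry()
  reg$name[reg$domain != "clinical"]
}

#' Extract the full feature table of one recording
#'
#' Applies the hemisphere swap, cuts 10-s epochs from the central
#' 180 s at the requested overlap, and computes the 221 EEG features
#' per epoch plus the clinical triple. Returned as a
#' `SummarizedExperiment`: rows = 224 features (rowData = the
#' registry), columns = epochs (colData = subject, epoch index, start
#' time, overlap).
#'
#' @param recording an [EEGRecording-class].
#' @param patient one-row patient record (`fmaue_T0`, `days_T0`,
#'   `days_T1` used); may be `NULL`, in which case the clinical triple
#'   is `NA`.
#' @param overlap epoch overlap fraction (0, 0.25, 0.5, 0.75).
#' @param seed RNG seed for the omega surrogate ensemble.
#' @return a `SummarizedExperiment` with assay `"features"`.
#' @export
extractFeatures <- function(recording, patient = NULL, overlap = 0,
                            seed = 1L) {
  rec <- swapHemispheres(recording)
  epochs <- extractEpochs(rec, overlap = overlap)
  clin <- c(
    fmaue_t0 = if (is.null(patient)) NA_real_ else patient$fmaue_T0,
    days_since_stroke = if (is.null(patient)) NA_real_ else patient$days_T0,
    days_to_followup = if (is.null(patient)) NA_real_
      else patient$days_T1 - patient$days_T0
  )
  mats <- vapply(epochs, function(ep) {
    psd <- welchPSD(ep)
    c(spectralBlock(psd), connectivityBlock(ep, seed = seed), clin)
  }, numeric(224))
  reg <- featureRegistry()
  stopifnot(identical(rownames(mats), reg$name))
  cd <- S4Vectors::DataFrame(
    subject_id = vapply(epochs, `[[`, "", "subject_id"),
    epoch_index = vapply(epochs, `[[`, 0L, "epoch_index"),
    start = vapply(epochs, `[[`, 0, "start"),
    overlap = overlap
  )
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mats),
    rowData = S4Vectors::DataFrame(reg[, -1], row.names = reg$name),
    colData = cd
  )
}

#' Combine per-subject feature tables into one cohort table
#' @param feature_list list of [extractFeatures()] results.
#' @return a single `SummarizedExperiment` with epochs of all subjects
#'   as columns.
#' @export
bindFeatureTables <- function(feature_list) {
  do.call(SummarizedExperiment::cbind, feature_list)
}
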
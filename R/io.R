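# Cohort and EEG readers. The cohort CSV mirrors the clinical tables:
# subject_id, sex, age, affected_hemisphere (L/R), days_T0, days_T1,
# fmaue_T0, fmaue_T1. EEG comes either as EDF or as a plain delimited
# channel x sample matrix with a JSON sidecar {labels, fs}.

.COHORT_COLS <- c("subject_id", "sex", "age", "affected_hemisphere",
                  "days_T0", "days_T1", "fmaue_T0", "fmaue_T1")

#' Read and validate a cohort table
#'
#' @param path CSV file with columns `subject_id, sex, age,
#'   affected_hemisphere (L/R), days_T0, days_T1, fmaue_T0, fmaue_T1`.
#'   FMA-UE scores must lie in 0-66 and the follow-up must postdate the
#'   baseline.
#' @return a `data.frame` of patient records (one row per subject).
#' @examples
#' tab <- readCohort(system.file("extdata", "fdg_subacute_cohort.csv",
#'                               package = "StrokeRecovNet"))
#' nrow(tab)  # 17
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("cohort file is empty: ", path)
  missing <- setdiff(.COHORT_COLS, names(tab))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  validateCohort(tab)
}

validateCohort <- function(tab) {
  tab$subject_id <- as.character(tab$subject_id)
  bad_h <- !tab$affected_hemisphere %in% c("L", "R")
  if (any(bad_h))
    stop("unknown affected_hemisphere code for subject(s): ",
         paste(tab$subject_id[bad_h], collapse = ", "))
  for (col in c("fmaue_T0", "fmaue_T1")) {
    bad <- !is.finite(tab[[col]]) | tab[[col]] < 0 | tab[[col]] > 66
    if (any(bad))
      stop(col, " outside [0, 66] for subject(s): ",
           paste(tab$subject_id[bad], collapse = ", "))
  }
  bad_d <- tab$days_T1 <= tab$days_T0
  if (any(bad_d))
    stop("days_T1 must exceed days_T0 for subject(s): ",
         paste(tab$subject_id[bad_d], collapse = ", "))
  tab
}

#' Packaged clinical cohort tables
#'
#' The two cohorts shipped with the package: 23 acute-phase patients
#' (AOUP-Acute) and 17 subacute-phase patients (FDG-Subacute), as
#' validated patient tables. These drive the proportional-recovery-rule
#' benchmarks; no EEG is attached.
#'
#' @return a named list with `data.frame`s `aoup` (23 rows) and `fdg`
#'   (17 rows).
#' @export
cohortFixtures <- function() {
  list(
    aoup = readCohort(system.file("extdata", "aoup_acute_cohort.csv",
                                  package = "StrokeRecovNet")),
    fdg = readCohort(system.file("extdata", "fdg_subacute_cohort.csv",
                                 package = "StrokeRecovNet"))
  )
}

#' Read an EEG recording from disk
#'
#' @param path an EDF file, or a delimited text matrix (one row per
#'   channel) accompanied by a JSON sidecar `<path>.json` holding
#'   `{"labels": [...], "fs": <Hz>}`.
#' @param format `"edf"` or `"csv-matrix"`; guessed from the extension
#'   by default.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param lesion_side lesioned hemisphere.
#' @return an [EEGRecording-class].
#' @export
readEEG <- function(path, format = c("auto", "edf", "csv-matrix"),
                    subject_id = NULL,
                    lesion_side = c("right", "left")) {
  format <- match.arg(format)
  lesion_side <- match.arg(lesion_side)
  if (!file.exists(path)) stop("EEG file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE))
      "edf" else "csv-matrix"
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "edf") {
    edf <- readEDF(path)
    return(EEGRecording(subject_id, edf$data, edf$labels, edf$fs,
                        lesion_side))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("csv-matrix EEG requires a JSON sidecar at ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$labels) || is.null(meta$fs))
    stop("sidecar must provide 'labels' and 'fs'")
  mat <- as.matrix(read.table(path, sep = ",", header = FALSE))
  if (nrow(mat) != length(meta$labels))
    stop("matrix has ", nrow(mat), " rows but sidecar lists ",
         length(meta$labels), " labels")
  EEGRecording(subject_id, mat, meta$labels, meta$fs, lesion_side)
}

# Minimal EDF (European Data Format) reader: continuous recordings,
# identical sampling rate across signals, 16-bit samples.
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdChar <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rdNum <- function(n) as.numeric(rdChar(n))
  rdChar(8)                       # version
  rdChar(80); rdChar(80)          # patient / recording id
  rdChar(8); rdChar(8)            # start date / time
  rdNum(8)                        # header length
  rdChar(44)
  n_rec <- rdNum(8)
  rec_dur <- rdNum(8)
  n_sig <- as.integer(rdNum(4))
  fld <- function(w) vapply(seq_len(n_sig), function(i) rdChar(w), "")
  labels <- fld(16)
  fld(80); fld(8)                 # transducer, physical dimension
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                         # prefiltering
  spr <- as.integer(fld(8))       # samples per record
  fld(32)
  if (length(unique(spr)) != 1)
    stop("EDF signals with heterogeneous sampling rates are not supported")
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  data <- matrix(0, n_sig, n_rec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  off <- pmin - gain * dmin
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      seg <- raw[(pos + 1L):(pos + spr[s])]
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        gain[s] * seg + off[s]
      pos <- pos + spr[s]
    }
  }
  list(labels = normalizeLabels(labels), fs = fs, data = data)
}

# Companion EDF writer (internal; lets tests round-trip a file built in
# code rather than shipping a binary fixture).
writeEDF <- function(path, data, labels, fs, rec_dur = 1) {
  n_sig <- nrow(data)
  spr <- as.integer(fs * rec_dur)
  n_rec <- ncol(data) %/% spr
  data <- data[, seq_len(n_rec * spr), drop = FALSE]
  pmax <- max(1, ceiling(max(abs(data))))
  dmax <- 32767
  dig <- round(data / pmax * dmax)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeChar(substr(s, 1, w), con, eos = NULL)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 * (n_sig + 1), 8); pad("", 44)
  pad(n_rec, 8); pad(format(rec_dur), 8); pad(n_sig, 4)
  for (l in labels) pad(l, 16)
  for (i in seq_len(n_sig)) pad("", 80)
  for (i in seq_len(n_sig)) pad("uV", 8)
  for (i in seq_len(n_sig)) pad(-pmax, 8)
  for (i in seq_len(n_sig)) pad(pmax, 8)
  for (i in seq_len(n_sig)) pad(-dmax, 8)
  for (i in seq_len(n_sig)) pad(dmax, 8)
  for (i in seq_len(n_sig)) pad("", 80)
  for (i in seq_len(n_sig)) pad(spr, 8)
  for (i in seq_len(n_sig)) pad("", 32)
  for (r in seq_len(n_rec))
    for (s in seq_len(n_sig))
      writeBin(as.integer(dig[s, ((r - 1) * spr + 1):(r * spr)]),
               con, size = 2, endian = "little")
  invisible(path)
}
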
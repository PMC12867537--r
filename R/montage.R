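# 10-10 montage: the 50 lateral channels feeding the six regions of
# interest, and the homologous left/right pairing used by the hemisphere
# swap. Midline channels are accepted on input but never used.

.ROI_CHANNELS <- list(
  FR = c("Fp2", "AF4", "AF8", "F2", "F4", "F6", "F8"),
  FL = c("Fp1", "AF3", "AF7", "F1", "F3", "F5", "F7"),
  CR = c("FC2", "FC4", "FC6", "FT8", "C2", "C4", "C6", "T4",
         "CP2", "CP4", "CP6"),
  CL = c("FC1", "FC3", "FC5", "FT7", "C1", "C3", "C5", "T3",
         "CP1", "CP3", "CP5"),
  OR = c("P2", "P4", "P6", "T6", "PO8", "PO4", "O2"),
  OL = c("P1", "P3", "P5", "T5", "PO7", "PO3", "O1")
)

#' Region-of-interest layout of the 50-channel lateral montage
#'
#' Six lateral ROIs (frontal/central/occipital x right/left), their
#' merged bilateral unions F, C, O, and the affected/unaffected
#' hemisphere channel sets AH and UH. After [swapHemispheres()] the
#' right-hand side always refers to the lesioned (affected) hemisphere,
#' so AH is the union of the three right ROIs and UH of the three left.
#'
#' @return named list of character vectors of channel labels:
#'   `FR, FL, CR, CL, OR, OL` (7, 7, 11, 11, 7, 7 channels), `F`, `C`,
#'   `O` (bilateral unions), `AH`, `UH` (25 channels each).
#' @examples
#' lengths(roiLayout())
#' @export
roiLayout <- function() {
  r <- .ROI_CHANNELS
  c(r, list(
    F = c(r$FR, r$FL), C = c(r$CR, r$CL), O = c(r$OR, r$OL),
    AH = c(r$FR, r$CR, r$OR), UH = c(r$FL, r$CL, r$OL)
  ))
}

#' @rdname roiLayout
#' @return `lateralChannels()`: the 50 lateral channel labels in
#'   canonical (ROI) order.
#' @export
lateralChannels <- function() unname(unlist(.ROI_CHANNELS))

#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-48 Hz, plus
#' the 1-48 Hz broadband. The five bands tile 1-48 Hz; the upper bound
#' is capped at 48 Hz to stay clear of power-line residue.
#'
#' @return named list of `c(lower, upper)` Hz pairs.
#' @export
bandSet <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 48), broad = c(1, 48))
}

# canonical case for a 10-10 label: "FP1" -> "Fp1", "po8" -> "PO8", etc.
normalizeLabels <- function(labels) {
  labels <- gsub("[[:space:].]", "", as.character(labels))
  canon <- c(lateralChannels(), "Fz", "Cz", "Pz", "Oz", "Fpz", "AFz",
             "FCz", "CPz", "POz", "T7", "T8", "P7", "P8")
  idx <- match(toupper(labels), toupper(canon))
  out <- ifelse(is.na(idx), labels, canon[idx])
  # T7/T8 and P7/P8 are the modern names of T3/T4 and T5/T6
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  hit <- out %in% names(alias)
  out[hit] <- alias[out[hit]]
  out
}

# homologous pair of a lateral label, by 10-10 digit parity:
# odd-numbered (left) label <-> same prefix with digit + 1 (right).
homologousPairs <- function(overrides = NULL) {
  left <- unlist(.ROI_CHANNELS[c("FL", "CL", "OL")], use.names = FALSE)
  digit <- as.integer(sub("^[A-Za-z]+", "", left))
  right <- paste0(sub("[0-9]+$", "", left), digit + 1L)
  map <- setNames(right, left)
  if (!is.null(overrides)) map[names(overrides)] <- overrides
  map
}

#' Swap homologous channels so the affected hemisphere is on the right
#'
#' For a left-hemisphere lesion, every homologous lateral channel pair
#' (Fp1/Fp2, C3/C4, ...) has its signals exchanged so the right-hand
#' channels always carry the lesioned hemisphere; a right-hemisphere
#' lesion returns the recording unchanged. Midline and unpaired channels
#' are untouched. Applied twice (with `force = TRUE`), the swap is its
#' own inverse.
#'
#' @param recording an [EEGRecording-class].
#' @param force swap regardless of lesion side (testing aid).
#' @return an `EEGRecording` with signals exchanged where required.
#' @export
swapHemispheres <- function(recording, force = FALSE) {
  stopifnot(is(recording, "EEGRecording"))
  if (!force && recording@lesion_side != "left") return(recording)
  pairs <- homologousPairs()
  labels <- recording@channel_labels
  lat_left <- intersect(names(pairs), labels)
  missing <- lat_left[!pairs[lat_left] %in% labels]
  if (length(missing))
    stop("montage error: no right homologue present for channel(s) ",
         paste(missing, collapse = ", "))
  out <- recording
  li <- match(lat_left, labels)
  ri <- match(pairs[lat_left], labels)
  out@data[c(li, ri), ] <- recording@data[c(ri, li), ]
  rownames(out@data) <- labels
  out
}

#' Cut fixed-length epochs from the central 180 s of a recording
#'
#' The temporally centered 180 s of the (artifact-free) signal are
#' segmented into `epoch_len`-second windows with the requested overlap;
#' step = `epoch_len * (1 - overlap)`, so the number of epochs is
#' `floor((180 - epoch_len) / step) + 1`.
#'
#' @param recording an [EEGRecording-class] of at least 180 s.
#' @param epoch_len epoch duration in seconds (default 10).
#' @param overlap fractional overlap of consecutive epochs: 0, 0.25,
#'   0.5 or 0.75.
#' @param analysis_len length of the centered analysis window (s).
#' @return list of epochs; each has `subject_id`, `epoch_index`,
#'   `start` (s, relative to recording onset), `fs` and `data`
#'   (channel x sample matrix).
#' @examples
#' rec <- EEGRecording("s1", matrix(rnorm(50 * 256 * 200), 50),
#'                     lateralChannels(), 256)
#' length(extractEpochs(rec))            # 18
#' length(extractEpochs(rec, overlap = 0.75))  # 69
#' @export
extractEpochs <- function(recording, epoch_len = 10,
                          overlap = c(0, 0.25, 0.5, 0.75),
                          analysis_len = 180) {
  stopifnot(is(recording, "EEGRecording"))
  overlap <- overlap[1]
  if (!overlap %in% c(0, 0.25, 0.5, 0.75))
    stop("overlap must be one of 0, 0.25, 0.5, 0.75")
  dur <- recordingDuration(recording)
  if (dur < analysis_len)
    stop(sprintf("recording is %.1f s; %.1f s required (%.1f s short)",
                 dur, analysis_len, analysis_len - dur))
  fs <- recording@fs
  start_s <- (dur - analysis_len) / 2
  step <- epoch_len * (1 - overlap)
  n_ep <- floor((analysis_len - epoch_len) / step) + 1L
  n_samp <- round(epoch_len * fs)
  lapply(seq_len(n_ep), function(i) {
    t0 <- start_s + (i - 1L) * step
    i0 <- round(t0 * fs)
    list(subject_id = recording@subject_id, epoch_index = i,
         start = t0, fs = fs,
         data = recording@data[, (i0 + 1L):(i0 + n_samp), drop = FALSE])
  })
}
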
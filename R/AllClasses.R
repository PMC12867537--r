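#' @import methods
#' @importFrom stats median quantile fft mvfft sd var cor IQR dist
#'   wilcox.test runif rnorm setNames hclust cutree as.dist
#' @importFrom utils read.csv write.csv write.table head combn
NULL

#' Multichannel resting-state EEG recording
#'
#' Container for one subject's artifact-free resting-state EEG: a channel
#' x sample matrix (microvolts) with ordered 10-10 channel labels, the
#' sampling rate, and the lesioned hemisphere. All lateral-ROI channels
#' of the standard 50-channel montage (see [roiLayout()]) must be present;
#' extra channels (e.g. midline Fz/Cz/Pz) are carried along but ignored
#' by every feature.
#'
#' @slot subject_id character scalar.
#' @slot fs sampling rate in Hz.
#' @slot channel_labels ordered 10-10 labels, one per data row.
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot lesion_side `"left"` or `"right"`.
#'
#' @seealso [EEGRecording()] constructor, [swapHemispheres()],
#'   [extractEpochs()]
#' @export
setClass("EEGRecording",
  representation(
    subject_id = "character",
    fs = "numeric",
    channel_labels = "character",
    data = "matrix",
    lesion_side = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@lesion_side) != 1 ||
      !object@lesion_side %in% c("left", "right"))
    msg <- c(msg, "lesion_side must be 'left' or 'right'")
  if (nrow(object@data) != length(object@channel_labels))
    msg <- c(msg, "data must have one row per channel label")
  if (anyDuplicated(object@channel_labels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@data) && !all(is.finite(object@data)))
    msg <- c(msg, "data contains non-finite samples")
  missing <- setdiff(lateralChannels(), object@channel_labels)
  if (length(missing))
    msg <- c(msg, paste0("missing required lateral channels: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param subject_id subject identifier.
#' @param data numeric matrix, channels x samples (microvolts).
#' @param channel_labels 10-10 labels, one per row of `data`; labels are
#'   normalized (whitespace stripped, canonical case) before validation.
#' @param fs sampling rate in Hz.
#' @param lesion_side `"left"` or `"right"` lesioned hemisphere.
#' @return a validated [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording("s1", matrix(rnorm(50 * 512), 50),
#'                     lateralChannels(), fs = 256, lesion_side = "right")
#' nChannels(rec)
#' @export
EEGRecording <- function(subject_id, data, channel_labels, fs,
                         lesion_side = c("right", "left")) {
  lesion_side <- match.arg(lesion_side)
  data <- as.matrix(data)
  labels <- normalizeLabels(channel_labels)
  rownames(data) <- labels
  new("EEGRecording", subject_id = as.character(subject_id), fs = fs,
      channel_labels = labels, data = data, lesion_side = lesion_side)
}

#' @describeIn EEGRecording-class number of channels
#' @param x,object an `EEGRecording`
#' @export
nChannels <- function(x) length(x@channel_labels)

#' @describeIn EEGRecording-class recording duration in seconds
#' @export
recordingDuration <- function(x) ncol(x@data) / x@fs

#' @describeIn EEGRecording-class channel labels
#' @export
channelLabels <- function(x) x@channel_labels

#' @describeIn EEGRecording-class sampling rate (Hz)
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EEGRecording-class lesioned hemisphere
#' @export
lesionSide <- function(x) x@lesion_side

#' @describeIn EEGRecording-class subject identifier
#' @export
subjectId <- function(x) x@subject_id

#' @describeIn EEGRecording-class channel x sample signal matrix
#' @export
eegData <- function(x) x@data

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording '", object@subject_id, "': ",
      nChannels(object), " channels x ", ncol(object@data), " samples (",
      round(recordingDuration(object), 1), " s at ", object@fs, " Hz), ",
      object@lesion_side, "-hemisphere lesion\n", sep = "")
})
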
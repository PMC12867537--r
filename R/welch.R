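# Welch averaged-periodogram machinery shared by the spectral and
# connectivity features: 2-s Hamming-tapered segments, no overlap,
# one-sided densities on a 0.5 Hz grid (0-128 Hz at fs = 256).

hammingWindow <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# segment a channel x sample matrix into seg_len-sample columns and
# return the tapered DFTs as an array [freq bin, segment, channel]
segmentDFT <- function(x, seg_len) {
  n_ch <- nrow(x)
  n_seg <- ncol(x) %/% seg_len
  w <- hammingWindow(seg_len)
  segs <- matrix(0, seg_len, n_seg * n_ch)
  for (ch in seq_len(n_ch)) {
    m <- matrix(x[ch, seq_len(n_seg * seg_len)], seg_len, n_seg)
    segs[, ((ch - 1) * n_seg + 1):(ch * n_seg)] <- m * w
  }
  Z <- mvfft(segs)
  n_bin <- seg_len %/% 2 + 1
  array(Z[seq_len(n_bin), ], dim = c(n_bin, n_seg, n_ch))
}

#' Welch power spectral density of one epoch
#'
#' Averaged periodogram over consecutive non-overlapping 2-s segments
#' with Hamming tapers; one-sided density in signal-units^2/Hz on a
#' `1/seg_len` Hz grid (0.5 Hz at the default 2-s segment).
#'
#' @param epoch one element of [extractEpochs()] (fields `data`, `fs`,
#'   ...); its duration must be an integer multiple of `seg_len`.
#' @param seg_len segment length in seconds.
#' @return list with `freqs` (bin centers, Hz), `psd` (channel x bin
#'   matrix, rows named by channel), and `welch_params`.
#' @examples
#' rec <- EEGRecording("s", matrix(rep(sin(2 * pi * 10 * (0:(256 * 200 - 1)) / 256),
#'                     each = 50), 50), lateralChannels(), 256)
#' p <- welchPSD(extractEpochs(rec)[[1]])
#' p$freqs[which.max(p$psd[1, ])]  # 10
#' @export
welchPSD <- function(epoch, seg_len = 2) {
  fs <- epoch$fs
  nseg_samp <- round(seg_len * fs)
  if (ncol(epoch$data) %% nseg_samp != 0)
    stop("epoch length (", ncol(epoch$data), " samples) is not a ",
         "multiple of the ", seg_len, " s segment length")
  Z <- segmentDFT(epoch$data, nseg_samp)
  w <- hammingWindow(nseg_samp)
  scale <- 1 / (fs * sum(w^2))
  n_bin <- dim(Z)[1]
  psd <- t(apply(Z, 3, function(z) rowMeans(Mod(z)^2))) * scale
  psd[, 2:(n_bin - 1)] <- 2 * psd[, 2:(n_bin - 1)]  # one-sided
  rownames(psd) <- rownames(epoch$data)
  list(freqs = (0:(n_bin - 1)) * fs / nseg_samp, psd = psd,
       welch_params = list(seg_len = seg_len, taper = "hamming",
                           overlap = 0))
}

# Welch cross-spectral matrix of a small set of signals; returns
# S[i, j, bin] with S[i, i, ] the (one-sided) auto-spectra.
welchCrossSpectra <- function(x, fs, seg_len = 2) {
  nseg_samp <- round(seg_len * fs)
  if (ncol(x) %% nseg_samp != 0)
    stop("signal length is not a multiple of the segment length")
  Z <- segmentDFT(x, nseg_samp)
  n_bin <- dim(Z)[1]; n_sig <- dim(Z)[3]
  S <- array(0 + 0i, dim = c(n_sig, n_sig, n_bin))
  for (i in seq_len(n_sig))
    for (j in i:n_sig) {
      s <- rowMeans(Z[, , i, drop = FALSE][, , 1] *
                    Conj(Z[, , j, drop = FALSE][, , 1]))
      S[i, j, ] <- s
      S[j, i, ] <- Conj(s)
    }
  list(freqs = (0:(n_bin - 1)) * fs / nseg_samp, S = S)
}

# trapezoid integral of a density sampled at freqs over [lo, hi]
trapzBand <- function(freqs, dens, lo, hi) {
  sel <- freqs >= lo & freqs <= hi
  f <- freqs[sel]; d <- dens[sel]
  if (length(f) < 2) return(0)
  sum(diff(f) * (head(d, -1) + d[-1]) / 2)
}

# indices of PSD bins belonging to a band: lower-closed, upper-open,
# except that a 48 Hz upper edge is closed (gamma / broadband cap)
bandBins <- function(freqs, band, closed_upper = band[2] >= 48) {
  if (closed_upper) which(freqs >= band[1] & freqs <= band[2])
  else which(freqs >= band[1] & freqs < band[2])
}
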
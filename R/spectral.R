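# The 141 spectral and brain-symmetry features: relative band powers,
# delta/alpha ratio (DAR), (delta+theta)/(alpha+beta) ratio (DTABR),
# pairwise-derived brain symmetry index (pdBSI) and its directional
# variant, and the individual alpha frequency (IAF).

scopeMeanPSD <- function(psd, scope) {
  if (identical(scope, "avg")) chans <- lateralChannels()
  else chans <- roiLayout()[[scope]]
  miss <- setdiff(chans, rownames(psd$psd))
  if (length(miss)) stop("scope '", scope, "' misses channel(s): ",
                         paste(miss, collapse = ", "))
  colMeans(psd$psd[chans, , drop = FALSE])
}

#' Relative band power of a scope-mean spectrum
#'
#' Trapezoid-integrated power of the scope-averaged PSD over a band,
#' normalized by the 1-48 Hz total. Because integration runs over
#' contiguous intervals, the five canonical bands tile 1-48 Hz exactly
#' and their relative powers sum to 1.
#'
#' @param psd a [welchPSD()] result.
#' @param scope `"avg"`, an ROI name (`FR, FL, CR, CL, OR, OL, F, C,
#'   O`), or a hemisphere (`AH`, `UH`).
#' @param band a band name from [bandSet()] or a `c(lo, hi)` Hz pair.
#' @return fraction in \[0, 1\].
#' @export
relativeBandPower <- function(psd, scope = "avg", band = "alpha") {
  if (is.character(band)) band <- bandSet()[[band]]
  dens <- scopeMeanPSD(psd, scope)
  total <- trapzBand(psd$freqs, dens, 1, 48)
  if (total <= 0) stop("degenerate epoch: zero total 1-48 Hz power in ",
                       "scope '", scope, "'")
  trapzBand(psd$freqs, dens, band[1], band[2]) / total
}

#' Delta/alpha ratio (DAR)
#'
#' @inheritParams relativeBandPower
#' @return relative delta power divided by relative alpha power.
#' @export
dar <- function(psd, scope = "avg") {
  a <- relativeBandPower(psd, scope, "alpha")
  if (a <= 0) stop("flagged epoch: zero alpha power in scope '", scope, "'")
  relativeBandPower(psd, scope, "delta") / a
}

#' (Delta + theta) / (alpha + beta) ratio (DTABR)
#'
#' @inheritParams relativeBandPower
#' @export
dtabr <- function(psd, scope = "avg") {
  den <- relativeBandPower(psd, scope, "alpha") +
    relativeBandPower(psd, scope, "beta")
  if (den <= 0) stop("flagged epoch: zero alpha+beta power in scope '",
                     scope, "'")
  (relativeBandPower(psd, scope, "delta") +
     relativeBandPower(psd, scope, "theta")) / den
}

# left/right summed PSD per bin for a symmetry scope
symmetryInput <- function(psd, scope, band) {
  lr <- switch(scope,
    F = c("FL", "FR"), C = c("CL", "CR"), O = c("OL", "OR"),
    avg = c("UH", "AH"),
    stop("symmetry scope must be one of F, C, O, avg"))
  layout <- roiLayout()
  bins <- bandBins(psd$freqs, if (is.character(band)) bandSet()[[band]]
                   else band)
  list(
    L = colSums(psd$psd[layout[[lr[1]]], bins, drop = FALSE]),
    R = colSums(psd$psd[layout[[lr[2]]], bins, drop = FALSE])
  )
}

#' Pairwise-derived brain symmetry index (pdBSI)
#'
#' Mean over band bins of `|L_n - R_n| / (L_n + R_n)`, where `L_n` and
#' `R_n` sum the PSD over the left (unaffected) and right (affected)
#' channel sets of the scope. Bins with zero bilateral power are
#' dropped (the bin count K is adjusted accordingly). The directional
#' variant omits the absolute value, so positive values mean
#' unaffected-hemisphere power excess.
#'
#' @inheritParams relativeBandPower
#' @param scope `"F"`, `"C"`, `"O"`, or `"avg"` (all 25 vs 25 lateral
#'   channels).
#' @param band one of the six bands (`broad` = 1-48 Hz whole spectrum).
#' @return pdBSI in \[0, 1\]; dirPdbsi in \[-1, 1\].
#' @export
pdbsi <- function(psd, scope = "avg", band = "broad") {
  s <- symmetryInput(psd, scope, band)
  .bsi(s$L, s$R, directional = FALSE)
}

#' @rdname pdbsi
#' @export
dirPdbsi <- function(psd, scope = "avg", band = "broad") {
  s <- symmetryInput(psd, scope, band)
  .bsi(s$L, s$R, directional = TRUE)
}

.bsi <- function(L, R, directional) {
  tot <- L + R
  keep <- tot > 0
  if (!any(keep)) stop("pdBSI undefined: zero power in every band bin")
  r <- (L[keep] - R[keep]) / tot[keep]
  if (directional) mean(r) else mean(abs(r))
}

#' Individual alpha frequency (IAF)
#'
#' Center-of-gravity frequency of the scope-mean PSD over the alpha
#' band (8-13 Hz, both edge bins included):
#' `sum(P_n * f_n) / sum(P_n)`.
#'
#' @inheritParams relativeBandPower
#' @return frequency in Hz, in \[8, 13\].
#' @export
iaf <- function(psd, scope = "avg") {
  dens <- scopeMeanPSD(psd, scope)
  bins <- which(psd$freqs >= 8 & psd$freqs <= 13)
  p <- dens[bins]
  if (sum(p) <= 0) stop("IAF undefined: zero alpha power in scope '",
                        scope, "'")
  sum(p * psd$freqs[bins]) / sum(p)
}

.RELPOW_SCOPES <- c("avg", "FR", "FL", "CR", "CL", "OR", "OL",
                    "F", "C", "O", "AH", "UH")
.DTABR_SCOPES <- c("avg", "FR", "FL", "CR", "CL", "OR", "OL", "AH", "UH")
.SYM_SCOPES <- c("F", "C", "O", "avg")
.SYM_BANDS <- c("broad", "delta", "theta", "alpha", "beta", "gamma")
.POW_BANDS <- c("delta", "theta", "alpha", "beta", "gamma")

#' Per-epoch spectral feature block (141 features)
#'
#' Computes, on one epoch's Welch PSD, the full spectral inventory:
#' 60 relative powers (5 bands x \{average, 9 ROIs, AH, UH\}), 12 DAR,
#' 9 DTABR (average, the six lateral ROIs, AH, UH), 24 pdBSI and 24
#' directional pdBSI (6 bands x \{F, C, O, average\}), and 12 IAF.
#' Names and order follow [featureRegistry()] and are stable across
#' calls.
#'
#' @param psd a [welchPSD()] result covering the 50-channel lateral
#'   montage.
#' @return named numeric vector of length 141.
#' @export
spectralBlock <- function(psd) {
  out <- numeric(0)
  for (scope in .RELPOW_SCOPES)
    for (band in .POW_BANDS)
      out[paste("relpow", band, scope, sep = "_")] <-
        relativeBandPower(psd, scope, band)
  for (scope in .RELPOW_SCOPES)
    out[paste("dar", scope, sep = "_")] <- dar(psd, scope)
  for (scope in .DTABR_SCOPES)
    out[paste("dtabr", scope, sep = "_")] <- dtabr(psd, scope)
  for (band in .SYM_BANDS)
    for (scope in .SYM_SCOPES)
      out[paste("pdbsi", band, scope, sep = "_")] <- pdbsi(psd, scope, band)
  for (band in .SYM_BANDS)
    for (scope in .SYM_SCOPES)
      out[paste("dirpdbsi", band, scope, sep = "_")] <-
        dirPdbsi(psd, scope, band)
  for (scope in .RELPOW_SCOPES)
    out[paste("iaf", scope, sep = "_")] <- iaf(psd, scope)
  out
}
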
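# Synthetic cohort generator: band-limited ROI oscillators with
# hemispheric asymmetries, 1/f background noise, lagged inter-ROI
# coupling (so imaginary coherency is nonzero where planted), and
# follow-up FMA-UE outcomes coupled to baseline score and, optionally,
# to an EEG feature. This is the test bed for every pipeline stage; no
# patient data are required.

#' Simulation configuration
#'
#' Defaults describe a plausible eyes-closed resting cohort:
#' narrowband stochastic rhythms (band-limited Gaussian noise,
#' alpha-dominant with delta/theta slowing), a 1/f background, a
#' within- and across-hemisphere lagged alpha coupling backbone, a
#' continuous subject-level hemispheric-asymmetry trait expressed over
#' the central ROIs, and a non-recoverer subgroup with doubled
#' affected-hemisphere delta. Follow-up scores follow either the
#' proportional recovery rule alone (`"prr_only"`) or the rule plus a
#' planted EEG effect (`"prr_plus_eeg"`) acting through the central
#' broadband directional pdBSI.
#'
#' @param n_subjects cohort size.
#' @param fs sampling rate (Hz).
#' @param duration_s recording length in seconds (>= 180).
#' @param seed cohort RNG seed.
#' @param band_amplitude per-band oscillator amplitudes (signal units).
#' @param noise_exponent 1/f^a background exponent.
#' @param noise_amplitude background noise scale.
#' @param couplings list of lagged couplings, each
#'   `list(from, to, band, lag, gain)` with lag in samples (> 0).
#' @param asym_sd standard deviation of the subject asymmetry trait
#'   (0 = mirror-symmetric hemispheres).
#' @param asym_gain log-amplitude change of the central ROIs per unit
#'   trait (left up, right/affected down).
#' @param norec_fraction fraction of subjects given the non-recoverer
#'   EEG profile.
#' @param norec_delta_scale affected-hemisphere delta amplitude
#'   multiplier in that profile.
#' @param mirror force mirror-symmetric hemispheres (left ROI sources
#'   copy the right ones; overrides the asymmetry trait).
#' @param outcome `"prr_plus_eeg"` or `"prr_only"`.
#' @param effect_size planted effect in FMA-UE points per standard
#'   deviation of the effect feature.
#' @param effect_feature feature carrying the planted effect.
#' @param outcome_noise_sd residual outcome noise (FMA-UE points).
#' @param fmaue_T0_range baseline scores are drawn from a
#'   severe/moderate mixture inside this range. The default stops at
#'   45 so that proportional recovery plus a +/-2 sigma planted effect
#'   stays inside the 0-66 scale: outcomes censored at the ceiling
#'   would erase the very signal the planted-effect experiments are
#'   meant to recover (the clinical cohorts handle this by excluding
#'   ceiling patients from testing).
#' @return config list.
#' @export
simConfig <- function(n_subjects = 20, fs = 256, duration_s = 184,
                      seed = 1L,
                      band_amplitude = c(delta = 6, theta = 4,
                                         alpha = 10, beta = 3,
                                         gamma = 1.2),
                      noise_exponent = 1, noise_amplitude = 4,
                      couplings = list(
                        list(from = "CR", to = "CL", band = "alpha",
                             lag = 6, gain = 0.8),
                        list(from = "FR", to = "CR", band = "alpha",
                             lag = 4, gain = 0.5),
                        list(from = "FL", to = "CL", band = "alpha",
                             lag = 4, gain = 0.5),
                        list(from = "OR", to = "CR", band = "alpha",
                             lag = 5, gain = 0.4),
                        list(from = "OL", to = "CL", band = "alpha",
                             lag = 5, gain = 0.4)),
                      asym_sd = 1, asym_gain = 0.3,
                      norec_fraction = 0.3, norec_delta_scale = 2,
                      mirror = FALSE,
                      outcome = c("prr_plus_eeg", "prr_only"),
                      effect_size = 10,
                      effect_feature = "dirpdbsi_broad_C",
                      outcome_noise_sd = 3,
                      fmaue_T0_range = c(0, 45)) {
  stopifnot(duration_s >= 180, n_subjects >= 1, fs > 0,
            all(band_amplitude >= 0),
            all(vapply(couplings, function(cp) cp$lag > 0, TRUE)))
  outcome <- match.arg(outcome)
  as.list(environment())
}

# 1/f^a noise of length n (FFT-filtered white noise), unit sd
pinkNoise <- function(n, exponent) {
  f <- c(1, seq_len(n %/% 2), rev(seq_len((n - 1) %/% 2)))
  z <- fft(rnorm(n)) * f^(-exponent / 2)
  x <- Re(fft(z, inverse = TRUE)) / n
  x / sd(x)
}

# narrowband stochastic oscillator: band-limited Gaussian noise at
# unit sd. A band-spanning rhythm (rather than a pure sinusoid) is
# what lets hemispheric *amplitude* asymmetries reach every band bin
# of the symmetry features, while independent draws stay incoherent
# across ROIs.
.bandOsc <- function(band, n, fs) {
  rng <- bandSet()[[band]]
  f <- c(0:(n %/% 2), -(((n - 1) %/% 2):1)) * fs / n
  z <- fft(rnorm(n))
  x <- Re(fft(z * (abs(f) >= rng[1] & abs(f) < rng[2]),
              inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Simulate a synthetic stroke cohort
#'
#' @param cfg a [simConfig()].
#' @return list with `cohort` (patient table plus `group`, `asym`
#'   trait and the realized planted feature `effect_value`),
#'   `recordings` (list of [EEGRecording-class]s), and `config`.
#'   Re-running with the same config is byte-identical.
#' @export
simulateCohort <- function(cfg = simConfig()) {
  withSeed(cfg$seed, {
    n_samp <- round(cfg$duration_s * cfg$fs)
    layout <- roiLayout()
    nodes <- c("FR", "FL", "CR", "CL", "OR", "OL")
    recs <- list(); rows <- list()
    for (si in seq_len(cfg$n_subjects)) {
      id <- sprintf("sim%02d", si)
      group <- if (runif(1) < cfg$norec_fraction) "NO-REC" else "REC"
      asym <- if (cfg$mirror) 0 else rnorm(1, 0, cfg$asym_sd)
      lesion <- sample(c("left", "right"), 1)
      # per-ROI band oscillators; the affected hemisphere is the
      # anatomical lesion side, later mapped to the right by the swap
      osc <- list()
      for (r in nodes)
        for (b in names(cfg$band_amplitude)) {
          amp <- cfg$band_amplitude[[b]]
          right_is_affected <- (lesion == "right")
          is_right <- grepl("R$", r)
          is_affected <- is_right == right_is_affected
          if (grepl("^C", r))
            amp <- amp * exp(if (is_affected) -cfg$asym_gain * asym
                             else cfg$asym_gain * asym)
          if (group == "NO-REC" && b == "delta" && is_affected)
            amp <- amp * cfg$norec_delta_scale
          osc[[paste(r, b)]] <-
            if (cfg$mirror && !is_right)
              osc[[paste(sub("L$", "R", r), b)]]
            else amp * .bandOsc(b, n_samp, cfg$fs)
        }
      src <- lapply(nodes, function(r)
        Reduce(`+`, osc[paste(r, names(cfg$band_amplitude))]))
      names(src) <- nodes
      for (cp in cfg$couplings) {
        lagged <- c(rep(0, cp$lag),
                    osc[[paste(cp$from, cp$band)]][1:(n_samp - cp$lag)])
        src[[cp$to]] <- src[[cp$to]] + cp$gain * lagged
      }
      chans <- lateralChannels()
      data <- matrix(0, length(chans), n_samp,
                     dimnames = list(chans, NULL))
      for (r in nodes)
        for (ch in layout[[r]])
          data[ch, ] <- src[[r]] +
            cfg$noise_amplitude * pinkNoise(n_samp, cfg$noise_exponent)
      recs[[id]] <- EEGRecording(id, data, chans, cfg$fs, lesion)
      lo <- cfg$fmaue_T0_range[1]; hi <- cfg$fmaue_T0_range[2]
      t0 <- if (runif(1) < 0.5)  # severe/moderate mixture
        sample(lo:min(lo + 15, hi), 1)
      else
        sample(max(hi - 15, lo):hi, 1)
      rows[[id]] <- data.frame(
        subject_id = id, sex = sample(c("M", "F"), 1),
        age = sample(45:82, 1),
        affected_hemisphere = if (lesion == "left") "L" else "R",
        days_T0 = sample(2:30, 1), days_T1 = 0, fmaue_T0 = t0,
        fmaue_T1 = NA_real_, group = group, asym = asym,
        stringsAsFactors = FALSE)
      rows[[id]]$days_T1 <- rows[[id]]$days_T0 + sample(80:110, 1)
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    # realized planted feature, measured the way the pipeline will
    feat <- vapply(recs, function(r) {
      eps <- extractEpochs(swapHemispheres(r))
      mean(vapply(eps, function(ep) {
        psd <- welchPSD(ep)
        parts <- strsplit(cfg$effect_feature, "_")[[1]]
        switch(parts[1],
               dirpdbsi = dirPdbsi(psd, parts[3], parts[2]),
               pdbsi = pdbsi(psd, parts[3], parts[2]),
               stop("unsupported effect feature"))
      }, 0))
    }, 0)
    cohort$effect_value <- as.numeric(feat)
    z <- if (length(feat) > 1 && sd(feat) > 0)
      (feat - mean(feat)) / sd(feat) else feat * 0
    delta <- prrPredict(cohort$fmaue_T0) +
      rnorm(cfg$n_subjects, 0, cfg$outcome_noise_sd) +
      if (cfg$outcome == "prr_plus_eeg") cfg$effect_size * z else 0
    cohort$fmaue_T1 <- round(pmin(pmax(cohort$fmaue_T0 + delta, 0), 66))
    list(cohort = cohort, recordings = recs, config = cfg)
  })
}

#' Feature tables of a simulated cohort
#'
#' Convenience wrapper: extracts and binds [extractFeatures()] tables
#' for every subject of a [simulateCohort()] result, per overlap.
#'
#' @param sim a [simulateCohort()] result.
#' @param overlaps overlap fractions to extract.
#' @param seed seed for the connectivity surrogate ensemble.
#' @return named list of cohort `SummarizedExperiment`s keyed by
#'   overlap (as character), ready for [nestedLoso()].
#' @export
simulatedFeatureTables <- function(sim, overlaps = 0, seed = 1L) {
  out <- lapply(overlaps, function(o) {
    tabs <- lapply(seq_along(sim$recordings), function(i) {
      extractFeatures(sim$recordings[[i]],
                      patient = sim$cohort[i, , drop = FALSE],
                      overlap = o, seed = seed)
    })
    bindFeatureTables(tabs)
  })
  names(out) <- as.character(overlaps)
  out
}
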
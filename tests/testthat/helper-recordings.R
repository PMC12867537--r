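# Small recordings built in code for the unit tests. Everything is
# seeded; the heavier shared objects are built once per test run.

# a recording whose 50 lateral channels all carry the given
# per-channel signals (list or matrix), default white noise
makeRecording <- function(signals = NULL, duration_s = 180, fs = 256,
                          lesion = "right", seed = 1,
                          subject_id = "tst") {
  n <- round(duration_s * fs)
  chans <- lateralChannels()
  if (is.null(signals)) {
    set.seed(seed)
    signals <- matrix(rnorm(length(chans) * n), length(chans), n)
  }
  EEGRecording(subject_id, signals, chans, fs, lesion)
}

# recording with one sinusoid on every channel (same phase everywhere)
sineRecording <- function(freq = 10, duration_s = 180, fs = 256,
                          amp = 1, noise = 0, lesion = "right",
                          seed = 1) {
  n <- round(duration_s * fs)
  base <- amp * sin(2 * pi * freq * (0:(n - 1)) / fs)
  set.seed(seed)
  sig <- t(matrix(base, n, 50)) + if (noise > 0)
    matrix(rnorm(50 * n, 0, noise), 50, n) else 0
  makeRecording(sig, duration_s, fs, lesion, seed)
}

firstEpoch <- function(rec, overlap = 0)
  extractEpochs(rec, overlap = overlap)[[1]]

# shared small simulated cohort (3 subjects) for structural tests
sharedSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCohort(simConfig(n_subjects = 3, seed = 500))
    cache
  }
})

sharedFeatures <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulatedFeatureTables(sharedSim(), overlaps = 0)
    cache
  }
})
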
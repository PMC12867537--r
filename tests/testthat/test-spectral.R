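test_that("Welch PSD matches a direct-DFT oracle and basic line spectra", {
  rec <- sineRecording(freq = 10, duration_s = 180)
  ep <- firstEpoch(rec)
  p <- welchPSD(ep)
  expect_equal(diff(p$freqs[1:2]), 0.5)
  expect_true(all(p$psd >= 0))
  expect_equal(p$freqs[which.max(p$psd[1, ])], 10)

  # oracle: direct DFT periodogram of one noisy channel
  set.seed(3)
  x <- rnorm(2560)
  epx <- ep
  epx$data <- matrix(rep(x, each = 2), 2, 2560)
  rownames(epx$data) <- c("C3", "C4")
  ref <- bfWelchPSD(x, 256)
  got <- welchPSD(epx)
  expect_equal(got$psd[1, ], ref$psd, tolerance = 1e-8,
               ignore_attr = TRUE)

  # DC epoch: no power in 1-48 Hz
  epdc <- ep
  epdc$data <- matrix(5, 50, 2560,
                      dimnames = list(lateralChannels(), NULL))
  pdc <- welchPSD(epdc)
  sel <- pdc$freqs >= 1 & pdc$freqs <= 48
  # only Hamming sidelobe leakage remains in-band, vanishing relative
  # to the DC line
  expect_lt(sum(pdc$psd[, sel]) / sum(pdc$psd), 1e-5)

  # white noise at two seeds: comparable total power
  tot <- sapply(c(11, 12), function(s) {
    set.seed(s)
    e <- ep
    e$data <- matrix(rnorm(50 * 2560), 50, 2560,
                     dimnames = list(lateralChannels(), NULL))
    pw <- welchPSD(e)
    sum(pw$psd[, pw$freqs >= 1 & pw$freqs <= 48])
  })
  expect_lt(max(tot) / min(tot), 3)

  epbad <- ep
  epbad$data <- ep$data[, 1:2000]
  expect_error(welchPSD(epbad), "multiple")
})

test_that("relative band power behaves on line and flat spectra", {
  ep <- firstEpoch(sineRecording(freq = 10))
  psd <- welchPSD(ep)
  expect_gt(relativeBandPower(psd, "avg", "alpha"), 0.95)
  expect_lt(relativeBandPower(psd, "avg", "delta"), 0.05)

  # synthetic flat spectrum on 1-48: alpha fraction = 5/47
  flat <- psd
  flat$psd <- matrix(1, 50, length(psd$freqs),
                     dimnames = list(lateralChannels(), NULL))
  expect_equal(relativeBandPower(flat, "avg", "alpha"), 5 / 47)

  # five bands partition the 1-48 Hz power exactly, any scope
  ep2 <- firstEpoch(makeRecording(seed = 21))
  p2 <- welchPSD(ep2)
  for (scope in c("avg", "CR", "F", "AH"))
    expect_equal(sum(sapply(c("delta", "theta", "alpha", "beta",
                              "gamma"),
                            function(b) relativeBandPower(p2, scope, b))),
                 1, tolerance = 1e-9)
})

test_that("DAR and DTABR follow their defining ratios", {
  ep <- firstEpoch(makeRecording(seed = 4))
  psd <- welchPSD(ep)
  for (scope in c("avg", "CL", "AH")) {
    expect_equal(dar(psd, scope),
                 relativeBandPower(psd, scope, "delta") /
                   relativeBandPower(psd, scope, "alpha"))
    expect_equal(dtabr(psd, scope),
                 (relativeBandPower(psd, scope, "delta") +
                    relativeBandPower(psd, scope, "theta")) /
                   (relativeBandPower(psd, scope, "alpha") +
                      relativeBandPower(psd, scope, "beta")))
  }
  # flat spectrum: DTABR = (3+4)/(5+17)
  flat <- psd
  flat$psd <- matrix(1, 50, length(psd$freqs),
                     dimnames = list(lateralChannels(), NULL))
  expect_equal(dar(flat, "avg"), 3 / 5)
  expect_equal(dtabr(flat, "avg"), 7 / 22)
  # delta-only signal: only taper leakage is left in alpha, so the
  # ratio explodes; an exactly-zero denominator errors (DC case below)
  epd <- firstEpoch(sineRecording(freq = 2))
  expect_gt(dar(welchPSD(epd), "avg"), 100)
  dc <- psd
  dc$psd <- matrix(0, 50, length(psd$freqs),
                   dimnames = list(lateralChannels(), NULL))
  dc$psd[, psd$freqs == 2] <- 1
  expect_error(dar(dc, "avg"), "zero alpha")
})

test_that("pdBSI and directional pdBSI obey definition, sign and invariances", {
  ep <- firstEpoch(makeRecording(seed = 8))
  psd <- welchPSD(ep)
  # hand-built symmetric case: L = R
  sym <- psd
  layout <- roiLayout()
  sym$psd[layout$UH, ] <- sym$psd[layout$AH, ]
  expect_equal(pdbsi(sym, "avg", "broad"), 0, tolerance = 1e-12)
  expect_equal(dirPdbsi(sym, "C", "alpha"), 0, tolerance = 1e-12)
  # L = 3R: pdBSI 0.5, directional +0.5 (unaffected excess positive)
  tri <- sym
  tri$psd[layout$UH, ] <- 3 * tri$psd[layout$AH, ]
  expect_equal(pdbsi(tri, "avg", "broad"), 0.5)
  expect_equal(dirPdbsi(tri, "avg", "broad"), 0.5)
  # R = 3L: affected-side excess gives the negative sign
  tri$psd[layout$UH, ] <- tri$psd[layout$AH, ] / 3
  expect_equal(dirPdbsi(tri, "avg", "broad"), -0.5)

  for (scope in c("F", "C", "O", "avg")) {
    p1 <- pdbsi(psd, scope, "alpha")
    d1 <- dirPdbsi(psd, scope, "alpha")
    expect_gte(p1, 0); expect_lte(p1, 1)
    expect_lte(abs(d1), p1)
    # scale invariance
    sc <- psd; sc$psd <- sc$psd * 7.3
    expect_equal(pdbsi(sc, scope, "alpha"), p1)
    expect_equal(dirPdbsi(sc, scope, "alpha"), d1)
    # hemisphere exchange flips the directional sign only
    sw <- psd
    sw$psd[c(layout$UH, layout$AH), ] <- psd$psd[c(layout$AH,
                                                   layout$UH), ]
    expect_equal(dirPdbsi(sw, scope, "alpha"), -d1)
    expect_equal(pdbsi(sw, scope, "alpha"), p1)
  }
})

test_that("IAF is the alpha-band spectral centroid", {
  psd <- welchPSD(firstEpoch(sineRecording(freq = 10)))
  expect_equal(iaf(psd, "avg"), 10, tolerance = 0.01)
  flat <- psd
  flat$psd <- matrix(1, 50, length(psd$freqs),
                     dimnames = list(lateralChannels(), NULL))
  expect_equal(iaf(flat, "avg"), 10.5)
  # two equal lines at the band edges average to the midpoint
  two <- flat
  two$psd[] <- 0
  two$psd[, flat$freqs %in% c(8, 13)] <- 1
  expect_equal(iaf(two, "avg"), 10.5)
  # property: always inside [8, 13]
  for (s in 1:3) {
    p <- welchPSD(firstEpoch(makeRecording(seed = s)))
    v <- iaf(p, "CR")
    expect_gte(v, 8); expect_lte(v, 13)
  }
})

test_that("spectral block emits exactly the 141 registered features", {
  psd <- welchPSD(firstEpoch(makeRecording(seed = 13)))
  blk <- spectralBlock(psd)
  expect_length(blk, 141)
  expect_false(anyDuplicated(names(blk)) > 0)
  reg <- featureRegistry()
  expect_identical(names(blk),
                   reg$name[reg$domain %in% c("spectral",
                                              "brain_symmetry")])
  expect_true(all(is.finite(blk)))
  # order-stable across calls
  expect_identical(names(spectralBlock(psd)), names(blk))
  # mirrored hemispheres: all 24 pdBSI near zero
  layout <- roiLayout()
  sym <- psd
  sym$psd[layout$UH, ] <- sym$psd[layout$AH, ]
  bsym <- spectralBlock(sym)
  expect_lt(max(abs(bsym[grep("^pdbsi_", names(bsym))])), 1e-12)
})
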
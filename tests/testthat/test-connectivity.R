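test_that("ROI signals are member-channel means with linearity", {
  ep <- firstEpoch(makeRecording(seed = 2, duration_s = 180))
  rs <- roiSignals(ep)
  expect_identical(rownames(rs), c("FR", "FL", "CR", "CL", "OR", "OL"))
  expect_equal(rs["CR", ],
               colMeans(ep$data[roiLayout()$CR, ]))
  # identical channels reproduce the channel; x and -x cancel
  ep2 <- ep
  ep2$data[roiLayout()$FR, ] <-
    matrix(ep$data[1, ], 7, ncol(ep$data), byrow = TRUE)
  expect_equal(roiSignals(ep2)["FR", ], ep$data[1, ],
               ignore_attr = TRUE)
  # linearity
  epa <- ep; epb <- ep
  epb$data <- 2 * ep$data
  eps <- ep; eps$data <- epa$data + epb$data
  expect_equal(roiSignals(eps), roiSignals(epa) + roiSignals(epb))
})

test_that("imaginary coherency suppresses zero-lag and detects quadrature coupling", {
  n <- 2560; fs <- 256
  t <- (0:(n - 1)) / fs
  chans <- lateralChannels()
  layout <- roiLayout()
  set.seed(77)
  base <- matrix(rnorm(50 * n, 0, 1), 50, n,
                 dimnames = list(chans, NULL))
  # FR and FL perfectly identical signals: zero-lag, weight ~ 0
  shared <- rnorm(n)
  base[layout$FR, ] <- matrix(shared, 7, n, byrow = TRUE)
  base[layout$FL, ] <- matrix(shared, 7, n, byrow = TRUE)
  # CR carries alpha-band noise, CL its quadrature (90-degree shifted)
  # copy built by rotating every positive-frequency component
  spec <- fft(rnorm(n))
  keep <- rep(0, n)
  fgrid <- c(0:(n / 2), -((n / 2 - 1):1)) * fs / n
  keep[abs(fgrid) >= 8 & abs(fgrid) <= 13] <- 1
  s1 <- Re(fft(spec * keep, inverse = TRUE)) / n
  rot <- complex(argument = -pi / 2 * sign(fgrid))
  s2 <- Re(fft(spec * keep * rot, inverse = TRUE)) / n
  s1 <- s1 / sd(s1); s2 <- s2 / sd(s2)
  base[layout$CR, ] <- base[layout$CR, ] * 0.02 +
    matrix(s1, 11, n, byrow = TRUE)
  base[layout$CL, ] <- base[layout$CL, ] * 0.02 +
    matrix(s2, 11, n, byrow = TRUE)
  ep <- list(subject_id = "x", epoch_index = 1L, start = 0, fs = fs,
             data = base)
  cm <- imagCoherency(ep)
  expect_lt(cm$alpha["FR", "FL"], 0.05)
  expect_gt(cm$alpha["CR", "CL"], 0.9)
  # independent-noise pairs stay small at 5 Welch segments
  expect_lt(cm$alpha["OR", "OL"], 0.3)
  # structure: symmetric, zero diagonal, weights in [0, 1]
  for (b in names(cm)) {
    expect_equal(cm[[b]], t(cm[[b]]))
    expect_equal(diag(cm[[b]]), setNames(rep(0, 6), rownames(cm[[b]])))
    expect_true(all(cm[[b]] >= 0 & cm[[b]] <= 1))
  }
  # normalization: common rescaling of the signals changes nothing
  eps <- ep; eps$data <- ep$data * 3.7
  expect_equal(imagCoherency(eps)$alpha, cm$alpha, tolerance = 1e-9)
})

test_that("proportional-threshold pruning matches exhaustive search", {
  nodes <- c("FR", "FL", "CR", "CL", "OR", "OL")
  # star: hub strong to all, the rest zero
  star <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  star[1, 2:6] <- star[2:6, 1] <- 0.8
  g <- pruneGraph(star)
  expect_equal(sum(g$adjacency > 0) / 2, 5)
  expect_false(g$fallback)
  # equal weights: ties retained, p* = 99
  eq <- matrix(0.4, 6, 6, dimnames = list(nodes, nodes)); diag(eq) <- 0
  geq <- pruneGraph(eq)
  expect_equal(geq$percentile, 99)
  expect_equal(sum(geq$adjacency > 0) / 2, 15)
  # random matrices: p* agrees with brute-force threshold enumeration
  set.seed(31)
  for (i in 1:20) {
    w <- randomConnectedGraph()
    got <- pruneGraph(w)
    uw <- w[upper.tri(w)]
    bf <- NA
    for (p in seq(99, 0, by = -1)) {
      thr <- quantile(uw, p / 100, type = 7, names = FALSE)
      adj <- w * (w >= thr); diag(adj) <- 0
      if (all(is.finite(bfDistances(adj)))) { bf <- p; break }
    }
    expect_equal(got$percentile, bf)
    expect_true(all(is.finite(bfDistances(got$adjacency))))
  }
})

test_that("global graph metrics match brute-force references", {
  nodes <- c("FR", "FL", "CR", "CL", "OR", "OL")
  # complete unit-weight graph
  cg <- matrix(1, 6, 6, dimnames = list(nodes, nodes)); diag(cg) <- 0
  m <- graphMetrics(list(adjacency = cg), seed = 1)
  expect_equal(m$degree, 5)
  expect_equal(m$strength, 5)
  expect_equal(m$pathlen, 1)
  expect_equal(m$clustering, 1)
  # equal strengths: nobody exceeds the 75th percentile, rich club 0
  expect_equal(m$richclub, 0)
  # random graphs: path length and clustering vs oracles
  set.seed(55)
  for (i in 1:15) {
    w <- randomConnectedGraph()
    g <- list(adjacency = w)
    got <- graphMetrics(g, seed = i)
    d <- bfDistances(w)
    expect_equal(got$pathlen, mean(d[upper.tri(d)]), tolerance = 1e-10)
    expect_equal(got$clustering, mean(bfOnnela(w)), tolerance = 1e-10)
    expect_equal(got$degree, mean(rowSums(w > 0)))
    expect_equal(got$strength, mean(rowSums(w)))
    # rich club by direct construction
    str <- rowSums(w)
    rich <- str > quantile(str, 0.75, type = 7)
    rc <- mean(sapply(1:6, function(i2)
      sum(w[i2, rich] > 0) / str[i2]))
    expect_equal(got$richclub, rc)
  }
  expect_error(graphMetrics(list(adjacency = diag(0, 6))), "connected")
})

test_that("shortest distances agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(66)
  for (i in 1:10) {
    w <- randomConnectedGraph()
    gr <- igraph::graph_from_adjacency_matrix(
      ifelse(w > 0, 1 / w, 0), mode = "undirected", weighted = TRUE)
    expect_equal(unname(StrokeRecovNet:::shortestDistances(w)),
                 unname(igraph::distances(gr)), tolerance = 1e-10)
  }
})

test_that("omega separates lattice-like from randomized arrangements", {
  # same weight multiset and degree sequence, arranged (a) as the
  # ring lattice (its own lattice surrogate, so C_w/C_l = 1) and (b)
  # shuffled by degree-preserving rewiring (C_w drops, C_l is a
  # function of the weight multiset alone): omega must be lower for
  # the lattice-ordered arrangement
  nodes <- c("FR", "FL", "CR", "CL", "OR", "OL")
  base <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  w <- seq(0.2, 1, length.out = 12)
  k <- 0
  for (i in 1:6) for (d in 1:2) {
    j <- ((i + d - 1) %% 6) + 1
    k <- k + 1
    base[i, j] <- base[j, i] <- w[k]
  }
  lat <- StrokeRecovNet:::latticeSurrogate(base)
  dimnames(lat) <- dimnames(base)
  m_lat <- graphMetrics(list(adjacency = lat), seed = 3)
  # the lattice-ordered arrangement is its own lattice surrogate:
  # clustering ratio 1, omega pinned near 0 (Lr/Lw - 1)
  ls <- StrokeRecovNet:::latticeSurrogate(lat)
  expect_equal(sort(ls[upper.tri(ls)]), sort(lat[upper.tri(lat)]))
  expect_lt(abs(m_lat$omega), 0.15)
  # a triangle-free hub graph sits at the opposite, random-like end:
  # clustering ratio 0 and (no rewirable pair) Lr = Lw, so omega = 1
  star <- matrix(0, 6, 6, dimnames = dimnames(base))
  star[1, 2:6] <- star[2:6, 1] <- 0.7
  m_star <- graphMetrics(list(adjacency = star), seed = 3)
  expect_equal(m_star$omega, 1)
  expect_lt(m_lat$omega, m_star$omega)
  # omega recomposes from independently recomputed components
  d <- bfDistances(lat)
  Lw <- mean(d[upper.tri(d)])
  Cw <- mean(bfOnnela(lat))
  Cl <- mean(bfOnnela(ls))
  Lr <- StrokeRecovNet:::withSeed(3, mean(sapply(1:10, function(i) {
    dr <- bfDistances(StrokeRecovNet:::rewireGraph(lat))
    mean(dr[upper.tri(dr)])
  })))
  expect_equal(m_lat$omega, Lr / Lw - Cw / Cl, tolerance = 1e-10)
})

test_that("nodal metrics match hand computation on structured graphs", {
  nodes <- c("FR", "FL", "CR", "CL", "OR", "OL")
  # star centered on CR: leaves have clustering and local efficiency 0
  star <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  star[3, -3] <- star[-3, 3] <- 1
  leaf <- nodalMetrics(list(adjacency = star), "CL")
  expect_equal(leaf$degree, 1)
  expect_equal(leaf$clustering, 0)
  expect_equal(leaf$localeff, 0)
  # unit triangle CR-CL-FR embedded in a connected graph
  tri <- star
  tri["CL", "FR"] <- tri["FR", "CL"] <- 1
  tri["CR", "CL"] <- tri["CL", "CR"] <- 1
  nm <- nodalMetrics(list(adjacency = tri), "CL")
  expect_equal(nm$clustering, 1)
  # path graph FR-FL-CR chain: nodal path lengths by hand (Dijkstra)
  path <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  d <- bfDistances(path)
  expect_equal(d[1, 3], 2)
  # random graphs: all five nodal metrics vs brute force
  set.seed(91)
  for (i in 1:10) {
    w <- randomConnectedGraph()
    for (node in c("CR", "CL")) {
      got <- nodalMetrics(list(adjacency = w), node)
      ni <- match(node, nodes)
      dref <- bfDistances(w)
      expect_equal(got$pathlen, mean(dref[ni, -ni]), tolerance = 1e-10)
      expect_equal(got$clustering, bfOnnela(w)[ni], tolerance = 1e-10)
      expect_equal(got$degree, sum(w[ni, ] > 0))
      expect_equal(got$strength, sum(w[ni, ]))
      nb <- which(w[ni, ] > 0)
      eff <- 0
      if (length(nb) >= 2) {
        ds <- bfDistances(w[nb, nb, drop = FALSE])
        iv <- 1 / ds[upper.tri(ds)]
        eff <- mean(ifelse(is.finite(iv), iv, 0))
      }
      expect_equal(got$localeff, eff, tolerance = 1e-10)
    }
  }
})

test_that("connectivity block: 80 features, swap symmetry, determinism", {
  sim <- sharedSim()
  rec <- sim$recordings[[1]]
  ep <- firstEpoch(swapHemispheres(rec))
  blk <- connectivityBlock(ep, seed = 5)
  expect_length(blk, 80)
  expect_true(all(is.finite(blk)))
  reg <- featureRegistry()
  expect_identical(names(blk),
                   reg$name[reg$domain %in% c("network",
                                              "node_connectivity")])
  # same seed, same omega
  expect_identical(connectivityBlock(ep, seed = 5), blk)
  # force-swapped epoch exchanges affected/unaffected nodal features
  eps <- firstEpoch(swapHemispheres(swapHemispheres(rec),
                                    force = TRUE))
  blks <- connectivityBlock(eps, seed = 5)
  for (m in c("degree", "strength", "pathlen", "clustering",
              "localeff")) {
    expect_equal(blks[paste0("node_", m, "_AH_alpha")],
                 blk[paste0("node_", m, "_UH_alpha")],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(blks[paste0("node_", m, "_UH_alpha")],
                 blk[paste0("node_", m, "_AH_alpha")],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})
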
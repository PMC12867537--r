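# Functional connectivity among the six lateral ROIs: imaginary part of
# the coherency (insensitive to zero-lag/volume-conducted coupling),
# proportional-threshold pruning to the sparsest connected graph, and
# weighted graph metrics in Brain Connectivity Toolbox conventions
# (path length on 1/w distances, Onnela clustering, small-world omega,
# rich club, local efficiency).

.NET_NODES <- c("FR", "FL", "CR", "CL", "OR", "OL")

#' ROI-average time series of one epoch
#'
#' Each of the six lateral ROI signals is the plain mean of its member
#' channels' time series.
#'
#' @param epoch one element of [extractEpochs()].
#' @return 6 x sample matrix with rows `FR, FL, CR, CL, OR, OL`.
#' @export
roiSignals <- function(epoch) {
  layout <- roiLayout()
  out <- t(vapply(.NET_NODES, function(r) {
    chans <- layout[[r]]
    miss <- setdiff(chans, rownames(epoch$data))
    if (length(miss)) stop("ROI ", r, " misses channel(s): ",
                           paste(miss, collapse = ", "))
    colMeans(epoch$data[chans, , drop = FALSE])
  }, numeric(ncol(epoch$data))))
  rownames(out) <- .NET_NODES
  out
}

#' Band-wise imaginary-coherency connectivity matrices
#'
#' Coherency between ROI signals i and j is
#' `S_ij(f) / sqrt(S_ii(f) S_jj(f))` from Welch cross-spectra (2-s
#' Hamming segments, no overlap); the edge weight per band is the mean
#' over band bins of the *rectified* imaginary part, giving symmetric
#' nonnegative weights in \[0, 1\] with zero diagonal. Identical
#' (zero-lag) signals yield weight 0.
#'
#' @param epoch one element of [extractEpochs()].
#' @return named list (delta...gamma) of 6 x 6 symmetric weight
#'   matrices over nodes `FR, FL, CR, CL, OR, OL`.
#' @export
imagCoherency <- function(epoch) {
  x <- roiSignals(epoch)
  cs <- welchCrossSpectra(x, epoch$fs)
  n <- nrow(x)
  auto <- t(vapply(seq_len(n), function(i) Re(cs$S[i, i, ]),
                   numeric(length(cs$freqs))))
  bands <- bandSet()[.POW_BANDS]
  out <- lapply(bands, function(band) {
    bins <- bandBins(cs$freqs, band)
    if (any(auto[, bins] <= 0))
      stop("zero auto-spectrum in band bins; coherency undefined")
    w <- matrix(0, n, n, dimnames = list(.NET_NODES, .NET_NODES))
    for (i in seq_len(n - 1))
      for (j in (i + 1):n) {
        coh <- cs$S[i, j, bins] / sqrt(auto[i, bins] * auto[j, bins])
        w[i, j] <- w[j, i] <- mean(abs(Im(coh)))
      }
    w
  })
  names(out) <- names(bands)
  out
}

#' Prune a connectivity matrix with a proportional threshold
#'
#' Scans percentiles 99, 98, ..., 0 of the 15 off-diagonal weights
#' (linear-interpolation quantiles); at each step edges with weight >=
#' the percentile are retained (ties kept), and the first — i.e.
#' largest — percentile whose graph is connected over all six nodes is
#' returned. If no threshold connects the graph (zero-weight patterns),
#' the full graph at p = 0 is returned with `fallback = TRUE`.
#'
#' @param w 6 x 6 symmetric nonnegative weight matrix.
#' @return list with `adjacency` (pruned weights), `percentile` (p*),
#'   and `fallback`.
#' @export
pruneGraph <- function(w) {
  uw <- w[upper.tri(w)]
  thrs <- quantile(uw, seq(99, 0, by = -1) / 100, type = 7,
                   names = FALSE)
  for (k in seq_along(thrs)) {
    adj <- w * (w >= thrs[k])
    diag(adj) <- 0
    if (isConnectedGraph(adj))
      return(list(adjacency = adj, percentile = 100 - k,
                  fallback = FALSE))
  }
  adj <- w; diag(adj) <- 0
  warning("no proportional threshold keeps the graph connected; ",
          "falling back to the full graph")
  list(adjacency = adj, percentile = 0, fallback = TRUE)
}

isConnectedGraph <- function(adj) {
  # reachability by repeated squaring of (A + I); n is tiny
  m <- (adj > 0) + diag(nrow(adj))
  m <- m %*% m          # <= 2 hops
  m <- m %*% m          # <= 4 hops
  m <- m %*% m          # <= 8 hops
  all(m[1, ] > 0)
}

# all-pairs shortest path distances with edge length 1/w (absent edge =
# Inf), by Floyd-Warshall; tiny n so plain loops are fine
shortestDistances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1 / adj, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Onnela weighted clustering coefficient per node: geometric mean of
# triangle weights normalized by the maximum weight in the graph
onnelaClustering <- function(adj) {
  mx <- max(adj)
  if (mx <= 0) return(rep(0, nrow(adj)))
  w3 <- (adj / mx)^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(adj > 0)
  out <- ifelse(k > 1, num / (k * (k - 1)), 0)
  unname(out)
}

# degree-preserving randomization: Maslov-Sneppen double edge swaps
# (weights follow their edges); each swap that would disconnect the
# graph is reverted, so the surrogate is always connected. Two swaps
# per edge suffice to mix a six-node graph; sparse pruned graphs
# (trees) may admit few or no valid swaps.
rewireGraph <- function(adj, swaps_per_edge = 2) {
  m <- adj
  el <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  E <- nrow(el)
  if (E < 2) return(m)
  n_swaps <- swaps_per_edge * E
  done <- 0
  r2 <- runif(5 * n_swaps)  # one draw per attempt, pre-drawn
  for (attempt in seq_len(5 * n_swaps)) {
    if (done >= n_swaps) break
    pick <- sample.int(E, 2)
    i <- el[pick[1], 1]; j <- el[pick[1], 2]
    k <- el[pick[2], 1]; l <- el[pick[2], 2]
    if (r2[attempt] < 0.5) { tmp <- k; k <- l; l <- tmp }
    if (i == k || i == l || j == k || j == l) next
    if (m[i, l] > 0 || m[k, j] > 0) next
    wi <- m[i, j]; wk <- m[k, l]
    m[i, j] <- m[j, i] <- 0; m[k, l] <- m[l, k] <- 0
    m[i, l] <- m[l, i] <- wi; m[k, j] <- m[j, k] <- wk
    if (!isConnectedGraph(m)) {  # revert
      m[i, l] <- m[l, i] <- 0; m[k, j] <- m[j, k] <- 0
      m[i, j] <- m[j, i] <- wi; m[k, l] <- m[l, k] <- wk
      next
    }
    el[pick[1], ] <- c(min(i, l), max(i, l))
    el[pick[2], ] <- c(min(k, j), max(k, j))
    done <- done + 1
  }
  m
}

# deterministic weight-preserving ring-lattice surrogate: strongest
# weights on the shortest ring chords
latticeSurrogate <- function(adj) {
  n <- nrow(adj)
  w <- sort(adj[upper.tri(adj)][adj[upper.tri(adj)] > 0],
            decreasing = TRUE)
  pos <- which(upper.tri(adj), arr.ind = TRUE)
  ring <- pmin(abs(pos[, 1] - pos[, 2]), n - abs(pos[, 1] - pos[, 2]))
  ord <- order(ring, pos[, 1], pos[, 2])
  m <- matrix(0, n, n)
  for (e in seq_along(w)) {
    i <- pos[ord[e], 1]; j <- pos[ord[e], 2]
    m[i, j] <- m[j, i] <- w[e]
  }
  m
}

#' Global weighted graph metrics of a pruned connectivity graph
#'
#' Computes, on the six-node pruned graph: mean node degree and
#' strength, weighted characteristic path length `L_w` (mean shortest
#' 1/w-distance over node pairs), mean Onnela weighted clustering
#' `C_w`, the small-world omega `L_r / L_w - C_w / C_l` (with `L_r`
#' averaged over seeded degree-preserving rewirings and `C_l` from a
#' deterministic weight-preserving ring lattice), and the rich-club
#' coefficient (per node, edges to nodes whose strength exceeds the
#' 75th strength percentile, divided by the node's own strength;
#' averaged over nodes).
#'
#' @param g a [pruneGraph()] result (the graph must be connected).
#' @param n_random number of rewired surrogates for `L_r`.
#' @param seed RNG seed for the surrogate ensemble.
#' @return named list: `degree`, `strength`, `pathlen`, `clustering`,
#'   `omega`, `richclub`.
#' @export
graphMetrics <- function(g, n_random = 10, seed = 1L) {
  adj <- g$adjacency
  if (!isConnectedGraph(adj))
    stop("graphMetrics requires a connected graph (prune contract)")
  deg <- rowSums(adj > 0)
  str <- rowSums(adj)
  d <- shortestDistances(adj)
  Lw <- mean(d[upper.tri(d)])
  Cw <- mean(onnelaClustering(adj))
  Lr <- withSeed(seed, {
    mean(vapply(seq_len(n_random), function(i) {
      dr <- shortestDistances(rewireGraph(adj))
      mean(dr[upper.tri(dr)])
    }, 0))
  })
  lat <- latticeSurrogate(adj)
  Cl <- mean(onnelaClustering(lat))
  # sparse pruned graphs are often triangle-free (Cw = 0) and so is a
  # <= 6-edge ring lattice (Cl = 0); the clustering ratio is taken as 0
  # whenever the lattice reference has no triangles, keeping the
  # feature finite
  cratio <- if (Cl > 0) Cw / Cl else 0
  omega <- Lr / Lw - cratio
  thr <- quantile(str, 0.75, type = 7, names = FALSE)
  rich <- str > thr
  rc <- mean(vapply(seq_len(nrow(adj)), function(i) {
    if (str[i] <= 0) return(0)
    sum(adj[i, rich] > 0) / str[i]
  }, 0))
  list(degree = mean(deg), strength = mean(str), pathlen = Lw,
       clustering = Cw, omega = omega, richclub = rc)
}

#' Nodal metrics of one motor ROI node
#'
#' Degree, strength, nodal path length (mean 1/w-distance to the other
#' five nodes), Onnela clustering of the node, and local efficiency
#' (mean inverse shortest-path length within the weighted subgraph
#' induced by the node's neighbours; 0 when fewer than two neighbours).
#'
#' @param g a [pruneGraph()] result.
#' @param node node name, typically `"CR"` (affected motor ROI) or
#'   `"CL"` (unaffected).
#' @return named list: `degree`, `strength`, `pathlen`, `clustering`,
#'   `localeff`.
#' @export
nodalMetrics <- function(g, node) {
  adj <- g$adjacency
  i <- match(node, rownames(adj))
  if (is.na(i)) stop("unknown node: ", node)
  d <- shortestDistances(adj)
  nb <- which(adj[i, ] > 0)
  localeff <- 0
  if (length(nb) >= 2) {
    sub <- adj[nb, nb, drop = FALSE]
    ds <- shortestDistances(sub)
    inv <- 1 / ds[upper.tri(ds)]
    localeff <- mean(ifelse(is.finite(inv), inv, 0))
  }
  list(degree = sum(adj[i, ] > 0), strength = sum(adj[i, ]),
       pathlen = mean(d[i, -i]),
       clustering = onnelaClustering(adj)[i],
       localeff = localeff)
}

#' Per-epoch connectivity feature block (80 features)
#'
#' For each of the five bands: the six global metrics of
#' [graphMetrics()] (30 features) plus the five [nodalMetrics()] of
#' the affected (`CR`) and unaffected (`CL`) central/motor ROI nodes
#' (50 features). Names and order follow [featureRegistry()].
#'
#' @param epoch one element of [extractEpochs()].
#' @param seed RNG seed for the omega surrogate ensemble.
#' @return named numeric vector of length 80.
#' @export
connectivityBlock <- function(epoch, seed = 1L) {
  cm <- imagCoherency(epoch)
  out <- numeric(0)
  for (band in names(cm)) {
    g <- pruneGraph(cm[[band]])
    gm <- graphMetrics(g, seed = seed)
    for (m in names(gm))
      out[paste("net", m, band, sep = "_")] <- gm[[m]]
    for (lab in c("AH", "UH")) {
      nm <- nodalMetrics(g, if (lab == "AH") "CR" else "CL")
      for (m in names(nm))
        out[paste("node", m, lab, band, sep = "_")] <- nm[[m]]
    }
  }
  out
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
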
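# Independent brute-force references used to cross-check the package's
# spectral and graph code. These deliberately share no code with the
# implementation: distances come from exhaustive simple-path
# enumeration, spectra from a direct DFT sum, U statistics from pair
# counting.

# exhaustive all-pairs shortest 1/w-distances by simple-path enumeration
bfDistances <- function(adj) {
  n <- nrow(adj)
  len <- ifelse(adj > 0, 1 / adj, Inf)
  best <- matrix(Inf, n, n); diag(best) <- 0
  explore <- function(path, dist) {
    tail <- path[length(path)]
    if (dist < best[path[1], tail])
      best[path[1], tail] <<- dist
    for (nxt in seq_len(n))
      if (!(nxt %in% path) && is.finite(len[tail, nxt]))
        explore(c(path, nxt), dist + len[tail, nxt])
  }
  for (s in seq_len(n)) explore(s, 0)
  best
}

# Onnela clustering written straight from the triple sum definition
bfOnnela <- function(adj) {
  n <- nrow(adj); mx <- max(adj)
  if (mx <= 0) return(rep(0, n))
  sapply(seq_len(n), function(i) {
    k <- sum(adj[i, ] > 0)
    if (k < 2) return(0)
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        acc <- acc + (adj[i, j] * adj[i, h] * adj[j, h] / mx^3)^(1 / 3)
    acc / (k * (k - 1))
  })
}

# Mann-Whitney U by O(n^2) pair counting (ties counted half)
bfMannWhitneyU <- function(x, y) {
  u <- 0
  for (a in x) for (b in y)
    u <- u + (a > b) + 0.5 * (a == b)
  u
}

# one-sided Welch PSD of a single channel by direct DFT sums
bfWelchPSD <- function(x, fs, seg_len = 2) {
  N <- seg_len * fs
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(N - 1)) / (N - 1))
  n_seg <- length(x) %/% N
  n_bin <- N / 2 + 1
  acc <- numeric(n_bin)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * N + 1):(s * N)] * w
    for (k in 0:(N / 2)) {
      z <- sum(seg * exp(-2i * pi * k * (0:(N - 1)) / N))
      acc[k + 1] <- acc[k + 1] + Mod(z)^2
    }
  }
  p <- acc / n_seg / (fs * sum(w^2))
  p[2:(n_bin - 1)] <- 2 * p[2:(n_bin - 1)]
  list(freqs = (0:(N / 2)) / seg_len, psd = p)
}

# random connected 6-node weighted graph (for oracle sweeps)
randomConnectedGraph <- function(n = 6, p_edge = 0.6) {
  repeat {
    m <- matrix(0, n, n)
    up <- which(upper.tri(m))
    on <- runif(length(up)) < p_edge
    m[up[on]] <- runif(sum(on), 0.05, 1)
    m <- m + t(m)
    d <- bfDistances(m)
    if (all(is.finite(d))) {
      dimnames(m) <- list(c("FR", "FL", "CR", "CL", "OR", "OL"),
                          c("FR", "FL", "CR", "CL", "OR", "OL"))
      return(m)
    }
  }
}
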
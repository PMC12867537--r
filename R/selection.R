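# Feature ranking on the training epochs of a fold: RReliefF (the
# regression form of ReliefF) and greedy mRMR with a correlation-based
# difference criterion. Both are deterministic: all instances are used
# (no subsampling) and ties break by canonical feature name.

#' Rank features with RReliefF (regression Relief)
#'
#' Robnik-Sikonja/Kononenko regression Relief: for every instance its
#' `k` nearest neighbours (Manhattan distance on min-max scaled
#' features, uniform neighbour weighting) update the probability
#' accumulators of "different feature value" and "different target",
#' giving the weight
#' `W[f] = NdC&dA/NdC - (NdA - NdC&dA)/(m*k - NdC)`.
#' Constant features receive weight 0.
#'
#' @param X numeric matrix, instances x features (named columns).
#' @param y continuous target, one value per instance.
#' @param k neighbour count (default 10).
#' @return `data.frame` with columns `feature` and `score`, sorted by
#'   decreasing score (ties by name).
#' @export
relieffRank <- function(X, y, k = 10) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (k >= m) stop("k (", k, ") must be below the instance count (", m, ")")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  rng <- apply(X, 2, function(col) diff(range(col)))
  keep_rng <- ifelse(rng > 0, rng, 1)
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, keep_rng, "/")
  yr <- diff(range(y)); if (yr == 0) yr <- 1
  ys <- (y - min(y)) / yr
  NdC <- 0
  NdA <- numeric(ncol(X))
  NdCdA <- numeric(ncol(X))
  D <- as.matrix(dist(Xs, method = "manhattan"))
  for (i in seq_len(m)) {
    d <- D[i, ]; d[i] <- Inf
    nb <- order(d, seq_len(m))[seq_len(k)]
    dy <- abs(ys[nb] - ys[i])
    dA <- abs(Xs[nb, , drop = FALSE] -
                matrix(Xs[i, ], k, ncol(X), byrow = TRUE))
    NdC <- NdC + sum(dy)
    NdA <- NdA + colSums(dA)
    NdCdA <- NdCdA + colSums(dA * dy)
  }
  w <- if (NdC > 0 && NdC < m * k)
    NdCdA / NdC - (NdA - NdCdA) / (m * k - NdC)
  else numeric(ncol(X))
  w[rng == 0] <- 0
  out <- data.frame(feature = colnames(X), score = as.numeric(w),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$feature), , drop = FALSE]
}

#' Rank features with mRMR (minimum redundancy, maximum relevance)
#'
#' Greedy forward selection with the difference criterion: relevance =
#' `|Pearson cor(f, y)|`, redundancy = mean `|Pearson cor(f, s)|` over
#' the already-selected set. The first pick is the relevance argmax.
#' Zero-variance features are excluded (with a warning) and appended
#' at the end of the ranking.
#'
#' @inheritParams relieffRank
#' @return `data.frame` with columns `feature` and `score` (the greedy
#'   criterion value at selection time), in selection order.
#' @export
mrmrRank <- function(X, y) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("at least one candidate feature required")
  sds <- apply(X, 2, sd)
  flat <- sds == 0
  if (any(flat))
    warning("excluding zero-variance feature(s): ",
            paste(colnames(X)[flat], collapse = ", "))
  live <- colnames(X)[!flat]
  if (!length(live))
    return(data.frame(feature = colnames(X), score = 0))
  Xl <- X[, live, drop = FALSE]
  rel <- abs(suppressWarnings(cor(Xl, y)))[, 1]
  rel[is.na(rel)] <- 0
  C <- abs(suppressWarnings(cor(Xl)))
  C[is.na(C)] <- 0
  selected <- character(0); scores <- numeric(0)
  remaining <- live
  while (length(remaining)) {
    red <- if (length(selected))
      rowMeans(C[remaining, selected, drop = FALSE]) else 0
    crit <- rel[remaining] - red
    best <- remaining[order(-crit, remaining)][1]
    selected <- c(selected, best)
    scores <- c(scores, crit[match(best, remaining)])
    remaining <- setdiff(remaining, best)
  }
  out <- data.frame(feature = c(selected, colnames(X)[flat]),
                    score = c(scores, rep(-Inf, sum(flat))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' All non-empty subsets of the top-ranked features
#'
#' @param ranked a ranking from [relieffRank()] or [mrmrRank()].
#' @param top_m how many leading features to combine (default 4, giving
#'   `2^4 - 1 = 15` candidate sets).
#' @return list of character vectors, ordered by subset size then
#'   lexicographically by member rank (deterministic).
#' @export
candidateSets <- function(ranked, top_m = 4) {
  feats <- head(ranked$feature, top_m)
  if (length(feats) < top_m) stop("ranking shorter than top_m")
  out <- list()
  for (sz in seq_len(top_m))
    out <- c(out, combn(feats, sz, simplify = FALSE))
  out
}
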
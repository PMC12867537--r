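# The regression network: a small fully connected feed-forward net
# (ReLU hidden units, linear output) trained for 20 epochs with Adam at
# learning rate 0.01 under mean-squared-error loss. Implemented directly
# in matrix algebra; everything is deterministic given the seed (He
# initialization and the shuffling stream both draw from it).

.HIDDEN_CONFIGS <- list(c(8L), c(16L), c(32L), c(16L, 8L), c(32L, 16L),
                        c(32L, 16L, 8L))
.BATCH_SIZES <- c("64", "128", "full")

#' Network hyperparameter configuration
#'
#' @param hidden integer vector of hidden-layer widths; must be one of
#'   the six grid configurations `8; 16; 32; (16, 8); (32, 16);
#'   (32, 16, 8)`.
#' @param batch_size `"64"`, `"128"`, or `"full"` (one batch of all
#'   rows).
#' @param epochs training passes (fixed grid value 20).
#' @param lr Adam learning rate (fixed grid value 0.01).
#' @return named list.
#' @export
netConfig <- function(hidden = c(8L), batch_size = "full", epochs = 20L,
                      lr = 0.01) {
  hidden <- as.integer(hidden)
  if (!any(vapply(.HIDDEN_CONFIGS, identical, TRUE, hidden)))
    stop("hidden layout must be one of the six grid configurations")
  batch_size <- match.arg(as.character(batch_size), .BATCH_SIZES)
  list(hidden = hidden, batch_size = batch_size,
       epochs = as.integer(epochs), lr = lr)
}

#' Train the feed-forward regression network
#'
#' Inputs and targets are standardized by training-set mean/sd (stored
#' in the model; predictions are mapped back to the raw FMA-UE scale).
#' Target standardization is what makes the short fixed training
#' budget (20 epochs at learning rate 0.01) workable: Adam moves each
#' parameter by roughly the learning rate per step, so an
#' unstandardized output could never travel the ~40 points from its
#' initialization to the score range. He-normal initialization,
#' per-epoch reshuffling, MSE loss, Adam (beta1 = 0.9, beta2 = 0.999).
#'
#' @param X numeric matrix, training rows x input features.
#' @param y numeric targets (each training epoch row carries its
#'   subject's follow-up FMA-UE).
#' @param config a [netConfig()].
#' @param seed RNG seed; the same seed gives bit-identical models.
#' @return model list (weights, standardization stats, config).
#' @export
mlpTrain <- function(X, y, config = netConfig(), seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  y_mu <- mean(y)
  y_sd <- sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  y <- (y - y_mu) / y_sd
  sizes <- c(ncol(X), config$hidden, 1L)
  L <- length(sizes) - 1L
  withSeed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    n <- nrow(Xs)
    bs <- if (config$batch_size == "full") n else
      min(as.integer(config$batch_size), n)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        Xb <- Xs[idx, , drop = FALSE]; yb <- y[idx]
        nb <- length(idx)
        # forward
        A <- vector("list", L + 1); A[[1]] <- Xb
        for (l in seq_len(L)) {
          Z <- A[[l]] %*% W[[l]]
          Z <- Z + rep(b[[l]], rep.int(nb, length(b[[l]])))
          A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
        }
        # backward (MSE)
        delta <- 2 * (A[[L + 1]] - yb) / length(yb)
        t <- t + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1)
            delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          W[[l]] <- W[[l]] - config$lr * (mW[[l]] / (1 - b1^t)) /
            (sqrt(vW[[l]] / (1 - b2^t)) + eps)
          b[[l]] <- b[[l]] - config$lr * (mb[[l]] / (1 - b1^t)) /
            (sqrt(vb[[l]] / (1 - b2^t)) + eps)
        }
      }
    }
    if (anyNA(W[[L]]) || any(!is.finite(W[[L]])))
      stop("training diverged (non-finite loss); config: ",
           paste(config$hidden, collapse = "-"), " batch ",
           config$batch_size)
    list(W = W, b = b, mu = mu, sd = sdv, y_mu = y_mu, y_sd = y_sd,
         config = config, features = colnames(X))
  })
}

#' Predict with a trained network
#' @param model a [mlpTrain()] result.
#' @param X matrix of rows to score (columns as in training).
#' @return numeric vector of predictions.
#' @export
mlpPredict <- function(model, X) {
  X <- as.matrix(X)
  A <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  L <- length(model$W)
  n <- nrow(A)
  for (l in seq_len(L)) {
    Z <- A %*% model$W[[l]]
    Z <- Z + rep(model$b[[l]], rep.int(n, length(model$b[[l]])))
    A <- if (l < L) pmax(Z, 0) else Z
  }
  as.numeric(A) * model$y_sd + model$y_mu
}

#' Aggregate epoch-level predictions into a subject prediction
#'
#' The subject's predicted follow-up FMA-UE is the median of its
#' epoch-level predictions, clipped to the FMA-UE range \[0, 66\]
#' after aggregation.
#'
#' @param model a [mlpTrain()] result.
#' @param X_epochs matrix of the subject's epoch rows.
#' @return list with `epoch_predictions`, `aggregate` (raw median) and
#'   `prediction` (clipped).
#' @export
predictSubject <- function(model, X_epochs) {
  p <- mlpPredict(model, X_epochs)
  agg <- median(p)
  list(epoch_predictions = p, aggregate = agg,
       prediction = min(max(agg, 0), 66))
}
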
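# Nested leave-one-subject-out cross-validation over the hyperparameter
# grid, plus the test metrics and statistics used to compare the network
# with the proportional recovery rule.
#
# Leakage contract: for an outer test subject s, feature ranking,
# standardization statistics and training only ever see epochs of
# subjects other than s; the inner loop additionally holds out one
# validation subject v per iteration.

.CLINICAL <- c("fmaue_t0", "days_since_stroke", "days_to_followup")

#' Hyperparameter grid
#'
#' Full grid: 4 overlaps x 2 selectors x 15 feature subsets (all
#' non-empty subsets of the fold's top-4 ranking) x 6 hidden-layer
#' layouts x 3 batch sizes = 2160 points. Canonical order (the
#' tie-break for grid selection): overlap ascending, selector, subset
#' (size then rank), smaller network first, batch size.
#'
#' @param overlaps epoch overlap fractions to include.
#' @param selectors ranking methods, subset of `c("relieff", "mrmr")`.
#' @param hidden_ids indices into the six layer layouts (1 = `8`, ...,
#'   6 = `32-16-8`).
#' @param batch_sizes subset of `c("64", "128", "full")`.
#' @param subset_ids indices into the 15 candidate subsets.
#' @return `data.frame`, one row per grid point.
#' @export
makeGrid <- function(overlaps = c(0, 0.25, 0.5, 0.75),
                     selectors = c("relieff", "mrmr"),
                     hidden_ids = 1:6,
                     batch_sizes = c("64", "128", "full"),
                     subset_ids = 1:15) {
  g <- expand.grid(batch = batch_sizes, hidden_id = hidden_ids,
                   subset_id = subset_ids, selector = selectors,
                   overlap = overlaps, stringsAsFactors = FALSE)
  g <- g[, c("overlap", "selector", "subset_id", "hidden_id", "batch")]
  g <- g[order(g$overlap, g$selector, g$subset_id, g$hidden_id,
               match(g$batch, .BATCH_SIZES)), ]
  rownames(g) <- NULL
  g
}

#' @rdname makeGrid
#' @details `reducedGrid()` is the desk-scale grid used by the
#'   synthetic-cohort experiments: no overlap, mRMR ranking, all 15
#'   feature subsets, a single 8-unit hidden layer, batch size 64
#'   (minibatches give the fixed 20-epoch training budget enough
#'   optimizer steps to converge on a few hundred rows).
#' @export
reducedGrid <- function() {
  makeGrid(overlaps = 0, selectors = "mrmr", hidden_ids = 1,
           batch_sizes = "64")
}

# deterministic integer seed stream derived from a root seed
seedFrom <- function(seed, ...) {
  x <- as.double(seed %% 2147483647)
  for (k in c(...)) x <- (x * 69069 + as.double(k)) %% 2147483647
  as.integer(x) + 1L
}

# flatten a feature SummarizedExperiment into epochs x features matrix
.flattenSE <- function(se) {
  list(X = t(SummarizedExperiment::assay(se, "features")),
       subject = as.character(SummarizedExperiment::colData(se)$subject_id))
}

.rankFeatures <- function(X, y, selector, relieff_k) {
  if (selector == "relieff") relieffRank(X, y, k = relieff_k)
  else mrmrRank(X, y)
}

#' Nested leave-one-subject-out cross-validation
#'
#' For every outer test subject: an inner LOSO over the remaining
#' subjects scores every grid point (features are re-ranked on each
#' inner-fold training matrix; the network is trained on the inner
#' training epochs and each held-out subject is predicted by the
#' clipped epoch median), by the subject-level validation RMSE. The
#' RMSE-minimizing grid point (ties: canonical grid order) is refit on
#' all non-test subjects and predicts the test subject. Subjects at
#' the configured score ceilings are kept for training but never
#' tested.
#'
#' @param features_by_overlap named list (names = overlap fractions as
#'   characters, e.g. `"0"`, `"0.5"`) of cohort feature tables from
#'   [bindFeatureTables()]; must cover every overlap in the grid.
#' @param cohort patient table ([readCohort()] layout) supplying the
#'   targets (`fmaue_T1`).
#' @param grid a [makeGrid()] / [reducedGrid()] `data.frame`.
#' @param test_subjects subjects to test on (default: all non-excluded
#'   cohort subjects); exclusions are applied on top.
#' @param exclude_baseline_ceiling,exclude_followup_ceiling ceiling
#'   exclusions for testing (training always keeps everyone).
#' @param relieff_k RReliefF neighbour count.
#' @param seed root seed; all trainings derive deterministic seeds
#'   from it.
#' @return a CV report: list with `folds` (per-subject `data.frame`),
#'   `selected` (per-subject character vectors of chosen EEG
#'   features), `inner_rmse_grid` (per-subject numeric vector over the
#'   grid), `summary` (`median`, `iqr`), and `grid`.
#' @export
nestedLoso <- function(features_by_overlap, cohort, grid = reducedGrid(),
                       test_subjects = NULL,
                       exclude_baseline_ceiling = TRUE,
                       exclude_followup_ceiling = FALSE,
                       relieff_k = 10, seed = 1L) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  need <- as.character(unique(grid$overlap))
  miss <- setdiff(need, names(features_by_overlap))
  if (length(miss))
    stop("feature tables missing for overlap(s): ",
         paste(miss, collapse = ", "))
  flat <- lapply(features_by_overlap, .flattenSE)
  all_subj <- unique(flat[[need[1]]]$subject)
  if (any(vapply(flat[need], function(f)
        !setequal(unique(f$subject), all_subj), TRUE)))
    stop("overlap tables cover different subject sets")
  y_subj <- setNames(as.numeric(cohort$fmaue_T1),
                     as.character(cohort$subject_id))
  if (anyNA(y_subj[all_subj]))
    stop("cohort lacks fmaue_T1 for subject(s): ",
         paste(setdiff(all_subj, names(y_subj)), collapse = ", "))
  eeg <- eegFeatureNames()
  eligible <- all_subj
  t0 <- setNames(cohort$fmaue_T0, as.character(cohort$subject_id))
  if (exclude_baseline_ceiling)
    eligible <- eligible[t0[eligible] < 66]
  if (exclude_followup_ceiling)
    eligible <- eligible[y_subj[eligible] < 66]
  if (is.null(test_subjects)) test_subjects <- eligible
  else test_subjects <- intersect(test_subjects, eligible)
  if (length(all_subj) - 1L < 2L)
    stop("nested LOSO needs at least 3 subjects")

  hidden_cfgs <- .HIDDEN_CONFIGS
  folds <- list(); selected <- list(); rmse_grids <- list()
  for (s in test_subjects) {
    train_subj <- setdiff(all_subj, s)
    rmse_acc <- matrix(0, nrow(grid), length(train_subj))
    for (vi in seq_along(train_subj)) {
      v <- train_subj[vi]
      rank_cache <- list()
      pred_cache <- list()
      for (gi in seq_len(nrow(grid))) {
        g <- grid[gi, ]
        o <- as.character(g$overlap)
        dat <- flat[[o]]
        inner_rows <- !dat$subject %in% c(s, v)
        key <- paste(o, g$selector)
        if (is.null(rank_cache[[key]])) {
          rk <- .rankFeatures(dat$X[inner_rows, eeg, drop = FALSE],
                              y_subj[dat$subject[inner_rows]],
                              g$selector, relieff_k)
          rank_cache[[key]] <- candidateSets(rk)
        }
        feats <- c(rank_cache[[key]][[g$subset_id]], .CLINICAL)
        pkey <- paste(key, g$subset_id, g$hidden_id, g$batch)
        if (is.null(pred_cache[[pkey]])) {
          cfg <- netConfig(hidden_cfgs[[g$hidden_id]], g$batch)
          model <- mlpTrain(dat$X[inner_rows, feats, drop = FALSE],
                            y_subj[dat$subject[inner_rows]], cfg,
                            seed = seedFrom(seed, match(s, all_subj),
                                            vi, gi))
          vp <- predictSubject(
            model, dat$X[dat$subject == v, feats, drop = FALSE])
          pred_cache[[pkey]] <- vp$prediction
        }
        rmse_acc[gi, vi] <- (pred_cache[[pkey]] - y_subj[v])^2
      }
    }
    rmse <- sqrt(rowMeans(rmse_acc))
    best <- which.min(rmse)  # first index on ties = canonical order
    g <- grid[best, ]
    o <- as.character(g$overlap)
    dat <- flat[[o]]
    outer_rows <- dat$subject != s
    rk <- .rankFeatures(dat$X[outer_rows, eeg, drop = FALSE],
                        y_subj[dat$subject[outer_rows]],
                        g$selector, relieff_k)
    feats_eeg <- candidateSets(rk)[[g$subset_id]]
    feats <- c(feats_eeg, .CLINICAL)
    cfg <- netConfig(hidden_cfgs[[g$hidden_id]], g$batch)
    model <- mlpTrain(dat$X[outer_rows, feats, drop = FALSE],
                      y_subj[dat$subject[outer_rows]], cfg,
                      seed = seedFrom(seed, match(s, all_subj), 0L, best))
    sp <- predictSubject(model,
                         dat$X[dat$subject == s, feats, drop = FALSE])
    folds[[s]] <- data.frame(
      subject_id = s, prediction = sp$prediction, truth = y_subj[s],
      abs_error = abs(sp$prediction - y_subj[s]),
      inner_rmse = rmse[best], grid_index = best,
      overlap = g$overlap, selector = g$selector,
      subset_id = g$subset_id,
      hidden = paste(hidden_cfgs[[g$hidden_id]], collapse = "-"),
      batch = g$batch, stringsAsFactors = FALSE
    )
    selected[[s]] <- feats_eeg
    rmse_grids[[s]] <- rmse
  }
  folds <- do.call(rbind, folds)
  rownames(folds) <- NULL
  list(folds = folds, selected = selected, inner_rmse_grid = rmse_grids,
       summary = medianAbsError(folds$prediction, folds$truth),
       grid = grid)
}

#' Median absolute error with interquartile range
#' @param predictions,truths equal-length numeric vectors.
#' @return list with `median` and `iqr` of `|prediction - truth|`.
#' @export
medianAbsError <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths),
            length(predictions) >= 1)
  err <- abs(predictions - truths)
  list(median = median(err), iqr = IQR(err))
}

#' Feature and domain selection frequencies of a CV report
#'
#' Per feature: the fraction of outer folds whose final model included
#' it. Per domain (spectral, brain symmetry, node connectivity,
#' network): the fraction of folds selecting at least one feature of
#' that domain.
#'
#' @param report a [nestedLoso()] result.
#' @return list with named numeric vectors `feature` (selected
#'   features only) and `domain` (all four EEG domains).
#' @export
selectionFrequency <- function(report) {
  sel <- report$selected
  if (!length(sel)) stop("report contains no folds")
  n <- length(sel)
  feats <- sort(unique(unlist(sel)))
  ff <- vapply(feats, function(f)
    mean(vapply(sel, function(s) f %in% s, TRUE)), 0)
  reg <- featureRegistry()
  domains <- c("spectral", "brain_symmetry", "node_connectivity",
               "network")
  df <- vapply(domains, function(d) {
    members <- reg$name[reg$domain == d]
    mean(vapply(sel, function(s) any(s %in% members), TRUE))
  }, 0)
  list(feature = ff, domain = df)
}

#' Paired sign-flip permutation test on error differences
#'
#' The null distribution is built by randomly flipping the sign of
#' each paired difference `errors_A - errors_B`; the permuted
#' statistic is the *mean* difference (the median is degenerate under
#' sign flips whenever the differences share a magnitude, e.g. tied
#' errors), while the reported effect size is the median difference,
#' the quantity quoted alongside the p-value in this design.
#' Two-sided p-value with +1 smoothing.
#'
#' @param errors_A,errors_B paired per-subject absolute errors.
#' @param n_perm number of permutations (10000 in the study design).
#' @param seed RNG seed.
#' @return list with `statistic` (median difference), `mean_difference`
#'   (the permuted statistic) and `p.value`.
#' @export
pairedPermutationTest <- function(errors_A, errors_B, n_perm = 10000,
                                  seed = 1L) {
  stopifnot(length(errors_A) == length(errors_B))
  d <- errors_A - errors_B
  if (length(d) < 2) stop("need at least two pairs")
  obs <- mean(d)
  exceed <- withSeed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * length(d),
                           replace = TRUE), n_perm)
    sum(abs(flips %*% d) / length(d) >= abs(obs) - 1e-12)
  })
  list(statistic = median(d), mean_difference = obs,
       p.value = (1 + exceed) / (n_perm + 1))
}

#' Window-level recoverer vs non-recoverer feature tests
#'
#' Two-sided Mann-Whitney U on pooled windows per feature, Bonferroni
#' correction by the number of tested features, and Cohen's d with the
#' pooled standard deviation. Run on the no-overlap feature table, as
#' group sizes are small at the subject level.
#'
#' @param se a cohort feature table ([bindFeatureTables()], overlap 0).
#' @param labels named character vector (subject -> `"REC"` /
#'   `"NO-REC"`), e.g. from [prrEvaluate()].
#' @param tested_features feature names to test.
#' @param alpha family-wise significance level before correction.
#' @return `data.frame`: feature, U, p, p_bonferroni, cohen_d,
#'   significant (at `alpha / n_tested`).
#' @export
groupFeatureTests <- function(se, labels, tested_features,
                              alpha = 0.05) {
  dat <- .flattenSE(se)
  grp <- labels[dat$subject]
  if (length(unique(grp[!is.na(grp)])) < 2)
    stop("both REC and NO-REC groups must be represented")
  n_tested <- length(tested_features)
  out <- lapply(tested_features, function(f) {
    x <- dat$X[grp == "REC", f]
    y <- dat$X[grp == "NO-REC", f]
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    d <- if (sp > 0) (mean(x) - mean(y)) / sp else 0
    data.frame(feature = f, U = unname(wt$statistic), p = wt$p.value,
               p_bonferroni = min(1, wt$p.value * n_tested),
               cohen_d = d,
               significant = wt$p.value < alpha / n_tested,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
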
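# Distance-weighted ReliefF feature ranking and wrapper-based selection of
# the feature count by cross-validated MCC.
#
# Parameters mirror the defaults of the classic implementation with
# distance weighting enabled: k = 10 nearest neighbours per class, every
# instance sampled, Manhattan distance on range-normalized features, and
# exponential rank-based neighbour weights exp(-(rank/sigma)^2) with
# sigma = 2, normalized to sum to one within each neighbour set.

#' Rank features by ReliefF merit
#'
#' For every instance, the k nearest hits (same class) and k nearest
#' misses (other class) are found under Manhattan distance; each feature's
#' merit accumulates the distance-weighted feature mismatch with misses
#' minus the mismatch with hits, averaged over instances. Feature
#' differences are normalized by the feature's observed range, so a
#' constant feature has merit exactly 0. Ties in merit are broken by
#' canonical (column) order; neighbour ties in distance by instance index.
#'
#' @param x Feature matrix (scaled features recommended).
#' @param labels Class labels, exactly two classes.
#' @param k Neighbours per class (default 10).
#' @param sigma Width of the exponential rank weighting (default 2).
#' @param seed Unused when all instances are sampled (kept for interface
#'   stability).
#' @return data.frame with `rank`, `feature`, `merit`, merits
#'   non-increasing.
#' @export
relieff_rank <- function(x, labels, k = 10, sigma = 2, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("ReliefF requires exactly two classes")
  n <- nrow(x)
  for (cl in classes)
    if (sum(labels == cl) < k + 1)
      stop("class '", cl, "' needs at least k+1 = ", k + 1, " instances")
  rng <- apply(x, 2, max) - apply(x, 2, min)
  xn <- sweep(x, 2, ifelse(rng > 0, rng, 1), "/")
  xn[, rng == 0] <- 0
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  rank_w <- exp(-(seq_len(k) / sigma)^2)
  rank_w <- rank_w / sum(rank_w)
  merit <- numeric(ncol(x))
  idx_by_class <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    contrib <- function(cand) {
      cand <- cand[cand != i]
      nb <- cand[order(d[i, cand], cand)][seq_len(k)]
      colSums(rank_w * abs(xn[nb, , drop = FALSE] -
                             matrix(xn[i, ], k, ncol(x), byrow = TRUE)))
    }
    merit <- merit + contrib(which(same)) * -1 + contrib(which(!same))
  }
  merit <- merit / n
  ord <- order(-merit, seq_along(merit))
  out <- data.frame(rank = seq_along(merit), feature = colnames(x)[ord],
                    merit = merit[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the feature count maximizing cross-validated MCC
#'
#' Walks down the ReliefF ranking, evaluating the classifier on the top-c
#' features for increasing c by stratified k-fold cross-validation, and
#' picks the count attaining the maximum MCC (ties resolved toward fewer
#' features). The SVM hyperparameters are held fixed across counts rather
#' than re-tuned per count.
#'
#' @param ranking data.frame from [relieff_rank()].
#' @param x Feature matrix containing at least the ranked features.
#' @param labels Class labels.
#' @param config `sumo_svm_config` used at every count.
#' @param folds CV folds (default 10).
#' @param stride Evaluate counts `stride, 2*stride, ...` (the full count
#'   is always included).
#' @param repeats CV repeats per count.
#' @param seed Integer seed.
#' @return List of class `sumo_selection` with `curve` (data.frame
#'   `count`, `mcc`), `chosen` (count), `features` (chosen feature names).
#' @export
select_feature_count <- function(ranking, x, labels, config = sumo_svm_config(),
                                 folds = 10, stride = 1, repeats = 1, seed = 1) {
  stopifnot(all(ranking$feature %in% colnames(x)))
  p <- nrow(ranking)
  counts <- unique(c(seq(stride, p, by = stride), p))
  mcc <- vapply(counts, function(cnt) {
    feats <- ranking$feature[seq_len(cnt)]
    builder <- function(xtr, ytr)
      sumo_svm(xtr[, feats, drop = FALSE], ytr, config = config, seed = seed)
    cross_validate(x[, feats, drop = FALSE], labels, builder,
                   n_folds = folds, repeats = repeats, seed = seed)$mean[["MCC"]]
  }, numeric(1))
  chosen <- counts[which.max(mcc)]   # which.max takes the first (fewest) maximum
  structure(list(curve = data.frame(count = counts, mcc = mcc),
                 chosen = chosen,
                 features = ranking$feature[seq_len(chosen)]),
            class = "sumo_selection")
}

#' @export
print.sumo_selection <- function(x, ...) {
  cat(sprintf("Feature-count selection: %d counts evaluated, chosen %d (CV MCC %.3f)\n",
              nrow(x$curve), x$chosen, max(x$curve$mcc)))
  invisible(x)
}

#' @export
plot.sumo_selection <- function(x, ...) {
  plot(x$curve$count, x$curve$mcc, type = "b", xlab = "Number of features",
       ylab = "Cross-validated MCC", ...)
  graphics::abline(v = x$chosen, lty = 2, col = "grey")
  invisible(x)
}
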
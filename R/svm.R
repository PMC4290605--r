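# The classifier core: a class-weighted RBF support vector machine
# (libsvm via e1071) with exponential (C, gamma) grid search and named
# decision-value thresholds.
#
# Decision values are always oriented so that larger means more
# confidently positive; a site is called positive when its decision value
# exceeds the chosen threshold. The named thresholds low/medium/high
# (-0.5 / 0 / 0.5) trade sensitivity against specificity.

#' SVM configuration
#'
#' @param cost,gamma RBF-SVM hyperparameters (positive).
#' @param class_weights Named per-class multipliers of C; the default 1:5
#'   up-weights the positive minority class.
#' @param thresholds Named, strictly increasing decision-value cutoffs.
#' @return Object of class `sumo_svm_config`.
#' @export
sumo_svm_config <- function(cost = 1, gamma = 0.05,
                            class_weights = c(negative = 1, positive = 5),
                            thresholds = c(low = -0.5, medium = 0, high = 0.5)) {
  stopifnot(cost > 0, gamma > 0, all(class_weights > 0),
            all(c("negative", "positive") %in% names(class_weights)),
            length(thresholds) >= 1, !is.unsorted(thresholds, strictly = TRUE))
  structure(list(cost = cost, gamma = gamma, class_weights = class_weights,
                 thresholds = thresholds),
            class = "sumo_svm_config")
}

#' Hyperparameter grid specification
#'
#' Exponential base-2 grid: C over `2^c_exponents`, gamma over
#' `2^gamma_exponents`. When the cross-validated optimum lands on a grid
#' border, the grid is extended stepwise, up to `max_extension` exponent
#' steps beyond the original margins.
#'
#' @param c_exponents,gamma_exponents Integer exponent sequences (defaults
#'   -5..15 and -15..3).
#' @param step Exponent step used for extension (and for coarser grids).
#' @param max_extension Maximum exponent distance past the original
#'   margins.
#' @return Object of class `sumo_grid_spec`.
#' @export
grid_spec <- function(c_exponents = seq(-5, 15, by = step),
                      gamma_exponents = seq(-15, 3, by = step),
                      step = 1, max_extension = 5) {
  stopifnot(step >= 1, max_extension >= 0)
  structure(list(c_exponents = c_exponents, gamma_exponents = gamma_exponents,
                 step = step, max_extension = max_extension),
            class = "sumo_grid_spec")
}

label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- !labels %in% c("positive", "negative")
  if (any(bad)) stop("labels must be 'positive'/'negative'")
  factor(labels, levels = c("negative", "positive"))
}

fit_libsvm <- function(x, y, cost, gamma, class_weights) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, class.weights = class_weights,
             scale = FALSE)
}

# decision values oriented so larger = more positive
oriented_decision_values <- function(fit, x) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  v <- as.numeric(dv[, 1])
  if (startsWith(colnames(dv)[1], "negative/")) v <- -v
  v
}

cv_mcc_point <- function(x, y, cost, gamma, class_weights, fold) {
  k <- max(fold)
  mean(vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_libsvm(x[tr, , drop = FALSE], y[tr], cost, gamma, class_weights)
    dv <- oriented_decision_values(fit, x[!tr, , drop = FALSE])
    pred <- ifelse(dv > 0, "positive", "negative")
    confusion_metrics(confusion_counts(pred, as.character(y[!tr])))[["MCC"]]
  }, numeric(1)))
}

#' Grid search for (C, gamma)
#'
#' Evaluates stratified k-fold cross-validated MCC at every grid point
#' (the same fold assignment is reused across points so the comparison is
#' paired) and returns the configuration with the highest MCC; ties go to
#' the smaller C, then the smaller gamma. If the optimum sits on a grid
#' border the grid is extended per the spec's allowance and the search
#' repeats.
#'
#' @param x Scaled feature matrix.
#' @param labels "positive"/"negative" labels.
#' @param grid A [grid_spec()].
#' @param class_weights Per-class C multipliers.
#' @param folds CV folds inside the search (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List with `config` (a [sumo_svm_config()] at the optimum),
#'   `curve` (data.frame of evaluated points and their MCC) and
#'   `extended` (logical).
#' @export
grid_search <- function(x, labels, grid = grid_spec(),
                        class_weights = c(negative = 1, positive = 5),
                        folds = 10, seed = 1) {
  y <- label_factor(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  fold <- stratified_folds(as.character(y), folds, seed = seed)
  ce <- sort(grid$c_exponents); ge <- sort(grid$gamma_exponents)
  lim <- list(c = range(ce) + c(-1, 1) * grid$max_extension,
              g = range(ge) + c(-1, 1) * grid$max_extension)
  seen <- new.env(parent = emptyenv())
  curve <- list()
  extended <- FALSE
  repeat {
    pts <- expand.grid(ce = ce, ge = ge)
    for (i in seq_len(nrow(pts))) {
      key <- paste(pts$ce[i], pts$ge[i])
      if (!is.null(seen[[key]])) next
      mcc <- cv_mcc_point(x, y, 2^pts$ce[i], 2^pts$ge[i], class_weights, fold)
      seen[[key]] <- TRUE
      curve[[length(curve) + 1L]] <-
        data.frame(c_exp = pts$ce[i], gamma_exp = pts$ge[i], mcc = mcc)
    }
    cv <- do.call(rbind, curve)
    cv <- cv[order(-cv$mcc, cv$c_exp, cv$gamma_exp), ]
    best <- cv[1, ]
    grew <- FALSE
    if (best$c_exp == min(ce) && min(ce) - grid$step >= lim$c[1]) {
      ce <- c(min(ce) - grid$step, ce); grew <- TRUE
    }
    if (best$c_exp == max(ce) && max(ce) + grid$step <= lim$c[2]) {
      ce <- c(ce, max(ce) + grid$step); grew <- TRUE
    }
    if (best$gamma_exp == min(ge) && min(ge) - grid$step >= lim$g[1]) {
      ge <- c(min(ge) - grid$step, ge); grew <- TRUE
    }
    if (best$gamma_exp == max(ge) && max(ge) + grid$step <= lim$g[2]) {
      ge <- c(ge, max(ge) + grid$step); grew <- TRUE
    }
    if (!grew) break
    extended <- TRUE
  }
  cv <- do.call(rbind, curve)
  list(config = sumo_svm_config(cost = 2^best$c_exp, gamma = 2^best$gamma_exp,
                                class_weights = class_weights),
       curve = cv, extended = extended)
}

#' Fit the weighted RBF-SVM sumoylation-site classifier
#'
#' The central fitting function. Optionally restricts to a selected
#' feature subset, fits a min-max scaler on the training matrix, runs the
#' (C, gamma) grid search when no configuration is supplied, and trains
#' the final class-weighted RBF-SVM on all training data.
#'
#' @param x Raw (unscaled) feature matrix, rows = sites.
#' @param labels "positive"/"negative" labels.
#' @param config A [sumo_svm_config()]; `NULL` triggers [grid_search()].
#' @param grid Grid for the search (ignored when `config` given).
#' @param features Optional character vector restricting the feature set
#'   (e.g. from [select_feature_count()]).
#' @param scale Fit and apply min-max scaling (default TRUE).
#' @param folds CV folds inside the grid search.
#' @param seed Integer seed (grid-search folds).
#' @return Object of class `sumo_svm` with predict/print/summary/plot
#'   methods.
#' @export
sumo_svm <- function(x, labels, config = NULL, grid = grid_spec(),
                     features = NULL, scale = TRUE, folds = 10, seed = 1) {
  stopifnot(is.matrix(x))
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- label_factor(labels)
  if (length(unique(y)) < 2) stop("both classes required for training")
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing))
      stop("features not in matrix: ", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  scaler <- NULL
  xs <- x
  if (scale) {
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
  }
  grid_result <- NULL
  if (is.null(config)) {
    grid_result <- grid_search(xs, as.character(y), grid = grid,
                               folds = folds, seed = seed)
    config <- grid_result$config
  }
  stopifnot(inherits(config, "sumo_svm_config"))
  fit <- fit_libsvm(xs, y, config$cost, config$gamma, config$class_weights)
  obj <- structure(list(
    svm = fit, scaler = scaler, features = colnames(x), config = config,
    grid_result = grid_result, seed = seed, n = nrow(x),
    class_counts = table(y),
    train_decision_values = oriented_decision_values(fit, xs),
    train_labels = as.character(y)), class = "sumo_svm")
  obj
}

resolve_threshold <- function(object, threshold) {
  if (is.numeric(threshold)) return(threshold)
  th <- object$config$thresholds
  if (!threshold %in% names(th))
    stop("invalid threshold '", threshold, "'; use one of {",
         paste(names(th), collapse = ", "), "} or a numeric value")
  th[[threshold]]
}

#' Predict sumoylation sites with a fitted model
#'
#' @param object A `sumo_svm` model.
#' @param newdata Raw feature matrix containing the model's features.
#' @param threshold Named threshold (`"low"`, `"medium"`, `"high"` by
#'   default) or a numeric decision-value cutoff.
#' @param ... Unused.
#' @return data.frame with `decision_value` and `label` (positive iff
#'   decision value > threshold).
#' @export
predict.sumo_svm <- function(object, newdata, threshold = "medium", ...) {
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  x <- newdata[, object$features, drop = FALSE]
  if (!is.null(object$scaler)) x <- apply_scaler(object$scaler, x)
  dv <- oriented_decision_values(object$svm, x)
  thr <- resolve_threshold(object, threshold)
  data.frame(decision_value = dv,
             label = ifelse(dv > thr, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' @export
print.sumo_svm <- function(x, ...) {
  cat("Weighted RBF-SVM sumoylation-site classifier\n")
  cat(sprintf("  features: %d   training sites: %d (%s)\n",
              length(x$features), x$n,
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = ", ")))
  cat(sprintf("  C = %g, gamma = %g, class weights %s\n",
              x$config$cost, x$config$gamma,
              paste(sprintf("%s:%g", names(x$config$class_weights),
                            x$config$class_weights), collapse = " ")))
  cat(sprintf("  thresholds: %s\n",
              paste(sprintf("%s=%g", names(x$config$thresholds),
                            x$config$thresholds), collapse = " ")))
  invisible(x)
}

#' @export
summary.sumo_svm <- function(object, ...) {
  sc <- confusion_metrics(confusion_counts(
    ifelse(object$train_decision_values > resolve_threshold(object, "medium"),
           "positive", "negative"),
    object$train_labels))
  out <- list(model = object, self_consistency = sc,
              support_vectors = object$svm$tot.nSV)
  class(out) <- "summary.sumo_svm"
  out
}

#' @export
print.summary.sumo_svm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  support vectors: %d\n", x$support_vectors))
  cat(sprintf("  self-consistency: Acc %.2f  Sp %.2f  Sn %.2f  MCC %.2f\n",
              x$self_consistency[["Acc"]], x$self_consistency[["Sp"]],
              x$self_consistency[["Sn"]], x$self_consistency[["MCC"]]))
  invisible(x)
}

#' @export
plot.sumo_svm <- function(x, ...) {
  dv <- x$train_decision_values
  pos <- x$train_labels == "positive"
  brk <- pretty(range(dv), 40)
  hn <- graphics::hist(dv[!pos], breaks = brk, plot = FALSE)
  hp <- graphics::hist(dv[pos], breaks = brk, plot = FALSE)
  ylim <- c(0, max(hn$density, hp$density))
  plot(hn, freq = FALSE, col = grDevices::adjustcolor("grey40", 0.5),
       border = NA, ylim = ylim, xlab = "Decision value",
       main = "Training decision values by class", ...)
  plot(hp, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
       border = NA, add = TRUE)
  graphics::abline(v = x$config$thresholds, lty = 2)
  graphics::legend("topright", fill = c("grey40", "firebrick"),
                   legend = c("negative", "positive"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model bundle
#'
#' The bundle contains the SVM, scaler parameters, feature list,
#' configuration and seed, and round-trips to identical decision values.
#'
#' @param object A `sumo_svm` model.
#' @param path File path (.rds).
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "sumo_svm"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "sumo_svm"))
  obj
}
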
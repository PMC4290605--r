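# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately use naive algorithms so they stay
# independent of the package's implementation paths.

# naive O(n^2 p) ReliefF: plain loops, k nearest hits/misses, exponential
# rank weights normalized per neighbour set, diffs normalized by range
ref_relieff <- function(x, labels, k = 10, sigma = 2) {
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(col) diff(range(col)))
  merit <- numeric(p)
  w <- exp(-(seq_len(k) / sigma)^2)
  w <- w / sum(w)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) {
      s <- 0
      for (f in seq_len(p)) if (rng[f] > 0)
        s <- s + abs(x[i, f] - x[j, f]) / rng[f]
      d[j] <- s
    }
    for (grp in list(hits = which(labels == labels[i] & seq_len(n) != i),
                     miss = which(labels != labels[i]))) {
      nb <- grp[order(d[grp], grp)][seq_len(k)]
      sign <- if (identical(labels[nb[1]], labels[i])) -1 else 1
      for (jj in seq_along(nb)) for (f in seq_len(p)) if (rng[f] > 0)
        merit[f] <- merit[f] + sign * w[jj] * abs(x[i, f] - x[nb[jj], f]) / rng[f]
    }
  }
  merit / n
}

# exhaustive pair-counting Mann-Whitney U (positive-group orientation)
brute_U <- function(pos, neg) {
  u <- 0
  for (a in pos) for (b in neg)
    u <- u + (a > b) + 0.5 * (a == b)
  u
}

# pairwise-probability AUC oracle
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "positive"]; neg <- scores[labels == "negative"]
  brute_U(pos, neg) / (length(pos) * length(neg))
}

# every-K regex check written without the window machinery
brute_scan <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] != "K" || i < 2 || i + 2 > n) next
    if (chars[i - 1] %in% c("I", "V", "L", "M", "A", "P") &&
        chars[i + 2] %in% c("D", "E"))
      hits <- c(hits, i)
  }
  hits
}

random_protein <- function(len, alphabet = c(aa_alphabet(), "X")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small fully annotated protein fixture: one protein, constant annotations
tiny_protein <- function(sequence, id = "p1", flexible = 0, disorder = 0) {
  proteins <- data.frame(id = id, sequence = sequence,
                         length = nchar(sequence), stringsAsFactors = FALSE)
  annotations <- data.frame(protein_id = id, position = seq_len(nchar(sequence)),
                            flexible = flexible, disorder = disorder,
                            stringsAsFactors = FALSE)
  list(proteins = proteins, annotations = annotations)
}

# linearly separable two-feature toy with both classes
separable_toy <- function(n_per_class = 20, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = 3, sd = 0.3), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, labels = rep(c("negative", "positive"), each = n_per_class))
}

# a cheap deterministic classifier for exercising the evaluation
# machinery: thresholds the first feature at the midpoint of the class
# means
mean_threshold_builder <- function(x, labels) {
  structure(list(cut = mean(x[labels == "positive", 1]) / 2 +
                   mean(x[labels == "negative", 1]) / 2),
            class = "mean_threshold")
}
predict.mean_threshold <- function(object, newdata, threshold = "medium", ...) {
  dv <- newdata[, 1] - object$cut
  data.frame(decision_value = dv,
             label = ifelse(dv > 0, "positive", "negative"))
}
registerS3method("predict", "mean_threshold", predict.mean_threshold,
                 envir = asNamespace("stats"))

`%||%` <- function(a, b) if (is.null(a)) b else a

# run the installed CLI script in a child process that sees the same
# library paths as this session
run_cli <- function(args) {
  cli <- system.file("cli", "sumosite.R", package = "sumosite")
  rscript <- file.path(R.home("bin"), "Rscript")
  suppressWarnings(system2(
    rscript, c(cli, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
}
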
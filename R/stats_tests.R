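# Statistical screening of features: chi-square tests of independence for
# binary features (Yates continuity correction when an observed cell is
# below 5), two-tailed Mann-Whitney U tests for real-valued features with
# probability-of-superiority and normal-approximation z, and
# Benjamini-Hochberg FDR control within each comparison strategy.

#' Chi-square test of independence on a 2x2 table
#'
#' Pearson chi-square with 1 df. The Yates continuity correction is
#' applied exactly when some observed cell is below 5 (the observed-count
#' reading; set `yates_on` to `"expected"` for the expected-count
#' convention).
#'
#' @param table 2x2 matrix of observed counts (rows = group,
#'   columns = feature present/absent).
#' @param yates_on `"observed"` (default) or `"expected"`: which counts
#'   trigger the continuity correction.
#' @return List with `statistic`, `p`, `corrected`, `untestable`. A zero
#'   column or row sum makes the test untestable (NA statistic and p).
#' @export
chi2_independence <- function(table, yates_on = c("observed", "expected")) {
  yates_on <- match.arg(yates_on)
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  o <- matrix(as.numeric(table), 2, 2)
  if (any(rowSums(o) == 0) || any(colSums(o) == 0))
    return(list(statistic = NA_real_, p = NA_real_, corrected = FALSE,
                untestable = TRUE))
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  corrected <- if (yates_on == "observed") any(o < 5) else any(e < 5)
  dev <- if (corrected) pmax(0, abs(o - e) - 0.5) else abs(o - e)
  stat <- sum(dev^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       corrected = corrected, untestable = FALSE)
}

#' Mann-Whitney U test with probability of superiority
#'
#' U is computed by the midrank method and oriented to the first
#' (positive) group, so PS = U / (n1 n2) estimates P(positive value >
#' negative value) with ties counted half. The z value uses the plain
#' normal approximation z = (U - n1 n2 / 2) / sqrt(n1 n2 (n1+n2+1) / 12);
#' an optional tie-corrected variance is available but off by default.
#' The two-tailed p comes from the normal approximation.
#'
#' @param group_pos,group_neg Numeric vectors of the two groups.
#' @param tie_correction Use the tie-corrected variance in z.
#' @return List with `U`, `n1`, `n2`, `PS`, `z`, `p`.
#' @export
mann_whitney <- function(group_pos, group_neg, tie_correction = FALSE) {
  n1 <- length(group_pos); n2 <- length(group_neg)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(group_pos, group_neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sigma <- if (tie_correction) {
    n <- n1 + n2
    ties <- table(r)
    sqrt(n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  } else {
    sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  }
  z <- if (sigma > 0) (u - n1 * n2 / 2) / sigma else 0
  list(U = u, n1 = n1, n2 = n2, PS = u / (n1 * n2), z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (p * m / rank with monotonicity enforcement,
#' capped at 1); input order is preserved.
#'
#' @param pvalues Numeric vector of raw p-values in \[0,1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

strategy_groups <- function(labels, consensus) {
  list(
    pos_vs_neg = list(g1 = labels == "positive", g2 = labels == "negative"),
    cons_pos_vs_noncons_pos = list(g1 = labels == "positive" & consensus,
                                   g2 = labels == "positive" & !consensus),
    cons_neg_vs_noncons_neg = list(g1 = labels == "negative" & consensus,
                                   g2 = labels == "negative" & !consensus)
  )
}

#' Per-feature statistical screening across comparison strategies
#'
#' For each strategy — positive vs negative windows, consensus vs
#' non-consensus positives, consensus vs non-consensus negatives — every
#' binary feature is tested with a chi-square test of independence (Yates
#' rule as in [chi2_independence()]) and every real-valued feature with a
#' two-tailed Mann-Whitney U test. BH adjustment is applied within each
#' strategy's family of tests.
#'
#' @param x Raw (unscaled) feature matrix.
#' @param labels Character vector "positive"/"negative".
#' @param consensus Logical consensus status per site.
#' @param strategies Which strategies to run.
#' @param alpha Significance level for the `significant` flag (on adjusted
#'   p-values).
#' @param yates_on Passed to [chi2_independence()].
#' @return data.frame, one row per (strategy, feature): test type,
#'   statistic, descriptives (proportions or means/SDs plus PS and z),
#'   raw and adjusted p, significance flag. Untestable features are kept
#'   as explicit rows with NA statistics.
#' @export
run_comparisons <- function(x, labels, consensus,
                            strategies = c("pos_vs_neg",
                                           "cons_pos_vs_noncons_pos",
                                           "cons_neg_vs_noncons_neg"),
                            alpha = 0.05, yates_on = "observed") {
  stopifnot(nrow(x) == length(labels), length(labels) == length(consensus))
  binary <- intersect(colnames(x), binary_feature_names())
  real <- intersect(colnames(x), real_feature_names())
  groups <- strategy_groups(labels, consensus)[strategies]
  out <- list()
  for (s in names(groups)) {
    g1 <- groups[[s]]$g1; g2 <- groups[[s]]$g2
    if (!any(g1) || !any(g2)) {
      warning("strategy ", s, " skipped: empty group")
      next
    }
    rows <- lapply(colnames(x), function(f) {
      v1 <- x[g1, f]; v2 <- x[g2, f]
      if (f %in% binary) {
        tab <- rbind(c(sum(v1 == 1), sum(v1 == 0)),
                     c(sum(v2 == 1), sum(v2 == 0)))
        ct <- chi2_independence(tab, yates_on = yates_on)
        data.frame(strategy = s, feature = f,
                   test = if (ct$untestable) "untestable"
                          else if (ct$corrected) "chi2_yates" else "chi2",
                   statistic = ct$statistic,
                   prop1 = mean(v1), prop2 = mean(v2),
                   mean1 = NA_real_, sd1 = NA_real_,
                   mean2 = NA_real_, sd2 = NA_real_,
                   PS = NA_real_, z = NA_real_, p = ct$p,
                   stringsAsFactors = FALSE)
      } else {
        mw <- mann_whitney(v1, v2)
        data.frame(strategy = s, feature = f, test = "mannwhitney",
                   statistic = mw$U,
                   prop1 = NA_real_, prop2 = NA_real_,
                   mean1 = mean(v1), sd1 = stats::sd(v1),
                   mean2 = mean(v2), sd2 = stats::sd(v2),
                   PS = mw$PS, z = mw$z, p = mw$p,
                   stringsAsFactors = FALSE)
      }
    })
    res <- do.call(rbind, rows)
    res$p_adj <- NA_real_
    testable <- !is.na(res$p)
    res$p_adj[testable] <- bh_adjust(res$p[testable])
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
    out[[s]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write statistical screening results to TSV (one file per strategy)
#'
#' @param results data.frame from [run_comparisons()].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_stats_results <- function(results, dir) {
  paths <- vapply(unique(results$strategy), function(s) {
    p <- file.path(dir, paste0("stats_", s, ".tsv"))
    utils::write.table(results[results$strategy == s, ], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
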
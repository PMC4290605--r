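# Chi-square with the Yates rule, Mann-Whitney PS/z, BH adjustment and
# the three-strategy screening.

test_that("chi-square matches hand computations and the Yates rule", {
  r <- chi2_independence(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_false(r$corrected)

  # all expected counts 12.5, statistic 4 * 7.5^2 / 12.5 = 18
  r <- chi2_independence(rbind(c(20, 5), c(5, 20)))
  expect_equal(r$statistic, 18)
  expect_false(r$corrected)

  # an observed cell below 5 triggers the continuity correction
  r <- chi2_independence(rbind(c(4, 353), c(712, 7197)))
  expect_true(r$corrected)

  # constant feature across both groups is untestable
  r <- chi2_independence(rbind(c(0, 10), c(0, 20)))
  expect_true(r$untestable)
  expect_true(is.na(r$p))
})

test_that("chi-square agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:300) {
    tab <- matrix(rpois(4, lambda = sample(c(2, 8, 40), 1)) +
                    matrix(c(1, 0, 0, 1), 2), 2, 2)
    mine <- chi2_independence(tab)
    if (mine$untestable) next
    ref <- suppressWarnings(chisq.test(tab, correct = mine$corrected))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U, PS and z follow the printed formulas", {
  # all positives above all negatives: U = n1 n2, PS = 1
  r <- mann_whitney(c(5, 6, 7), c(1, 2))
  expect_equal(r$U, 6)
  expect_equal(r$PS, 1)

  # identical groups: U = n1 n2 / 2, PS = 0.5, z = 0
  r <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$PS, 0.5)
  expect_equal(r$z, 0)

  # small mixed case against the exhaustive pair-counting oracle
  set.seed(9)
  for (i in 1:200) {
    pos <- sample(1:6, 4, TRUE); neg <- sample(1:6, 4, TRUE)
    r <- mann_whitney(pos, neg)
    expect_equal(r$U, brute_U(pos, neg))
    expect_equal(r$PS, r$U / 16)
    expect_equal(r$z, (r$U - 8) / sqrt(4 * 4 * 9 / 12))
  }
})

test_that("Mann-Whitney U matches the reference implementation", {
  set.seed(31)
  for (i in 1:300) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    pos <- round(rnorm(n1), sample(0:2, 1)); neg <- round(rnorm(n2), 2)
    r <- mann_whitney(pos, neg)
    ref <- suppressWarnings(wilcox.test(pos, neg))
    expect_equal(r$U, unname(ref$statistic), tolerance = 1e-9)
    # with the tie-corrected variance, p matches the reference's normal
    # approximation (no continuity correction)
    rt <- mann_whitney(pos, neg, tie_correction = TRUE)
    ref2 <- suppressWarnings(wilcox.test(pos, neg, exact = FALSE, correct = FALSE))
    expect_equal(rt$p, ref2$p.value, tolerance = 1e-9)
  }
})

test_that("PS orientations are complementary under midranks", {
  set.seed(5)
  for (i in 1:50) {
    a <- sample(1:8, 6, TRUE); b <- sample(1:8, 5, TRUE)
    expect_equal(mann_whitney(a, b)$PS + mann_whitney(b, a)$PS, 1)
  }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  # order invariance up to the preserved indexing
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("three-strategy screening tests every feature with the right test", {
  ds <- generate_dataset(synthetic_spec(n_sites = 900, seed = 5))
  enc <- encode_dataset(ds)
  res <- run_comparisons(enc$x, enc$labels, enc$consensus)
  expect_equal(sort(unique(res$strategy)),
               sort(c("pos_vs_neg", "cons_pos_vs_noncons_pos",
                      "cons_neg_vs_noncons_neg")))
  per <- table(res$strategy)
  expect_true(all(per == 137))
  expect_true(all(res$test[res$feature %in% real_feature_names()] == "mannwhitney"))
  expect_true(all(res$test[!res$feature %in% real_feature_names()]
                  %in% c("chi2", "chi2_yates", "untestable")))
  # both corrected and uncorrected chi-square paths are exercised
  expect_true(any(res$test == "chi2") && any(res$test == "chi2_yates"))
  # Mann-Whitney rows carry PS and z descriptives
  mw <- res[res$test == "mannwhitney", ]
  expect_true(all(is.finite(mw$PS)) && all(is.finite(mw$z)))
  # adjusted never below raw
  ok <- !is.na(res$p_adj)
  expect_true(all(res$p_adj[ok] >= res$p[ok] - 1e-12))
  # the planted Glu-at-+2 enrichment is detected in strategy 1
  hit <- res[res$strategy == "pos_vs_neg" & res$feature == "w+E_2", ]
  expect_lt(hit$p_adj, 0.05)
  expect_gt(hit$prop1, hit$prop2)

  f <- withr::local_tempdir()
  paths <- write_stats_results(res, f)
  expect_true(all(file.exists(paths)))
})

test_that("screening controls the false positive rate under the null", {
  # equal effects across classes: labels carry no information
  spec <- synthetic_spec(
    n_sites = 700,
    effects = list(e_plus2 = c(pos = 0.07, neg = 0.07),
                   k_plus2 = c(pos = 0.09, neg = 0.09),
                   k_minus3 = c(pos = 0.09, neg = 0.09),
                   r_plus2 = c(pos = 0.06, neg = 0.06),
                   r_minus3 = c(pos = 0.07, neg = 0.07),
                   h_plus2 = c(pos = 0.03, neg = 0.03),
                   p_plus3 = c(pos = 0.06, neg = 0.06)),
    flexible = c(pos = 0.44, neg = 0.44),
    disorder = c(pos = 0.39, neg = 0.39),
    noncons_pos_e_plus2 = 0.07, seed = 8)
  fracs <- vapply(1:5, function(s) {
    spec$seed <- s
    ds <- generate_dataset(spec)
    enc <- encode_dataset(ds)
    res <- run_comparisons(enc$x, enc$labels, enc$consensus,
                           strategies = "pos_vs_neg")
    # consensus-linked features still differ by construction of the class
    # mix; exclude them and judge the null features only
    motif <- c("Consensus", "w+E_2", "w+D_2", "w+2_Hydro",
               grep("^w-[IVLMAP]_3$", res$feature, value = TRUE),
               "w-3_Hydro", "wDE")
    null_res <- res[!res$feature %in% motif & !is.na(res$p_adj), ]
    mean(null_res$significant)
  }, numeric(1))
  expect_lt(mean(fracs), 0.10)
})

test_that("empty strategy groups are skipped with a warning", {
  x <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("w-1_Hydro", "wDE")))
  x[, "wDE"] <- rep(0:1, 10)
  labels <- rep(c("positive", "negative"), each = 10)
  expect_warning(expect_warning(
    res <- run_comparisons(x, labels, consensus = rep(FALSE, 20)),
    "skipped"), "skipped")
  expect_true(all(res$strategy != "cons_pos_vs_noncons_pos"))
})
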
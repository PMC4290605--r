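# The synthetic-data generator: determinism, class structure, planted
# effect sizes, file round-trips.

test_that("generation is byte-identical given the same seed", {
  spec <- synthetic_spec(n_sites = 300, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(spec), d1)
  write_dataset(generate_dataset(spec), d2)
  for (f in c("proteins.fasta", "sites.tsv", "annotations.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  write_dataset(generate_dataset(synthetic_spec(n_sites = 300, seed = 100)), d2)
  expect_false(identical(readLines(file.path(d1, "proteins.fasta")),
                         readLines(file.path(d2, "proteins.fasta"))))
})

test_that("every labeled position is a lysine and classes are consistent", {
  ds <- generate_dataset(synthetic_spec(n_sites = 400, seed = 3))
  w <- site_windows(ds$proteins, ds$sites)
  chars <- mapply(function(id, pos) {
    substr(ds$proteins$sequence[ds$proteins$id == id], pos, pos)
  }, ds$sites$protein_id, ds$sites$position)
  expect_true(all(chars == "K"))
  expect_equal(consensus_status(w),
               ds$sites$site_class %in% c("cons_pos", "cons_neg"))
  expect_equal(ds$sites$label == "positive",
               ds$sites$site_class %in% c("cons_pos", "noncons_pos"))
  # protein lengths within the configured band
  expect_true(all(ds$proteins$length >= 100 & ds$proteins$length <= 600))
})

test_that("realized class counts follow the configured mix", {
  ds <- generate_dataset(synthetic_spec(n_sites = 5000, seed = 13))
  counts <- table(factor(ds$sites$site_class,
                         c("cons_pos", "noncons_pos", "cons_neg", "noncons_neg")))
  expect_equal(sum(counts), 5000)
  mix <- synthetic_spec()$class_mix
  for (cl in names(mix)) {
    # 99.9% binomial band around the expected count
    band <- qbinom(c(5e-4, 1 - 5e-4), 5000, mix[[cl]])
    expect_gte(counts[[cl]], band[1])
    expect_lte(counts[[cl]], band[2])
  }
})

test_that("planted Glu-at-+2 frequency matches its target in positives", {
  # roughly 400 positive and 10,000 negative windows
  mix <- c(cons_pos = 0.75 * 400 / 10400, noncons_pos = 0.25 * 400 / 10400,
           cons_neg = 0.034, noncons_neg = NA)
  mix["noncons_neg"] <- 1 - sum(mix, na.rm = TRUE)
  ds <- generate_dataset(synthetic_spec(n_sites = 10400, class_mix = mix,
                                        seed = 17))
  w <- site_windows(ds$proteins, ds$sites)
  pos <- w$label == "positive"
  n_e <- sum(w$wp2[pos] == "E")
  band <- qbinom(c(0.005, 0.995), sum(pos), 0.81)
  expect_gte(n_e, band[1])
  expect_lte(n_e, band[2])
  # depletion effects present: extra Lys at +2 rarer in positives
  expect_lt(mean(w$wp2[pos] == "K"), mean(w$wp2[!pos] == "K"))
  # Pro at +3 enriched in positives
  expect_gt(mean(w$wp3[pos] == "P"), mean(w$wp3[!pos] == "P"))
})

test_that("flexibility and disorder are enriched at positive sites", {
  ds <- generate_dataset(synthetic_spec(n_sites = 4000, seed = 19))
  enc <- encode_dataset(ds)
  pos <- enc$labels == "positive"
  expect_gt(mean(enc$x[pos, "Flexible"]), mean(enc$x[!pos, "Flexible"]))
  expect_gt(mean(enc$x[pos, "DisorderBinary"]), mean(enc$x[!pos, "DisorderBinary"]))
  # the binary disorder feature is the 0.5 cutoff of the real one
  expect_equal(enc$x[, "DisorderBinary"],
               as.numeric(enc$x[, "DisorderReal"] >= 0.5))
})

test_that("datasets round-trip through the on-disk formats", {
  ds <- generate_dataset(synthetic_spec(n_sites = 250, seed = 23))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_dataset(d)
  expect_equal(back$proteins, ds$proteins)
  expect_equal(back$sites, ds$sites)
  expect_equal(back$annotations$flexible, ds$annotations$flexible)
  expect_equal(back$annotations$disorder, ds$annotations$disorder,
               tolerance = 1e-12)
  # reloaded consensus positives still satisfy the motif
  w <- site_windows(back$proteins, back$sites)
  expect_true(all(consensus_status(w)[back$sites$site_class == "cons_pos"]))
  expect_false(any(consensus_status(w)[back$sites$site_class %in%
                                         c("noncons_pos", "noncons_neg")]))
})

test_that("equal effects across classes erase the learnable signal", {
  spec <- synthetic_spec(
    n_sites = 450,
    effects = list(e_plus2 = c(pos = 0.07, neg = 0.07),
                   k_plus2 = c(pos = 0.09, neg = 0.09),
                   k_minus3 = c(pos = 0.09, neg = 0.09),
                   r_plus2 = c(pos = 0.06, neg = 0.06),
                   r_minus3 = c(pos = 0.07, neg = 0.07),
                   h_plus2 = c(pos = 0.03, neg = 0.03),
                   p_plus3 = c(pos = 0.06, neg = 0.06)),
    # keep positives consensus-free so the motif carries no label signal
    class_mix = c(cons_pos = 0, noncons_pos = 0.3,
                  cons_neg = 0, noncons_neg = 0.7),
    flexible = c(pos = 0.44, neg = 0.44),
    disorder = c(pos = 0.39, neg = 0.39),
    noncons_pos_e_plus2 = 0.07, seed = 29)
  ds <- generate_dataset(spec)
  enc <- encode_dataset(ds)
  cv <- cross_validate(enc$x, enc$labels,
                       function(x, y) sumo_svm(x, y, config = sumo_svm_config(
                         cost = 8, gamma = 2^-5,
                         class_weights = c(negative = 1, positive = 2))),
                       n_folds = 3, repeats = 2, seed = 29)
  expect_lt(abs(cv$mean[["MCC"]]), 0.15)
})

test_that("infeasible class mixes are refused", {
  expect_error(synthetic_spec(class_mix = c(cons_pos = 0.5, noncons_pos = 0.5,
                                            cons_neg = 0.2, noncons_neg = 0.2)))
  expect_error(generate_dataset(synthetic_spec(
    n_sites = 3, class_mix = c(cons_pos = 1, noncons_pos = 0,
                               cons_neg = 0, noncons_neg = 0))),
    "infeasible")
})
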
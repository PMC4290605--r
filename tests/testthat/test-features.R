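# The 137-feature encoding and min-max scaling.

encode_one <- function(sequence, position = NULL, flexible = 0, disorder = 0) {
  fx <- tiny_protein(sequence, flexible = flexible, disorder = disorder)
  w <- extract_lysine_windows(fx$proteins)
  if (!is.null(position)) w <- w[w$position == position, , drop = FALSE]
  encode_sites(w, fx$proteins, fx$annotations)
}

test_that("feature space decomposes into 137 = 126 binary + 11 real", {
  fn <- feature_names()
  expect_length(fn, 137)
  expect_false(anyDuplicated(fn) > 0)
  expect_length(binary_feature_names(), 126)
  expect_length(real_feature_names(), 11)
  expect_setequal(fn, c(binary_feature_names(), real_feature_names()))
  cb <- feature_codebook()
  expect_equal(cb$feature, fn)
  expect_true(all(nzchar(cb$definition)))
})

test_that("an encoded window is 137-wide with binary features in {0,1}", {
  x <- encode_one("AAIKSEA")
  expect_equal(dim(x), c(1L, 137L))
  expect_equal(colnames(x), feature_names())
  expect_true(all(x[, binary_feature_names()] %in% c(0, 1)))
  # direct reading of the encoding definitions
  expect_equal(x[1, "w-I_3"], c(`w-I_3` = 1))
  expect_equal(unname(x[1, "w+E_2"]), 1)
  expect_equal(unname(x[1, "Consensus"]), 1)
  expect_equal(unname(x[1, "wDE"]), 1)
  expect_equal(unname(x[1, "wK"]), 0)
  # one-hot: exactly one indicator per non-padded slot
  onehot <- grepl("^w[-+][A-Z]_[123]$", colnames(x))
  expect_equal(sum(x[1, onehot]), 6)
})

test_that("padded and non-standard slots contribute zeros", {
  x <- encode_one("KAAA")  # all upstream slots padded
  up <- grepl("^w-[A-Z]_[123]$", colnames(x))
  expect_true(all(x[1, up] == 0))
  expect_equal(unname(x[1, "BeforeVol"]), 0)
  expect_equal(unname(x[1, c("w-1_Hydro", "w-2_Hydro", "w-3_Hydro")]),
               c(0, 0, 0))
  xx <- encode_one("XXXKXXX")  # non-standard residues carry no identity
  expect_true(all(xx[1, grepl("^w[-+][A-Z]_", colnames(xx))] == 0))
  expect_equal(unname(xx[1, "BeforeVol"]), 0)
})

test_that("hydrophobicity features look up the Hopp-Woods table per slot", {
  fx <- tiny_protein("WDAKRGC")
  w <- extract_lysine_windows(fx$proteins)
  h <- hydrophobicity_features(w)
  hw <- hopp_woods_scale()
  expect_equal(unname(h[1, ]),
               unname(hw[c("W", "D", "A", "R", "G", "C")]))
  # locality: changing one slot leaves the others untouched
  fx2 <- tiny_protein("YDAKRGC")
  h2 <- hydrophobicity_features(extract_lysine_windows(fx2$proteins))
  expect_equal(h[1, -1], h2[1, -1])
  expect_equal(unname(h2[1, 1]), unname(hw["Y"]))
})

test_that("composition flags detect acidic residues and extra lysines", {
  flags <- function(s, pos = 4L) {
    w <- extract_lysine_windows(s)
    unname(composition_flags(w[w$position == pos, ])[1, ])
  }
  expect_equal(flags("AAAKAAA"), c(0, 0))
  expect_equal(flags("ADAKAAA"), c(1, 0))
  expect_equal(flags("KAAKAAE"), c(1, 1))
})

test_that("terminal flag and signed length use exact fractional bounds", {
  expect_equal(as.numeric(terminal_and_length(5, 100)), c(1, -100))
  expect_equal(as.numeric(terminal_and_length(50, 100)), c(0, 100))
  expect_equal(as.numeric(terminal_and_length(95, 100)), c(1, -100))
  expect_equal(as.numeric(terminal_and_length(10, 100)), c(1, -100))  # 10 <= 10
  expect_equal(as.numeric(terminal_and_length(90, 100)), c(0, 100))   # 90 <= 90
  expect_equal(as.numeric(terminal_and_length(91, 100)), c(1, -100))  # 91 > 90
})

test_that("sub-window volumes sum Kharakoz values and difference is exact", {
  fx <- tiny_protein("WDAKRGC")
  w <- extract_lysine_windows(fx$proteins)
  v <- subwindow_volumes(w)
  kv <- kharakoz_volumes()
  expect_equal(unname(v[1, "BeforeVol"]), sum(kv[c("W", "D", "A")]))
  expect_equal(unname(v[1, "AfterVol"]), sum(kv[c("R", "G", "C")]))
  expect_equal(unname(v[1, "Difference"]),
               unname(v[1, "AfterVol"] - v[1, "BeforeVol"]))
  # symmetric sub-windows give zero difference
  v2 <- subwindow_volumes(extract_lysine_windows("ADGKADG"))
  expect_equal(unname(v2[1, "Difference"]), 0)
})

test_that("disorder features apply the inclusive 0.5 cutoff", {
  ann <- data.frame(protein_id = "p", position = 1:3,
                    flexible = c(1, 0, 0), disorder = c(0.7, 0.3, 0.5))
  d <- disorder_features(ann, rep("p", 3), 1:3)
  expect_equal(unname(d[, "DisorderBinary"]), c(1, 0, 1))
  expect_equal(unname(d[, "DisorderReal"]), c(0.7, 0.3, 0.5))
  expect_equal(unname(d[, "Flexible"]), c(1, 0, 0))
  expect_error(disorder_features(ann, "p", 9L),
               "no flexibility/disorder annotation for p position 9")
})

test_that("encoding is a pure function of its inputs", {
  x1 <- encode_one("IDAKREC", flexible = 1, disorder = 0.61)
  x2 <- encode_one("IDAKREC", flexible = 1, disorder = 0.61)
  expect_identical(x1, x2)
})

test_that("feature ablation drops the named columns", {
  fx <- tiny_protein("AAIKSEA")
  w <- extract_lysine_windows(fx$proteins)
  x <- encode_sites(w, fx$proteins, fx$annotations,
                    exclude = c("Flexible", "DisorderReal", "DisorderBinary"))
  expect_equal(ncol(x), 134)
  expect_false(any(c("Flexible", "DisorderReal", "DisorderBinary")
                   %in% colnames(x)))
  expect_error(encode_sites(w, fx$proteins, fx$annotations,
                            exclude = "NoSuchFeature"), "unknown feature")
})

test_that("min-max scaling maps the training range onto [0,1]", {
  set.seed(3)
  x <- cbind(a = runif(20, -3, 7), b = rep(2, 20), c = rnorm(20))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(min(xs[, "a"]), 0)
  expect_equal(max(xs[, "a"]), 1)
  expect_true(all(xs[, "b"] == 0))          # constant column -> 0
  # test values outside the training range are not clamped
  xt <- cbind(a = 10, b = 2, c = 0)
  expect_gt(apply_scaler(sc, xt)[, "a"], 1)
  # idempotence on already-scaled data
  expect_equal(apply_scaler(fit_scaler(xs), xs), xs, tolerance = 1e-12)
  # mismatched feature sets are refused
  expect_error(apply_scaler(sc, cbind(a = 1, z = 2, c = 3)),
               "does not match")
})

test_that("binary features survive scaling when both values occur", {
  set.seed(4)
  x <- cbind(bin = sample(0:1, 30, TRUE), real = rnorm(30))
  xs <- apply_scaler(fit_scaler(x), x)
  expect_equal(xs[, "bin"], x[, "bin"])
})

test_that("feature matrix and sparse writers round-trip / format correctly", {
  fx <- tiny_protein("AAIKSEAKLM")
  w <- extract_lysine_windows(fx$proteins)
  w$label <- c("positive", "negative")
  x <- encode_sites(w, fx$proteins, fx$annotations)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(x, w, f)
  back <- read_feature_matrix(f)
  expect_equal(back$x, x)
  expect_equal(back$sites$label, w$label)

  sp <- withr::local_tempfile(fileext = ".txt")
  write_sparse_matrix(x, w$label, sp)
  lines <- readLines(sp)
  expect_length(lines, 2)
  expect_match(lines[1], "^\\+1( \\d+:-?[0-9.]+)+$")
  expect_match(lines[2], "^-1 ")
  # indices are 1-based positions of the non-zero entries in canonical order
  first <- as.integer(sub(":.*", "", strsplit(lines[1], " ")[[1]][2]))
  expect_equal(first, which(x[1, ] != 0)[1], ignore_attr = TRUE)
})

test_that("annotation TSV round-trips and validates ranges", {
  ann <- data.frame(protein_id = "p", position = 1:4,
                    flexible = c(0, 1, 0, 1),
                    disorder = c(0, 0.25, 0.5, 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  expect_equal(read_annotations(f), ann)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tflexible\tdisorder", "p\t1\t0\t1.4"), bad)
  expect_error(read_annotations(bad), "0,1")
})
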
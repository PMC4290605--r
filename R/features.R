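# 137-feature encoding of lysine-centered windows and min-max scaling.
#
# Feature layout (canonical order, see feature_names()):
#   120 positional one-hot indicators, 6 per-slot Hopp-Woods values,
#   Consensus, wDE, wK, Flexible, DisorderReal, DisorderBinary,
#   TerminalBinary, SignedLength, BeforeVol, AfterVol, Difference.
# Padded and non-standard residues contribute 0 to one-hot, hydrophobicity
# and volume features: 0 is the neutral value under min-max scaling and
# keeps the dimensionality fixed for near-terminal sites.

#' Read a flexibility/disorder annotation TSV
#'
#' Columns `protein_id`, `position` (1-based), `flexible` (0/1),
#' `disorder` (real in \[0,1\]); '#' lines are comments. One row per
#' annotated residue.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the four columns.
#' @export
read_annotations <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "flexible", "disorder")
  if (!all(need %in% names(x)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (any(x$disorder < 0 | x$disorder > 1))
    stop("disorder tendency must lie in [0,1]")
  if (!all(x$flexible %in% c(0, 1)))
    stop("flexible flag must be 0/1")
  x$position <- as.integer(x$position)
  x[need]
}

#' Write a flexibility/disorder annotation TSV
#'
#' @param annotations data.frame as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[c("protein_id", "position", "flexible", "disorder")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Null flexibility/disorder annotations
#'
#' All-zero annotations so the pipeline can run without external
#' flexibility/disorder predictions (the corresponding features then carry
#' no information, as in the all-zero ablation).
#'
#' @param proteins Protein set.
#' @return Annotation data.frame covering every residue.
#' @export
null_annotations <- function(proteins) {
  do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    data.frame(protein_id = proteins$id[i],
               position = seq_len(proteins$length[i]),
               flexible = 0, disorder = 0, stringsAsFactors = FALSE)
  }))
}

#' Per-slot hydrophobicity features
#'
#' @param windows Window data.frame.
#' @param scale Named per-residue scale; default Hopp-Woods.
#' @return Numeric matrix, one column per slot (`w-1_Hydro` .. `w+3_Hydro`);
#'   padded/non-standard slots give 0.
#' @export
hydrophobicity_features <- function(windows, scale = hopp_woods_scale()) {
  out <- vapply(slot_ids(), function(s) {
    v <- scale[windows[[s]]]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(nrow(windows)))
  out <- matrix(out, nrow = nrow(windows),
                dimnames = list(NULL, c(sprintf("w-%d_Hydro", 1:3),
                                        sprintf("w+%d_Hydro", 1:3))))
  out
}

#' Position-unspecific composition flags
#'
#' `wDE`: any flanking slot holds Asp or Glu. `wK`: any flanking slot holds
#' an extra lysine (the central K does not count).
#'
#' @param windows Window data.frame.
#' @return Two-column 0/1 matrix `wDE`, `wK`.
#' @export
composition_flags <- function(windows) {
  slots <- as.matrix(windows[slot_ids()])
  cbind(wDE = as.numeric(rowSums(slots == "D" | slots == "E", na.rm = TRUE) > 0),
        wK  = as.numeric(rowSums(slots == "K", na.rm = TRUE) > 0))
}

#' Terminal-region flag and signed protein length
#'
#' A site is "terminal" when it lies within 10% of either terminus
#' (position <= 0.1 L or position > 0.9 L, exact fractional comparison).
#' SignedLength is the protein length, negated for terminal sites.
#'
#' @param position 1-based site position(s).
#' @param length Protein length(s).
#' @return Two-column matrix `TerminalBinary`, `SignedLength`.
#' @export
terminal_and_length <- function(position, length) {
  stopifnot(all(position >= 1), all(position <= length))
  terminal <- position <= 0.1 * length | position > 0.9 * length
  cbind(TerminalBinary = as.numeric(terminal),
        SignedLength = ifelse(terminal, -length, length))
}

#' Sub-window volume features
#'
#' Sums of per-residue volumes over the upstream and downstream 3-residue
#' sub-windows, plus their difference (downstream minus upstream).
#'
#' @param windows Window data.frame.
#' @param volumes Named per-residue volume table; default Kharakoz.
#' @return Three-column matrix `BeforeVol`, `AfterVol`, `Difference`.
#' @export
subwindow_volumes <- function(windows, volumes = kharakoz_volumes()) {
  vol <- function(s) {
    v <- volumes[windows[[s]]]
    v[is.na(v)] <- 0
    unname(v)
  }
  before <- vol("wm1") + vol("wm2") + vol("wm3")
  after <- vol("wp1") + vol("wp2") + vol("wp3")
  cbind(BeforeVol = before, AfterVol = after, Difference = after - before)
}

#' Flexibility/disorder features for central lysines
#'
#' @param annotations Annotation data.frame.
#' @param protein_id,position Vectors identifying the central lysines.
#' @return Three-column matrix `Flexible`, `DisorderReal`, `DisorderBinary`
#'   (tendency >= 0.5 maps to 1).
#' @export
disorder_features <- function(annotations, protein_id, position) {
  key <- paste(annotations$protein_id, annotations$position)
  idx <- match(paste(protein_id, position), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("no flexibility/disorder annotation for %s position %d",
                 protein_id[bad], position[bad]))
  }
  cbind(Flexible = annotations$flexible[idx],
        DisorderReal = annotations$disorder[idx],
        DisorderBinary = as.numeric(annotations$disorder[idx] >= 0.5))
}

#' Encode sites as the 137-feature matrix
#'
#' Builds the full feature matrix for a set of windows. Feature columns
#' follow the canonical order of [feature_names()]; `exclude` drops named
#' features (e.g. the flexibility/disorder ablation).
#'
#' @param windows Window data.frame (one row per site).
#' @param proteins Protein set the windows came from.
#' @param annotations Flexibility/disorder annotations covering every
#'   central lysine; default [null_annotations()].
#' @param hydro_scale,volume_scale Per-residue lookup tables.
#' @param exclude Character vector of feature names to drop.
#' @return Numeric matrix, rows = sites, columns = features.
#' @export
encode_sites <- function(windows, proteins,
                         annotations = NULL,
                         hydro_scale = hopp_woods_scale(),
                         volume_scale = kharakoz_volumes(),
                         exclude = character(0)) {
  n <- nrow(windows)
  if (is.null(annotations)) annotations <- null_annotations(proteins)
  aa <- aa_alphabet()
  onehot <- matrix(0, n, 120L)
  cn <- character(120L)
  j <- 0L
  for (side in c("-", "+")) for (i in 1:3) {
    slot <- windows[[paste0(if (side == "-") "wm" else "wp", i)]]
    hit <- match(slot, aa)
    rows <- which(!is.na(hit))
    onehot[cbind(rows, j + hit[rows])] <- 1
    cn[j + seq_along(aa)] <- sprintf("w%s%s_%d", side, aa, i)
    j <- j + 20L
  }
  colnames(onehot) <- cn
  plen <- proteins$length[match(windows$protein_id, proteins$id)]
  if (anyNA(plen)) stop("window references unknown protein id")
  x <- cbind(
    onehot,
    hydrophobicity_features(windows, hydro_scale),
    Consensus = as.numeric(consensus_status(windows)),
    composition_flags(windows),
    disorder_features(annotations, windows$protein_id, windows$position),
    terminal_and_length(windows$position, plen),
    subwindow_volumes(windows, volume_scale)
  )
  x <- x[, feature_names(), drop = FALSE]
  if (length(exclude)) {
    unknown <- setdiff(exclude, colnames(x))
    if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
    x <- x[, setdiff(colnames(x), exclude), drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Fit a min-max scaler on a training matrix
#'
#' Records per-feature minima and maxima of the training data; test data
#' are later scaled with these same parameters.
#'
#' @param x Training feature matrix.
#' @return Object of class `sumo_scaler`.
#' @export
fit_scaler <- function(x) {
  if (!is.matrix(x) || nrow(x) == 0) stop("training matrix must be non-empty")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 features = colnames(x)),
            class = "sumo_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Scaled value = (x - min) / (max - min). Constant training columns map
#' to 0. Values outside the training range are not clamped, so test values
#' may fall outside \[0,1\].
#'
#' @param scaler A `sumo_scaler`.
#' @param x Feature matrix with the scaler's feature columns.
#' @return Scaled matrix of the same shape.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "sumo_scaler"))
  if (!identical(colnames(x), scaler$features))
    stop("feature set does not match the fitted scaler")
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out
}

#' Write a feature matrix TSV
#'
#' Header row of site metadata plus the canonical feature names.
#'
#' @param x Feature matrix.
#' @param sites data.frame with `protein_id`, `position`, `label` rows
#'   parallel to `x`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, sites, path) {
  stopifnot(nrow(x) == nrow(sites))
  df <- cbind(sites[c("protein_id", "position", "label")],
              as.data.frame(x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix TSV written by [write_feature_matrix()]
#'
#' @param path Path to the TSV.
#' @return List with `x` (matrix) and `sites` (data.frame).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("protein_id", "position", "label")
  list(x = as.matrix(df[setdiff(names(df), meta)]), sites = df[meta])
}

#' Write a sparse "label index:value" matrix
#'
#' The sparse vector format used by common SVM trainers: one line per
#' site, label +1/-1 followed by 1-based `index:value` pairs for the
#' non-zero features in canonical column order.
#'
#' @param x Feature matrix.
#' @param labels Character vector "positive"/"negative".
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sparse_matrix <- function(x, labels, path) {
  stopifnot(nrow(x) == length(labels))
  lab <- ifelse(labels == "positive", "+1", "-1")
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(c(lab[i], sprintf("%d:%g", nz, x[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
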
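# Sequence ingestion and lysine-centered window extraction.
#
# All coordinates are 1-based. A window spans 3 residues on each side of a
# central lysine; slots that fall outside the protein are "padded" and are
# stored as NA. Slot numbering follows the sub-window convention: the
# upstream sub-window is numbered w-_1..w-_3 with w-_3 adjacent to the
# lysine, the downstream sub-window w+_1..w+_3 with w+_1 adjacent to it.

PSI_SET <- c("I", "V", "L", "M", "A", "P")

new_protein_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id))
    stop("duplicate protein ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- !nzchar(sequence)
  if (any(bad))
    stop("empty sequence for protein(s): ", paste(id[bad], collapse = ", "))
  out <- data.frame(id = as.character(unname(id)),
                    sequence = toupper(as.character(unname(sequence))),
                    length = nchar(sequence),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  names(out$length) <- NULL
  out
}

#' Read protein sequences from a FASTA file
#'
#' Standard FASTA dialect: '>' headers, wrapped sequence lines. The first
#' whitespace-delimited token of each header is taken as the protein id.
#' Sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    warning("FASTA file contains no sequences: ", path)
    return(new_protein_set(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1)
  if (any(!nzchar(ids))) stop("malformed FASTA header (empty id) in ", path)
  new_protein_set(ids, as.character(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Extract all lysine-centered windows from proteins
#'
#' One window per 'K' residue, ordered by protein then by position. Slots
#' beyond the protein termini are padded and recorded as NA.
#'
#' @param proteins data.frame as returned by [read_fasta()], or a single
#'   sequence given as a character scalar (id "protein1").
#' @return data.frame with columns `protein_id`, `position`, the six slot
#'   columns `wm1..wm3`, `wp1..wp3` (single characters, NA where padded).
#' @export
extract_lysine_windows <- function(proteins) {
  if (is.character(proteins))
    proteins <- new_protein_set("protein1", proteins)
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    n <- proteins$length[i]
    pos <- which(strsplit(s, "")[[1]] == "K")
    if (length(pos) == 0) return(NULL)
    slot_at <- function(off) {
      p <- pos + off
      r <- rep(NA_character_, length(pos))
      ok <- which(p >= 1 & p <= n)
      if (length(ok)) r[ok] <- substring(s, p[ok], p[ok])
      r
    }
    data.frame(protein_id = proteins$id[i], position = pos,
               wm1 = slot_at(-3L), wm2 = slot_at(-2L), wm3 = slot_at(-1L),
               wp1 = slot_at(1L), wp2 = slot_at(2L), wp3 = slot_at(3L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), position = integer(0),
                      wm1 = character(0), wm2 = character(0), wm3 = character(0),
                      wp1 = character(0), wp2 = character(0), wp3 = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Windows at labeled sites
#'
#' Extract the windows for an explicit table of (protein, position) sites,
#' carrying the site labels along. Every listed position must hold a
#' lysine in its protein.
#'
#' @param proteins Protein set.
#' @param sites data.frame with columns `protein_id`, `position` and
#'   optionally `label`.
#' @return Window data.frame as [extract_lysine_windows()] plus a `label`
#'   column (`"unknown"` when absent from `sites`).
#' @export
site_windows <- function(proteins, sites) {
  all_w <- extract_lysine_windows(proteins)
  key <- paste(all_w$protein_id, all_w$position)
  skey <- paste(sites$protein_id, sites$position)
  idx <- match(skey, key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("site %s:%d is not a lysine in the given proteins",
                 sites$protein_id[bad], sites$position[bad]))
  }
  w <- all_w[idx, , drop = FALSE]
  w$label <- if ("label" %in% names(sites)) as.character(sites$label) else "unknown"
  rownames(w) <- NULL
  w
}

#' Consensus-motif status of windows
#'
#' A window matches the sumoylation consensus motif (Psi-K-x-E/D,
#' operationalised as `[IVLMAP]K.[DE]`) when the residue immediately before
#' the central lysine is one of I/V/L/M/A/P and the residue two after it is
#' D or E. Padded slots never match.
#'
#' @param windows Window data.frame.
#' @return Logical vector, one element per window.
#' @export
consensus_status <- function(windows) {
  !is.na(windows$wm3) & windows$wm3 %in% PSI_SET &
    !is.na(windows$wp2) & windows$wp2 %in% c("D", "E")
}

#' Consensus-motif regular-expression scan
#'
#' The baseline predictor: report every lysine whose 4-mer context matches
#' `[IVLMAP]K.[DE]`. Each lysine is judged on its own context, so
#' overlapping motifs are all reported.
#'
#' @param proteins Protein set, or a single sequence string.
#' @return data.frame with columns `protein_id`, `position`.
#' @export
scan_regex <- function(proteins) {
  w <- extract_lysine_windows(proteins)
  w[consensus_status(w), c("protein_id", "position")]
}

#' Read a site-label TSV
#'
#' Columns `protein_id`, `position` (1-based), `label` in
#' positive/negative; lines starting with '#' are ignored.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the three columns, `position` integer.
#' @export
read_site_labels <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(x)))
    stop("site TSV must have columns: ", paste(need, collapse = ", "))
  bad <- !x$label %in% c("positive", "negative")
  if (any(bad))
    stop("invalid label(s): ", paste(unique(x$label[bad]), collapse = ", "))
  x$position <- as.integer(x$position)
  x[need]
}

#' Write a site-label TSV
#'
#' @param sites data.frame with `protein_id`, `position`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_labels <- function(sites, path) {
  utils::write.table(sites[c("protein_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dataset accounting by site class
#'
#' Tabulates sites into the four classes (consensus/non-consensus crossed
#' with positive/negative), with percentages of the total and the
#' non-consensus fraction among positives.
#'
#' @param labels Character vector, "positive"/"negative".
#' @param consensus Logical vector of consensus status, same length.
#' @return List with `table` (class, count, percent) and
#'   `nonconsensus_positive_fraction`.
#' @export
dataset_accounting <- function(labels, consensus) {
  stopifnot(length(labels) == length(consensus))
  cls <- factor(paste(ifelse(labels == "positive", "positive", "negative"),
                      ifelse(consensus, "consensus", "non-consensus")),
                levels = c("positive consensus", "positive non-consensus",
                           "negative consensus", "negative non-consensus"))
  counts <- as.vector(table(cls))
  tab <- data.frame(class = levels(cls), count = counts,
                    percent = round(100 * counts / length(labels), 2),
                    stringsAsFactors = FALSE)
  npos <- sum(labels == "positive")
  list(table = tab,
       nonconsensus_positive_fraction =
         if (npos > 0) counts[2] / npos else NA_real_)
}
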
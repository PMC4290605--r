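# Physicochemical lookup tables and the canonical feature-name registry.
#
# Both scales are transcribed from their primary sources; neither is fitted
# or tuned by this package. Non-standard residues (X, B, Z, U, ...) are not
# listed and contribute 0 wherever a scale value is required.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in alphabetical order. This
#' ordering fixes the canonical order of the positional one-hot features.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Hopp-Woods hydrophilicity scale
#'
#' Per-residue hydrophilicity values (Hopp & Woods 1981). Positive values
#' are hydrophilic; the six flanking-slot hydrophobicity features are direct
#' lookups into this table.
#'
#' @return Named numeric vector over [aa_alphabet()].
#' @export
hopp_woods_scale <- function() {
  c(A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
    G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
    M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
    S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
}

#' Kharakoz amino-acid volumes
#'
#' Partial molar volumes of amino-acid residues in aqueous solution
#' (Kharakoz 1997), in cm^3/mol at 25 degrees C. Summed over each 3-residue
#' sub-window to form the BeforeVol / AfterVol features.
#'
#' @return Named numeric vector over [aa_alphabet()].
#' @export
kharakoz_volumes <- function() {
  c(A =  60.4, C =  73.4, D =  73.8, E =  85.9, F = 121.5,
    G =  43.2, H =  98.8, I = 107.7, K = 108.5, L = 107.8,
    M = 105.3, N =  78.0, P =  82.3, Q =  93.9, R = 127.3,
    S =  60.6, T =  76.8, V =  90.8, W = 143.9, Y = 123.6)
}

# Window slot ids in canonical order. wm3 and wp1 are adjacent to the
# central lysine; numbering increases away from the window start, so the
# residue just before K is slot 3 of the upstream ("-") sub-window.
slot_ids <- function() c("wm1", "wm2", "wm3", "wp1", "wp2", "wp3")

slot_display <- function() {
  c(wm1 = "w-_1", wm2 = "w-_2", wm3 = "w-_3",
    wp1 = "w+_1", wp2 = "w+_2", wp3 = "w+_3")
}

#' Canonical feature names
#'
#' The ordered names of the 137 features used by the encoder: 120
#' positional one-hot indicators (20 amino acids at each of 6 flanking
#' slots, named e.g. `w-A_3` for alanine just before the central lysine),
#' 6 per-slot hydrophobicity values, then the consensus flag, the
#' position-unspecific charge/lysine flags, flexibility and disorder
#' features, terminal/length features and the three sub-window volume
#' features.
#'
#' @return Character vector of length 137.
#' @export
feature_names <- function() {
  aa <- aa_alphabet()
  onehot <- c(
    as.vector(vapply(1:3, function(i) sprintf("w-%s_%d", aa, i), character(20))),
    as.vector(vapply(1:3, function(i) sprintf("w+%s_%d", aa, i), character(20)))
  )
  hydro <- c(sprintf("w-%d_Hydro", 1:3), sprintf("w+%d_Hydro", 1:3))
  c(onehot, hydro,
    "Consensus", "wDE", "wK", "Flexible", "DisorderReal", "DisorderBinary",
    "TerminalBinary", "SignedLength", "BeforeVol", "AfterVol", "Difference")
}

#' Names of the binary features
#'
#' The 126 features that take only values 0/1 before scaling: the 120
#' one-hot indicators plus Consensus, wDE, wK, Flexible, DisorderBinary and
#' TerminalBinary.
#'
#' @return Character vector of length 126.
#' @export
binary_feature_names <- function() {
  fn <- feature_names()
  setdiff(fn, real_feature_names())
}

#' Names of the real-valued features
#'
#' The 11 real-valued features: six per-slot hydrophobicity values,
#' DisorderReal, SignedLength and the three sub-window volume features.
#'
#' @return Character vector of length 11.
#' @export
real_feature_names <- function() {
  c(sprintf("w-%d_Hydro", 1:3), sprintf("w+%d_Hydro", 1:3),
    "DisorderReal", "SignedLength", "BeforeVol", "AfterVol", "Difference")
}

#' Feature codebook
#'
#' Machine-readable table mapping every canonical feature name to its type
#' and a one-line definition.
#'
#' @return data.frame with columns `feature`, `type` and `definition`.
#' @export
feature_codebook <- function() {
  fn <- feature_names()
  type <- ifelse(fn %in% real_feature_names(), "real", "binary")
  def <- character(length(fn))
  onehot <- grepl("^w[-+][A-Z]_[123]$", fn)
  def[onehot] <- vapply(fn[onehot], function(x) {
    aa <- substr(x, 3, 3)
    side <- if (substr(x, 2, 2) == "-") "upstream" else "downstream"
    sprintf("1 if residue %s occupies %s slot %s of the window", aa, side,
            substr(x, 5, 5))
  }, character(1))
  hydro <- grepl("_Hydro$", fn)
  def[hydro] <- sprintf("Hopp-Woods hydrophilicity of the residue at slot %s",
                        sub("_Hydro$", "", fn[hydro]))
  singles <- c(
    Consensus = "1 if the window matches the [IVLMAP]K.[DE] consensus motif",
    wDE = "1 if Asp or Glu occurs anywhere in the 6 flanking slots",
    wK = "1 if an extra Lys occurs anywhere in the 6 flanking slots",
    Flexible = "1 if the central lysine is predicted conformationally flexible",
    DisorderReal = "predicted disorder tendency of the central lysine in [0,1]",
    DisorderBinary = "1 if disorder tendency >= 0.5",
    TerminalBinary = "1 if the site lies within 10% of either protein terminus",
    SignedLength = "protein length, negated when the site is terminal",
    BeforeVol = "sum of Kharakoz volumes over the upstream sub-window",
    AfterVol = "sum of Kharakoz volumes over the downstream sub-window",
    Difference = "AfterVol minus BeforeVol")
  def[match(names(singles), fn)] <- unname(singles)
  data.frame(feature = fn, type = type, definition = def,
             stringsAsFactors = FALSE)
}
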
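# Feature-space audit at load time: the canonical name list must
# decompose into exactly 120 one-hot + 6 hydrophobicity + 11 singletons =
# 137 features, 126 binary and 11 real-valued.
.onLoad <- function(libname, pkgname) {
  fn <- feature_names()
  stopifnot(length(fn) == 137L, !anyDuplicated(fn),
            length(binary_feature_names()) == 126L,
            length(real_feature_names()) == 11L,
            sum(grepl("^w[-+][A-Z]_[123]$", fn)) == 120L)
  invisible()
}
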
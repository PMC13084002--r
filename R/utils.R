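`%||%` <- function(x, y) if (is.null(x)) y else x

# Benjamini-Hochberg via stats::p.adjust, kept in one place
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
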
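# Canonical internal residue alphabet (alphabetical single-letter codes).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column order of PSI-BLAST ASCII PSSM files (both 20-column blocks).
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Flexibility states, in fixed order. Ties in argmax break toward the
# earlier state in this order.
FLEX_STATES <- c("R", "I", "F")
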
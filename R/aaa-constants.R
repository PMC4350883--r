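# Package-wide constants (this file loads first).

# Session cache for shipped tables read from extdata.
.wrky_cache <- new.env(parent = emptyenv())

# Amino-acid alphabet: the 20 standard residues plus X (unknown).
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")
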
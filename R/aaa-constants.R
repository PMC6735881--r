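# Amino-acid vocabulary. AA_ALPHABET20 is the biological alphabet used for
# sequence validation; MAP_ROW_ORDER is the fixed display/storage order of
# map rows (hydrophobic, polar, special, charged), followed by stop.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
MAP_ROW_ORDER <- c("A", "V", "L", "I", "M", "F", "Y", "W",
                   "S", "T", "N", "Q", "C", "G", "P",
                   "R", "H", "K", "D", "E")
MAP_SUBSTITUTIONS <- c(MAP_ROW_ORDER, "*")

AA_THREE_TO_ONE <- c(
    Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
    Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
    Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
    Tyr = "Y", Val = "V", Ter = "*")
AA_ONE_TO_THREE <- c(stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE))
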
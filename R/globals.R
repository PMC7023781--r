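# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "p_het", "sample", "mid", "status",
  "support", "n_co", "cM", "rate", "start", "end", "win", "k", "cat",
  "group", "prop", "dist", "mother", "cohort", "fecundity", "condition",
  "batch", "read_count", "carriers", "x", "N", "i.N", "i.x", "i.group",
  "i.condition", "position", "dir", "gametes"))
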
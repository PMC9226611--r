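# data.table NSE column names
utils::globalVariables(c(
  ".", "kmer", "uid", "duplicated", "offset", "first95", "site", "dup",
  "gene_id", "strand", "gstart", "gend", "i.gene_id", "i.start", "i.end",
  "i.strand", "x.pos", "x.dup", "x.reads_total", "x.replicon", "reads",
  "raw_reads", "rpk", "norm_rpk", "log2_norm_rpk", "excluded",
  "gene_length_bp", "replicon", "pos", "reads_fwd", "reads_rev",
  "reads_total", "read_id", "seq", "status", "N", "mutagenized",
  "abundance", "post_abundance", "class", "replicate"))
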
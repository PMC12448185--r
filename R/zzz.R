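.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "chrom", "start", "end", "name", "sample_id", "cn_major", "cn_minor",
  "cn_total", "scope", "value", "segment", "p", "q", "stat", "keep"
))
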
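# silence R CMD check notes for data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".I", ".SD", ".BY", "hit", "mate", "pair", "read", "ref", "pos",
  "strand", "edits", "span", "kind", "c_ref", "tag_lo", "tag_hi", "tstr",
  "sp1", "sp2", "unfl", "cpos1", "cpos2", "cend1", "cend2", "cstr1", "cstr2",
  "pos1", "pos2", "end1", "end2", "strand1", "strand2", "span1", "span2",
  "edits1", "edits2", "ref1", "ref2", "kind1", "kind2", "hit1", "hit2",
  "op_ov", "drop", "left1", "insert", "orient_ok", "tag_overlap1",
  "tag_overlap2", "class", "score", "best", "n_clone", "clone_ref",
  "clone_id", "pool_id", "pair_id", "special", "special1", "special2",
  "space", "type", "alt", "support", "coverage", "category", "stratum",
  "match", "expected_category", "true_clone", "dup_of", "roi_lo", "roi_hi"
))
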
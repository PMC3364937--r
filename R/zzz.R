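# data.table non-standard-evaluation column names
utils::globalVariables(c(
  "term", "namespace", "count", "total", "freq", "ic",
  "n_confirmed", "n_rejected_explicit", "n_removed", "n_uninformative",
  "denom", "reliability", "classification", "predicted",
  "n_predicted", "n_missed", "coverage"
))
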
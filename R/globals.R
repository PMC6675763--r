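utils::globalVariables(c(
  "movie_id", "boundary_index", "viewer_id", "response", "class",
  "mean_response", "count", "n_viewers", "label"
))
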
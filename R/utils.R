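# fast data.frame construction for hot paths: columns are already
# equal-length atomic vectors, so skip data.frame()'s coercion machinery
quick_df <- function(cols) {
  n <- length(cols[[1]])
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}
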
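# Deterministically derive a child seed from a root seed and a label, so
# every stochastic stage of a run has its own reproducible stream.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% (2^31 - 1))
}

pad_id <- function(prefix, i, width = 5) {
  sprintf("%s%0*d", prefix, width, i)
}
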
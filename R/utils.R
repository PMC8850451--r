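# deterministic combination of seed components (numbers or labels), kept
# within 32-bit range
mix_seed <- function(...) {
  v <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) vapply(x, function(s) sum(utf8ToInt(s) * seq_len(nchar(s))), numeric(1))
    else as.numeric(x)
  }), use.names = FALSE)
  h <- 0
  for (x in v) h <- (h * 48271 + abs(x) + 1) %% 2147483629
  as.integer(h)
}
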
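## small shared helpers

# Deterministic per-stage/per-gene seed derivation from a single master
# seed: seed_k = (seed + k * 9973) mod (2^31 - 1), kept strictly positive.
.stageSeed <- function(seed, k) {
  s <- (as.numeric(seed) + as.numeric(k) * 9973) %% 2147483647
  as.integer(if (s == 0) 1 else s)
}
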
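# Draw n reproducible sub-seeds from a master seed without disturbing the
# caller's RNG state. Sub-seeds stay within the 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}
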
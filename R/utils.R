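# Derive n child seeds from one master seed (or from the current RNG state
# when seed is NULL), all below 2^31 so they remain valid integer seeds.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

# mean per-sample energy of a numeric matrix or vector
mean_energy <- function(x) mean(x^2)
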
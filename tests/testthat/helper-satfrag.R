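# shared test helpers: small truth-labelled arrays and a character-level
# Hamming oracle independent of the package's C-backed scanning

make_test_array <- function(n_units = 10L, divergence = 0, seed = 1L,
                            period = 340L, noise_sd = 0.9, occ_seed = 2L) {
  arr <- evolve_array(build_dimer(period = period), n_units, divergence,
                      seed = seed)
  assign_truth_occupancy(arr, noise_sd = noise_sd, seed = occ_seed)
}

# brute-force Hamming distance between two equal-length strings
hamming_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# mutate exactly k distinct positions of a DNA string (to a different base)
mutate_k <- function(seq, k, seed = 1L) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

random_dna_str <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
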
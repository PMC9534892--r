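# Shared fixtures, built once per test run. Small three-chromosome hybrid
# genome: enough markers for segmentation tests, fast to simulate.
tiny_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- build_hybrid_genome(
      c(chrI = 120000, chrII = 100000, chrIII = 100000),
      snv_density = 0.007, seed = 421)
    g
  }
})

# marker-call data.frame straight from states, for segmentation unit tests
fake_calls <- function(states, chrom = "chrI", spacing = 100,
                       depth = c(25, 25)) {
  n <- length(states)
  data.frame(chrom = chrom, pos = seq_len(n) * spacing, state = states,
             depth_A = depth[1], depth_B = depth[2],
             stringsAsFactors = FALSE)
}

# evidence for a genotype, defaulting to noiseless 50x
noiseless_evidence <- function(gt, seed = 1, ...) {
  simulate_evidence(gt, mean_depth = 50, dispersion = 0, seed = seed, ...)
}
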
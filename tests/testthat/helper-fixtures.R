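# Shared small fixtures built in code.

# A single-SNP panel for fast cohort simulations.
one_snp_panel <- function(log_or = 0, freq = 0.3) {
  list(snp_spec("rsTEST", "A", freq, log_or = log_or))
}

# Scaled-down eight-study design used where the full sample sizes would be
# wasteful: same structure (8 studies x 9 SNPs), n per arm as given.
scaled_design <- function(n = 150L, effects = NULL) {
  d <- default_study_design(effects = effects)
  d$studies <- lapply(d$studies, function(s)
    study_spec(s$name, s$cancer_type, n, n))
  d
}

# A large random panel for ancestry-PCA tests.
random_panel <- function(k, seed = 1) {
  set.seed(seed)
  freqs <- runif(k, 0.1, 0.5)
  lapply(seq_len(k), function(i)
    snp_spec(sprintf("rsP%03d", i), "A", freqs[i]))
}

ref_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- load_reference_grid()
    g
  }
})
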
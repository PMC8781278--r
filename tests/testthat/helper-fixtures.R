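# Shared fixtures: everything is generated in code at test time.

ferm_design <- function(seed = 1) generate_ccd(seed = seed)

# Default synthetic study: 31 runs x 18 responses with the five-module truth.
ferm_sim <- function(noise_sd = 0.05, seed = 42, design_seed = 1) {
  simulate_responses(ferm_design(design_seed), default_truth(noise_sd),
                     seed = seed)
}

# A small hand-rolled term_set with a reduced candidate list, for oracle
# comparisons on <= 7 candidates.
small_term_set <- function(n = 12, k = 2, seed = 1) {
  set.seed(seed)
  fnames <- c("A", "B", "C")[seq_len(k)]
  coded <- matrix(sample(c(-1L, 0L, 1L), n * k, replace = TRUE), n, k,
                  dimnames = list(NULL, fnames))
  # regenerate until no term column is constant
  ts <- build_terms(coded)
  while (any(apply(ts$values, 2, stats::sd) == 0)) {
    coded <- matrix(sample(c(-1L, 0L, 1L), n * k, replace = TRUE), n, k,
                    dimnames = list(NULL, fnames))
    ts <- build_terms(coded)
  }
  ts
}
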
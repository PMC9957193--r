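# shared fixture builders; all randomness is locally seeded

rand_markers <- function(n, p, prefix = "L", seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(sample(0:2, n * p, replace = TRUE, prob = c(0.3, 0.4, 0.3)),
                n, p)
    dimnames(M) <- list(paste0(prefix, seq_len(n)), paste0("m", seq_len(p)))
    M
  })
}

rand_psd <- function(n, ids = paste0("e", seq_len(n)), seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * (n + 2)), n + 2, n)
    K <- crossprod(A) / n
    dimnames(K) <- list(ids, ids)
    K
  })
}

small_config <- function(...) {
  synth_config(n_males = 4, n_females = 8, n_markers = 60, n_envs = 2,
               n_hybrids_per_env = c(14, 12), overlap = 0.3, ...)
}

toy_dosage_path <- function() {
  system.file("extdata", "toy_dosage.tsv", package = "hybridcov")
}
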
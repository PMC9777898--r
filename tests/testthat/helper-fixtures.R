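# Small shared fixtures, all generated in code.

tiny_spec <- function(n = 60, seed = 1, ...) {
  cohort_spec(n_subjects = n, seed = seed,
              chapter_prevalences = c(ch_III = 0.3, ch_IX = 0.4), ...)
}

# fast training configs for smoke/determinism tests (full recipe is exercised
# in the acceptance suite)
fast_ae <- function(seed = 1, ...) {
  ae_config(epochs_phase_a = 2L, epochs_phase_b = 1L, latent_dim = 16L,
            seed = seed, ...)
}

fast_fusion <- function(seed = 1, ...) {
  fusion_config(epochs = 30L, seed = seed, ...)
}

# brute-force pairwise Mann-Whitney AUC (the independent oracle)
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
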
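# Shared fixtures: everything is generated in code at test time.

# Small deterministic nonnegative matrix.
random_nonneg <- function(nr, nc, seed = 1) {
  withr::with_seed(seed, matrix(runif(nr * nc), nr, nc))
}

# A small single-subject trial list from the synthetic generator.
make_trials <- function(n_trials = 4, k_true = 3, snr_db = 20, seed = 11,
                        n_time = 101) {
  cfg <- synth_config(k_true = k_true, snr_db = snr_db, n_trials = n_trials,
                      n_subjects = 1, n_time = n_time, seed = seed)
  gt <- make_ground_truth(cfg)
  trials <- lapply(seq_len(n_trials), function(i) {
    generate_trial(gt, cfg, "emg", trial_seed = seed * 100 + i)
  })
  list(trials = trials, gt = gt, cfg = cfg)
}

# Noiseless variant of a config (the generator treats Inf SNR as no noise).
noiseless <- function(cfg) {
  cfg$snr_db <- Inf
  cfg
}

# Independent cosine helper for oracles (kept separate from the package's
# scalar_product_similarity on purpose).
cos_sim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# Brute-force best assignment between columns of two weight matrices,
# maximizing total cosine; enumerates every permutation.
brute_force_match <- function(wa, wb) {
  k <- ncol(wa)
  perms <- gtools_permutations(k)
  totals <- apply(perms, 1, function(p) {
    sum(vapply(seq_len(k), function(i) cos_sim(wa[, i], wb[, p[i]]), numeric(1)))
  })
  list(perm = perms[which.max(totals), ], total = max(totals))
}

# Minimal permutation enumerator for the oracle (independent of the package).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# Concatenate one subject's trials of one modality from a cohort tibble.
bind_cohort_subject <- function(co, s, mod) {
  emgsynergy:::bind_trials(co$data[co$subject == s & co$modality == mod])
}
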
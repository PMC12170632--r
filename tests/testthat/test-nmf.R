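test_that("multiplicative updates keep factors nonnegative and the objective non-increasing", {
  for (seed in 1:5) {
    m <- random_nonneg(8, 30, seed)
    s <- nmf_decompose(m, k = 3, n_restarts = 3, max_iter = 80, seed = seed)
    expect_true(all(s$w >= 0))
    expect_true(all(s$c >= 0))
    expect_true(all(diff(s$trace) <= 1e-10), label = paste("seed", seed))
  }
})

test_that("rank-1 matrices are recovered essentially exactly at k = 1", {
  u <- withr::with_seed(2, runif(10))
  v <- withr::with_seed(3, runif(40))
  m <- outer(u, v)
  s <- nmf_decompose(m, k = 1, n_restarts = 10, max_iter = 500, seed = 1)
  expect_lt(s$objective, 1e-8 * sqrt(sum(m^2)))
})

test_that("degenerate and full-rank cases behave as the definitions require", {
  # all-zero matrix factorizes to zero with zero error
  z <- matrix(0, 5, 12)
  s0 <- nmf_decompose(z, k = 2, n_restarts = 2, seed = 1)
  expect_equal(s0$objective, 0)
  expect_equal(reconstruct(s0), matrix(0, 5, 12), ignore_attr = TRUE)

  # k = full row rank admits a near-exact fit
  m <- random_nonneg(6, 40, seed = 8)
  s <- nmf_decompose(m, k = 6, n_restarts = 10, max_iter = 500, seed = 2)
  expect_gte(global_vaf(m, reconstruct(s)), 0.999)
})

test_that("compiled updates agree with a pure-R reference implementation", {
  m <- random_nonneg(7, 25, seed = 4)
  init <- withr::with_seed(99, list(w = matrix(runif(7 * 2), 7, 2),
                                    c = matrix(runif(2 * 25), 2, 25)))
  cpp <- emgsynergy:::.nmf_mu_cpp(m, init$w, init$c, 60, 0, 1e-12)
  ref <- emgsynergy:::nmf_mu_reference(m, init$w, init$c, max_iter = 60, tol = 0)
  expect_equal(cpp$w, ref$w, tolerance = 1e-12)
  expect_equal(cpp$c, ref$c, tolerance = 1e-12)
  expect_equal(as.numeric(cpp$trace), ref$trace, tolerance = 1e-12)
})

test_that("global and local VAF follow the uncentered definitions", {
  m <- matrix(c(3, 4), 1, 2)
  expect_equal(global_vaf(m, m), 1)
  expect_equal(global_vaf(m, matrix(0, 1, 2)), 0)
  expect_equal(global_vaf(m, matrix(c(3, 0), 1, 2)), 1 - 16 / 25)
  expect_error(global_vaf(matrix(0, 2, 2), matrix(0, 2, 2)), "undefined")

  m2 <- rbind(a = c(3, 4), b = c(1, 2))
  mh <- rbind(c(3, 4), c(0, 0))
  lv <- local_vaf(m2, mh)
  expect_equal(unname(lv), c(1, 0))
  # row m = (3,4) vs (3,9): residual 25 equals the row's energy -> VAF 0
  expect_equal(unname(local_vaf(rbind(c(3, 4)), rbind(c(3, 9)))), 0)
  # zero-activity muscle is flagged NA, not an error
  lv0 <- local_vaf(rbind(c(0, 0), c(1, 1)), rbind(c(0, 0), c(1, 1)))
  expect_true(is.na(lv0[1]) && lv0[2] == 1)
})

test_that("normalization fixes the scale convention without changing the product", {
  w <- matrix(c(3, 4, 0, 5), 2, 2)
  cc <- matrix(runif(2 * 6), 2, 6)
  s <- emgsynergy:::synergy_set(w, cc)
  expect_equal(unname(colSums(s$w^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(s$w %*% s$c, w %*% cc, tolerance = 1e-12, ignore_attr = TRUE)

  # normalizing twice is the identity
  s2 <- normalize_synergies(s)
  expect_equal(s2$w, s$w)
  expect_equal(s2$c, s$c)

  # zero column is left alone and flagged
  sz <- emgsynergy:::synergy_set(cbind(c(1, 0), c(0, 0)), matrix(0, 2, 4))
  expect_true(sz$zero_components[2])
})

test_that("reconstruction is the plain matrix product", {
  w <- diag(2) * c(2, 3)
  cc <- matrix(1:6, 2, 3)
  s <- structure(list(w = w, c = cc, k = 2, muscle_labels = c("a", "b")),
                 class = "synergy_set")
  expect_equal(unname(reconstruct(s)), w %*% cc)
  expect_equal(unname(reconstruct(emgsynergy:::synergy_set(diag(2), matrix(0, 2, 3)))),
               matrix(0, 2, 3))
})

test_that("scaling the input by a positive constant leaves normalized W unchanged and scales C", {
  m <- random_nonneg(6, 30, seed = 5)
  s1 <- nmf_decompose(m, k = 2, n_restarts = 5, seed = 3)
  s2 <- nmf_decompose(4 * m, k = 2, n_restarts = 5, seed = 3)
  mt <- match_synergies(s1, s2)
  expect_true(all(mt$w_similarity > 1 - 1e-6))
  for (j in seq_len(nrow(mt))) {
    expect_equal(4 * s1$c[mt$index_a[j], ], s2$c[mt$index_b[j], ],
                 tolerance = 1e-3)
  }
})

test_that("ground-truth weights are recovered from noiseless synthetic data", {
  # overlap between adjacent coefficient bumps leaves a sliver of rotational
  # freedom in the exact factorization, so individual matched cosines can sit
  # slightly below the per-column ideal while the fit itself is exact
  for (seed in c(21, 42, 55)) {
    fx <- make_trials(n_trials = 1, snr_db = Inf, seed = seed)
    m <- fx$trials[[1]]
    s <- nmf_decompose(m, k = 3, n_restarts = 20, max_iter = 2000, seed = 6)
    expect_gt(global_vaf(m, reconstruct(s)), 1 - 1e-8)
    mt <- match_synergies(s, emgsynergy:::synergy_set(fx$gt$w_true, fx$gt$c_true))
    expect_equal(nrow(mt), 3)
    expect_true(all(mt$w_similarity > 0.98), label = paste("seed", seed))
    expect_gt(mean(mt$w_similarity), 0.99)
  }
})

test_that("invalid factorization requests are rejected", {
  m <- random_nonneg(5, 10)
  expect_error(nmf_decompose(m - 1, k = 2), "nonnegative")
  expect_error(nmf_decompose(m, k = 0), "k")
  expect_error(nmf_decompose(m, k = 6), "min")
})

test_that("fit_coefficients solves the fixed-W nonnegative least-squares problem", {
  fx <- make_trials(n_trials = 1, snr_db = Inf, seed = 31)
  m <- fx$trials[[1]]
  cc <- fit_coefficients(fx$gt$w_true, m)
  expect_true(all(cc >= 0))
  expect_lt(frobenius_gap <- sqrt(sum((fx$gt$w_true %*% cc - unclass(m))^2)) /
              sqrt(sum(m^2)), 1e-8)
})
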
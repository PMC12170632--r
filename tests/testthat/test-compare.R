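test_that("scalar-product similarity matches its closed-form values", {
  v <- withr::with_seed(1, runif(10))
  expect_equal(scalar_product_similarity(v, v), 1)
  expect_equal(scalar_product_similarity(v, 3 * v), 1)  # scale invariance
  expect_equal(scalar_product_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(scalar_product_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(scalar_product_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(scalar_product_similarity(1:3, 1:4), "length")
})

test_that("scalar product lies in [0, 1] over many random nonnegative pairs", {
  vals <- withr::with_seed(7, vapply(1:2000, function(i) {
    scalar_product_similarity(runif(15), runif(15))
  }, numeric(1)))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("Pearson similarity matches hand-computed correlations", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_similarity(x, 2 * x + 1), 1)
  expect_equal(pearson_similarity(x, -x), -1)
  # centered sums by hand: r((1,2,3), (1,3,2)) = 0.5
  expect_equal(pearson_similarity(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_similarity(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_similarity(1:2, 1:2), "3 samples")
})

test_that("matching recovers permutations and equals the brute-force optimum", {
  w <- withr::with_seed(3, matrix(runif(15 * 4), 15, 4))
  cc <- withr::with_seed(4, matrix(runif(4 * 101), 4, 101))
  a <- emgsynergy:::synergy_set(w, cc, default_muscle_labels())

  # column-permuted copy: the permutation is recovered with similarity 1
  perm <- c(3, 1, 4, 2)
  b <- emgsynergy:::synergy_set(w[, perm], cc[perm, ], default_muscle_labels())
  mt <- match_synergies(a, b)
  expect_equal(order(perm), unname(mt$index_b[order(mt$index_a)]))
  expect_true(all(mt$w_similarity > 1 - 1e-9))

  # k = 1 vs k = 1: the single pair
  a1 <- emgsynergy:::synergy_set(w[, 1, drop = FALSE], cc[1, , drop = FALSE],
                                 default_muscle_labels())
  expect_equal(nrow(match_synergies(a1, a1)), 1)

  # random instances: total similarity equals exhaustive brute force
  for (seed in 1:10) {
    wa <- withr::with_seed(seed, matrix(runif(15 * 3), 15, 3))
    wb <- withr::with_seed(seed + 100, matrix(runif(15 * 3), 15, 3))
    sa <- emgsynergy:::synergy_set(wa, matrix(1, 3, 4), default_muscle_labels())
    sb <- emgsynergy:::synergy_set(wb, matrix(1, 3, 4), default_muscle_labels())
    mt <- match_synergies(sa, sb)
    bf <- brute_force_match(sa$w, sb$w)
    expect_equal(sum(mt$w_similarity), bf$total, tolerance = 1e-12,
                 label = paste("seed", seed))
  }
})

test_that("matching handles a greedy trap and unequal component counts", {
  # hand-built 2x2 trap: greedy picks (1,1) but the optimum is (1,2),(2,1)
  wa <- cbind(c(1, 1, 0), c(1, 0, 0))
  wb <- cbind(c(1, 0.9, 0), c(1, 1.1, 0))
  sa <- emgsynergy:::synergy_set(wa, matrix(1, 2, 3), c("a", "b", "c"))
  sb <- emgsynergy:::synergy_set(wb, matrix(1, 2, 3), c("a", "b", "c"))
  mt <- match_synergies(sa, sb)
  bf <- brute_force_match(sa$w, sb$w)
  expect_equal(sum(mt$w_similarity), bf$total, tolerance = 1e-12)

  # unequal k: bijection on min(k_a, k_b)
  sa2 <- emgsynergy:::synergy_set(wa[, 1, drop = FALSE], matrix(1, 1, 3),
                                  c("a", "b", "c"))
  mt2 <- match_synergies(sa2, sb)
  expect_equal(nrow(mt2), 1)
  mt2r <- match_synergies(sb, sa2)
  expect_equal(nrow(mt2r), 1)

  s_bad <- emgsynergy:::synergy_set(wa, matrix(1, 2, 3), c("x", "y", "z"))
  expect_error(match_synergies(sa, s_bad), "labels")
})

test_that("per-muscle similarity isolates muscles whose weights moved", {
  w <- withr::with_seed(5, matrix(runif(5 * 3), 5, 3))
  cc <- matrix(1, 3, 8)
  a <- emgsynergy:::synergy_set(w, cc, letters[1:5])
  pm <- per_muscle_similarity(a, a)
  expect_equal(pm$similarity, rep(1, 5), tolerance = 1e-12)

  # swap one muscle's weights between two synergies in b
  w2 <- w
  w2[2, c(1, 2)] <- w[2, c(2, 1)] + c(0.5, -0.05)
  w2 <- pmax(w2, 0)
  b <- emgsynergy:::synergy_set(w2, cc, letters[1:5])
  pm2 <- per_muscle_similarity(a, b, match_synergies(a, b))
  expect_lt(pm2$similarity[2], 1 - 1e-6)

  # orthogonal row profiles score zero
  wa <- rbind(c(1, 0, 0), matrix(0.5, 2, 3))
  wb <- rbind(c(0, 1, 0), matrix(0.5, 2, 3))
  sa <- emgsynergy:::synergy_set(wa, cc, c("m1", "m2", "m3"))
  sb <- emgsynergy:::synergy_set(wb, cc, c("m1", "m2", "m3"))
  mt_id <- tibble::tibble(index_a = 1:3, index_b = 1:3, w_similarity = 1)
  expect_equal(per_muscle_similarity(sa, sb, mt_id)$similarity[1], 0)
})

test_that("full comparison reports are symmetric and exact on identical sets", {
  fx <- make_trials(n_trials = 1, seed = 41)
  s <- nmf_decompose(fx$trials[[1]], 3, n_restarts = 10, seed = 2)
  rep_same <- compare_decompositions(s, s)
  expect_equal(rep_same$matching$w_similarity, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep_same$matching$c_similarity, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep_same$per_muscle$similarity, rep(1, 15), tolerance = 1e-12)

  # symmetry: a-vs-b equals b-vs-a with the matching transposed
  s2 <- nmf_decompose(fx$trials[[1]], 3, n_restarts = 10, seed = 99)
  r_ab <- compare_decompositions(s, s2)
  r_ba <- compare_decompositions(s2, s)
  ab <- dplyr::arrange(r_ab$matching, index_a)
  ba <- dplyr::arrange(r_ba$matching, index_b)
  expect_equal(ab$w_similarity, ba$w_similarity[order(ba$index_b)],
               tolerance = 1e-12)
  expect_equal(r_ab$summary$w_similarity_mean, r_ba$summary$w_similarity_mean)

  # both per-muscle definitions are available
  r_rec <- compare_decompositions(s, s2, per_muscle_method = "reconstruction")
  expect_true(all(r_rec$per_muscle$similarity <= 1, na.rm = TRUE))
})

test_that("cross-modality similarity on the default generator sits high but below 1", {
  cfg <- synth_config(n_subjects = 3, n_trials = 3, seed = 51)
  co <- generate_cohort(cfg)
  sims <- vapply(unique(co$subject), function(s) {
    emg <- bind_cohort_subject(co, s, "emg")
    mod <- bind_cohort_subject(co, s, "model")
    se <- nmf_decompose(emg, 3, n_restarts = 10, seed = 1)
    sm <- nmf_decompose(mod, 3, n_restarts = 10, seed = 2)
    compare_decompositions(se, sm)$summary$w_similarity_mean
  }, numeric(1))
  expect_true(all(sims > 0.9 & sims < 1))
})
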
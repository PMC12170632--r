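two_muscle_task <- function(arms = c(1, 1), moment = 1, peak = c(1, 1)) {
  p <- tibble::tibble(name = c("a", "b"), peak_force = peak,
                      pennation_angle = c(0, 0))
  joint_task(matrix(arms, 1, 2), matrix(moment, 1, 1), p)
}

test_that("muscle force follows the rigid-tendon nominal-length model", {
  expect_equal(muscle_force(list(peak_force = 100, pennation_angle = 0), 0), 0)
  expect_equal(muscle_force(list(peak_force = 100, pennation_angle = 0), 1), 100)
  # published DELT2 parameters: 1103.5 N at 15 degrees pennation
  expect_equal(muscle_force(list(peak_force = 1103.5, pennation_angle = 15), 1),
               1103.5 * cos(15 * pi / 180), tolerance = 1e-12)
  expect_equal(round(muscle_force(list(peak_force = 1103.5, pennation_angle = 15), 1), 1),
               1065.9)
  # hooks scale multiplicatively
  expect_equal(muscle_force(list(peak_force = 100, pennation_angle = 0), 0.5,
                            fl = 0.8, fv = 1.2), 48)
  expect_error(muscle_force(list(peak_force = 100, pennation_angle = 0), 1.2),
               "activation")
  expect_error(muscle_force(list(peak_force = 100, pennation_angle = 0), 1, fl = 2),
               "fl")
})

test_that("closed-form symmetric solutions are reproduced to 1e-9", {
  # two identical muscles sharing the load equally
  tk <- two_muscle_task()
  expect_equal(unname(solve_frame(tk, 1)), c(0.5, 0.5), tolerance = 1e-9)

  # one muscle with r * Fmax = 2 M -> a = 0.5
  p1 <- tibble::tibble(name = "a", peak_force = 2, pennation_angle = 0)
  tk1 <- joint_task(matrix(1, 1, 1), matrix(1, 1, 1), p1)
  expect_equal(unname(solve_frame(tk1, 1)), 0.5, tolerance = 1e-9)

  # arms (1, 1, 2), unit strength, M = 1: least-norm solution a ~ r
  p3 <- tibble::tibble(name = c("a", "b", "c"), peak_force = rep(1, 3),
                       pennation_angle = rep(0, 3))
  tk3 <- joint_task(matrix(c(1, 1, 2), 1, 3), matrix(1, 1, 1), p3)
  expect_equal(unname(solve_frame(tk3, 1)), c(1 / 6, 1 / 6, 1 / 3),
               tolerance = 1e-9)
})

test_that("QP solutions match a dense grid search on small problems", {
  # 2 muscles, 1 constraint: brute force over a1 with a2 implied
  grid_2 <- function(arms, phi, moment, res = 1e-3) {
    a1 <- seq(0, 1, by = res)
    a2 <- (moment - arms[1] * phi[1] * a1) / (arms[2] * phi[2])
    ok <- a2 >= 0 & a2 <= 1
    obj <- a1^2 + a2^2
    min(obj[ok])
  }
  cases <- list(
    list(arms = c(1, 1), peak = c(1, 1), m = 1),
    list(arms = c(1, 2), peak = c(1, 1), m = 1.2),
    list(arms = c(0.5, 2), peak = c(2, 1), m = 0.9)
  )
  for (cs in cases) {
    tk <- two_muscle_task(cs$arms, cs$m, cs$peak)
    a <- solve_frame(tk, 1)
    expect_equal(sum(a^2), grid_2(cs$arms, cs$peak, cs$m),
                 tolerance = 1e-4, label = paste(unlist(cs), collapse = ","))
  }

  # 3 muscles, 1 constraint: grid over (a1, a2), a3 implied
  arms <- c(1, 1, 2); phi <- c(1, 1, 1); m <- 1
  g <- expand.grid(a1 = seq(0, 1, by = 1e-3), a2 = seq(0, 1, by = 1e-3))
  a3 <- (m - arms[1] * phi[1] * g$a1 - arms[2] * phi[2] * g$a2) / (arms[3] * phi[3])
  ok <- a3 >= 0 & a3 <= 1
  brute <- min((g$a1^2 + g$a2^2 + a3^2)[ok])
  p3 <- tibble::tibble(name = c("a", "b", "c"), peak_force = phi,
                       pennation_angle = rep(0, 3))
  tk3 <- joint_task(matrix(arms, 1, 3), matrix(m, 1, 1), p3)
  expect_equal(sum(solve_frame(tk3, 1)^2), brute, tolerance = 1e-4)
})

test_that("solutions respect bounds, equilibrium and permutation symmetry", {
  tk <- default_joint_task(n_time = 31)
  expect_true(all(tk$feasible))
  phi <- tk$params$peak_force * cos(tk$params$pennation_angle * pi / 180)
  for (t in c(1, 11, 21, 31)) {
    a <- solve_frame(tk, t)
    expect_true(all(a >= -1e-12 & a <= 1 + 1e-12))
    resid <- tk$moment_arms %*% (phi * a) - tk$required_moments[, t]
    expect_lt(max(abs(resid)), 1e-6)
  }

  # permutation equivariance: swapping two identical muscles swaps solutions
  p <- tibble::tibble(name = c("a", "b", "c"), peak_force = c(1, 1, 2),
                      pennation_angle = c(0, 0, 0))
  tkp <- joint_task(matrix(c(1, 1, 0.5), 1, 3), matrix(0.8, 1, 1), p)
  a <- solve_frame(tkp, 1)
  expect_equal(a[["a"]], a[["b"]], tolerance = 1e-9)
})

test_that("whole-task simulation is linear below the bounds and flags infeasibility", {
  tk <- default_joint_task(n_time = 41)
  act <- simulate_model_activations(tk)
  expect_s3_class(act, "activation_matrix")
  expect_equal(dim(act), c(15L, 41L))
  expect_true(all(act >= 0))

  # zero moments -> zero activations
  tk0 <- joint_task(tk$moment_arms, matrix(0, 2, 5), tk$params)
  expect_equal(max(simulate_model_activations(tk0)), 0, tolerance = 1e-9)

  # halving the demand halves the activations while bounds stay inactive
  tk_half <- joint_task(tk$moment_arms, tk$required_moments / 2, tk$params)
  act_half <- simulate_model_activations(tk_half)
  expect_equal(unclass(act_half), unclass(act) / 2, tolerance = 1e-6)

  # with all-nonnegative arms and demands no bound activates, the frame map
  # is a single linear map of the moments and the activation matrix has rank
  # at most the number of joints (the default task instead clamps antagonists
  # at zero during the follow-through, which is piecewise linear)
  p <- toy_muscle_params()
  groups <- emgsynergy:::default_synergy_groups()
  arms2 <- matrix(0, 2, 15)
  arms2[1, p$name %in% groups$scapular] <- 0.05
  arms2[2, p$name %in% c(groups$anterior, groups$posterior)] <- 0.04
  tt <- seq(0, 1, length.out = 41)
  mom2 <- rbind(30 * exp(-(tt - 0.3)^2 / 0.01), 25 * exp(-(tt - 0.6)^2 / 0.01))
  tk_lin <- joint_task(arms2, mom2, p)
  act_lin <- simulate_model_activations(tk_lin)
  sv <- svd(unclass(act_lin))$d
  expect_lt(sv[3] / sv[1], 1e-8)

  # an unreachable moment names the joint and shortfall
  tk_bad <- try(joint_task(tk$moment_arms, matrix(c(1e5, 0), 2, 1), tk$params),
                silent = TRUE)
  expect_false(all(tk_bad$feasible))
  expect_error(solve_frame(tk_bad, 1), "infeasible|shortfall")
})

test_that("published and toy muscle parameter tables are well-formed", {
  hp <- hill_muscle_params()
  expect_equal(nrow(hp), 15)
  expect_true(all(hp$peak_force > 0))
  expect_true(all(hp$pennation_angle >= 0 & hp$pennation_angle < 90))
  expect_equal(hp$peak_force[hp$name == "DELT1"], 1218.9)

  tp <- toy_muscle_params()
  expect_setequal(tp$name, default_muscle_labels())
})
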
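#' Hill-type muscle-tendon parameters
#'
#' Published parameter table for the shoulder musculotendon actuators of the
#' upper-extremity model: optimal fiber length, peak isometric force, tendon
#' slack length and pennation angle. Values are stored exactly as printed,
#' including the source's internally inconsistent fiber/tendon length scales
#' (trapezius lengths around 0.1 versus deltoid around 10 under the same
#' "cm" heading); lengths are therefore labelled units-as-printed and only
#' `peak_force` and `pennation_angle` enter the default toy computation.
#'
#' @return A tibble with columns `name`, `optimal_fiber_length`,
#'   `peak_force` (N), `tendon_slack_length`, `pennation_angle` (degrees).
#' @export
hill_muscle_params <- function() {
  tibble::tribble(
    ~name,      ~optimal_fiber_length, ~peak_force, ~tendon_slack_length, ~pennation_angle,
    "TRPL1",    0.1127,                1043,        0.027,                0,
    "TRPL2",    0.0832,                470.4,       0.032,                0,
    "TRPL3",    0.1264,                414.4,       0.035,                0,
    "TRPL4",    0.1116,                201.6,       0.027,                0,
    "DELT1",    9.8,                   1218.9,      9.3,                  22,
    "DELT2",    10.8,                  1103.5,      11,                   15,
    "DELT3",    13.7,                  201.6,       3.8,                  18,
    "SUPRA",    6.8,                   499.2,       4,                    7,
    "INFRA",    7.6,                   1075.8,      3.1,                  19,
    "SUBSCAP",  8.7,                   1306.9,      3.3,                  20,
    "TMIN",     7.4,                   269.5,       7.1,                  24,
    "TMAJ",     16.2,                  144,         2,                    16,
    "PECM1",    14.4,                  444.3,       0.3,                  17,
    "PECM2",    13.8,                  658.3,       8.9,                  26,
    "PECM3",    13.8,                  498.1,       13.2,                 25
  )
}

#' Synthetic muscle parameters for the toy joint task
#'
#' Parameter set covering the fifteen surface-EMG muscle labels used by the
#' synthetic cohort. Where a label corresponds to an actuator in
#' [hill_muscle_params()] the published peak force and pennation angle are
#' reused (TRP1/TRP3/TRP4 map to the trapezius actuators, INFSP to
#' infraspinatus); the remaining entries (LAT2, TRIlat, TRImed, BIClong,
#' SRA) are synthetic, chosen at physiologically plausible magnitudes.
#'
#' @return A tibble with `name`, `peak_force` (N), `pennation_angle`
#'   (degrees).
#' @export
toy_muscle_params <- function() {
  tibble::tribble(
    ~name,     ~peak_force, ~pennation_angle,
    "DELT1",   1218.9,      22,
    "DELT2",   1103.5,      15,
    "DELT3",   201.6,       18,
    "INFSP",   1075.8,      19,
    "PECM1",   444.3,       17,
    "PECM2",   658.3,       26,
    "PECM3",   498.1,       25,
    "LAT2",    650,         21,   # synthetic
    "TRIlat",  620,         12,   # synthetic
    "TRImed",  600,         10,   # synthetic
    "BIClong", 430,         0,    # synthetic
    "TRP1",    1043,        0,
    "TRP3",    414.4,       0,
    "TRP4",    201.6,       0,
    "SRA",     550,         8     # synthetic
  )
}

#' Active muscle force under the rigid-tendon, nominal-length model
#'
#' `F = activation * peak_force * cos(pennation) * fl * fv`. In the default
#' toy stage the force-length (`fl`) and force-velocity (`fv`) factors are
#' fixed at 1 (nominal state); hooks accept multiplicative factors in
#' `[0, 1.8]` for sensitivity experiments.
#'
#' @param p A list or one-row data frame with `peak_force` (N) and
#'   `pennation_angle` (degrees).
#' @param activation Activation level in `[0, 1]`.
#' @param fl,fv Force-length and force-velocity multipliers in `[0, 1.8]`.
#' @return Force in newtons.
#' @export
#' @examples
#' muscle_force(list(peak_force = 1103.5, pennation_angle = 15), 1)
muscle_force <- function(p, activation, fl = 1, fv = 1) {
  if (any(activation < 0 | activation > 1)) {
    abort("`activation` must lie in [0, 1].")
  }
  if (fl < 0 || fl > 1.8 || fv < 0 || fv > 1.8) {
    abort("`fl` and `fv` must lie in [0, 1.8].")
  }
  if (p$peak_force <= 0) abort("`peak_force` must be positive.")
  if (p$pennation_angle < 0 || p$pennation_angle >= 90) {
    abort("`pennation_angle` must lie in [0, 90).")
  }
  activation * p$peak_force * cos(p$pennation_angle * pi / 180) * fl * fv
}

# Effective moment-generating capacity per unit activation (N): peak force
# projected through the pennation angle.
effective_strength <- function(params) {
  params$peak_force * cos(params$pennation_angle * pi / 180)
}

#' Construct a joint task for static optimization
#'
#' A task is a signed moment-arm matrix (joints x muscles, metres), a
#' required-moment time series (joints x time, N m) and activation bounds
#' `[0, 1]`. On construction every frame is checked for feasibility (the
#' required moment must be reachable within activation bounds) and the
#' certificate is stored.
#'
#' @param moment_arms Numeric matrix, joints x muscles, signed, in metres.
#' @param required_moments Numeric matrix, joints x time, in N m.
#' @param params Muscle parameter tibble with `name`, `peak_force`,
#'   `pennation_angle`; columns of `moment_arms` must follow its row order.
#' @return A `joint_task` list with a logical `feasible` vector per frame.
#' @export
joint_task <- function(moment_arms, required_moments, params) {
  if (ncol(moment_arms) != nrow(params)) {
    abort("`moment_arms` must have one column per muscle in `params`.")
  }
  if (nrow(moment_arms) != nrow(required_moments)) {
    abort("`moment_arms` and `required_moments` must agree on the number of joints.")
  }
  task <- structure(
    list(moment_arms = moment_arms, required_moments = required_moments,
         params = params),
    class = "joint_task")
  task$feasible <- vapply(seq_len(ncol(required_moments)), function(t) {
    !inherits(try(solve_frame(task, t, check_feasible = FALSE), silent = TRUE),
              "try-error")
  }, logical(1))
  task
}

#' Solve one frame of the static-optimization problem
#'
#' Minimizes the sum of squared activations subject to joint moment
#' equilibrium `sum_i r_ij F_i(a_i) = M_j` for every joint `j` and activation
#' bounds `0 <= a_i <= 1`. With the rigid-tendon linear force model this is a
#' strictly convex quadratic program with a unique solution, solved by an
#' active-set QP; the equilibrium residual of the returned solution is
#' checked against 1e-6.
#'
#' @param task A [joint_task()].
#' @param t Frame (time sample) index.
#' @param check_feasible Internal; skip the stored certificate lookup.
#' @return Numeric activation vector named by muscle.
#' @export
#' @examples
#' p <- tibble::tibble(name = c("a", "b"), peak_force = c(1, 1),
#'                     pennation_angle = c(0, 0))
#' tk <- joint_task(matrix(1, 1, 2), matrix(1, 1, 1), p)
#' solve_frame(tk, 1)  # (0.5, 0.5)
solve_frame <- function(task, t, check_feasible = TRUE) {
  stopifnot(inherits(task, "joint_task"))
  n <- nrow(task$params)
  phi <- effective_strength(task$params)
  aeq <- task$moment_arms %*% diag(phi, n)
  beq <- task$required_moments[, t]

  sol <- tryCatch(
    pracma::quadprog(diag(2, n), rep(0, n), Aeq = aeq, beq = beq,
                     lb = rep(0, n), ub = rep(1, n)),
    error = function(e) NULL)
  ok <- !is.null(sol) && !is.null(sol$xmin) && all(is.finite(sol$xmin))
  if (ok) {
    a <- pmin(pmax(sol$xmin, 0), 1)
    resid <- aeq %*% a - beq
    ok <- max(abs(resid)) < 1e-6
  }
  if (!ok) {
    # Report the shortfall of the closest bounded solution per joint; a tiny
    # ridge keeps the least-squares system positive definite.
    ls <- pracma::lsqlincon(rbind(aeq, diag(1e-3, n)), c(beq, rep(0, n)),
                            lb = rep(0, n), ub = rep(1, n))
    short <- aeq %*% ls - beq
    j <- which.max(abs(short))
    abort(sprintf("Frame %d infeasible: joint %d moment shortfall %.4g N m.",
                  t, j, short[j]))
  }
  setNames(as.numeric(a), task$params$name)
}

#' Predict activations for a whole task by static optimization
#'
#' Solves every frame with [solve_frame()] and assembles the solutions into a
#' model-modality [activation_matrix()] (muscles x time).
#'
#' @param task A [joint_task()].
#' @return An [activation_matrix()] with `modality = "model"`.
#' @export
simulate_model_activations <- function(task) {
  stopifnot(inherits(task, "joint_task"))
  nt <- ncol(task$required_moments)
  out <- vapply(seq_len(nt), function(t) solve_frame(task, t),
                numeric(nrow(task$params)))
  activation_matrix(matrix(out, nrow = nrow(task$params)),
                    muscle_labels = task$params$name, modality = "model")
}

#' Default desk-scale joint task
#'
#' A two-joint (shoulder elevation, internal rotation) task over the
#' normalized movement cycle with hand-authored signed moment arms such that
#' the three functional muscle groups of the smash are the efficient
#' actuators of the three phase-specific demands: the scapular group has a
#' large elevation arm (preparation-phase elevation bump at 20% of the
#' cycle), the anterior group a positive internal-rotation arm (impact-phase
#' bump at 50%), and the posterior group a negative internal-rotation arm
#' (follow-through external-rotation demand at 80%).
#'
#' @param n_time Number of time samples (default 101).
#' @param amplitudes Moment bump amplitudes in N m: elevation, internal
#'   rotation, external rotation.
#' @return A [joint_task()].
#' @export
default_joint_task <- function(n_time = 101, amplitudes = c(30, 35, 30)) {
  params <- toy_muscle_params()
  groups <- default_synergy_groups()
  labs <- params$name
  arms <- matrix(0, 2, length(labs),
                 dimnames = list(c("elevation", "internal_rotation"), labs))
  arms["elevation", labs %in% groups$scapular] <- 0.05
  arms["internal_rotation", labs %in% groups$anterior] <- 0.04
  arms["internal_rotation", labs %in% groups$posterior] <- -0.04

  tt <- seq(0, 1, length.out = n_time)
  bump <- function(mu) exp(-(tt - mu)^2 / (2 * 0.075^2))
  moments <- rbind(
    elevation = amplitudes[1] * bump(0.20),
    internal_rotation = amplitudes[2] * bump(0.50) - amplitudes[3] * bump(0.80)
  )
  joint_task(arms, moments, params)
}
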
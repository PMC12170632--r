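#' Default shoulder muscle labels
#'
#' The fifteen surface-EMG muscle abbreviations used throughout the package:
#' three deltoid heads, infraspinatus, three pectoralis major regions,
#' latissimus dorsi, two triceps heads, biceps long head, three trapezius
#' regions, and serratus anterior.
#'
#' @return Character vector of length 15.
#' @export
default_muscle_labels <- function() {
  c("DELT1", "DELT2", "DELT3", "INFSP", "PECM1", "PECM2", "PECM3",
    "LAT2", "TRIlat", "TRImed", "BIClong", "TRP1", "TRP3", "TRP4", "SRA")
}

# Functional grouping used for the default three-synergy ground truth:
# scapular stabilisers (trapezius group + serratus), anterior power
# generators (pectoralis + anterior deltoid + biceps), and posterior
# decelerators (posterior/middle deltoid, infraspinatus, latissimus, triceps).
default_synergy_groups <- function() {
  list(
    scapular  = c("TRP1", "TRP3", "TRP4", "SRA"),
    anterior  = c("PECM1", "PECM2", "PECM3", "DELT1", "BIClong"),
    posterior = c("DELT2", "DELT3", "INFSP", "LAT2", "TRIlat", "TRImed")
  )
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the synthetic generator emulates: a cohort of
#' elite players each performing several maximal-effort smash trials, with
#' fifteen shoulder muscles recorded, activations driven by a small number of
#' ground-truth synergies spanning the movement phases, additive noise at a
#' target signal-to-noise ratio, and a systematic weight perturbation for the
#' model modality.
#'
#' @param n_muscles Number of muscles (default 15).
#' @param muscle_labels Labels, one per muscle.
#' @param n_time Number of normalized time samples over the 0-100% cycle
#'   (default 101).
#' @param k_true Number of ground-truth synergies (default 3).
#' @param n_subjects Number of subjects (default 20).
#' @param n_trials Trials per subject (default 5).
#' @param snr_db Target signal-to-noise ratio in dB (default 20; `Inf`
#'   disables noise).
#' @param modality_perturb Fractional multiplicative weight perturbation
#'   applied to the model modality (default 0.10).
#' @param envelope_width Fraction of the cycle occupied by each coefficient
#'   bump (Gaussian sigma = `envelope_width / 2`; default 0.15).
#' @param subject_jitter Fractional multiplicative jitter applied to each
#'   subject's weights (default 0.05).
#' @param seed Master seed; all randomness derives from it.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_muscles = 15,
                         muscle_labels = NULL,
                         n_time = 101,
                         k_true = 3,
                         n_subjects = 20,
                         n_trials = 5,
                         snr_db = 20,
                         modality_perturb = 0.10,
                         envelope_width = 0.15,
                         subject_jitter = 0.05,
                         seed = 42) {
  n_muscles <- assert_count(n_muscles, "n_muscles")
  if (is.null(muscle_labels)) {
    muscle_labels <- if (n_muscles == 15) default_muscle_labels()
                     else paste0("m", seq_len(n_muscles))
  }
  if (length(muscle_labels) != n_muscles || anyDuplicated(muscle_labels)) {
    abort("`muscle_labels` must be unique and match `n_muscles`.")
  }
  n_time <- assert_count(n_time, "n_time", min = 2)
  k_true <- assert_count(k_true, "k_true")
  if (k_true > n_muscles) abort("`k_true` must not exceed `n_muscles`.")
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_trials <- assert_count(n_trials, "n_trials")
  assert_scalar_number(snr_db, "snr_db", allow_inf = TRUE)
  if (is.na(snr_db) || (!is.finite(snr_db) && snr_db < 0)) abort("`snr_db` must be finite or +Inf.")
  assert_scalar_number(modality_perturb, "modality_perturb", lower = 0, upper = 1 - 1e-12)
  assert_scalar_number(envelope_width, "envelope_width", lower = 1e-6, upper = 1)
  assert_scalar_number(subject_jitter, "subject_jitter", lower = 0, upper = 1)
  seed <- assert_count(seed, "seed", min = 0)
  structure(
    list(n_muscles = n_muscles, muscle_labels = muscle_labels,
         n_time = n_time, k_true = k_true, n_subjects = n_subjects,
         n_trials = n_trials, snr_db = snr_db,
         modality_perturb = modality_perturb,
         envelope_width = envelope_width, subject_jitter = subject_jitter,
         seed = seed),
    class = "synth_config")
}

# Assign each muscle to a dominant synergy. With the default 15 labels and
# three synergies the functional grouping is used (scapular -> synergy 1,
# anterior -> 2, posterior -> 3); otherwise muscles are split into k roughly
# equal contiguous groups.
synergy_group_index <- function(config) {
  labs <- config$muscle_labels
  k <- config$k_true
  if (k == 3 && setequal(labs, default_muscle_labels())) {
    groups <- default_synergy_groups()
    idx <- integer(length(labs))
    for (g in seq_along(groups)) idx[labs %in% groups[[g]]] <- g
    return(idx)
  }
  sort(rep(seq_len(k), length.out = length(labs)))
}

#' Ground-truth synergies for the synthetic generator
#'
#' Builds a nonnegative weight matrix with unit-norm columns, each dominated
#' by one functional muscle group (dominant-group mean weight at least twice
#' the non-dominant mean), and smooth unimodal coefficient bumps whose
#' centres march through the movement cycle (20%, 50%, 80% for three
#' synergies), mirroring the preparation / impact / follow-through phase
#' ordering of the smash.
#'
#' @param config A [synth_config()].
#' @return A `ground_truth` list with `w_true` (muscles x k, unit-norm
#'   columns) and `c_true` (k x time).
#' @export
#' @examples
#' gt <- make_ground_truth(synth_config(seed = 42))
#' colSums(gt$w_true^2)  # unit-norm columns
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_muscles
  k <- config$k_true
  group <- synergy_group_index(config)

  w <- withr::with_seed(derive_seed(config$seed, 1), {
    w <- matrix(runif(n * k, 0.05, 0.30), n, k)
    for (j in seq_len(k)) {
      dom <- group == j
      w[dom, j] <- runif(sum(dom), 0.70, 1.00)
    }
    w
  })
  w <- sweep(w, 2, sqrt(colSums(w^2)), "/")

  centers <- if (k == 1) 0.5 else seq(0.20, 0.80, length.out = k)
  tt <- seq(0, 1, length.out = config$n_time)
  sigma <- config$envelope_width / 2
  c_true <- t(vapply(centers, function(mu) exp(-(tt - mu)^2 / (2 * sigma^2)),
                     numeric(config$n_time)))
  dimnames(w) <- list(config$muscle_labels, paste0("S", seq_len(k)))
  rownames(c_true) <- paste0("S", seq_len(k))
  structure(list(w_true = w, c_true = c_true), class = "ground_truth")
}

# Multiplicative perturbation of weights followed by column renormalization.
perturb_weights <- function(w, magnitude) {
  if (magnitude == 0) return(w)
  wp <- pmax(w * (1 + magnitude * rnorm(length(w))), 0)
  dim(wp) <- dim(w)
  dimnames(wp) <- dimnames(w)
  nrm <- sqrt(colSums(wp^2))
  nrm[nrm == 0] <- 1
  sweep(wp, 2, nrm, "/")
}

# Shared trial synthesis: M = W (C .* gains) + noise, clipped at zero. Noise
# is scaled so the empirical pre-clipping SNR equals snr_db exactly.
synth_trial_matrix <- function(w, c_true, snr_db, trial_seed) {
  withr::with_seed(trial_seed, {
    k <- ncol(w)
    gains <- rlnorm(k, meanlog = 0, sdlog = 0.1)
    s <- w %*% (c_true * gains)
    if (is.finite(snr_db)) {
      e <- matrix(rnorm(length(s)), nrow(s), ncol(s))
      e <- e * (frob(s) / (frob(e) * 10^(snr_db / 20)))
      s <- s + e
    }
    pmax(s, 0)
  })
}

#' Generate one synthetic activation trial
#'
#' For the `emg` modality the ground-truth weights are used as is; for the
#' `model` modality they receive an entrywise multiplicative perturbation of
#' magnitude `config$modality_perturb` (then column renormalization),
#' emulating systematic differences between model-predicted and
#' EMG-derived weightings. Per-trial lognormal gains (sdlog 0.1) scale each
#' synergy's coefficient, and zero-mean Gaussian noise is added at exactly
#' the configured SNR before clipping at zero.
#'
#' @param gt A [make_ground_truth()] result.
#' @param config The [synth_config()].
#' @param modality `"emg"` or `"model"`.
#' @param trial_seed Integer seed for this trial's gains, perturbation and
#'   noise.
#' @return An [activation_matrix()].
#' @export
generate_trial <- function(gt, config, modality = c("emg", "model"),
                           trial_seed = 1) {
  modality <- match.arg(modality)
  stopifnot(inherits(gt, "ground_truth"))
  w <- gt$w_true
  if (modality == "model") {
    w <- withr::with_seed(derive_seed(trial_seed, 7),
                          perturb_weights(w, config$modality_perturb))
  }
  m <- synth_trial_matrix(w, gt$c_true, config$snr_db, trial_seed)
  activation_matrix(m, muscle_labels = config$muscle_labels,
                    trial_id = as.character(trial_seed), modality = modality)
}

#' Generate a synthetic two-modality cohort
#'
#' Produces `n_subjects * n_trials` activation matrices per modality.
#' Each subject's weights are the ground truth jittered by
#' `subject_jitter` multiplicative noise (then renormalized), emulating
#' inter-subject variability; the model modality additionally carries one
#' per-subject weight perturbation of magnitude `modality_perturb`, so a
#' subject's model trials differ systematically (not just noisily) from
#' their EMG trials.
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `subject`, `trial`, `modality`, `seed`
#'   and a `data` list-column of [activation_matrix()] objects, plus the
#'   ground truth in attribute `"ground_truth"`.
#' @export
#' @examples
#' co <- generate_cohort(synth_config(n_subjects = 2, n_trials = 2, seed = 1))
#' nrow(co)  # 2 subjects x 2 trials x 2 modalities
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  gt <- make_ground_truth(config)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    w_subj <- withr::with_seed(
      derive_seed(config$seed, 2, s),
      perturb_weights(gt$w_true, config$subject_jitter))
    w_model <- withr::with_seed(
      derive_seed(config$seed, 3, s),
      perturb_weights(w_subj, config$modality_perturb))
    for (tr in seq_len(config$n_trials)) {
      for (mod in c("emg", "model")) {
        w <- if (mod == "emg") w_subj else w_model
        ts <- derive_seed(config$seed, 4, s, tr, if (mod == "emg") 0 else 1)
        m <- synth_trial_matrix(w, gt$c_true, config$snr_db, ts)
        am <- activation_matrix(m, muscle_labels = config$muscle_labels,
                                subject_id = sprintf("S%02d", s),
                                trial_id = sprintf("T%d", tr),
                                modality = mod)
        rows[[length(rows) + 1]] <- tibble(
          subject = sprintf("S%02d", s), trial = sprintf("T%d", tr),
          modality = mod, seed = ts, data = list(am))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "ground_truth") <- gt
  out
}

#' Default per-trial kinematic variable specification
#'
#' Three scalar kinematic variables with cohort means, within-subject
#' variability (derived from the per-subject coefficient of variation) and a
#' target intraclass correlation controlling the between- to within-subject
#' variance ratio: shoulder abduction angle 45.2 deg (CV 3.2%, ICC 0.92),
#' elbow flexion angle 85.6 deg (CV 4.5%, ICC 0.89), scapular protraction
#' 12.3 deg (CV 5.1%, ICC 0.85).
#'
#' @return A tibble with columns `variable`, `mean`, `within_sd`, `icc`.
#' @export
default_kinematic_spec <- function() {
  tibble(
    variable = c("shoulder_abduction", "elbow_flexion", "scapular_protraction"),
    mean = c(45.2, 85.6, 12.3),
    within_sd = c(0.032 * 45.2, 0.045 * 85.6, 0.051 * 12.3),
    icc = c(0.92, 0.89, 0.85)
  )
}

#' Generate per-trial scalar kinematic variables
#'
#' Each subject receives a Normal between-subject offset and each trial a
#' Normal within-subject deviation; the between-subject standard deviation is
#' `within_sd * sqrt(icc / (1 - icc))`, so the generating model's population
#' ICC(3,1) equals the requested `icc` in closed form (a variance ratio of
#' 9:1 gives ICC 0.9).
#'
#' @param config A [synth_config()] (supplies `n_subjects`, `n_trials`,
#'   `seed`).
#' @param spec Variable specification tibble; see [default_kinematic_spec()].
#' @return A tibble with `subject`, `trial`, and one column per variable.
#' @export
generate_kinematic_trials <- function(config, spec = default_kinematic_spec()) {
  stopifnot(inherits(config, "synth_config"))
  req <- c("variable", "mean", "within_sd", "icc")
  if (!all(req %in% names(spec))) abort("`spec` needs variable, mean, within_sd, icc columns.")
  if (any(spec$icc < 0 | spec$icc >= 1)) abort("`icc` must lie in [0, 1).")

  ns <- config$n_subjects
  nt <- config$n_trials
  out <- tibble(
    subject = rep(sprintf("S%02d", seq_len(ns)), each = nt),
    trial = rep(sprintf("T%d", seq_len(nt)), times = ns)
  )
  for (i in seq_len(nrow(spec))) {
    v <- spec[i, ]
    between_sd <- if (v$icc == 0) 0 else v$within_sd * sqrt(v$icc / (1 - v$icc))
    vals <- withr::with_seed(derive_seed(config$seed, 5, i), {
      offs <- rnorm(ns, 0, between_sd)
      v$mean + rep(offs, each = nt) + rnorm(ns * nt, 0, v$within_sd)
    })
    out[[v$variable]] <- vals
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' One CSV per trial in the standard activation layout, a manifest CSV
#' mapping file to subject/trial/modality/seed, and the ground truth as a
#' `ground_truth_w.csv` / `ground_truth_c.csv` pair.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- dplyr::mutate(
    dplyr::select(cohort, "subject", "trial", "modality", "seed"),
    file = sprintf("%s_%s_%s.csv", .data$subject, .data$trial, .data$modality))
  purrr::walk2(cohort$data, manifest$file,
               ~ write_activation_csv(.x, file.path(dir, .y)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    readr::write_csv(as.data.frame(gt$w_true) |> tibble::rownames_to_column("muscle"),
                     file.path(dir, "ground_truth_w.csv"), progress = FALSE)
    readr::write_csv(as.data.frame(t(gt$c_true)),
                     file.path(dir, "ground_truth_c.csv"), progress = FALSE)
  }
  invisible(manifest)
}
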
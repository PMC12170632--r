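#' VAF curves over candidate synergy numbers
#'
#' Runs [nmf_decompose()] for every `k` in `k_range` on the same matrix and
#' collects global and per-muscle (local) VAF, the percentage-point
#' improvement of global VAF from `k` to `k + 1`, and the fitted
#' decompositions themselves for reuse.
#'
#' @param m An [activation_matrix()] or nonnegative matrix.
#' @param k_range Contiguous integer range of candidate synergy numbers
#'   (default `1:8`).
#' @param n_restarts,max_iter,tol,seed Passed to [nmf_decompose()]; all k use
#'   the same master seed.
#' @return An `order_selection` object: list with a `curves` tibble
#'   (`k`, `global_vaf`, `improvement_pts`, `min_local_vaf`, `local_vaf`
#'   list-column) and a `decompositions` list indexed by `k`.
#' @export
vaf_curve <- function(m, k_range = 1:8, n_restarts = 50, max_iter = 100,
                      tol = 1e-6, seed = 1) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(diff(k_range) != 1)) abort("`k_range` must be contiguous.")
  if (min(k_range) < 1 || max(k_range) > min(dim(m))) {
    abort("`k_range` must lie within [1, min(dim(m))].")
  }
  fits <- lapply(k_range, function(k) {
    nmf_decompose(m, k, n_restarts = n_restarts, max_iter = max_iter,
                  tol = tol, seed = seed)
  })
  gv <- vapply(fits, function(s) global_vaf(m, reconstruct(s)), numeric(1))
  lv <- lapply(fits, function(s) local_vaf(m, reconstruct(s)))
  improvement <- c(100 * diff(gv), NA_real_)
  curves <- tibble(
    k = k_range,
    global_vaf = gv,
    improvement_pts = improvement,
    min_local_vaf = vapply(lv, function(v) {
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1)),
    local_vaf = lv
  )
  structure(list(curves = curves,
                 decompositions = setNames(fits, paste0("k", k_range))),
            class = "order_selection")
}

#' Select the number of synergies by the multi-criterion rule
#'
#' The selected order is the smallest `k` satisfying all three criteria
#' conjunctively: global VAF above `global_thresh` (default 0.90), every
#' defined local (per-muscle) VAF above `local_thresh` (default 0.75), and
#' the addition of the next synergy improving global VAF by less than
#' `slope_thresh` percentage points (default 5). Local VAF of zero-activity
#' muscles is undefined and excluded from the conjunction; at the largest
#' tested `k` the improvement is unobservable and treated as satisfied. If no
#' `k` qualifies, the largest tested `k` is returned with `selected = FALSE`.
#'
#' @param os An `order_selection` from [vaf_curve()].
#' @param global_thresh Global VAF threshold (fraction).
#' @param local_thresh Local VAF threshold (fraction).
#' @param slope_thresh Improvement threshold in percentage points.
#' @return The `order_selection` augmented with `k_selected`, `selected`
#'   (logical: did any k meet all criteria), thresholds, and per-k criterion
#'   flags appended to `curves`.
#' @export
#' @examples
#' m <- matrix(runif(6 * 40), 6, 40)
#' os <- select_order(vaf_curve(m, k_range = 1:4, n_restarts = 5, seed = 1))
#' os$k_selected
select_order <- function(os, global_thresh = 0.90, local_thresh = 0.75,
                         slope_thresh = 5) {
  stopifnot(inherits(os, "order_selection"))
  cv <- os$curves
  global_ok <- cv$global_vaf > global_thresh
  local_ok <- vapply(cv$local_vaf, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || all(v > local_thresh)
  }, logical(1))
  slope_ok <- is.na(cv$improvement_pts) | cv$improvement_pts < slope_thresh
  all_ok <- global_ok & local_ok & slope_ok

  if (any(all_ok)) {
    k_selected <- cv$k[which(all_ok)[1]]
    selected <- TRUE
  } else {
    k_selected <- max(cv$k)
    selected <- FALSE
  }
  os$curves <- dplyr::mutate(cv, global_ok = global_ok, local_ok = local_ok,
                             slope_ok = slope_ok, all_ok = all_ok)
  os$k_selected <- k_selected
  os$selected <- selected
  os$thresholds <- c(global = global_thresh, local = local_thresh,
                     slope = slope_thresh)
  os
}

#' @export
print.order_selection <- function(x, ...) {
  cat(sprintf("<order_selection> k in [%d, %d]", min(x$curves$k), max(x$curves$k)))
  if (!is.null(x$k_selected)) {
    cat(sprintf("; selected k = %d%s", x$k_selected,
                if (isTRUE(x$selected)) "" else " (no k met all criteria)"))
  }
  cat("\n")
  print(dplyr::select(x$curves, -"local_vaf"))
  invisible(x)
}

#' Leave-one-out cross-validation of synergy generalization
#'
#' For each trial: synergy weights are extracted from the remaining trials
#' concatenated along time, coefficients for the held-out trial are fitted by
#' nonnegative least squares with those weights fixed, and the generalization
#' gap is `delta_vaf = held-out VAF - within-sample VAF` (the VAF of the
#' training-set reconstruction). Values near zero indicate the synergy
#' structure generalizes across repetitions.
#'
#' @param trials List of [activation_matrix()] objects with shared muscle
#'   labels (at least 2).
#' @param k Number of synergies.
#' @param n_restarts,max_iter,tol,seed Passed to [nmf_decompose()].
#' @return A list with a per-trial tibble (`held_out`, `vaf_heldout`,
#'   `vaf_within`, `delta_vaf`) and `mean_delta`, `sd_delta`.
#' @export
leave_one_out_vaf <- function(trials, k, n_restarts = 20, max_iter = 100,
                              tol = 1e-6, seed = 1) {
  if (length(trials) < 2) abort("Leave-one-out needs at least 2 trials.")
  rows <- purrr::map_dfr(seq_along(trials), function(i) {
    train <- bind_trials(trials[-i])
    s <- nmf_decompose(train, k, n_restarts = n_restarts,
                       max_iter = max_iter, tol = tol,
                       seed = derive_seed(seed, 21, i))
    vaf_within <- global_vaf(train, reconstruct(s))
    held <- trials[[i]]
    c_held <- fit_coefficients(s$w, held)
    vaf_held <- global_vaf(held, s$w %*% c_held)
    tibble(held_out = i, vaf_heldout = vaf_held, vaf_within = vaf_within,
           delta_vaf = vaf_held - vaf_within)
  })
  list(per_trial = rows,
       mean_delta = mean(rows$delta_vaf),
       sd_delta = sd(rows$delta_vaf))
}

#' Split-half consistency of extracted synergies
#'
#' Randomly divides the trials into two halves, extracts synergies from each
#' half (trials concatenated along time), matches components across halves by
#' maximal total scalar-product similarity, and reports the matched cosine
#' similarity of weight columns and both cosine and Pearson similarity of
#' coefficient rows, repeated over `n_splits` random divisions. As a summary
#' consistency index, ICC(3,1) is computed on the splits-by-component matrix
#' of weight cosines (components as targets, splits as raters) together with
#' the corresponding SEM.
#'
#' @inheritParams leave_one_out_vaf
#' @param n_splits Number of random split-half divisions (default 10).
#' @return A list with a per-split tibble (`split`, `component`,
#'   `w_cosine`, `c_cosine`, `c_pearson`), a per-component summary, and
#'   `icc`, `sem`.
#' @export
split_half_consistency <- function(trials, k, n_splits = 10, seed = 1,
                                   n_restarts = 20, max_iter = 100,
                                   tol = 1e-6) {
  if (length(trials) < 2) abort("Split-half needs at least 2 trials.")
  n <- length(trials)
  rows <- purrr::map_dfr(seq_len(n_splits), function(sp) {
    idx_a <- withr::with_seed(derive_seed(seed, 31, sp),
                              sort(sample(n, floor(n / 2))))
    idx_b <- setdiff(seq_len(n), idx_a)
    # one extraction seed per split (shared by both halves): identical half
    # data then yields identical factorizations, so duplicated halves score
    # a similarity of exactly 1
    sa <- nmf_decompose(bind_trials(trials[idx_a]), k, n_restarts = n_restarts,
                        max_iter = max_iter, tol = tol,
                        seed = derive_seed(seed, 32, sp))
    sb <- nmf_decompose(bind_trials(trials[idx_b]), k, n_restarts = n_restarts,
                        max_iter = max_iter, tol = tol,
                        seed = derive_seed(seed, 32, sp))
    mt <- match_synergies(sa, sb)
    # Coefficients are compared as the mean per-cycle profile of each half
    # (the concatenated C rows are reshaped trial-wise and averaged), so
    # halves with different trial counts remain comparable.
    nt <- ncol(trials[[1]])
    mean_profile <- function(row) rowMeans(matrix(row, nrow = nt))
    purrr::map_dfr(seq_len(nrow(mt)), function(j) {
      ia <- mt$index_a[j]; ib <- mt$index_b[j]
      ca <- mean_profile(sa$c[ia, ]); cb <- mean_profile(sb$c[ib, ])
      tibble(split = sp, component = ia,
             w_cosine = mt$w_similarity[j],
             c_cosine = scalar_product_similarity(ca, cb),
             c_pearson = if (sd(ca) > 0 && sd(cb) > 0) cor(ca, cb) else NA_real_)
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(rows, .data$component),
    w_cosine_mean = mean(.data$w_cosine), w_cosine_sd = sd(.data$w_cosine),
    c_cosine_mean = mean(.data$c_cosine),
    c_pearson_mean = mean(.data$c_pearson, na.rm = TRUE),
    .groups = "drop")
  wmat <- tidyr::pivot_wider(rows[, c("split", "component", "w_cosine")],
                             names_from = "component",
                             values_from = "w_cosine")
  wmat <- as.matrix(wmat[, -1, drop = FALSE])
  icc <- if (nrow(wmat) >= 2 && ncol(wmat) >= 2) icc_3_1(t(wmat)) else NA_real_
  sd_between <- if (ncol(wmat) >= 2) sd(colMeans(wmat)) else NA_real_
  sem <- if (!is.na(icc) && !is.na(sd_between) && icc >= 0) {
    sem_from_icc(sd_between, icc)
  } else NA_real_
  list(per_split = rows, summary = summary, icc = icc, sem = sem)
}
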
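#' Non-negative matrix factorization of an activation matrix
#'
#' Decomposes a nonnegative muscles-by-time matrix `M` into synergy weights
#' `W` (muscles x k) and activation coefficients `C` (k x time) by minimizing
#' the Frobenius reconstruction error with Lee-Seung multiplicative updates.
#' The factorization is repeated from `n_restarts` random initializations and
#' the solution with the lowest reconstruction error is returned, normalized
#' so each column of `W` has unit Euclidean norm (the compensating scale is
#' moved into `C`).
#'
#' Each restart initializes `W` and `C` elementwise from Uniform(0, 1] scaled
#' to the magnitude of `M`, runs at most `max_iter` multiplicative updates,
#' and stops early once the relative change of the Frobenius objective drops
#' below `tol`. Within a run the objective is non-increasing at every
#' iteration (the defining property of the multiplicative updates); a small
#' epsilon (1e-12) guards denominators against division by zero.
#'
#' @param m An [activation_matrix()] or nonnegative numeric matrix
#'   (muscles x time).
#' @param k Number of synergies, `1 <= k <= min(dim(m))`.
#' @param n_restarts Number of random restarts (default 50).
#' @param max_iter Iteration cap per restart (default 100).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#' @param seed Master seed; restart seeds are derived from it.
#'
#' @return A `synergy_set`: list with `w`, `c`, `objective` (Frobenius
#'   error), `trace` (per-iteration objective of the winning restart),
#'   `restarts_used`, `converged`, `k`, `muscle_labels`.
#' @export
#' @examples
#' m <- matrix(runif(60), 6, 10)
#' s <- nmf_decompose(m, k = 2, n_restarts = 5, seed = 1)
#' global_vaf(m, reconstruct(s))
nmf_decompose <- function(m, k, n_restarts = 50, max_iter = 100,
                          tol = 1e-6, seed = 1) {
  labels <- rownames(m)
  m <- unclass(m)
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix.")
  if (any(m < 0)) abort("`m` must be nonnegative.")
  k <- assert_count(k, "k")
  if (k > min(dim(m))) abort("`k` must not exceed min(n_muscles, n_time).")
  n_restarts <- assert_count(n_restarts, "n_restarts")
  max_iter <- assert_count(max_iter, "max_iter")

  scale0 <- 2 * sqrt(max(mean(m), .Machine$double.eps) / k)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- withr::with_seed(derive_seed(seed, 11, r), {
      list(w = matrix(runif(nrow(m) * k), nrow(m), k) * scale0,
           c = matrix(runif(k * ncol(m)), k, ncol(m)) * scale0)
    })
    fit <- .nmf_mu_cpp(m, init$w, init$c, max_iter, tol, 1e-12)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }

  s <- structure(
    list(w = best$w, c = best$c, objective = best$objective,
         trace = as.numeric(best$trace), restarts_used = n_restarts,
         converged = isTRUE(best$converged), k = k,
         muscle_labels = labels %||% paste0("m", seq_len(nrow(m)))),
    class = "synergy_set")
  normalize_synergies(s)
}

# Pure-R reference implementation of one multiplicative-update run; used as
# an independent check of the compiled core in the test suite.
nmf_mu_reference <- function(m, w, c, max_iter = 100, tol = 1e-6, eps = 1e-12) {
  obj_prev <- frob(m - w %*% c)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    c <- c * (crossprod(w, m)) / (crossprod(w) %*% c + eps)
    w <- w * (m %*% t(c)) / (w %*% tcrossprod(c) + eps)
    obj <- frob(m - w %*% c)
    trace <- c(trace, obj)
    denom <- if (obj_prev > 0) obj_prev else 1
    if (abs(obj_prev - obj) / denom < tol) { converged <- TRUE; break }
    obj_prev <- obj
  }
  list(w = w, c = c, objective = trace[length(trace)], trace = trace,
       converged = converged)
}

#' Reconstruct an activation matrix from a synergy set
#'
#' @param s A `synergy_set`.
#' @return The nonnegative matrix product `W %*% C`.
#' @export
reconstruct <- function(s) {
  stopifnot(inherits(s, "synergy_set"))
  out <- s$w %*% s$c
  rownames(out) <- s$muscle_labels
  out
}

#' Global variance accounted for
#'
#' Uncentered VAF: `1 - ||m - m_hat||_F^2 / ||m||_F^2`. Equals 1 only for an
#' exact reconstruction and 0 for a zero reconstruction.
#'
#' @param m Observed nonnegative matrix.
#' @param m_hat Reconstruction of the same shape.
#' @return A fraction `<= 1`.
#' @export
global_vaf <- function(m, m_hat) {
  m <- unclass(m)
  if (!all(dim(m) == dim(m_hat))) abort("`m` and `m_hat` must have the same shape.")
  denom <- sum(m^2)
  if (denom == 0) abort("Global VAF is undefined for an all-zero matrix.")
  1 - sum((m - m_hat)^2) / denom
}

#' Per-muscle (local) variance accounted for
#'
#' Rowwise uncentered VAF. A zero-activity muscle (all-zero row in `m`) has
#' undefined VAF and is reported as `NA` rather than raising an error.
#'
#' @inheritParams global_vaf
#' @return Named numeric vector, one value (or `NA`) per muscle row.
#' @export
local_vaf <- function(m, m_hat) {
  m <- unclass(m)
  if (!all(dim(m) == dim(m_hat))) abort("`m` and `m_hat` must have the same shape.")
  denom <- rowSums(m^2)
  num <- rowSums((m - m_hat)^2)
  out <- ifelse(denom == 0, NA_real_, 1 - num / denom)
  names(out) <- rownames(m)
  out
}

#' Normalize a synergy set's scale convention
#'
#' NMF is scale-ambiguous per component; this fixes the convention by scaling
#' each column of `W` to unit Euclidean norm and moving the inverse scale
#' into the corresponding row of `C`, leaving the product `W %*% C`
#' unchanged. All-zero columns are left untouched and flagged.
#'
#' @param s A `synergy_set`.
#' @return The normalized `synergy_set`, with a logical `zero_components`
#'   field marking all-zero columns.
#' @export
normalize_synergies <- function(s) {
  stopifnot(inherits(s, "synergy_set"))
  nrm <- sqrt(colSums(s$w^2))
  zero <- nrm == 0
  scl <- ifelse(zero, 1, nrm)
  s$w <- sweep(s$w, 2, scl, "/")
  s$c <- sweep(s$c, 1, scl, "*")
  s$zero_components <- zero
  rownames(s$w) <- s$muscle_labels
  colnames(s$w) <- paste0("S", seq_len(s$k))
  rownames(s$c) <- paste0("S", seq_len(s$k))
  s
}

# Construct a synergy_set directly from factors (used by tests and matching).
synergy_set <- function(w, c, muscle_labels = rownames(w)) {
  if (ncol(w) != nrow(c)) abort("`w` and `c` are not conformable.")
  if (any(w < 0) || any(c < 0)) abort("Factors must be nonnegative.")
  s <- structure(
    list(w = w, c = c, objective = NA_real_, trace = numeric(0),
         restarts_used = 0L, converged = NA, k = ncol(w),
         muscle_labels = muscle_labels %||% paste0("m", seq_len(nrow(w)))),
    class = "synergy_set")
  normalize_synergies(s)
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> k = %d, %d muscles x %d samples, Frobenius error %.4g (%s)\n",
              x$k, nrow(x$w), ncol(x$c), x$objective,
              if (isTRUE(x$converged)) "converged" else "iteration cap"))
  invisible(x)
}

#' Fit coefficients for a fixed weight matrix
#'
#' Nonnegative least squares per time sample: given synergy weights `W`,
#' finds `C >= 0` minimizing `||m - W C||_F`. Used to project held-out trials
#' onto synergies extracted from the remaining trials.
#'
#' @param w Nonnegative weight matrix (muscles x k).
#' @param m Nonnegative activation matrix (muscles x time).
#' @return Nonnegative coefficient matrix (k x time).
#' @export
fit_coefficients <- function(w, m) {
  m <- unclass(m)
  if (nrow(w) != nrow(m)) abort("`w` and `m` must agree on the number of muscles.")
  out <- vapply(seq_len(ncol(m)),
                function(t) pracma::lsqnonneg(w, m[, t])$x,
                numeric(ncol(w)))
  matrix(out, nrow = ncol(w), ncol = ncol(m))
}
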
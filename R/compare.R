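#' Scalar-product (cosine) similarity of nonnegative vectors
#'
#' Normalized dot product `(u . v) / (||u|| ||v||)`. For nonnegative inputs
#' the value lies in `[0, 1]`, reaching 1 only for parallel vectors; values
#' approaching 1 indicate greater similarity between synergy weight vectors.
#'
#' @param u,v Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return Similarity in `[0, 1]` for nonnegative inputs.
#' @export
#' @examples
#' scalar_product_similarity(c(1, 1), c(1, 0))  # 1/sqrt(2)
scalar_product_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("`u` and `v` must have equal length.")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("Similarity is undefined for a zero vector.")
  sum(u * v) / (nu * nv)
}

#' Pearson correlation between activation coefficient profiles
#'
#' Standard centered product-moment correlation, used to compare the
#' time-varying activation coefficients of matched synergies.
#'
#' @param x,y Numeric sequences of equal length (at least 3), each with
#'   nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Pearson similarity needs at least 3 samples.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson similarity is undefined for a zero-variance sequence.")
  }
  cor(x, y)
}

# All permutations of 1..n (n small); returned as a matrix with one
# permutation per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Match synergies between two decompositions
#'
#' Finds the one-to-one assignment between the components of `a` and `b`
#' maximizing total scalar-product similarity of the weight columns. The
#' assignment is exhaustive over permutations for up to 8 components per
#' side (guaranteed optimal) and greedy beyond. When the two sets have
#' different numbers of components, the matching is a bijection on the
#' smaller number.
#'
#' @param a,b `synergy_set` objects over the same muscles (same label
#'   order).
#' @return A tibble with `index_a`, `index_b`, `w_similarity`, ordered by
#'   `index_a`.
#' @export
match_synergies <- function(a, b) {
  stopifnot(inherits(a, "synergy_set"), inherits(b, "synergy_set"))
  if (!identical(a$muscle_labels, b$muscle_labels)) {
    abort("Synergy sets must share the same muscle labels in the same order.")
  }
  ka <- ncol(a$w); kb <- ncol(b$w)
  sim <- matrix(0, ka, kb)
  for (i in seq_len(ka)) {
    for (j in seq_len(kb)) {
      sim[i, j] <- scalar_product_similarity(a$w[, i], b$w[, j])
    }
  }
  swap <- ka > kb
  s <- if (swap) t(sim) else sim  # rows = smaller side
  nr <- nrow(s); nc <- ncol(s)

  if (nc <= 8) {
    perms <- all_permutations(nc)
    totals <- apply(perms, 1, function(p) {
      sum(s[cbind(seq_len(nr), p[seq_len(nr)])])
    })
    best <- as.integer(perms[which.max(totals), seq_len(nr)])
  } else {
    best <- integer(nr)
    avail <- rep(TRUE, nc)
    for (i in seq_len(nr)) {
      j <- which(avail)[which.max(s[i, avail])]
      best[i] <- j
      avail[j] <- FALSE
    }
  }
  out <- if (swap) {
    tibble(index_a = best, index_b = seq_len(nr),
           w_similarity = s[cbind(seq_len(nr), best)])
  } else {
    tibble(index_a = seq_len(nr), index_b = best,
           w_similarity = s[cbind(seq_len(nr), best)])
  }
  dplyr::arrange(out, .data$index_a)
}

#' Per-muscle similarity of matched synergy weights
#'
#' For each muscle, the scalar-product similarity of its weight profile
#' across synergies (its row of `W`, with `b`'s columns reordered by the
#' matching) between the two decompositions (`method = "weight_profile"`,
#' the default). Alternatively (`method = "reconstruction"`), the Pearson
#' correlation of the muscle's reconstructed activation signal in the two
#' sets.
#'
#' @param a,b Matched `synergy_set` objects.
#' @param matching Output of [match_synergies()].
#' @param method Similarity definition (see Details).
#' @return A tibble with `muscle` and `similarity` (`NA` where undefined).
#' @export
per_muscle_similarity <- function(a, b, matching = match_synergies(a, b),
                                  method = c("weight_profile", "reconstruction")) {
  method <- match.arg(method)
  wa <- a$w[, matching$index_a, drop = FALSE]
  wb <- b$w[, matching$index_b, drop = FALSE]
  if (method == "weight_profile") {
    vals <- vapply(seq_len(nrow(wa)), function(i) {
      ra <- wa[i, ]; rb <- wb[i, ]
      if (all(ra == 0) || all(rb == 0)) return(NA_real_)
      scalar_product_similarity(ra, rb)
    }, numeric(1))
  } else {
    ra_mat <- reconstruct(a); rb_mat <- reconstruct(b)
    vals <- vapply(seq_len(nrow(wa)), function(i) {
      xa <- ra_mat[i, ]; xb <- rb_mat[i, ]
      if (sd(xa) == 0 || sd(xb) == 0) return(NA_real_)
      cor(xa, xb)
    }, numeric(1))
  }
  tibble(muscle = a$muscle_labels, similarity = vals)
}

#' Compare two synergy decompositions
#'
#' Full similarity report between an EMG-derived and a model-derived
#' decomposition: optimal component matching, scalar-product similarity of
#' matched weight vectors, Pearson correlation of matched activation
#' coefficients, and per-muscle weight-profile similarity.
#'
#' @inheritParams per_muscle_similarity
#' @param per_muscle_method Per-muscle similarity definition, see
#'   [per_muscle_similarity()].
#' @return A `similarity_report`: list with `matching` (tibble adding
#'   `c_similarity` to the matched pairs), `per_muscle`, and a one-row
#'   `summary` tibble of means and SDs.
#' @export
#' @examples
#' w <- matrix(runif(12), 4, 3); cc <- matrix(runif(30), 3, 10)
#' a <- emgsynergy:::synergy_set(w, cc)
#' rep <- compare_decompositions(a, a)
#' rep$summary$w_similarity_mean  # 1
compare_decompositions <- function(a, b,
                                   per_muscle_method = c("weight_profile",
                                                         "reconstruction")) {
  per_muscle_method <- match.arg(per_muscle_method)
  mt <- match_synergies(a, b)
  c_sim <- vapply(seq_len(nrow(mt)), function(j) {
    ca <- a$c[mt$index_a[j], ]; cb <- b$c[mt$index_b[j], ]
    if (sd(ca) == 0 || sd(cb) == 0) return(NA_real_)
    pearson_similarity(ca, cb)
  }, numeric(1))
  mt$c_similarity <- c_sim
  pm <- per_muscle_similarity(a, b, mt, method = per_muscle_method)
  summary <- tibble(
    w_similarity_mean = mean(mt$w_similarity),
    w_similarity_sd = sd(mt$w_similarity),
    c_similarity_mean = mean(c_sim, na.rm = TRUE),
    c_similarity_sd = sd(c_sim, na.rm = TRUE),
    per_muscle_mean = mean(pm$similarity, na.rm = TRUE),
    per_muscle_sd = sd(pm$similarity, na.rm = TRUE)
  )
  structure(list(matching = mt, per_muscle = pm, summary = summary),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n")
  print(x$matching)
  cat(sprintf("mean W similarity %.3f, mean C similarity %.3f\n",
              x$summary$w_similarity_mean, x$summary$c_similarity_mean))
  invisible(x)
}
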
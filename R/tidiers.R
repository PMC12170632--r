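#' Tidy a synergy set
#'
#' @param x A `synergy_set`.
#' @param matrix `"w"` for the weight matrix (one row per muscle and
#'   synergy) or `"c"` for the coefficient matrix (one row per synergy and
#'   time sample).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.synergy_set <- function(x, matrix = c("w", "c"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "w") {
    tibble(
      muscle = rep(x$muscle_labels, times = x$k),
      synergy = rep(colnames(x$w), each = nrow(x$w)),
      weight = as.vector(x$w)
    )
  } else {
    nt <- ncol(x$c)
    tibble(
      synergy = rep(rownames(x$c), times = nt),
      time = rep(seq(0, 100, length.out = nt), each = x$k),
      coefficient = as.vector(x$c)
    )
  }
}

#' One-row summary of a synergy set
#'
#' @param x A `synergy_set`.
#' @param ... Unused.
#' @export
glance.synergy_set <- function(x, ...) {
  tibble(k = x$k, objective = x$objective,
         iterations = length(x$trace),
         restarts_used = x$restarts_used, converged = x$converged)
}

#' Tidy an order-selection result
#'
#' @param x An `order_selection` from [vaf_curve()] / [select_order()].
#' @param ... Unused.
#' @return The per-k curves tibble (without the local-VAF list column).
#' @export
tidy.order_selection <- function(x, ...) {
  dplyr::select(x$curves, -"local_vaf")
}

#' @rdname tidy.order_selection
#' @export
glance.order_selection <- function(x, ...) {
  tibble(
    k_selected = x$k_selected %||% NA_integer_,
    selected = x$selected %||% NA,
    k_min = min(x$curves$k), k_max = max(x$curves$k),
    max_global_vaf = max(x$curves$global_vaf)
  )
}

#' Tidy a similarity report
#'
#' @param x A `similarity_report`.
#' @param type `"matching"` (per matched synergy pair) or `"per_muscle"`.
#' @param ... Unused.
#' @export
tidy.similarity_report <- function(x, type = c("matching", "per_muscle"), ...) {
  type <- match.arg(type)
  if (type == "matching") x$matching else x$per_muscle
}

#' @rdname tidy.similarity_report
#' @export
glance.similarity_report <- function(x, ...) {
  x$summary
}
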
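#' Activation matrix container
#'
#' Bundles a nonnegative muscles-by-time activation matrix with its muscle
#' labels and trial metadata. This is the `M` that non-negative matrix
#' factorization decomposes into synergy weights `W` and coefficients `C`.
#'
#' @param values Numeric matrix, muscles in rows, time samples in columns,
#'   all entries nonnegative.
#' @param muscle_labels Character vector of unique labels, one per row. If
#'   `values` already has rownames they are used as the default.
#' @param subject_id,trial_id Optional identifiers carried through the
#'   pipeline.
#' @param modality Either `"emg"` (surface-EMG-derived) or `"model"`
#'   (musculoskeletal-model-predicted).
#'
#' @return An object of class `activation_matrix` (a labelled numeric matrix
#'   with metadata attributes).
#' @export
#' @examples
#' m <- activation_matrix(matrix(runif(20), 4, 5),
#'                        muscle_labels = c("DELT1", "DELT2", "TRP1", "SRA"))
#' dim(m)
activation_matrix <- function(values, muscle_labels = rownames(values),
                              subject_id = NA_character_,
                              trial_id = NA_character_,
                              modality = c("emg", "model")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (muscles x time).")
  }
  if (anyNA(values)) abort("`values` must not contain missing entries.")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Activation values must be nonnegative; first negative entry at row %d, column %d.",
                  bad[1], bad[2]))
  }
  if (is.null(muscle_labels)) {
    muscle_labels <- paste0("m", seq_len(nrow(values)))
  }
  if (length(muscle_labels) != nrow(values)) {
    abort("`muscle_labels` must have one entry per matrix row.")
  }
  if (anyDuplicated(muscle_labels)) abort("Muscle labels must be unique.")
  rownames(values) <- muscle_labels
  structure(values,
            subject_id = as.character(subject_id),
            trial_id = as.character(trial_id),
            modality = modality,
            class = c("activation_matrix", "matrix", "array"))
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf("<activation_matrix> %d muscles x %d samples (subject %s, trial %s, %s)\n",
              nrow(x), ncol(x), attr(x, "subject_id"), attr(x, "trial_id"),
              attr(x, "modality")))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @rdname activation_matrix
#' @param x An `activation_matrix`.
#' @param ... Unused.
#' @export
as_tibble.activation_matrix <- function(x, ...) {
  tibble(
    muscle = rep(rownames(x), times = ncol(x)),
    time = rep(seq(0, 100, length.out = ncol(x)), each = nrow(x)),
    activation = as.vector(unclass(x)),
    subject_id = attr(x, "subject_id"),
    trial_id = attr(x, "trial_id"),
    modality = attr(x, "modality")
  )
}

# Concatenate trials along time (shared muscle label order enforced).
bind_trials <- function(trials) {
  if (length(trials) == 0) abort("No trials supplied.")
  labs <- rownames(trials[[1]])
  for (tr in trials) {
    if (!identical(rownames(tr), labs)) {
      abort("All trials must share the same muscle labels in the same order.")
    }
  }
  out <- do.call(cbind, lapply(trials, unclass))
  activation_matrix(out, muscle_labels = labs,
                    subject_id = attr(trials[[1]], "subject_id"),
                    modality = attr(trials[[1]], "modality"))
}

#' Read and write activation matrices as CSV
#'
#' The exchange layout is one row per time sample: a leading `time` column
#' holding the normalized cycle position (0-100) and one column per muscle,
#' with the muscle abbreviation as header. Values must be numeric and
#' nonnegative; violations are reported with their coordinates.
#'
#' @param path File path.
#' @param subject_id,trial_id,modality Metadata attached to the returned
#'   object (not stored in the file).
#' @return `read_activation_csv()` returns an [activation_matrix()];
#'   `write_activation_csv()` returns `path` invisibly.
#' @export
read_activation_csv <- function(path, subject_id = NA_character_,
                                trial_id = NA_character_,
                                modality = c("emg", "model")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) abort("Duplicate column labels in activation CSV.")
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort(sprintf("Could not parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort(sprintf("Empty or column-less activation file: %s", path))
  }
  if (anyDuplicated(names(df))) abort("Duplicate column labels in activation CSV.")
  vals <- df[, setdiff(names(df), "time"), drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = list(NULL, names(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric cell in %s at data row %d, column '%s'.",
                  path, bad[1], colnames(num)[bad[2]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative activation in %s at data row %d, column '%s'.",
                  path, bad[1], colnames(num)[bad[2]]))
  }
  activation_matrix(t(num), muscle_labels = colnames(num),
                    subject_id = subject_id, trial_id = trial_id,
                    modality = modality)
}

#' @rdname read_activation_csv
#' @param m An [activation_matrix()].
#' @export
write_activation_csv <- function(m, path) {
  if (!inherits(m, "activation_matrix")) abort("`m` must be an activation_matrix.")
  df <- as.data.frame(t(unclass(m)))
  df <- cbind(time = seq(0, 100, length.out = ncol(m)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
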
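#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synergy analysis with its default:
#' synthetic cohort settings, NMF parameters (50 restarts, 100-iteration cap,
#' 1e-6 relative tolerance), order-selection thresholds (global VAF 0.90,
#' local VAF 0.75, slope 5 percentage points), and comparison options.
#' Unknown arguments are rejected.
#'
#' @param synth A [synth_config()].
#' @param k_range Candidate synergy numbers (default `1:6`).
#' @param n_restarts,max_iter,tol NMF parameters.
#' @param global_thresh,local_thresh,slope_thresh Order-selection thresholds.
#' @param per_muscle_method Per-muscle similarity definition (see
#'   [per_muscle_similarity()]).
#' @param seed Master seed for all analysis-stage randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            k_range = 1:6,
                            n_restarts = 50,
                            max_iter = 100,
                            tol = 1e-6,
                            global_thresh = 0.90,
                            local_thresh = 0.75,
                            slope_thresh = 5,
                            per_muscle_method = "weight_profile",
                            seed = 1) {
  stopifnot(inherits(synth, "synth_config"))
  assert_count(n_restarts, "n_restarts")
  assert_count(max_iter, "max_iter")
  assert_scalar_number(tol, "tol", lower = 0)
  assert_scalar_number(global_thresh, "global_thresh", lower = 0, upper = 1)
  assert_scalar_number(local_thresh, "local_thresh", lower = 0, upper = 1)
  assert_scalar_number(slope_thresh, "slope_thresh", lower = 0, upper = 100)
  seed <- assert_count(seed, "seed", min = 0)
  structure(
    list(synth = synth, k_range = k_range, n_restarts = n_restarts,
         max_iter = max_iter, tol = tol, global_thresh = global_thresh,
         local_thresh = local_thresh, slope_thresh = slope_thresh,
         per_muscle_method = per_muscle_method, seed = seed),
    class = "pipeline_config")
}

# Per-subject, per-modality synergy analysis of a cohort tibble: trials are
# concatenated along time, the synergy number is selected by the
# multi-criterion rule, and the decomposition at the selected order is kept.
analyze_cohort <- function(cohort, config) {
  groups <- dplyr::group_split(dplyr::group_by(cohort, .data$subject,
                                               .data$modality))
  purrr::map_dfr(groups, function(g) {
    m <- bind_trials(g$data)
    os <- vaf_curve(m, k_range = config$k_range,
                    n_restarts = config$n_restarts,
                    max_iter = config$max_iter, tol = config$tol,
                    seed = derive_seed(config$seed, 41,
                                       match(g$subject[1], unique(cohort$subject)),
                                       if (g$modality[1] == "emg") 0 else 1))
    os <- select_order(os, global_thresh = config$global_thresh,
                       local_thresh = config$local_thresh,
                       slope_thresh = config$slope_thresh)
    fit <- os$decompositions[[paste0("k", os$k_selected)]]
    tibble(subject = g$subject[1], modality = g$modality[1],
           k_selected = os$k_selected, selected = os$selected,
           global_vaf = os$curves$global_vaf[os$curves$k == os$k_selected],
           order_selection = list(os), fit = list(fit))
  })
}

#' Run the full synergy analysis pipeline
#'
#' Synth mode end-to-end run: generates the two-modality cohort, performs
#' per-subject multi-criterion synergy-number selection on the concatenated
#' trials of each modality, compares each subject's EMG-derived and
#' model-derived decompositions, computes the kinematic reliability report,
#' and (optionally) writes all artifacts plus a manifest to `out_dir`.
#' Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when supplied, VAF curves,
#'   selection decisions, synergy weight/coefficient matrices, the
#'   similarity and reliability reports and a JSON manifest are written
#'   there as CSV/JSON.
#' @return A `pipeline_result`: list with `per_subject` (selection results
#'   and fits), `similarity` (per-subject summaries), `similarity_mean`,
#'   `reliability`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$synth)
  per_subject <- analyze_cohort(cohort, config)

  subjects <- unique(per_subject$subject)
  similarity <- purrr::map_dfr(subjects, function(s) {
    emg <- per_subject$fit[per_subject$subject == s &
                             per_subject$modality == "emg"][[1]]
    mod <- per_subject$fit[per_subject$subject == s &
                             per_subject$modality == "model"][[1]]
    rep <- compare_decompositions(emg, mod,
                                  per_muscle_method = config$per_muscle_method)
    dplyr::mutate(rep$summary, subject = s, .before = 1)
  })

  kin <- generate_kinematic_trials(config$synth)
  reliability <- reliability_report(kin)

  result <- structure(
    list(per_subject = per_subject,
         similarity = similarity,
         similarity_mean = dplyr::summarise(
           similarity,
           w_similarity = mean(.data$w_similarity_mean),
           c_similarity = mean(.data$c_similarity_mean),
           per_muscle = mean(.data$per_muscle_mean)),
         reliability = reliability,
         config = config,
         config_hash = rlang::hash(config)),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) dplyr::mutate(df, config_hash = result$config_hash)

  curves <- purrr::map_dfr(seq_len(nrow(result$per_subject)), function(i) {
    row <- result$per_subject[i, ]
    dplyr::mutate(dplyr::select(row$order_selection[[1]]$curves, -"local_vaf"),
                  subject = row$subject, modality = row$modality, .before = 1)
  })
  readr::write_csv(stamp(curves), file.path(out_dir, "vaf_curves.csv"),
                   progress = FALSE)
  readr::write_csv(
    stamp(dplyr::select(result$per_subject, "subject", "modality",
                        "k_selected", "selected", "global_vaf")),
    file.path(out_dir, "order_selection.csv"), progress = FALSE)

  weights <- purrr::map_dfr(seq_len(nrow(result$per_subject)), function(i) {
    row <- result$per_subject[i, ]
    dplyr::mutate(tidy(row$fit[[1]], matrix = "w"),
                  subject = row$subject, modality = row$modality, .before = 1)
  })
  readr::write_csv(stamp(weights), file.path(out_dir, "synergy_weights.csv"),
                   progress = FALSE)
  coefs <- purrr::map_dfr(seq_len(nrow(result$per_subject)), function(i) {
    row <- result$per_subject[i, ]
    dplyr::mutate(tidy(row$fit[[1]], matrix = "c"),
                  subject = row$subject, modality = row$modality, .before = 1)
  })
  readr::write_csv(stamp(coefs), file.path(out_dir, "synergy_coefficients.csv"),
                   progress = FALSE)
  readr::write_csv(stamp(result$similarity),
                   file.path(out_dir, "similarity.csv"), progress = FALSE)
  readr::write_csv(stamp(result$reliability),
                   file.path(out_dir, "reliability.csv"), progress = FALSE)

  manifest <- list(
    package = "emgsynergy",
    version = as.character(utils::packageVersion("emgsynergy")),
    config_hash = result$config_hash,
    seed = result$config$seed,
    synth_seed = result$config$synth$seed,
    parameters = result$config[c("k_range", "n_restarts", "max_iter", "tol",
                                 "global_thresh", "local_thresh",
                                 "slope_thresh", "per_muscle_method")],
    synth = result$config$synth[setdiff(names(result$config$synth),
                                        "muscle_labels")]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  tab <- table(x$per_subject$k_selected, x$per_subject$modality)
  cat("selected synergy numbers (subjects x modality):\n")
  print(tab)
  cat(sprintf("mean W similarity %.3f, mean C similarity %.3f\n",
              x$similarity_mean$w_similarity, x$similarity_mean$c_similarity))
  invisible(x)
}
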
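# Manual selection method: rank patients by their count of manual-list
# medications, break ties by overall unique medication count, then randomly.

#' Score profiles by manual-list medication count
#'
#' Counts, for each profile, the unique medications that appear on the
#' manual method's list, alongside the profile-wide unique medication count
#' used for tie-breaking (which includes medications outside the knowledge
#' base).
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param kb A `pgx_kb` object.
#' @return Tibble: `patient_id`, `manual_med_count`, `total_med_count`.
#' @export
manual_scores <- function(profiles, kb) {
  manual_list <- method_medications(kb, "manual")
  tibble::tibble(
    patient_id = profiles$patient_id,
    manual_med_count = vapply(profiles$medications,
                              function(m) sum(m %in% manual_list), 0L),
    total_med_count = profiles$n_unique_meds
  )
}

#' Rank patients for the manual method
#'
#' Orders patients by descending manual-list medication count, breaking ties
#' by descending overall unique medication count, then randomly using a
#' seeded stream so the full ordering is reproducible.
#'
#' @param scores Tibble from [manual_scores()].
#' @param seed Integer seed for the random tie-break.
#' @return The scores tibble sorted into rank order with `random_key` and
#'   `rank` columns added.
#' @export
rank_manual <- function(scores, seed = 1L) {
  if (nrow(scores) == 0) stop("no scores to rank")
  key <- withr::with_seed(seed, stats::runif(nrow(scores)))
  ord <- order(-scores$manual_med_count, -scores$total_med_count, key)
  out <- scores[ord, ]
  out$random_key <- key[ord]
  out$rank <- seq_len(nrow(out))
  out
}

#' Select a cohort at the natural cut nearest a target size
#'
#' Candidate thresholds are the distinct score values; the cohort at
#' threshold `t` is every patient scoring at least `t`. The threshold whose
#' cohort size is closest to the testing-budget target wins; when two
#' thresholds are equidistant the smaller cohort is chosen (conserving the
#' testing budget).
#'
#' @param scores Tibble with a `patient_id` column and the score column
#'   named by `score_col`.
#' @param target Target cohort size (positive integer).
#' @param score_col Name of the score column.
#' @param method Label stored on the result.
#' @return Object of class `pgx_cohort`: list with `method`, `threshold`,
#'   `target`, `size`, `selected_ids`, and `candidates` (tibble of all
#'   thresholds with their cohort sizes).
#' @export
#' @examples
#' scores <- tibble::tibble(patient_id = as.character(1:5),
#'                          score = c(5, 3, 3, 2, 1))
#' select_natural_cut(scores, target = 3, score_col = "score")
select_natural_cut <- function(scores, target, score_col, method = score_col) {
  stopifnot(target >= 1, score_col %in% names(scores))
  s <- scores[[score_col]]
  thresholds <- sort(unique(s), decreasing = TRUE)
  sizes <- vapply(thresholds, function(t) sum(s >= t), 0L)
  if (length(thresholds) == 1) {
    warning("all scores equal; single candidate threshold ", thresholds)
  }
  dist <- abs(sizes - target)
  # ties between thresholds -> smaller cohort, i.e. the higher threshold,
  # which comes first in descending threshold order
  best <- which.min(dist)
  structure(
    list(
      method = method,
      threshold = thresholds[best],
      target = as.integer(target),
      size = sizes[best],
      selected_ids = scores$patient_id[s >= thresholds[best]],
      candidates = tibble::tibble(threshold = thresholds, size = sizes)
    ),
    class = "pgx_cohort"
  )
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat("<pgx_cohort> method=", x$method, ": ", x$size, " patients at score >= ",
      x$threshold, " (target ", x$target, ")\n", sep = "")
  invisible(x)
}
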
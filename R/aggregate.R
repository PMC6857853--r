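#' Per-patient aggregate features of cell atypia scores
#'
#' Three features summarise a patient's scored cells; a cell is atypical
#' when its score exceeds 0.5 (strictly):
#'
#' * `percentage_atypical(s)` = 100 * |\{s > 0.5\}| / n
#' * `mean_score_atypical(s)` = mean of the scores above 0.5, *undefined*
#'   (`NA`) when the patient has no atypical cell
#' * `mean_score_all(s)` = arithmetic mean of all scores
#'
#' An undefined mean atypical score is a value, not an error: downstream the
#' risk cascade treats such patients as automatic Test-2 negatives, since a
#' patient with zero atypical cells cannot be flagged high grade.
#'
#' @param scores Numeric vector of per-cell scores in `[0, 1]`; must be
#'   non-empty and free of missing values.
#' @return `percentage_atypical()`: percent in `[0, 100]`.
#' @name patient_features
NULL

check_scores <- function(scores) {
  if (length(scores) == 0) abort("at least one cell score is required")
  if (any(is.na(scores))) abort("cell scores must not be missing")
  if (any(scores < 0 | scores > 1)) abort("cell scores must lie in [0, 1]")
  invisible(scores)
}

#' @rdname patient_features
#' @export
#' @examples
#' percentage_atypical(c(0.6, 0.4, 0.8, 0.2))  # 50
percentage_atypical <- function(scores) {
  check_scores(scores)
  100 * sum(scores > 0.5) / length(scores)
}

#' @rdname patient_features
#' @return `mean_score_all()`: mean score in `[0, 1]`.
#' @export
mean_score_all <- function(scores) {
  check_scores(scores)
  mean(scores)
}

#' @rdname patient_features
#' @return `mean_score_atypical()`: mean score of atypical cells in
#'   `(0.5, 1]`, or `NA_real_` when there is none.
#' @export
mean_score_atypical <- function(scores) {
  check_scores(scores)
  atyp <- scores[scores > 0.5]
  if (length(atyp) == 0) NA_real_ else mean(atyp)
}

#' Aggregate one patient's cell scores
#'
#' @inheritParams patient_features
#' @return One-row tibble: `n_cells`, `pct_atypical`, `mean_all`,
#'   `mean_atypical` (`NA` when the patient has no atypical cell).
#' @seealso [aggregate_cohort()] for whole-cohort tables.
#' @export
#' @examples
#' aggregate_patient(c(0.6, 0.4, 0.8, 0.2))
aggregate_patient <- function(scores) {
  check_scores(scores)
  tibble(
    n_cells = length(scores),
    pct_atypical = percentage_atypical(scores),
    mean_all = mean_score_all(scores),
    mean_atypical = mean_score_atypical(scores)
  )
}

#' Aggregate a cohort's per-cell score table to per-patient features
#'
#' @param cohort Data frame with columns `patient_id`, `score` and
#'   optionally `class` (carried through).
#' @return Tibble with one row per patient: `patient_id`, (`class`,)
#'   `n_cells`, `pct_atypical`, `mean_all`, `mean_atypical`.
#' @export
aggregate_cohort <- function(cohort) {
  stopifnot(all(c("patient_id", "score") %in% names(cohort)))
  grp <- if ("class" %in% names(cohort)) c("patient_id", "class") else "patient_id"
  cohort |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(
      n_cells = n(),
      pct_atypical = percentage_atypical(.data$score),
      mean_all = mean_score_all(.data$score),
      mean_atypical = mean_score_atypical(.data$score),
      .groups = "drop"
    )
}
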
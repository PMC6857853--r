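#' Generate a synthetic per-cell score cohort
#'
#' Simulates the table a per-cell atypia scorer would produce for a patient
#' cohort, without rendering any images. Each patient draws a latent atypical
#' fraction and latent component means from the class-level (between-patient)
#' distributions of the [cohort_spec()], then draws its cells from the
#' two-component mixture: normal cells score in `[0, 0.5]`, atypical cells in
#' `(0.5, 1]`. Over at least ~50 patients x 200 cells the empirical class
#' atypical fraction and mean atypical score match the spec values to within
#' sampling error.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble (class `cyto_cohort`) with columns `patient_id`, `class`,
#'   `cell_id` and `score`, one row per cell.
#' @export
#' @examples
#' coh <- generate_score_cohort(cohort_spec())
#' dplyr::count(coh, class)
generate_score_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  withr::with_seed(spec$seed, {
    rows <- vector("list", sum(spec$classes$n_patients))
    idx <- 0L
    pid <- 0L
    for (ci in seq_len(nrow(spec$classes))) {
      cl <- spec$classes[ci, ]
      p_class <- cl$atypical_fraction
      # class-level normal-component mean implied by the all-cell mean
      mu_n_class <- if (p_class < 1)
        (cl$all_mean - p_class * cl$atypical_mean) / (1 - p_class) else 0.25
      # between-patient spread of the normal component chosen so the
      # patient-level all-cell mean has roughly the class all_sd
      sd_n <- if (p_class < 1)
        max(0.01, (cl$all_sd - abs(cl$atypical_mean - mu_n_class) *
                     cl$atypical_fraction_sd) / (1 - p_class)) else 0.01
      for (j in seq_len(cl$n_patients)) {
        pid <- pid + 1L
        idx <- idx + 1L
        p_i <- clamp(rnorm(1, p_class, cl$atypical_fraction_sd), 0, 1)
        mu_a_i <- clamp(rnorm(1, cl$atypical_mean, cl$atypical_sd), 0.5 + 1e-6, 1)
        mu_n_i <- clamp(rnorm(1, mu_n_class, sd_n), 0, 0.5)
        n <- cl$cells_per_patient
        atyp <- runif(n) < p_i
        score <- numeric(n)
        score[atyp] <- clamp(rnorm(sum(atyp), mu_a_i, spec$cell_sd), 0.5 + 1e-6, 1)
        score[!atyp] <- clamp(rnorm(sum(!atyp), mu_n_i, spec$cell_sd), 0, 0.5)
        rows[[idx]] <- tibble(
          patient_id = sprintf("P%03d", pid),
          class = cl$class,
          cell_id = seq_len(n),
          score = score
        )
      }
    }
    out <- bind_rows(rows)
    class(out) <- c("cyto_cohort", class(out))
    out
  })
}
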
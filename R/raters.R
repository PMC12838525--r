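#' Expert-rater panel configuration
#'
#' Describes a panel of simulated expert raters, each with an individual
#' diagnostic operating point (sensitivity/specificity), an intrarater
#' repeatability model (the second presentation of a duplicated participant
#' flips the rater's first answer with probability `intrarater_flip_prob`),
#' and a small chance of recognizing a participant, which excludes that
#' rater's annotation. Default operating points are 12 fixed values with
#' median sensitivity 0.62 and median specificity 0.87, and the default
#' flip probability 0.07 yields an expected intrarater Cohen's kappa of
#' about 0.85 at those operating points (see
#' [expected_intrarater_kappa()]).
#'
#' @param n_raters Number of raters.
#' @param sensitivity,specificity Numeric vectors recycled to `n_raters`.
#' @param intrarater_flip_prob Probability that the second presentation of a
#'   duplicate flips the rater's first answer.
#' @param recognition_prob Per rater-participant probability that the rater
#'   recognizes the face, flagging the annotation excluded.
#' @param n_duplicates Number of participants presented twice per rater.
#'
#' @return A `rater_params` object.
#' @export
rater_params <- function(n_raters = 12,
                         sensitivity = c(
                           0.50, 0.54, 0.57, 0.59, 0.61, 0.615,
                           0.625, 0.64, 0.66, 0.68, 0.72, 0.76
                         ),
                         specificity = c(
                           0.80, 0.83, 0.85, 0.86, 0.865, 0.869,
                           0.871, 0.875, 0.88, 0.89, 0.91, 0.93
                         ),
                         intrarater_flip_prob = 0.07,
                         recognition_prob = 0.01,
                         n_duplicates = 50) {
  if (!is_count(n_raters) || n_raters < 1) {
    stop_config("`n_raters` must be a positive count")
  }
  sensitivity <- rep_len(sensitivity, n_raters)
  specificity <- rep_len(specificity, n_raters)
  for (v in list(sensitivity, specificity, intrarater_flip_prob, recognition_prob)) {
    if (!is_proportion(v)) stop_config("rater probabilities must lie in [0, 1]")
  }
  if (!is_count(n_duplicates)) stop_config("`n_duplicates` must be a count")
  structure(
    list(
      n_raters = as.integer(n_raters),
      sensitivity = sensitivity, specificity = specificity,
      intrarater_flip_prob = intrarater_flip_prob,
      recognition_prob = recognition_prob,
      n_duplicates = as.integer(n_duplicates)
    ),
    class = "rater_params"
  )
}

#' Simulate an expert rating session
#'
#' Each rater sees every participant once, in an individual random order,
#' with `n_duplicates` randomly chosen participants presented a second
#' time. A patient is labelled positive with the rater's sensitivity, a
#' control with one minus the rater's specificity. The second presentation
#' of a duplicate flips the rater's first answer with the intrarater flip
#' probability. Recognized participants are flagged excluded for that
#' rater (both presentations).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param params A [rater_params()].
#' @param seed Integer seed.
#' @return An annotation tibble with columns `rater_id`, `participant_id`,
#'   `presentation_index` (1 or 2), `label` (0/1) and `excluded` (0/1).
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' ann <- simulate_expert_raters(cohort, seed = 1)
#' dplyr::count(ann, presentation_index)
simulate_expert_raters <- function(cohort, params = rater_params(), seed = 1L) {
  if (params$n_duplicates > nrow(cohort)) {
    stop_config("`n_duplicates` exceeds the cohort size")
  }
  truth <- setNames(
    as.integer(cohort$group == "acromegaly"),
    cohort$participant_id
  )
  n <- nrow(cohort)
  sessions <- lapply(seq_len(params$n_raters), function(r) {
    withr::with_seed(derive_seed(seed, "rater", r), {
      order_ids <- sample(cohort$participant_id)
      y <- truth[order_ids]
      p_pos <- ifelse(y == 1, params$sensitivity[r], 1 - params$specificity[r])
      first <- as.integer(runif(n) < p_pos)
      excluded <- as.integer(runif(n) < params$recognition_prob)
      dup_ids <- sample(order_ids, params$n_duplicates)
      flip <- runif(params$n_duplicates) < params$intrarater_flip_prob
      second <- abs(first[match(dup_ids, order_ids)] - as.integer(flip))
      bind_rows(
        tibble(
          rater_id = sprintf("R%02d", r),
          participant_id = order_ids,
          presentation_index = 1L,
          label = first,
          excluded = excluded
        ),
        tibble(
          rater_id = sprintf("R%02d", r),
          participant_id = dup_ids,
          presentation_index = 2L,
          label = second,
          excluded = excluded[match(dup_ids, order_ids)]
        )
      )
    })
  })
  bind_rows(sessions)
}
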
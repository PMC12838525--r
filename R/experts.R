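#' Expert-ensemble scores and labels
#'
#' Aggregates an annotation table into the expert ensemble: for each
#' participant, the mean of the non-excluded first-presentation labels
#' (repeat presentations are reserved for intrarater reliability), and the
#' binary ensemble label, positive when at least half of the contributing
#' raters called the participant positive (mean >= 0.5). Participants
#' whose annotations are all excluded are reported with `NA`, never
#' imputed.
#'
#' @param annotations Annotation tibble from [simulate_expert_raters()] or
#'   [read_annotations()].
#' @return A tibble with `participant_id`, `n_raters`, `mean_score`,
#'   `label`.
#' @export
ensemble_experts <- function(annotations) {
  first <- annotations[annotations$presentation_index == 1, ]
  all_parts <- distinct(first, .data$participant_id)
  usable <- first[first$excluded == 0, ]
  agg <- usable |>
    group_by(.data$participant_id) |>
    summarise(
      n_raters = n(),
      mean_score = mean(.data$label),
      .groups = "drop"
    ) |>
    mutate(label = as.integer(.data$mean_score >= 0.5))
  out <- left_join(all_parts, agg, by = "participant_id")
  out$n_raters[is.na(out$n_raters)] <- 0L
  out
}

# Cohen's kappa from a 2x2 agreement table (a = both positive, b = first
# positive only, c = second positive only, d = both negative).
kappa_from_counts <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (abs(1 - pe) < 1e-12) {
    # Degenerate marginals: agreement is at chance ceiling.
    return(if (po >= 1 - 1e-12) 1 else NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Intrarater reliability (Cohen's kappa) per rater
#'
#' Compares each rater's first and second presentations of the duplicated
#' participants (both presentations non-excluded) in a 2x2 contingency
#' table and computes Cohen's kappa
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. With degenerate marginals
#' (\eqn{p_e = 1}), kappa is 1 under perfect agreement and `NA` otherwise.
#'
#' @param annotations Annotation tibble.
#' @param min_duplicates Minimum duplicated presentations required per
#'   rater.
#' @return A tibble with `rater_id`, `kappa`, and the 2x2 counts `a`
#'   (both positive), `b` (first only), `c` (second only), `d` (both
#'   negative).
#' @export
#' @examples
#' ann <- simulate_expert_raters(generate_cohort(seed = 1), seed = 1)
#' intrarater_kappa(ann)
intrarater_kappa <- function(annotations, min_duplicates = 2) {
  second <- annotations[annotations$presentation_index == 2, ]
  first <- annotations[annotations$presentation_index == 1, ]
  pairs <- inner_join(
    first, second,
    by = c("rater_id", "participant_id"), suffix = c("_1", "_2")
  ) |>
    filter(.data$excluded_1 == 0, .data$excluded_2 == 0)
  out <- pairs |>
    group_by(.data$rater_id) |>
    summarise(
      a = sum(.data$label_1 == 1 & .data$label_2 == 1),
      b = sum(.data$label_1 == 1 & .data$label_2 == 0),
      c = sum(.data$label_1 == 0 & .data$label_2 == 1),
      d = sum(.data$label_1 == 0 & .data$label_2 == 0),
      .groups = "drop"
    )
  if (any(out$a + out$b + out$c + out$d < min_duplicates)) {
    stop_config("a rater has fewer duplicated presentations than required")
  }
  out$kappa <- mapply(kappa_from_counts, out$a, out$b, out$c, out$d)
  out[, c("rater_id", "kappa", "a", "b", "c", "d")]
}

#' Analytic intrarater kappa under the flip model
#'
#' Expected Cohen's kappa for a rater whose second presentation flips the
#' first answer with probability `flip_prob`, given the rater's operating
#' point and the case prevalence among duplicated participants. The
#' rater's positive rate is \eqn{q = prev \cdot Se + (1 - prev)(1 - Sp)};
#' observed agreement is \eqn{1 - flip}; chance agreement follows from the
#' first/second marginals. Used to calibrate and check the simulated
#' panel's repeatability.
#'
#' @param sensitivity,specificity Rater operating point.
#' @param flip_prob Second-presentation flip probability.
#' @param prevalence Case fraction among duplicated participants.
#' @return Expected kappa (numeric scalar).
#' @export
expected_intrarater_kappa <- function(sensitivity, specificity, flip_prob,
                                      prevalence = 0.5) {
  q1 <- prevalence * sensitivity + (1 - prevalence) * (1 - specificity)
  q2 <- q1 * (1 - flip_prob) + (1 - q1) * flip_prob
  po <- 1 - flip_prob
  pe <- q1 * q2 + (1 - q1) * (1 - q2)
  (po - pe) / (1 - pe)
}

#' Write or read a rater annotation table as CSV
#'
#' @param annotations Annotation tibble.
#' @param path CSV path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns the annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
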
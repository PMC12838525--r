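#' Youden-optimal threshold
#'
#' Finds the cutoff maximizing Youden's J statistic (sensitivity +
#' specificity - 1) by complete search over all candidate cutpoints: the
#' midpoints between consecutive distinct sorted scores plus the -Inf/+Inf
#' boundary sentinels. A score greater than or equal to the threshold is a
#' positive prediction. Ties in J are broken in favour of the smallest
#' threshold.
#'
#' @param scores Numeric probability scores.
#' @param labels Binary truth labels (1 = case); both classes must be
#'   present.
#' @return A one-row tibble with `threshold`, `j`, `sensitivity`,
#'   `specificity`.
#' @export
#' @examples
#' youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
youden_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    stop_config("both classes must be present to select a threshold")
  }
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (head(s, -1) + s[-1]) / 2, Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  stats_at <- vapply(cand, function(tau) {
    pred <- scores >= tau
    se <- sum(pred & labels == 1) / n_pos
    sp <- sum(!pred & labels == 0) / n_neg
    c(se + sp - 1, se, sp)
  }, numeric(3))
  best <- which.max(stats_at[1, ]) # candidates ascend, so first max = smallest tau
  tibble(
    threshold = cand[best],
    j = stats_at[1, best],
    sensitivity = stats_at[2, best],
    specificity = stats_at[3, best]
  )
}

#' Discretize a probability score
#'
#' A score of `threshold` *or more* is a positive prediction.
#'
#' @param score Numeric score(s).
#' @param threshold Cutoff.
#' @return Integer 0/1 vector.
#' @export
discretize <- function(score, threshold) {
  as.integer(score >= threshold)
}

#' Majority vote over an odd number of binary labels
#'
#' @param labels Binary 0/1 labels, odd count (or supply `tie`).
#' @param tie Optional tie-break label for even counts; without it an even
#'   split is an error.
#' @return 0 or 1.
#' @export
#' @examples
#' majority_vote(c(1, 0, 1))
majority_vote <- function(labels, tie = NULL) {
  stopifnot(all(labels %in% c(0, 1)))
  pos <- sum(labels == 1)
  neg <- length(labels) - pos
  if (pos == neg) {
    if (is.null(tie)) {
      stop_config("even split with no tie rule configured")
    }
    return(as.integer(tie))
  }
  as.integer(pos > neg)
}

#' Collect participant-level predictions from final-model scores
#'
#' Each final model's test-image scores are discretized at that model's
#' Youden threshold and the majority over the participant's test views
#' becomes the model's prediction for the participant. Verifies that
#' every participant received exactly `k_inner` predictions per
#' architecture.
#'
#' @param scores Tibble with `participant_id`, `architecture`,
#'   `outer_fold`, `model_id`, `target_yaw`, `score`.
#' @param thresholds Tibble with `architecture`, `outer_fold`, `model_id`,
#'   `threshold`.
#' @param k_inner Expected predictions per participant per architecture.
#' @return A tibble with `participant_id`, `architecture`, `outer_fold`,
#'   `model_id`, `prediction`.
#' @export
collect_predictions <- function(scores, thresholds, k_inner = 10) {
  joined <- inner_join(
    scores, thresholds,
    by = c("architecture", "outer_fold", "model_id")
  )
  if (nrow(joined) != nrow(scores)) {
    stop_config("some scores have no matching threshold")
  }
  preds <- joined |>
    mutate(vote = discretize(.data$score, .data$threshold)) |>
    group_by(
      .data$participant_id, .data$architecture, .data$outer_fold,
      .data$model_id
    ) |>
    summarise(prediction = majority_vote(.data$vote), .groups = "drop")
  coverage <- count(preds, .data$participant_id, .data$architecture)
  bad <- coverage$participant_id[coverage$n != k_inner]
  if (length(bad)) {
    stop_config(paste0(
      "prediction coverage gap: participant(s) ",
      paste(unique(bad), collapse = ", "),
      " lack exactly ", k_inner, " predictions"
    ))
  }
  preds
}

#' Pool architectures into an ensemble prediction set
#'
#' Pools the member architectures' per-participant binary predictions by
#' concatenation (e.g. 3 architectures x 10 models = 30 predictions per
#' participant); the downstream bootstrap treats the pool exactly like a
#' single architecture's prediction set.
#'
#' @param predictions A prediction tibble from [collect_predictions()].
#' @param members Character vector of member architecture names.
#' @param name Name of the resulting ensemble.
#' @return A prediction tibble with `architecture` set to `name`.
#' @export
build_ensemble <- function(predictions, members,
                           name = paste(members, collapse = "+")) {
  if (!length(members)) stop_config("`members` must be non-empty")
  missing <- setdiff(members, unique(predictions$architecture))
  if (length(missing)) {
    stop_config(paste("unknown member architecture(s):",
      paste(missing, collapse = ", ")))
  }
  sets <- lapply(members, function(m) {
    sort(unique(predictions$participant_id[predictions$architecture == m]))
  })
  if (length(unique(sets)) != 1) {
    stop_config("member architectures cover different participants")
  }
  predictions |>
    filter(.data$architecture %in% members) |>
    mutate(architecture = name)
}
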
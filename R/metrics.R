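#' Confusion-matrix metrics of binary predictions
#'
#' Sensitivity, specificity, balanced accuracy (their mean), precision and
#' F1 (harmonic mean of precision and sensitivity). With no predicted
#' positives, precision is undefined (`NA`) and F1 is 0 by convention,
#' with a warning.
#'
#' @param predictions Binary 0/1 predictions.
#' @param truth Binary 0/1 truth labels; both classes must be present.
#' @return A one-row tibble with `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `precision`, `f1`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
confusion_metrics <- function(predictions, truth) {
  stopifnot(
    length(predictions) == length(truth),
    all(predictions %in% c(0, 1)), all(truth %in% c(0, 1))
  )
  if (length(unique(truth)) < 2) {
    stop_config("both classes must be present in `truth`")
  }
  tp <- sum(predictions == 1 & truth == 1)
  fp <- sum(predictions == 1 & truth == 0)
  tn <- sum(predictions == 0 & truth == 0)
  fn <- sum(predictions == 0 & truth == 1)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  if (tp + fp == 0) {
    warn("no predicted positives: precision undefined, F1 set to 0")
    prec <- NA_real_
    f1 <- 0
  } else {
    prec <- tp / (tp + fp)
    f1 <- if (prec + se == 0) 0 else 2 * prec * se / (prec + se)
  }
  tibble(
    sensitivity = se, specificity = sp,
    balanced_accuracy = (se + sp) / 2,
    precision = prec, f1 = f1
  )
}

#' Compound metrics reconstructed from an operating point
#'
#' Given a (possibly published) sensitivity/specificity operating point
#' and the class sizes, reconstructs the implied expected confusion matrix
#' and the compound metrics: balanced accuracy, precision and F1.
#'
#' @param sensitivity,specificity Operating point in `[0, 1]`.
#' @param n_pos,n_neg Case and control counts.
#' @return A one-row tibble with `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `precision`, `f1`.
#' @export
#' @examples
#' metrics_from_rates(0.66, 0.93, 155, 153)
metrics_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(is_proportion(sensitivity), is_proportion(specificity),
    n_pos > 0, n_neg > 0)
  tp <- sensitivity * n_pos
  fp <- (1 - specificity) * n_neg
  prec <- tp / (tp + fp)
  tibble(
    sensitivity = sensitivity, specificity = specificity,
    balanced_accuracy = (sensitivity + specificity) / 2,
    precision = prec,
    f1 = 2 * prec * sensitivity / (prec + sensitivity)
  )
}

#' ROC AUC by midranks
#'
#' The area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic via midranks: the probability that a random case outscores a
#' random control, with tied scores contributing one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.2, 0.4, 0.3, 0.9), c(0, 0, 1, 1))
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  if (n1 == 0 || n0 == 0) {
    stop_config("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap ensemble metrics
#'
#' Emulates the study's bootstrap of an ensemble predictor. In each of `B`
#' runs, every participant's set of binary predictions (by raters, or by
#' the 10 nested-fold models of an architecture, or the concatenated pool
#' of an ensemble) is resampled with replacement at its own size; the
#' resampled mean is the participant's ensemble score for that run. The
#' binary metrics of the run discretize the score at 0.5 or more, while
#' ROC AUC uses the mean scores themselves. Reported are the per-metric
#' mean and percentile 95% interval (2.5th-97.5th) over the runs.
#'
#' The default resampling unit is the within-participant prediction set,
#' which captures predictor-ensemble variability, not cohort sampling
#' variability; `resample = "participants"` additionally resamples
#' participants with replacement for users wanting sampling-variability
#' intervals.
#'
#' @param predictions Long tibble with `participant_id` and binary
#'   `prediction` (one row per predictor per participant). For rater
#'   annotations, see [rater_prediction_set()].
#' @param truth Truth tibble (`participant_id`, `label`); every truth
#'   participant needs at least one prediction.
#' @param B Bootstrap runs.
#' @param seed Integer seed.
#' @param resample `"predictions"` (default, within-participant) or
#'   `"participants"`.
#' @param keep_draws Keep the per-run metric draws (for diagnostics)?
#' @return A `boot_metrics` object: a tibble with `metric`, `mean`,
#'   `lower`, `upper`; attributes record `B`, `seed`, class sizes and, if
#'   requested, the per-run draws.
#' @export
bootstrap_ensemble_metrics <- function(predictions, truth, B = 10000,
                                       seed = 1L,
                                       resample = c("predictions", "participants"),
                                       keep_draws = FALSE) {
  resample <- match.arg(resample)
  if (!is_count(B) || B < 1) stop_config("`B` must be a positive count")
  agg <- predictions |>
    group_by(.data$participant_id) |>
    summarise(n = n(), k = sum(.data$prediction), .groups = "drop")
  df <- inner_join(truth, agg, by = "participant_id")
  if (nrow(df) < nrow(truth)) {
    stop_config("every participant needs at least one prediction")
  }
  npart <- nrow(df)
  y <- df$label

  draws <- withr::with_seed(derive_seed(seed, "bootstrap"), {
    if (resample == "predictions") {
      nn <- matrix(df$n, B, npart, byrow = TRUE)
      ss <- matrix(
        rbinom(B * npart, nn, matrix(df$k / df$n, B, npart, byrow = TRUE)),
        nrow = B
      ) / nn
      ymat <- NULL
    } else {
      idx <- matrix(sample.int(npart, B * npart, replace = TRUE), nrow = B)
      nn <- matrix(df$n[idx], nrow = B)
      ss <- matrix(rbinom(B * npart, nn, matrix(df$k[idx] / df$n[idx], nrow = B)),
        nrow = B
      ) / nn
      ymat <- matrix(y[idx], nrow = B)
    }
    run_metric_draws(ss, y, ymat)
  })

  summ <- purrr::map_dfr(names(draws), function(m) {
    v <- draws[[m]]
    tibble(
      metric = m,
      mean = mean(v, na.rm = TRUE),
      lower = unname(quantile(v, 0.025, na.rm = TRUE)),
      upper = unname(quantile(v, 0.975, na.rm = TRUE))
    )
  })
  structure(
    summ,
    class = c("boot_metrics", class(summ)),
    B = B, seed = seed, resample = resample,
    n_participants = npart, n_pos = sum(y == 1), n_neg = sum(y == 0),
    draws = if (keep_draws) as_tibble(draws) else NULL
  )
}

# Per-run metric vectors from a B x n matrix of ensemble scores.
run_metric_draws <- function(ss, y, ymat = NULL) {
  B <- nrow(ss)
  pred <- ss >= 0.5
  if (is.null(ymat)) {
    pos <- y == 1
    tp <- rowSums(pred[, pos, drop = FALSE])
    fp <- rowSums(pred[, !pos, drop = FALSE])
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    se <- tp / n_pos
    sp <- (n_neg - fp) / n_neg
    auc <- vapply(seq_len(B), function(b) roc_auc(ss[b, ], y), numeric(1))
  } else {
    posm <- ymat == 1
    tp <- rowSums(pred & posm)
    fp <- rowSums(pred & !posm)
    n_pos <- rowSums(posm)
    n_neg <- ncol(ymat) - n_pos
    se <- tp / n_pos
    sp <- (n_neg - fp) / n_neg
    auc <- vapply(seq_len(B), function(b) {
      if (n_pos[b] == 0 || n_neg[b] == 0) NA_real_ else roc_auc(ss[b, ], ymat[b, ])
    }, numeric(1))
  }
  prec <- ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  f1 <- ifelse(
    is.na(prec) | prec + se == 0, 0,
    2 * prec * se / (prec + se)
  )
  list(
    sensitivity = se, specificity = sp,
    balanced_accuracy = (se + sp) / 2,
    precision = prec, f1 = f1, roc_auc = auc
  )
}

#' @export
print.boot_metrics <- function(x, ...) {
  cat(
    "<boot_metrics> B =", attr(x, "B"),
    "| participants =", attr(x, "n_participants"),
    paste0("(", attr(x, "n_pos"), " cases / ", attr(x, "n_neg"), " controls)"),
    "\n"
  )
  print(as_tibble(x))
  invisible(x)
}

#' Tidy bootstrap metrics
#'
#' @param x A `boot_metrics` object.
#' @param ... Unused.
#' @return The metric/mean/lower/upper tibble.
#' @export
tidy.boot_metrics <- function(x, ...) as_tibble(x)

#' One-row summary of a bootstrap result
#'
#' @param x A `boot_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with the run count, cohort sizes and the mean
#'   of each metric.
#' @export
glance.boot_metrics <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    as_tibble(x)[, c("metric", "mean")],
    names_from = "metric", values_from = "mean"
  )
  dplyr::bind_cols(
    tibble(
      B = attr(x, "B"),
      n_participants = attr(x, "n_participants"),
      n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg")
    ),
    wide
  )
}

#' Rater annotations as a prediction set
#'
#' Non-excluded first-presentation annotations, renamed so the expert
#' panel can be bootstrapped exactly like a model ensemble.
#'
#' @param annotations Annotation tibble.
#' @return A tibble with `participant_id` and `prediction`.
#' @export
rater_prediction_set <- function(annotations) {
  annotations |>
    filter(.data$presentation_index == 1, .data$excluded == 0) |>
    select(participant_id = "participant_id", prediction = "label")
}

#' Equal-count age groups
#'
#' Splits realized ages into `n_groups` equal-count groups (default
#' tertiles) with ties assigned to the lower group, or uses supplied
#' break points.
#'
#' @param age Numeric ages.
#' @param n_groups Number of groups.
#' @param breaks Optional explicit upper bounds of all but the last group.
#' @return Integer group index (1 = youngest), with the break values in
#'   attribute `"breaks"`.
#' @export
age_groups <- function(age, n_groups = 3, breaks = NULL) {
  if (is.null(breaks)) {
    srt <- sort(age)
    cuts <- ceiling(seq_len(n_groups - 1) * length(age) / n_groups)
    breaks <- srt[cuts]
  }
  g <- 1L + rowSums(outer(age, breaks, `>`))
  structure(as.integer(g), breaks = breaks)
}

#' Subgroup bootstrap metrics
#'
#' Repeats the ensemble bootstrap within subgroups along one or more axes:
#' `sex` (cases and controls of each sex), `age_tertile` (3 equal-count
#' age groups), and `biochemical_control` (sensitivity evaluated on the
#' controlled / active patient subsets, each paired with *all* controls,
#' since controls carry no disease status). Empty subgroups are skipped
#' with a notice.
#'
#' @param predictions Long prediction tibble (see
#'   [bootstrap_ensemble_metrics()]).
#' @param truth Truth tibble.
#' @param cohort Cohort tibble supplying `sex`, `age`,
#'   `biochem_controlled`.
#' @param axes Subset of `c("sex", "age_tertile", "biochemical_control")`.
#' @param B,seed Bootstrap settings.
#' @param age_breaks Optional preset upper bounds of the lower age groups.
#' @return A tibble with `axis`, `subgroup`, `n_cases`, `n_controls` and
#'   the per-metric `metric`, `mean`, `lower`, `upper` rows.
#' @export
subgroup_metrics <- function(predictions, truth, cohort,
                             axes = c("sex", "age_tertile", "biochemical_control"),
                             B = 10000, seed = 1L, age_breaks = NULL) {
  axes <- match.arg(axes, several.ok = TRUE)
  groups <- list()
  if ("sex" %in% axes) {
    for (s in c("F", "M")) {
      groups[[length(groups) + 1]] <- list(
        axis = "sex", subgroup = s,
        ids = cohort$participant_id[cohort$sex == s]
      )
    }
  }
  if ("age_tertile" %in% axes) {
    g <- age_groups(cohort$age, 3, breaks = age_breaks)
    brk <- attr(g, "breaks")
    lab <- c(
      sprintf("age<=%.0f", brk[1]),
      sprintf("age%.0f-%.0f", brk[1], brk[2]),
      sprintf("age>%.0f", brk[2])
    )
    for (t in 1:3) {
      groups[[length(groups) + 1]] <- list(
        axis = "age_tertile", subgroup = lab[t],
        ids = cohort$participant_id[g == t]
      )
    }
  }
  if ("biochemical_control" %in% axes) {
    controls <- cohort$participant_id[cohort$group == "control"]
    for (st in c(TRUE, FALSE)) {
      pats <- cohort$participant_id[
        cohort$group == "acromegaly" &
          !is.na(cohort$biochem_controlled) &
          cohort$biochem_controlled == st
      ]
      groups[[length(groups) + 1]] <- list(
        axis = "biochemical_control",
        subgroup = if (st) "controlled" else "active",
        ids = c(pats, controls)
      )
    }
  }
  out <- purrr::map_dfr(seq_along(groups), function(gi) {
    grp <- groups[[gi]]
    sub_truth <- truth[truth$participant_id %in% grp$ids, ]
    if (nrow(sub_truth) == 0 || length(unique(sub_truth$label)) < 2) {
      inform(sprintf(
        "skipping empty or single-class subgroup %s/%s", grp$axis, grp$subgroup
      ))
      return(NULL)
    }
    bm <- bootstrap_ensemble_metrics(
      predictions[predictions$participant_id %in% grp$ids, ],
      sub_truth,
      B = B, seed = derive_seed(seed, "subgroup", grp$axis, grp$subgroup)
    )
    mutate(as_tibble(bm),
      axis = grp$axis, subgroup = grp$subgroup,
      n_cases = attr(bm, "n_pos"), n_controls = attr(bm, "n_neg"),
      .before = 1
    )
  })
  out
}

#' Agreement decomposition across predictors
#'
#' Cross-classifies each participant by which predictors (e.g. the expert
#' ensemble and two model ensembles) classified them correctly: for cases,
#' the overlap of true positives; for controls, of true negatives.
#'
#' @param labels Tibble with `participant_id`, `predictor`, `label` (the
#'   binary ensemble-level label of each predictor); every predictor must
#'   cover every truth participant.
#' @param truth Truth tibble.
#' @return An `agreement_table` tibble with `group` (`"case"`/
#'   `"control"`), `region` (the `+`-joined set of correct predictors, or
#'   `"none"`), and `count`. See [agreement_summary()].
#' @export
agreement_table <- function(labels, truth) {
  predictors <- sort(unique(labels$predictor))
  wide <- tidyr::pivot_wider(
    labels,
    names_from = "predictor", values_from = "label"
  )
  wide <- inner_join(truth, wide, by = "participant_id")
  if (nrow(wide) < nrow(truth) ||
    anyNA(wide[, predictors])) {
    stop_config("a predictor is missing labels for some participants")
  }
  correct <- as.data.frame(
    lapply(wide[predictors], function(l) as.integer(l == wide$label))
  )
  region <- apply(correct, 1, function(r) {
    if (!any(r == 1)) "none" else paste(predictors[r == 1], collapse = "+")
  })
  out <- tibble(
    group = ifelse(wide$label == 1, "case", "control"),
    region = region
  ) |>
    count(.data$group, .data$region, name = "count")
  structure(out,
    class = c("agreement_table", class(out)),
    predictors = predictors
  )
}

#' Summarise an agreement table
#'
#' @param x An [agreement_table()].
#' @return A tibble per class with the total, the number classified
#'   correctly by at least one predictor, by all predictors, and by none.
#' @export
agreement_summary <- function(x) {
  predictors <- attr(x, "predictors")
  all_region <- paste(predictors, collapse = "+")
  x |>
    group_by(.data$group) |>
    summarise(
      n = sum(.data$count),
      correct_by_at_least_one = sum(.data$count[.data$region != "none"]),
      correct_by_all = sum(.data$count[.data$region == all_region]),
      missed_by_all = sum(.data$count[.data$region == "none"]),
      .groups = "drop"
    )
}

#' Format bootstrap results as a publication-style table
#'
#' @param results Named list of `boot_metrics` objects (one per
#'   predictor).
#' @param digits Decimal places.
#' @return A tibble with one row per predictor and one
#'   `mean (lower-upper)` column per metric.
#' @export
format_metrics_table <- function(results, digits = 2) {
  purrr::imap_dfr(results, function(bm, nm) {
    t <- as_tibble(bm)
    fmt <- sprintf(
      paste0("%.", digits, "f(%.", digits, "f-%.", digits, "f)"),
      t$mean, t$lower, t$upper
    )
    dplyr::bind_cols(
      tibble(predictor = nm),
      tidyr::pivot_wider(
        tibble(metric = t$metric, value = fmt),
        names_from = "metric", values_from = "value"
      )
    )
  })
}
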
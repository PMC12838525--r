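test_that("confusion metrics and operating-point reconstructions are exact", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_true(all(unlist(perfect) == 1))

  # published expert operating point implies balanced accuracy 0.795 and F1 0.76
  experts <- metrics_from_rates(0.66, 0.93, 155, 153)
  expect_equal(experts$balanced_accuracy, 0.795)
  expect_equal(experts$precision, (0.66 * 155) / (0.66 * 155 + 0.07 * 153))
  expect_equal(round(experts$f1, 2), 0.76)

  # face-pretrained operating point: precision 127.1/146.99, F1 ~ 0.84
  farl <- metrics_from_rates(0.82, 0.87, 155, 153)
  expect_equal(farl$precision, 127.1 / 146.99, tolerance = 1e-10)
  expect_equal(round(farl$f1, 2), 0.84)

  expect_warning(
    zero <- confusion_metrics(c(0, 0, 0, 0), c(1, 0, 1, 0)),
    "precision"
  )
  expect_true(is.na(zero$precision))
  expect_equal(zero$f1, 0)
  expect_error(confusion_metrics(c(1, 0), c(1, 1)), "both classes")
})

test_that("midrank AUC matches enumerated pairwise comparisons", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.2, 0.4, 0.3, 0.9), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  withr::with_seed(99, {
    for (i in 1:1000) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(c(1, 3), 1))
      expect_identical(
        roc_auc(scores, labels),
        pairwise_auc(scores, labels)
      )
    }
  })
})

test_that("midrank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    scores <- runif(80)
    labels <- rbinom(80, 1, plogis(3 * scores - 1.5))
  })
  labels[1:2] <- 0:1
  expect_equal(
    roc_auc(scores, labels),
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
      direction = "<")))
  )
})

unanimous_predictions <- function(truth, k = 10) {
  tidyr::crossing(participant_id = truth$participant_id, model = seq_len(k)) |>
    dplyr::inner_join(truth, by = "participant_id") |>
    dplyr::transmute(participant_id, prediction = label)
}

test_that("the within-participant bootstrap behaves as specified", {
  truth <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:20),
    label = rep(0:1, 10)
  )
  bm <- bootstrap_ensemble_metrics(
    unanimous_predictions(truth), truth,
    B = 500, seed = 1, keep_draws = TRUE
  )
  expect_true(all(bm$mean == 1))
  expect_true(all(bm$upper - bm$lower == 0))
  expect_true(all(bm$lower <= bm$mean & bm$mean <= bm$upper))

  # balanced-accuracy identity holds in every single run
  draws <- attr(bm, "draws")
  expect_equal(draws$balanced_accuracy, (draws$sensitivity + draws$specificity) / 2)

  # reproducible at B = 1
  b1a <- bootstrap_ensemble_metrics(unanimous_predictions(truth), truth, B = 1, seed = 3)
  b1b <- bootstrap_ensemble_metrics(unanimous_predictions(truth), truth, B = 1, seed = 3)
  expect_identical(tidy(b1a), tidy(b1b))

  expect_error(
    bootstrap_ensemble_metrics(unanimous_predictions(truth), truth, B = 0),
    "B"
  )
  expect_error(
    bootstrap_ensemble_metrics(
      unanimous_predictions(truth[1:5, ]),
      truth[1:6, ]
    ),
    "at least one prediction"
  )
})

test_that("interval width shrinks as the per-participant predictor count grows", {
  cohort <- generate_cohort(cohort_config(), seed = 4)
  truth <- cohort_truth(cohort)
  width_at <- vapply(c(3, 10, 30), function(k) {
    ann <- simulate_expert_raters(
      cohort,
      rater_params(
        n_raters = k, sensitivity = 0.7, specificity = 0.9,
        recognition_prob = 0
      ),
      seed = 4
    )
    bm <- bootstrap_ensemble_metrics(
      rater_prediction_set(ann), truth,
      B = 1500, seed = 4
    )
    t <- tidy(bm)
    t$upper[t$metric == "sensitivity"] - t$lower[t$metric == "sensitivity"]
  }, numeric(1))
  expect_true(all(diff(width_at) < 0))
})

test_that("nominal intervals cover the generative ensemble value loosely", {
  # closed-form expectation of the discretized-majority ensemble for a
  # common-operating-point panel
  exp_boot <- function(p, n = 12) {
    k <- 0:n
    sum(dbinom(k, n, p) * (1 - pbinom(ceiling(n / 2) - 1, n, k / n)))
  }
  truth_se <- exp_boot(0.7)
  covered <- 0
  for (s in 1:60) {
    cohort <- small_cohort(seed = s, n_pairs = 40)
    truth <- cohort_truth(cohort)
    ann <- simulate_expert_raters(
      cohort,
      rater_params(sensitivity = 0.7, specificity = 0.9, recognition_prob = 0),
      seed = s
    )
    bm <- tidy(bootstrap_ensemble_metrics(
      rater_prediction_set(ann), truth,
      B = 400, seed = s
    ))
    se <- bm[bm$metric == "sensitivity", ]
    covered <- covered + (se$lower <= truth_se && truth_se <= se$upper)
  }
  expect_gte(covered / 60, 0.9)
})

test_that("subgroup metrics restrict participants along each axis correctly", {
  cohort <- generate_cohort(cohort_config(), seed = 6)
  truth <- cohort_truth(cohort)
  preds <- unanimous_predictions(truth, k = 5)
  # flip all female cases to wrong predictions
  females <- cohort$participant_id[cohort$sex == "F" & cohort$group == "acromegaly"]
  preds$prediction[preds$participant_id %in% females] <- 0L

  sg <- subgroup_metrics(preds, truth, cohort, axes = "sex", B = 200, seed = 6)
  se_m <- sg$mean[sg$subgroup == "M" & sg$metric == "sensitivity"]
  se_f <- sg$mean[sg$subgroup == "F" & sg$metric == "sensitivity"]
  expect_equal(se_m, 1)
  expect_equal(se_f, 0)

  bio <- subgroup_metrics(preds, truth, cohort,
    axes = "biochemical_control", B = 200, seed = 6
  )
  # specificity always uses the full control group
  expect_true(all(bio$n_controls == sum(cohort$group == "control")))

  tert <- subgroup_metrics(preds, truth, cohort,
    axes = "age_tertile", B = 200, seed = 6
  )
  sizes <- dplyr::distinct(tert, subgroup, n_cases, n_controls)
  expect_equal(sum(sizes$n_cases + sizes$n_controls), nrow(cohort))
  expect_lte(max(sizes$n_cases + sizes$n_controls) -
    min(sizes$n_cases + sizes$n_controls), 2)
})

test_that("age grouping uses equal counts with ties to the lower group", {
  g <- age_groups(c(20, 30, 40, 50, 60, 70))
  expect_equal(as.integer(g), c(1, 1, 2, 2, 3, 3))
  tie <- age_groups(c(30, 30, 30, 50, 60, 70))
  expect_equal(as.integer(tie)[1:3], c(1, 1, 1))
  preset <- age_groups(c(25, 51, 52, 64, 65), breaks = c(51, 64))
  expect_equal(as.integer(preset), c(1, 1, 2, 2, 3))
})

test_that("agreement tables decompose overlap regions exactly", {
  truth <- tibble::tibble(
    participant_id = c(paste0("p", 1:4), paste0("c", 1:2)),
    label = c(1, 1, 1, 1, 0, 0)
  )
  labels <- dplyr::bind_rows(
    tibble::tibble(
      participant_id = truth$participant_id, predictor = "A",
      label = c(1, 1, 0, 0, 0, 0)
    ),
    tibble::tibble(
      participant_id = truth$participant_id, predictor = "B",
      label = c(0, 1, 1, 0, 0, 0)
    ),
    tibble::tibble(
      participant_id = truth$participant_id, predictor = "C",
      label = c(0, 1, 0, 0, 0, 1)
    )
  )
  at <- agreement_table(labels, truth)
  summ <- agreement_summary(at)
  cases <- summ[summ$group == "case", ]
  expect_equal(cases$correct_by_at_least_one, 3)
  expect_equal(cases$correct_by_all, 1) # p2
  expect_equal(cases$missed_by_all, 1) # p4
  expect_equal(cases$n, 4)
  controls <- summ[summ$group == "control", ]
  expect_equal(controls$missed_by_all, 0)
  expect_equal(controls$correct_by_all, 1) # c1 (C calls c2 positive)
  # region counts sum to class sizes
  expect_equal(sum(at$count[at$group == "case"]), 4)
  expect_equal(sum(at$count[at$group == "control"]), 2)

  same <- agreement_table(
    dplyr::mutate(labels, label = rep(truth$label, 3)), truth
  )
  expect_setequal(same$region, "A+B+C")

  expect_error(
    agreement_table(labels[-1, ], truth),
    "missing labels"
  )
})
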
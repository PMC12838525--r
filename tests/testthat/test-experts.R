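panel_annotations <- function(labels_by_rater, participant = "P1",
                              excluded = NULL) {
  n <- length(labels_by_rater)
  tibble::tibble(
    rater_id = sprintf("R%02d", seq_len(n)),
    participant_id = participant,
    presentation_index = 1L,
    label = as.integer(labels_by_rater),
    excluded = as.integer(seq_len(n) %in% (excluded %||% integer()))
  )
}

test_that("expert ensemble means and labels follow the half-or-more rule", {
  seven <- ensemble_experts(panel_annotations(c(rep(1, 7), rep(0, 5))))
  expect_equal(seven$mean_score, 7 / 12)
  expect_equal(seven$label, 1L)

  six <- ensemble_experts(panel_annotations(c(rep(1, 6), rep(0, 6))))
  expect_equal(six$mean_score, 0.5)
  expect_equal(six$label, 1L) # at least half positive is positive

  # one excluded rater shrinks the denominator
  excl <- ensemble_experts(
    panel_annotations(c(rep(1, 6), rep(0, 6)), excluded = 12)
  )
  expect_equal(excl$n_raters, 11L)
  expect_equal(excl$mean_score, 6 / 11)
  expect_equal(excl$label, 1L)

  # fully excluded participants are reported missing, never imputed
  gone <- ensemble_experts(panel_annotations(rep(1, 3), excluded = 1:3))
  expect_equal(gone$n_raters, 0L)
  expect_true(is.na(gone$mean_score))
  expect_true(is.na(gone$label))
})

test_that("intrarater kappa matches the closed form and its oracles", {
  # a = 20, b = 2, c = 3, d = 25
  first <- tibble::tibble(
    rater_id = "R01",
    participant_id = sprintf("P%03d", 1:50),
    presentation_index = 1L,
    label = rep(c(1L, 1L, 0L, 0L), c(20, 2, 3, 25)),
    excluded = 0L
  )
  second <- first
  second$presentation_index <- 2L
  second$label <- rep(c(1L, 0L, 1L, 0L), c(20, 2, 3, 25))
  res <- intrarater_kappa(dplyr::bind_rows(first, second))
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
    c(20, 2, 3, 25))
  po <- 45 / 50
  pe <- (22 * 23 + 28 * 27) / 2500
  expect_equal(res$kappa, (po - pe) / (1 - pe))
  # independent implementation cross-check
  skip_if_not_installed("e1071")
  tab <- matrix(c(20, 3, 2, 25), 2)
  expect_equal(res$kappa, e1071::classAgreement(tab)$kappa)
})

test_that("identical repeats give kappa 1 and independent repeats near 0", {
  cohort <- small_cohort(seed = 1)
  same <- simulate_expert_raters(
    cohort,
    rater_params(intrarater_flip_prob = 0, recognition_prob = 0, n_duplicates = 20),
    seed = 1
  )
  expect_true(all(intrarater_kappa(same)$kappa == 1))

  # flip probability 0.5 makes the second answer independent: kappa ~ 0
  kaps <- unlist(lapply(1:10, function(s) {
    ann <- simulate_expert_raters(
      generate_cohort(cohort_config(), seed = s),
      rater_params(
        sensitivity = 0.5, specificity = 0.5,
        intrarater_flip_prob = 0.5, recognition_prob = 0, n_duplicates = 50
      ),
      seed = s
    )
    intrarater_kappa(ann)$kappa
  }))
  expect_lt(abs(mean(kaps)), 0.05)
})

test_that("simulated panels recover the analytic kappa of the flip model", {
  fp <- 0.07
  target <- expected_intrarater_kappa(0.62, 0.87, fp, prevalence = 155 / 308)
  meds <- vapply(1:5, function(s) {
    ann <- simulate_expert_raters(
      generate_cohort(cohort_config(), seed = s),
      rater_params(),
      seed = s
    )
    median(intrarater_kappa(ann)$kappa)
  }, numeric(1))
  expect_lt(abs(mean(meds) - target), 0.05)
  # and the default panel is calibrated near the published reliability level
  expect_lt(abs(target - 0.85), 0.01)
})

test_that("a panel of perfect raters yields a perfect ensemble", {
  cohort <- small_cohort(seed = 2)
  ann <- simulate_expert_raters(
    cohort,
    rater_params(
      sensitivity = 1, specificity = 1, recognition_prob = 0,
      n_duplicates = 10
    ),
    seed = 2
  )
  ens <- ensemble_experts(ann)
  truth <- cohort_truth(cohort)
  merged <- dplyr::inner_join(ens, truth, by = "participant_id")
  expect_true(all(merged$label.x == merged$label.y))
})

test_that("annotation CSV round trip preserves content", {
  ann <- simulate_expert_raters(
    small_cohort(seed = 3), rater_params(n_duplicates = 10), seed = 3
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(as.data.frame(read_annotations(path)), as.data.frame(ann))
})
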
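test_that("youden threshold maximizes J with the smallest-cutpoint tie rule", {
  sep <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$j, 1)
  expect_equal(sep$threshold, 0.5) # smallest candidate attaining J = 1

  mix <- youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(mix$j, 0.5)
  expect_equal(mix$threshold, 0.225)

  flat <- youden_threshold(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(flat$j, 0)

  expect_error(youden_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("youden search equals the exhaustive scan on 1000 random instances", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      n <- sample(4:20, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))
      res <- youden_threshold(scores, labels)
      expect_identical(res$j, brute_force_youden(scores, labels))
      # achieved operating point is consistent with the threshold
      pred <- discretize(scores, res$threshold)
      expect_equal(
        res$sensitivity, sum(pred == 1 & labels == 1) / sum(labels == 1)
      )
    }
  })
})

test_that("raising the threshold trades sensitivity for specificity monotonically", {
  withr::with_seed(7, {
    scores <- runif(60)
    labels <- as.integer(scores + rnorm(60, 0, 0.3) > 0.5)
  })
  labels[1:2] <- c(0, 1)
  grid <- seq(0, 1, by = 0.05)
  se <- vapply(grid, function(t) mean(discretize(scores[labels == 1], t)), numeric(1))
  sp <- vapply(grid, function(t) mean(1 - discretize(scores[labels == 0], t)), numeric(1))
  expect_true(all(diff(se) <= 0))
  expect_true(all(diff(sp) >= 0))
})

test_that("discretization treats the threshold itself as positive", {
  expect_equal(discretize(0.5, 0.5), 1L)
  expect_equal(discretize(0.49, 0.5), 0L)
  expect_equal(discretize(1.0, 0.0), 1L)
  expect_equal(discretize(c(0.2, 0.8), 0.5), c(0L, 1L))
})

test_that("majority voting returns the modal label and guards even splits", {
  expect_equal(majority_vote(c(1, 1, 0)), 1L)
  expect_equal(majority_vote(c(0, 0, 0)), 0L)
  expect_equal(majority_vote(c(1, 0, 1)), 1L)
  expect_error(majority_vote(c(1, 0)), "tie rule")
  expect_equal(majority_vote(c(1, 0), tie = 1), 1L)
})

test_that("prediction collection enforces full per-participant coverage", {
  scores <- tidyr::crossing(
    participant_id = c("A", "B"),
    architecture = "net", outer_fold = 1L, model_id = 1:2,
    target_yaw = c(0, 45, 90)
  )
  scores$score <- c(
    0.9, 0.8, 0.7, 0.9, 0.8, 0.7, # A: both models positive
    0.1, 0.2, 0.6, 0.1, 0.1, 0.1 # B: negative
  )
  thresholds <- tidyr::crossing(
    architecture = "net", outer_fold = 1L, model_id = 1:2
  )
  thresholds$threshold <- 0.5
  preds <- collect_predictions(scores, thresholds, k_inner = 2)
  expect_equal(nrow(preds), 4)
  expect_true(all(preds$prediction[preds$participant_id == "A"] == 1))
  expect_true(all(preds$prediction[preds$participant_id == "B"] == 0))

  expect_error(
    collect_predictions(scores[scores$model_id == 1 | scores$participant_id == "A", ],
      thresholds,
      k_inner = 2
    ),
    "coverage gap.*B"
  )
  expect_error(
    collect_predictions(scores, thresholds[0, ], k_inner = 2),
    "threshold"
  )
})

test_that("ensemble pooling concatenates member predictions", {
  preds <- tidyr::crossing(
    participant_id = c("A", "B"),
    architecture = c("m1", "m2", "m3"),
    outer_fold = 1L,
    model_id = 1:10
  )
  preds$prediction <- 1L
  pool <- build_ensemble(preds, c("m1", "m2", "m3"), "trio")
  expect_equal(nrow(pool), 60)
  expect_equal(unique(pool$architecture), "trio")
  expect_equal(sum(pool$participant_id == "A"), 30)
  # unanimous members pool to the unanimous label
  expect_equal(mean(pool$prediction), 1)

  single <- build_ensemble(preds, "m1", "solo")
  expect_equal(
    dplyr::select(single, -"architecture"),
    dplyr::select(preds[preds$architecture == "m1", ], -"architecture")
  )

  expect_error(build_ensemble(preds, character(0)), "non-empty")
  expect_error(build_ensemble(preds, c("m1", "nope")), "unknown member")
  lop <- preds[!(preds$architecture == "m2" & preds$participant_id == "B"), ]
  expect_error(build_ensemble(lop, c("m1", "m2")), "different participants")
})
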
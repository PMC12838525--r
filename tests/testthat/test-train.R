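linear_probe <- backbone_spec("linear_probe")

separable_samples <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    x <- cbind(y * 4 - 2 + rnorm(n, 0, 0.1), matrix(rnorm(n * 3), n))
    feature_samples(x, y)
  })
}

test_that("a separable problem is fit to development AUC 1", {
  s <- separable_samples(120)
  m <- train_model(
    s[1:80, ], s[81:120, ], linear_probe,
    training_config(lr_phase1 = 0.05, lr_phase2 = 0.05, seed = 1)
  )
  expect_equal(m$best_dev_auc, 1)
  expect_equal(max(m$trajectory$dev_auc), m$best_dev_auc)
})

test_that("permuted labels stay inside the null band", {
  withr::with_seed(2, {
    x <- matrix(rnorm(200 * 6), 200)
    y <- sample(rep(0:1, 100))
  })
  s <- feature_samples(x, y)
  m <- train_model(s[1:140, ], s[141:200, ], linear_probe, training_config(seed = 2))
  expect_gte(m$best_dev_auc, 0.35)
  expect_lte(m$best_dev_auc, 0.65)
})

test_that("early stopping halts patience epochs after the best epoch", {
  # constant features give a flat dev trajectory at 0.5
  s <- feature_samples(matrix(0, 60, 4), rep(0:1, 30))
  cfg <- training_config(
    phase1_epochs = 2, phase2_epochs = 18,
    early_stopping = TRUE, patience = 5, seed = 1
  )
  m <- train_model(s[1:40, ], s[41:60, ], linear_probe, cfg)
  expect_equal(m$selected_epoch, 1)
  expect_equal(m$stopped_epoch, 1 + 5)
  expect_equal(nrow(m$trajectory), 6)
  expect_gte(m$stopped_epoch, m$selected_epoch + 5)
})

test_that("the selected checkpoint attains the trajectory maximum", {
  withr::with_seed(3, {
    x <- cbind(rnorm(150), matrix(rnorm(150 * 5), 150))
    y <- as.integer(x[, 1] + rnorm(150) > 0)
  })
  s <- feature_samples(x, y)
  m <- train_model(s[1:100, ], s[101:150, ], linear_probe, training_config(seed = 3))
  expect_equal(m$best_dev_auc, max(m$trajectory$dev_auc))
  expect_equal(
    m$selected_epoch,
    which.max(m$trajectory$dev_auc)
  )
})

test_that("invalid training inputs are rejected", {
  s <- separable_samples(40)
  one_class <- s
  one_class$label <- 1L
  expect_error(
    train_model(s[1:20, ], one_class[21:40, ], linear_probe),
    "single class"
  )
  expect_error(train_model(s[0, ], s, linear_probe), "non-empty")
  expect_error(training_config(phase1_epochs = 0, phase2_epochs = 0), "epoch")
  expect_error(
    training_config(early_stopping = TRUE, patience = 0),
    "patience"
  )
})

test_that("training is bit-reproducible under a fixed seed", {
  s <- separable_samples(80, seed = 5)
  cfg <- training_config(seed = 11)
  m1 <- train_model(s[1:50, ], s[51:80, ], linear_probe, cfg)
  m2 <- train_model(s[1:50, ], s[51:80, ], linear_probe, cfg)
  expect_identical(m1$head_w, m2$head_w)
  expect_identical(m1$trajectory, m2$trajectory)
  m3 <- train_model(s[1:50, ], s[51:80, ], linear_probe, training_config(seed = 12))
  expect_false(identical(m1$head_w, m3$head_w))
})

test_that("phase 2 fine-tunes projection backbones when unfrozen", {
  cohort <- small_cohort(seed = 6, n_pairs = 10)
  fs <- lapply(c(1:6, 13:18), function(i) {
    sets <- build_image_sets(
      render_participant_video(cohort[i, ],
        params = face_params(image_size = 16), n_frames = 5, seed = 6
      ),
      angle_spec(test_angles = c(0, 45, 90))
    )
    sets[sets$role == "train", ]
  })
  samples <- dplyr::bind_rows(fs)
  truth <- setNames(cohort_truth(cohort)$label, cohort$participant_id)
  samples$label <- truth[samples$participant_id]

  bb <- backbone_spec("imagenet_style_a", feature_dim = 8, frozen = FALSE)
  w0 <- facescreen:::backbone_weights(bb, 256)
  n_half <- nrow(samples) / 2 # cases first, then controls
  dev_rows <- c(n_half - 19:0, nrow(samples) - 19:0)
  m <- train_model(samples[-dev_rows, ], samples[dev_rows, ], bb,
    training_config(phase1_epochs = 1, phase2_epochs = 3, seed = 1)
  )
  expect_true(m$finetuned)
  expect_false(identical(m$proj, w0))
  expect_length(predict(m, samples[1:5, ]), 5)
})

test_that("tidy and glance summarize models as expected", {
  s <- separable_samples(60)
  m <- train_model(s[1:40, ], s[41:60, ], linear_probe, training_config(seed = 1))
  t <- tidy(m)
  expect_named(t, c("epoch", "phase", "dev_auc"))
  g <- glance(m)
  expect_equal(g$backbone, "linear_probe")
  expect_equal(g$n_train, 40)
})
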
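#' Default architecture roster
#'
#' Three general-purpose pretrained-style backbones searched with 20
#' trials each, plus one face-pretrained-style backbone searched with 10
#' trials and trained with early stopping (it is the computationally
#' heavier model in the emulated study design). With 10 outer and 10 inner
#' folds this roster yields 300 trainings per 20-trial architecture, 200
#' for the 10-trial one — 1100 in total, of which 100 per architecture
#' contribute predictions.
#'
#' @return A named list of architecture entries, each with `backbone`,
#'   `n_trials` and `early_stopping`.
#' @export
default_architectures <- function() {
  list(
    imagenet_style_a = list(
      backbone = backbone_spec("imagenet_style_a"), n_trials = 20,
      early_stopping = FALSE
    ),
    imagenet_style_b = list(
      backbone = backbone_spec("imagenet_style_b"), n_trials = 20,
      early_stopping = FALSE
    ),
    imagenet_style_c = list(
      backbone = backbone_spec("imagenet_style_c"), n_trials = 20,
      early_stopping = FALSE
    ),
    face_pretrained_style = list(
      backbone = backbone_spec("face_pretrained_style"), n_trials = 10,
      early_stopping = TRUE
    )
  )
}

# Render every participant's sweep, build the two image sets, and extract
# per-architecture features, streaming one participant at a time so pixel
# matrices are never all held in memory.
prepare_study_samples <- function(cohort, params, spec, architectures,
                                  n_frames, seed) {
  truth <- setNames(
    as.integer(cohort$group == "acromegaly"), cohort$participant_id
  )
  backbones <- lapply(architectures, `[[`, "backbone")
  meta_rows <- vector("list", nrow(cohort))
  feats <- lapply(backbones, function(b) vector("list", nrow(cohort)))
  for (i in seq_len(nrow(cohort))) {
    fs <- render_participant_video(cohort[i, ], params,
      n_frames = n_frames, seed = seed
    )
    sets <- build_image_sets(fs, spec)
    x <- flatten_images(sets$image)
    meta_rows[[i]] <- tibble(
      participant_id = sets$participant_id,
      role = sets$role,
      target_yaw = sets$target_yaw,
      label = truth[sets$participant_id]
    )
    for (a in names(backbones)) {
      feats[[a]][[i]] <- extract_features(x, backbones[[a]])
    }
  }
  meta <- bind_rows(meta_rows)
  lapply(feats, function(fl) {
    s <- meta
    s$features <- do.call(rbind, fl)
    s
  })
}

#' Train the final nested-fold models for one outer fold
#'
#' Trains one model per inner fold with the supplied hyperparameters: the
#' inner fold's participants form the development set, the remaining
#' modeling participants the training set (training-role images only).
#'
#' @param samples Sample tibble with `participant_id`, `role`, `label` and
#'   `features`/`image`.
#' @param inner An inner-fold tibble from [plan_inner_folds()].
#' @param best Hyperparameter list (`lr`, `batch_size`, `phase1_epochs`).
#' @param backbone A [backbone_spec()].
#' @param base_config A [training_config()].
#' @param seed Integer seed.
#' @return A list of `face_model` objects, one per inner fold.
#' @export
run_nested_training <- function(samples, inner, best,
                                backbone = backbone_spec("linear_probe"),
                                base_config = training_config(),
                                seed = 1L) {
  train_pool <- samples[samples$role == "train", ]
  fold_of <- setNames(inner$inner_fold, inner$participant_id)
  pool_fold <- fold_of[train_pool$participant_id]
  if (anyNA(pool_fold)) {
    stop_config("samples contain participants missing from the inner plan")
  }
  k_inner <- max(inner$inner_fold)
  lapply(seq_len(k_inner), function(i) {
    trial <- c(best, list(seed = derive_seed(seed, "final_fit", i)))
    train_model(
      train_pool[pool_fold != i, ],
      train_pool[pool_fold == i, ],
      backbone,
      trial_training_config(trial, base_config)
    )
  })
}

#' Run the complete nested training-and-prediction protocol
#'
#' Executes the full study protocol on a cohort: renders each
#' participant's yaw sweep, builds the training and 3-view test image
#' sets, extracts features per architecture, then for every outer fold
#' runs the hyperparameter search on that fold's modeling set, trains one
#' final model per inner fold with the winning hyperparameters, derives
#' each final model's Youden threshold on its inner development set, and
#' scores the held-out participants' test images. Every participant ends
#' up with exactly `k_inner` binary predictions per architecture, each
#' from a model that never saw that participant.
#'
#' @param cohort A cohort tibble.
#' @param params A [face_params()].
#' @param spec An [angle_spec()].
#' @param architectures An architecture roster as in
#'   [default_architectures()].
#' @param k_outer,k_inner Outer/inner fold counts.
#' @param n_frames Frames per rendered sweep.
#' @param train_config Base [training_config()].
#' @param search An [hpo_config()] supplying the search space (each
#'   architecture's `n_trials` overrides the space's).
#' @param seed Master seed.
#' @param progress Print per-fold progress lines?
#' @return A `face_study` list: `plan`, `records` (one row per trained
#'   model, search and final), `scores` (per test image and final model),
#'   `thresholds`, `predictions` (per participant and final model) and
#'   `counts` (the [count_trainings()] accounting, which matches
#'   `records`).
#' @export
run_study <- function(cohort,
                      params = face_params(),
                      spec = angle_spec(),
                      architectures = default_architectures(),
                      k_outer = 10, k_inner = 10,
                      n_frames = 21,
                      train_config = training_config(),
                      search = hpo_config(),
                      seed = 1L,
                      progress = FALSE) {
  plan <- plan_nested(cohort, k_outer, k_inner, seed = derive_seed(seed, "plan"))
  samples_by_arch <- prepare_study_samples(
    cohort, params, spec, architectures, n_frames, seed
  )
  truth <- cohort_truth(cohort)

  records <- list()
  scores <- list()
  thresholds <- list()
  for (arch in names(architectures)) {
    entry <- architectures[[arch]]
    samples <- samples_by_arch[[arch]]
    base_cfg <- train_config
    base_cfg$early_stopping <- isTRUE(entry$early_stopping)
    arch_search <- search
    arch_search$n_trials <- entry$n_trials
    for (f in seq_len(k_outer)) {
      fold <- plan$folds[[f]]
      modeling <- samples[!(samples$participant_id %in% fold$held_out), ]
      hpo_res <- run_hpo(
        modeling, fold$hpo, entry$backbone, arch_search, base_cfg,
        seed = derive_seed(seed, "hpo", arch, f)
      )
      records[[length(records) + 1]] <- mutate(
        hpo_res$trials,
        architecture = arch, outer_fold = f, kind = "hpo",
        heldout_auc = NA_real_, threshold = NA_real_
      )
      models <- run_nested_training(
        modeling, fold$inner, hpo_res$best, entry$backbone, base_cfg,
        seed = derive_seed(seed, "nested", arch, f)
      )
      held_test <- samples[
        samples$participant_id %in% fold$held_out & samples$role == "test",
      ]
      for (i in seq_len(k_inner)) {
        model <- models[[i]]
        dev <- modeling[
          modeling$role == "train" &
            modeling$participant_id %in%
              fold$inner$participant_id[fold$inner$inner_fold == i],
        ]
        thr <- youden_threshold(predict(model, dev), dev$label)
        test_scores <- predict(model, held_test)
        by_part <- tapply(test_scores, held_test$participant_id, mean)
        part_labels <- truth$label[match(names(by_part), truth$participant_id)]
        heldout_auc <- roc_auc(as.numeric(by_part), part_labels)
        records[[length(records) + 1]] <- tibble(
          architecture = arch, outer_fold = f, kind = "final", trial = i,
          lr = hpo_res$best$lr, batch_size = hpo_res$best$batch_size,
          phase1_epochs = hpo_res$best$phase1_epochs,
          selected_epoch = model$selected_epoch,
          dev_auc = model$best_dev_auc,
          test_auc = NA_real_,
          heldout_auc = heldout_auc,
          threshold = thr$threshold
        )
        scores[[length(scores) + 1]] <- tibble(
          participant_id = held_test$participant_id,
          architecture = arch, outer_fold = f, model_id = i,
          target_yaw = held_test$target_yaw,
          score = test_scores
        )
        thresholds[[length(thresholds) + 1]] <- tibble(
          architecture = arch, outer_fold = f, model_id = i,
          threshold = thr$threshold, youden_j = thr$j
        )
      }
      if (progress) {
        inform(sprintf("[%s] outer fold %d/%d done", arch, f, k_outer))
      }
    }
  }
  scores <- bind_rows(scores)
  thresholds <- bind_rows(thresholds)
  predictions <- collect_predictions(scores, thresholds, k_inner = k_inner)
  structure(
    list(
      plan = plan,
      records = bind_rows(records),
      scores = scores,
      thresholds = thresholds,
      predictions = predictions,
      counts = count_trainings(
        k_outer,
        vapply(architectures, `[[`, numeric(1), "n_trials"),
        k_inner
      )
    ),
    class = "face_study"
  )
}

#' @export
print.face_study <- function(x, ...) {
  cat("<face_study>\n")
  cat("  trained models:", nrow(x$records), "\n")
  cat(
    "  final models:", sum(x$records$kind == "final"),
    "| architectures:", length(unique(x$records$architecture)), "\n"
  )
  cat("  predictions:", nrow(x$predictions), "\n")
  invisible(x)
}

#' One-row-per-architecture summary of a study
#'
#' @param x A `face_study`.
#' @param ... Unused.
#' @return A tibble with per-architecture model counts and the mean
#'   held-out participant-level AUC of the final models.
#' @export
glance.face_study <- function(x, ...) {
  x$records |>
    group_by(architecture = .data$architecture) |>
    summarise(
      n_trained = n(),
      n_final = sum(.data$kind == "final"),
      mean_heldout_auc = mean(.data$heldout_auc, na.rm = TRUE)
    )
}
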
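#' Hyperparameter-search configuration
#'
#' Random-search space for the two-phase trainer: learning rate sampled
#' log-uniformly, batch size from a small set, and phase-1 epoch count
#' from a small range. Each trial trains on the search-training part with
#' the search-development part for checkpoint selection and is scored by
#' ROC AUC on the search-test part; the best trial's hyperparameters win,
#' with ties going to the earliest trial.
#'
#' @param n_trials Number of search trials.
#' @param lr_range Length-2 positive numeric, log-uniform learning-rate
#'   bounds.
#' @param batch_choices Candidate batch sizes.
#' @param phase1_epoch_choices Candidate phase-1 epoch counts.
#' @return An `hpo_config` object.
#' @export
hpo_config <- function(n_trials = 20,
                       lr_range = c(1e-4, 1e-1),
                       batch_choices = c(16, 32, 64),
                       phase1_epoch_choices = 1:5) {
  if (!is_count(n_trials) || n_trials < 1) {
    stop_config("`n_trials` must be a positive count")
  }
  stopifnot(length(lr_range) == 2, all(lr_range > 0))
  structure(
    list(
      n_trials = as.integer(n_trials),
      lr_range = sort(as.numeric(lr_range)),
      batch_choices = as.integer(batch_choices),
      phase1_epoch_choices = as.integer(phase1_epoch_choices)
    ),
    class = "hpo_config"
  )
}

# Sample one trial's hyperparameters (inside an established RNG context).
# pick() avoids base sample()'s 1:x expansion for length-1 choice sets.
sample_trial <- function(hpo) {
  pick <- function(x) x[sample.int(length(x), 1)]
  list(
    lr = exp(runif(1, log(hpo$lr_range[1]), log(hpo$lr_range[2]))),
    batch_size = pick(hpo$batch_choices),
    phase1_epochs = pick(hpo$phase1_epoch_choices)
  )
}

trial_training_config <- function(trial, base) {
  training_config(
    phase1_epochs = trial$phase1_epochs,
    phase2_epochs = base$phase2_epochs,
    lr_phase1 = trial$lr, lr_phase2 = trial$lr,
    batch_size = trial$batch_size,
    early_stopping = base$early_stopping, patience = base$patience,
    seed = trial$seed %||% base$seed
  )
}

#' Run a hyperparameter search over one split
#'
#' @param samples Sample tibble (`participant_id`, `role`, `label`, and
#'   `features`/`image`); only training-role images are used during the
#'   search.
#' @param split An [plan_hpo_split()] result covering the modeling
#'   participants.
#' @param backbone A [backbone_spec()].
#' @param hpo An [hpo_config()].
#' @param base_config A [training_config()] supplying the non-searched
#'   settings (phase-2 epochs, early stopping, patience).
#' @param seed Integer seed for trial sampling and per-trial training.
#' @return A list with `best` (the winning trial's hyperparameters as a
#'   list), `trials` (one-row-per-trial tibble with `test_auc`) and
#'   `best_trial` (its index).
#' @export
run_hpo <- function(samples, split, backbone = backbone_spec("linear_probe"),
                    hpo = hpo_config(), base_config = training_config(),
                    seed = 1L) {
  train_pool <- samples[samples$role == "train", ]
  part_of <- setNames(split$part, split$participant_id)
  pool_part <- part_of[train_pool$participant_id]
  if (anyNA(pool_part)) {
    stop_config("samples contain participants missing from the split")
  }
  rows <- vector("list", hpo$n_trials)
  for (t in seq_len(hpo$n_trials)) {
    trial <- withr::with_seed(derive_seed(seed, "trial", t), sample_trial(hpo))
    trial$seed <- derive_seed(seed, "trial_fit", t)
    cfg <- trial_training_config(trial, base_config)
    model <- train_model(
      train_pool[pool_part == "train", ],
      train_pool[pool_part == "dev", ],
      backbone, cfg
    )
    test <- train_pool[pool_part == "test", ]
    test_auc <- roc_auc(predict(model, test), test$label)
    lr_t <- trial$lr
    batch_t <- trial$batch_size
    p1_t <- trial$phase1_epochs
    rows[[t]] <- tibble(
      trial = t, lr = lr_t, batch_size = batch_t,
      phase1_epochs = p1_t,
      selected_epoch = model$selected_epoch,
      dev_auc = model$best_dev_auc, test_auc = test_auc
    )
  }
  trials <- bind_rows(rows)
  best_trial <- which.max(trials$test_auc) # ties -> first trial reached
  list(
    best = as.list(trials[best_trial, c("lr", "batch_size", "phase1_epochs")]),
    trials = trials,
    best_trial = best_trial
  )
}
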
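#' Assemble a full study run configuration
#'
#' Bundles every stage's configuration into one object that drives
#' [run_pipeline()]: cohort composition, facial-morphology model, angle
#' specification, rater panel, fold counts, training schedule, search
#' space, architecture roster, bootstrap size and master seed. All stage
#' seeds are derived deterministically from the master seed and the stage
#' name, so adding stages never perturbs existing random streams.
#'
#' @param cohort A [cohort_config()].
#' @param faces A [face_params()].
#' @param angles An [angle_spec()].
#' @param raters A [rater_params()].
#' @param architectures Architecture roster (see
#'   [default_architectures()]).
#' @param training A [training_config()].
#' @param search An [hpo_config()].
#' @param k_outer,k_inner Fold counts.
#' @param n_frames Frames per rendered sweep.
#' @param bootstrap_B Bootstrap runs for the evaluation stage.
#' @param seed Master seed.
#' @param write_images Also write the masked image sets as PNG files plus
#'   a manifest CSV?
#' @return A `run_config` object.
#' @export
run_config <- function(cohort = cohort_config(),
                       faces = face_params(),
                       angles = angle_spec(),
                       raters = rater_params(),
                       architectures = default_architectures(),
                       training = training_config(),
                       search = hpo_config(),
                       k_outer = 10, k_inner = 10,
                       n_frames = 21,
                       bootstrap_B = 10000,
                       seed = 1L,
                       write_images = FALSE) {
  structure(
    list(
      cohort = cohort, faces = faces, angles = angles, raters = raters,
      architectures = architectures, training = training, search = search,
      k_outer = k_outer, k_inner = k_inner, n_frames = n_frames,
      bootstrap_B = bootstrap_B, seed = as.integer(seed),
      write_images = isTRUE(write_images)
    ),
    class = "run_config"
  )
}

#' A small configuration for smoke-testing the pipeline
#'
#' Forty-four participants (20 matched pairs plus singletons), 2 outer and
#' 2 inner folds, one linear-probe architecture with 2 search trials,
#' short sweeps and a small bootstrap — the complete pipeline in seconds.
#'
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
smoke_run_config <- function(seed = 1L) {
  run_config(
    cohort = cohort_config(
      n_patients = 22, n_controls = 22, n_matched_pairs = 20
    ),
    raters = rater_params(n_duplicates = 10),
    architectures = list(
      linear_probe = list(
        backbone = backbone_spec("linear_probe"), n_trials = 2,
        early_stopping = FALSE
      )
    ),
    training = training_config(phase1_epochs = 1, phase2_epochs = 3),
    search = hpo_config(n_trials = 2),
    k_outer = 2, k_inner = 2, n_frames = 7, bootstrap_B = 200,
    seed = seed
  )
}

#' Validate a run configuration
#'
#' Checks every stage's invariants and their cross-stage consistency
#' without running anything.
#'
#' @param config A [run_config()].
#' @return A tibble of violations (`field`, `message`); zero rows when
#'   the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1]] <<- tibble(field = field, message = message)
  }
  for (p in validate_cohort_config(config$cohort)) add("cohort", p)
  n_total <- config$cohort$n_patients + config$cohort$n_controls
  if (config$raters$n_duplicates > n_total) {
    add(
      "raters$n_duplicates",
      "more duplicated presentations than participants"
    )
  }
  n_test <- length(config$angles$test_angles)
  if (n_test %% 2 == 0) {
    add(
      "angles$test_angles",
      "even number of test views with no majority-vote tie rule"
    )
  }
  if (config$n_frames < 3) add("n_frames", "need at least 3 frames")
  n_units <- config$cohort$n_matched_pairs +
    (config$cohort$n_patients - config$cohort$n_matched_pairs) +
    (config$cohort$n_controls - config$cohort$n_matched_pairs)
  if (n_units < config$k_outer) {
    add("k_outer", "more outer folds than participant units")
  }
  if (floor(n_units * (config$k_outer - 1) / config$k_outer) < 10) {
    add(
      "k_outer",
      "modeling sets would have fewer than 10 units for the search split"
    )
  }
  if (!is_count(config$bootstrap_B) || config$bootstrap_B < 1) {
    add("bootstrap_B", "bootstrap run count must be positive")
  }
  if (length(v)) bind_rows(v) else tibble(field = character(), message = character())
}

strip_class <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), strip_class)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x) # YAML drops names of atomic vectors; lists keep them
  } else {
    x
  }
}

#' Write or read a run configuration as YAML
#'
#' The round trip is lossless: `read_run_config(write_run_config(cfg))`
#' reconstructs an identical configuration.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  obj <- strip_class(config)
  obj$architectures <- lapply(config$architectures, function(a) {
    list(
      name = a$backbone$name, feature_dim = a$backbone$feature_dim,
      frozen = a$backbone$frozen, n_trials = a$n_trials,
      early_stopping = isTRUE(a$early_stopping)
    )
  })
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  # YAML reads vectors back as lists; normalize to atomic vectors.
  vecs <- function(x) lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  archs <- lapply(obj$architectures, function(a) {
    list(
      backbone = backbone_spec(a$name,
        feature_dim = a$feature_dim, frozen = a$frozen
      ),
      n_trials = a$n_trials, early_stopping = a$early_stopping
    )
  })
  run_config(
    cohort = do.call(cohort_config, vecs(obj$cohort)),
    faces = do.call(face_params, vecs(obj$faces)),
    angles = do.call(angle_spec, vecs(obj$angles)),
    raters = do.call(rater_params, vecs(obj$raters)),
    architectures = archs,
    training = do.call(training_config, vecs(obj$training)),
    search = do.call(hpo_config, vecs(obj$search)),
    k_outer = obj$k_outer, k_inner = obj$k_inner,
    n_frames = obj$n_frames, bootstrap_B = obj$bootstrap_B,
    seed = obj$seed, write_images = obj$write_images
  )
}

#' Run the complete pipeline end to end
#'
#' Generates the cohort, simulates the expert session, runs the nested
#' training-and-prediction protocol, evaluates every architecture, the
#' pooled ensembles and the expert panel with bootstrap confidence
#' intervals, and writes all result tables plus a manifest with content
#' hashes to `outdir`. Reruns with an identical configuration and seed
#' reproduce identical file contents.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @param progress Print stage progress?
#' @return A `run_manifest` list (stage timings, output files with MD5
#'   hashes, and the in-memory results), invisibly.
#' @export
run_pipeline <- function(config = run_config(), outdir, progress = FALSE) {
  problems <- validate_config(config)
  if (nrow(problems)) {
    stop_config(paste0(
      "invalid configuration:\n",
      paste0("- ", problems$field, ": ", problems$message, collapse = "\n")
    ))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    if (progress) inform(sprintf("stage %s: %.1fs", name, timings[[name]]))
    res
  }

  cohort <- stage("cohort", {
    ch <- generate_cohort(config$cohort, seed = derive_seed(seed, "cohort_stage"))
    write_cohort(ch, file.path(outdir, "cohort.csv"))
    ch
  })
  truth <- cohort_truth(cohort)

  annotations <- stage("raters", {
    ann <- simulate_expert_raters(cohort, config$raters,
      seed = derive_seed(seed, "rater_stage")
    )
    write_annotations(ann, file.path(outdir, "annotations.csv"))
    write.csv(ensemble_experts(ann), file.path(outdir, "expert_ensemble.csv"),
      row.names = FALSE
    )
    write.csv(intrarater_kappa(ann), file.path(outdir, "kappa.csv"),
      row.names = FALSE
    )
    ann
  })

  if (config$write_images) {
    stage("images", {
      img_dir <- file.path(outdir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      manifest <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
        fs <- render_participant_video(cohort[i, ], config$faces,
          n_frames = config$n_frames,
          seed = derive_seed(seed, "render_stage")
        )
        sets <- build_image_sets(fs, config$angles)
        files <- sprintf(
          "%s_%s_%+04d.png", sets$participant_id, sets$role, sets$target_yaw
        )
        purrr::walk2(sets$image, files, function(img, f) {
          png::writePNG(img, file.path(img_dir, f))
        })
        tibble(
          participant_id = sets$participant_id, role = sets$role,
          target_yaw = sets$target_yaw, file = file.path("images", files)
        )
      })
      write.csv(manifest, file.path(outdir, "image_manifest.csv"),
        row.names = FALSE
      )
    })
  }

  study <- stage("study", {
    st <- run_study(
      cohort,
      params = config$faces, spec = config$angles,
      architectures = config$architectures,
      k_outer = config$k_outer, k_inner = config$k_inner,
      n_frames = config$n_frames,
      train_config = config$training, search = config$search,
      seed = derive_seed(seed, "render_stage"),
      progress = progress
    )
    write_fold_plan(st$plan, file.path(outdir, "fold_plan.json"))
    write.csv(st$records, file.path(outdir, "model_records.csv"), row.names = FALSE)
    write.csv(st$scores, file.path(outdir, "scores.csv"), row.names = FALSE)
    write.csv(st$predictions, file.path(outdir, "predictions.csv"), row.names = FALSE)
    st
  })

  results <- stage("evaluate", {
    arch_names <- names(config$architectures)
    pred_sets <- lapply(arch_names, function(a) {
      study$predictions[study$predictions$architecture == a, ]
    })
    names(pred_sets) <- arch_names
    imagenet_members <- grep("^imagenet_style", arch_names, value = TRUE)
    if (length(imagenet_members) > 1) {
      pred_sets$imagenet_ensemble <- build_ensemble(
        study$predictions, imagenet_members, "imagenet_ensemble"
      )
      if ("face_pretrained_style" %in% arch_names) {
        pred_sets$imagenet_ensemble_plus_face <- build_ensemble(
          study$predictions,
          c(imagenet_members, "face_pretrained_style"),
          "imagenet_ensemble_plus_face"
        )
      }
    }
    boots <- purrr::imap(pred_sets, function(p, nm) {
      bootstrap_ensemble_metrics(
        p, truth,
        B = config$bootstrap_B,
        seed = derive_seed(seed, "boot", nm)
      )
    })
    boots$experts <- bootstrap_ensemble_metrics(
      rater_prediction_set(annotations), truth,
      B = config$bootstrap_B, seed = derive_seed(seed, "boot", "experts")
    )
    write.csv(format_metrics_table(boots), file.path(outdir, "metrics.csv"),
      row.names = FALSE
    )

    ens_label <- function(p) {
      p |>
        group_by(.data$participant_id) |>
        summarise(label = as.integer(mean(.data$prediction) >= 0.5))
    }
    agreement_preds <- list()
    expert_lab <- ensemble_experts(annotations)
    agreement_preds$experts <- tibble(
      participant_id = expert_lab$participant_id,
      predictor = "experts", label = expert_lab$label
    )
    for (nm in intersect(
      c("face_pretrained_style", "imagenet_ensemble"),
      names(pred_sets)
    )) {
      el <- ens_label(pred_sets[[nm]])
      agreement_preds[[nm]] <- tibble(
        participant_id = el$participant_id, predictor = nm, label = el$label
      )
    }
    agr <- agreement_table(bind_rows(agreement_preds), truth)
    jsonlite::write_json(
      list(
        regions = agr,
        summary = agreement_summary(agr)
      ),
      file.path(outdir, "agreement.json"),
      auto_unbox = TRUE, digits = NA
    )

    subgroup_set <- pred_sets[["face_pretrained_style"]] %||% pred_sets[[1]]
    subgroups <- subgroup_metrics(
      subgroup_set,
      truth, cohort,
      B = config$bootstrap_B, seed = derive_seed(seed, "boot", "subgroups")
    )
    write.csv(subgroups, file.path(outdir, "subgroups.csv"), row.names = FALSE)
    list(bootstrap = boots, agreement = agr, subgroups = subgroups)
  })

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    stages = tibble(
      stage = names(timings),
      seconds = round(unlist(timings), 2)
    ),
    files = tibble(
      file = list.files(outdir, recursive = TRUE),
      md5 = unname(tools::md5sum(files))
    ),
    seed = seed
  )
  jsonlite::write_json(
    manifest[c("stages", "files", "seed")],
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(structure(
    c(manifest, list(cohort = cohort, study = study, results = results)),
    class = "run_manifest"
  ))
}
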
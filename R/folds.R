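#' Participant units for pair-aware splitting
#'
#' All data splits operate on *units*: a matched case-control pair is one
#' unit (the two members always co-travel across folds, so that matching
#' cannot leak across the train/test boundary), and every unmatched
#' participant is a singleton unit. Units are additionally stratified by
#' class (`"pair"`, `"case"`, `"control"`) so each fold keeps the
#' case/control balance.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return A tibble with `participant_id`, `unit_id`, `unit_class`, `group`.
#' @export
cohort_units <- function(cohort) {
  is_case <- cohort$group == "acromegaly"
  unit_id <- ifelse(
    is_case,
    paste0("U_", cohort$participant_id),
    ifelse(is.na(cohort$match_id),
      paste0("U_", cohort$participant_id),
      paste0("U_", cohort$match_id)
    )
  )
  paired <- cohort$participant_id[is_case & !is.na(cohort$match_id)]
  unit_class <- ifelse(
    unit_id %in% paste0("U_", paired), "pair",
    ifelse(is_case, "case", "control")
  )
  tibble(
    participant_id = cohort$participant_id,
    unit_id = unit_id,
    unit_class = unit_class,
    group = cohort$group
  )
}

# Round-robin allocation of the units of each stratum across k folds, with
# a shuffled unit order and a shuffled fold rotation, so per-fold stratum
# counts differ from perfect balance by at most one unit.
allocate_round_robin <- function(units, k) {
  out <- integer(nrow(units))
  for (cl in unique(units$unit_class)) {
    ids <- unique(units$unit_id[units$unit_class == cl])
    ids <- sample(ids)
    fold_order <- sample.int(k)
    fold_of <- setNames(
      fold_order[((seq_along(ids) - 1) %% k) + 1],
      ids
    )
    sel <- units$unit_class == cl
    out[sel] <- fold_of[units$unit_id[sel]]
  }
  out
}

#' Plan the outer cross-validation folds
#'
#' Partitions a cohort into `k` folds at the unit level (see
#' [cohort_units()]): matched pairs stay together, sampling is
#' participant-atomic so no image of one participant can cross folds, and
#' each unit stratum is balanced across folds to within one unit.
#'
#' @param cohort A cohort tibble.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, `unit_id`, `unit_class`,
#'   `group`, `fold`; attribute `k`.
#' @export
#' @examples
#' plan <- plan_outer_folds(generate_cohort(seed = 1), k = 10, seed = 1)
#' table(plan$fold, plan$group)
plan_outer_folds <- function(cohort, k = 10, seed = 1L) {
  if (!is_count(k) || k < 2) stop_config("`k` must be a count >= 2")
  units <- cohort_units(cohort)
  n_case_units <- length(unique(units$unit_id[units$unit_class %in% c("pair", "case")]))
  n_ctrl_units <- length(unique(units$unit_id[units$unit_class %in% c("pair", "control")]))
  if (n_case_units < k || n_ctrl_units < k) {
    stop_config(paste0(
      "`k` = ", k, " exceeds the available units of a class (",
      n_case_units, " case-bearing, ", n_ctrl_units, " control-bearing)"
    ))
  }
  units$fold <- withr::with_seed(
    derive_seed(seed, "outer_folds"),
    allocate_round_robin(units, k)
  )
  structure(units, k = k)
}

# Largest-remainder allocation of n items to the given proportions.
# Ties in the remainders keep the order of `props` (stable order()).
largest_remainder <- function(n, props) {
  q <- n * props / sum(props)
  fl <- floor(q)
  extra <- n - sum(fl)
  if (extra > 0) {
    ord <- order(q - fl, decreasing = TRUE)
    fl[ord[seq_len(extra)]] <- fl[ord[seq_len(extra)]] + 1
  }
  setNames(as.integer(fl), names(props))
}

#' Split modeling units into hyperparameter-search sets
#'
#' Splits the units of a modeling set into 80% search-training, 10%
#' search-development and 10% search-test parts, by unit count with
#' largest-remainder rounding, stratified by unit class and pair-cohesive.
#'
#' @param units A unit tibble (rows of [cohort_units()], e.g. the modeling
#'   part of an outer fold plan).
#' @param seed Integer seed.
#' @param props Named proportions for `train`, `dev`, `test`.
#' @return The unit tibble with an added `part` column.
#' @export
plan_hpo_split <- function(units, seed = 1L,
                           props = c(train = 0.8, dev = 0.1, test = 0.1)) {
  n_units <- length(unique(units$unit_id))
  if (n_units < 10) {
    stop_config("need at least 10 units for an 80/10/10 search split")
  }
  units$part <- withr::with_seed(derive_seed(seed, "hpo_split"), {
    out <- character(nrow(units))
    for (cl in unique(units$unit_class)) {
      ids <- sample(unique(units$unit_id[units$unit_class == cl]))
      alloc <- largest_remainder(length(ids), props)
      part_of <- setNames(
        rep(names(alloc), times = alloc),
        ids
      )
      sel <- units$unit_class == cl
      out[sel] <- part_of[units$unit_id[sel]]
    }
    out
  })
  units
}

#' Plan the inner cross-validation folds
#'
#' Partitions modeling units into `k_inner` folds (same stratified,
#' pair-cohesive scheme as [plan_outer_folds()]); during nested training
#' each inner fold acts once as the development set while the remaining
#' folds train.
#'
#' @inheritParams plan_hpo_split
#' @param k_inner Number of inner folds.
#' @return The unit tibble with an added `inner_fold` column.
#' @export
plan_inner_folds <- function(units, k_inner = 10, seed = 1L) {
  if (!is_count(k_inner) || k_inner < 2) {
    stop_config("`k_inner` must be a count >= 2")
  }
  if (length(unique(units$unit_id)) < k_inner) {
    stop_config("`k_inner` exceeds the number of units")
  }
  units$inner_fold <- withr::with_seed(
    derive_seed(seed, "inner_folds"),
    allocate_round_robin(units, k_inner)
  )
  units
}

#' Training-count accounting of the nested protocol
#'
#' For each architecture the protocol trains, per outer fold, one model per
#' hyperparameter-search trial plus one final model per inner fold; only
#' the final models contribute predictions.
#'
#' @param k_outer Outer fold count.
#' @param hpo_trials Named integer vector of search trials per architecture.
#' @param k_inner Inner fold count.
#' @return A tibble with one row per architecture (`architecture`,
#'   `hpo_trials`, `total`, `final`) plus a `"total"` summary row.
#' @export
#' @examples
#' count_trainings(10, c(cnn_a = 20, cnn_b = 20, cnn_c = 20, face = 10), 10)
count_trainings <- function(k_outer = 10,
                            hpo_trials = c(architecture = 20),
                            k_inner = 10) {
  stopifnot(k_outer >= 1, k_inner >= 1, all(hpo_trials >= 0))
  per <- tibble(
    architecture = names(hpo_trials) %||% paste0("arch", seq_along(hpo_trials)),
    hpo_trials = as.integer(hpo_trials),
    total = as.integer(k_outer * (hpo_trials + k_inner)),
    final = as.integer(k_outer * k_inner)
  )
  bind_rows(
    per,
    tibble(
      architecture = "total",
      hpo_trials = sum(per$hpo_trials),
      total = sum(per$total),
      final = sum(per$final)
    )
  )
}

#' Plan the complete nested partition
#'
#' Builds, for every outer fold, the held-out participant set, the
#' hyperparameter-search split of the modeling units (re-randomized per
#' fold) and the inner fold assignment.
#'
#' @param cohort A cohort tibble.
#' @param k_outer,k_inner Outer and inner fold counts.
#' @param seed Integer seed.
#' @return A `nested_plan` object: list with `outer` (the outer fold plan)
#'   and `folds`, one entry per outer fold with elements `fold`,
#'   `held_out` (participant ids), `hpo` (split tibble) and `inner`
#'   (inner-fold tibble).
#' @export
plan_nested <- function(cohort, k_outer = 10, k_inner = 10, seed = 1L) {
  outer <- plan_outer_folds(cohort, k = k_outer, seed = seed)
  folds <- lapply(seq_len(k_outer), function(f) {
    modeling <- outer[outer$fold != f, c("participant_id", "unit_id", "unit_class", "group")]
    list(
      fold = f,
      held_out = outer$participant_id[outer$fold == f],
      hpo = plan_hpo_split(modeling, seed = derive_seed(seed, "hpo", f)),
      inner = plan_inner_folds(modeling,
        k_inner = k_inner,
        seed = derive_seed(seed, "inner", f)
      )
    )
  })
  structure(
    list(outer = outer, folds = folds, k_outer = k_outer, k_inner = k_inner),
    class = "nested_plan"
  )
}

#' Serialize a nested plan to JSON
#'
#' Writes `{fold: {held_out: [...], hpo: {train, dev, test},
#' inner: [{dev: [...]}, ...]}}`; deterministic given the plan.
#'
#' @param plan A `nested_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_plan <- function(plan, path) {
  obj <- lapply(plan$folds, function(f) {
    list(
      held_out = f$held_out,
      hpo = lapply(
        split(f$hpo$participant_id, f$hpo$part)[c("train", "dev", "test")],
        identity
      ),
      inner = lapply(seq_len(plan$k_inner), function(i) {
        list(dev = f$inner$participant_id[f$inner$inner_fold == i])
      })
    )
  })
  names(obj) <- paste0("fold", seq_along(obj))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
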
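test_that("outer folds are pair-cohesive, stratified and participant-atomic", {
  cohort <- generate_cohort(cohort_config(), seed = 1)
  for (seed in 1:10) {
    plan <- plan_outer_folds(cohort, k = 10, seed = seed)
    # every participant in exactly one fold
    expect_equal(sort(plan$participant_id), sort(cohort$participant_id))
    # pairs co-travel
    split_units <- tapply(plan$fold, plan$unit_id, function(f) length(unique(f)))
    expect_true(all(split_units == 1))
    # per-stratum unit counts balanced to within one unit
    units <- dplyr::distinct(plan, unit_id, unit_class, fold)
    for (cl in unique(units$unit_class)) {
      per_fold <- table(factor(units$fold[units$unit_class == cl], levels = 1:10))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
    # patients per fold within the pigeonhole band for 155 cases / 10 folds
    cases <- table(plan$fold[plan$group == "acromegaly"])
    expect_true(all(cases >= 14 & cases <= 17))
  }
})

test_that("fold planning handles degenerate unit counts per contract", {
  two_pairs <- generate_cohort(
    cohort_config(n_patients = 2, n_controls = 2, n_matched_pairs = 2),
    seed = 1
  )
  plan <- plan_outer_folds(two_pairs, k = 2, seed = 1)
  units <- dplyr::distinct(plan, unit_id, fold)
  expect_equal(sort(as.integer(table(units$fold))), c(1, 1))

  one_pair <- generate_cohort(
    cohort_config(n_patients = 1, n_controls = 1, n_matched_pairs = 1),
    seed = 1
  )
  expect_error(plan_outer_folds(one_pair, k = 2), "units")
  expect_error(plan_outer_folds(two_pairs, k = 1), "k")
})

test_that("search split follows largest-remainder 80/10/10 with cohesion", {
  units100 <- tibble::tibble(
    participant_id = sprintf("U%03d", 1:100),
    unit_id = sprintf("U%03d", 1:100),
    unit_class = "case"
  )
  split <- plan_hpo_split(units100, seed = 1)
  expect_equal(
    as.integer(table(factor(split$part, c("train", "dev", "test")))),
    c(80, 10, 10)
  )

  units277 <- tibble::tibble(
    participant_id = sprintf("U%03d", 1:277),
    unit_id = sprintf("U%03d", 1:277),
    unit_class = "case"
  )
  split277 <- plan_hpo_split(units277, seed = 1)
  expect_equal(
    as.integer(table(factor(split277$part, c("train", "dev", "test")))),
    c(221, 28, 28)
  )

  # pair cohesion + determinism on a real modeling set
  cohort <- small_cohort(seed = 2)
  units <- cohort_units(cohort)
  s1 <- plan_hpo_split(units, seed = 5)
  s2 <- plan_hpo_split(units, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(tapply(s1$part, s1$unit_id, function(p) length(unique(p))) == 1))

  expect_error(plan_hpo_split(units100[1:5, ]), "10 units")
})

test_that("inner folds cover each unit as development exactly once", {
  cohort <- small_cohort(seed = 3)
  units <- cohort_units(cohort)
  inner <- plan_inner_folds(units, k_inner = 10, seed = 3)
  per_unit <- tapply(inner$inner_fold, inner$unit_id, function(f) length(unique(f)))
  expect_true(all(per_unit == 1))
  expect_equal(sort(unique(inner$inner_fold)), 1:10)
  # train/dev partition per fold
  for (i in 1:10) {
    dev_ids <- inner$participant_id[inner$inner_fold == i]
    train_ids <- inner$participant_id[inner$inner_fold != i]
    expect_length(intersect(dev_ids, train_ids), 0)
    expect_setequal(c(dev_ids, train_ids), cohort$participant_id)
  }
})

test_that("training-count accounting reproduces the study design numbers", {
  one <- count_trainings(10, c(net = 20), 10)
  expect_equal(one$total[one$architecture == "net"], 300)
  expect_equal(one$final[one$architecture == "net"], 100)

  expect_equal(count_trainings(10, c(x = 10), 10)$total[1], 200)
  expect_equal(count_trainings(1, c(x = 0), 1)$total[1], 1)

  roster <- count_trainings(10, c(a = 20, b = 20, c = 20, face = 10), 10)
  expect_equal(roster$total[roster$architecture == "total"], 1100)
  expect_equal(roster$final[roster$architecture == "total"], 400)
})

test_that("nested plans have no leakage between any split parts", {
  cohort <- generate_cohort(cohort_config(), seed = 4)
  plan <- plan_nested(cohort, k_outer = 10, k_inner = 10, seed = 4)
  for (f in plan$folds) {
    modeling_ids <- f$hpo$participant_id
    expect_length(intersect(f$held_out, modeling_ids), 0)
    expect_setequal(c(f$held_out, modeling_ids), cohort$participant_id)
    parts <- split(f$hpo$participant_id, f$hpo$part)
    expect_length(intersect(parts$train, parts$dev), 0)
    expect_length(intersect(parts$train, parts$test), 0)
    expect_length(intersect(parts$dev, parts$test), 0)
    for (i in seq_len(plan$k_inner)) {
      dev_ids <- f$inner$participant_id[f$inner$inner_fold == i]
      expect_length(intersect(dev_ids, f$held_out), 0)
    }
  }
})

test_that("fold plans serialize to the documented JSON layout", {
  cohort <- small_cohort(seed = 5)
  plan <- plan_nested(cohort, k_outer = 2, k_inner = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  obj <- jsonlite::read_json(path)
  expect_named(obj, c("fold1", "fold2"))
  expect_named(obj$fold1, c("held_out", "hpo", "inner"))
  expect_named(obj$fold1$hpo, c("train", "dev", "test"))
  expect_setequal(
    unlist(c(obj$fold1$held_out, obj$fold2$held_out)),
    cohort$participant_id
  )
})
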
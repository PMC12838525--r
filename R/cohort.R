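#' Cohort configuration
#'
#' Describes the composition of a synthetic matched case-control cohort.
#' Defaults mirror a national multi-centre screening study design:
#' 155 patients (42% women), 153 controls of whom 143 are individually
#' matched to a patient on sex, age (within 5 years) and recruitment site
#' across 7 sites, with 79% of patients biochemically controlled and 19
#' newly diagnosed.
#'
#' @param n_patients Number of case participants.
#' @param n_controls Number of control participants.
#' @param n_matched_pairs Number of case-control pairs matched on sex, age
#'   (within `match_age_tolerance` years) and site. Must not exceed
#'   `min(n_patients, n_controls)`.
#' @param female_fraction_patients Probability that a patient is female.
#' @param n_sites Number of recruitment sites.
#' @param age_range Length-2 numeric, inclusive age bounds in years.
#' @param age_peak Mode of the triangular age distribution, in years.
#' @param match_age_tolerance Maximum absolute age difference within a pair.
#' @param fraction_biochem_controlled Probability a patient is biochemically
#'   controlled.
#' @param fraction_newly_diagnosed Marginal probability a patient is newly
#'   diagnosed (newly diagnosed patients are drawn from the biochemically
#'   uncontrolled subset).
#'
#' @return A `cohort_config` object (a validated list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cohort_config(n_patients = 10, n_controls = 10, n_matched_pairs = 8)
cohort_config <- function(n_patients = 155,
                          n_controls = 153,
                          n_matched_pairs = 143,
                          female_fraction_patients = 65 / 155,
                          n_sites = 7,
                          age_range = c(23, 86),
                          age_peak = 58,
                          match_age_tolerance = 5,
                          fraction_biochem_controlled = 0.79,
                          fraction_newly_diagnosed = 19 / 155) {
  cfg <- structure(
    list(
      n_patients = n_patients,
      n_controls = n_controls,
      n_matched_pairs = n_matched_pairs,
      female_fraction_patients = female_fraction_patients,
      n_sites = n_sites,
      age_range = as.numeric(age_range),
      age_peak = age_peak,
      match_age_tolerance = match_age_tolerance,
      fraction_biochem_controlled = fraction_biochem_controlled,
      fraction_newly_diagnosed = fraction_newly_diagnosed
    ),
    class = "cohort_config"
  )
  problems <- validate_cohort_config(cfg)
  if (length(problems)) stop_config(problems)
  cfg
}

validate_cohort_config <- function(cfg) {
  p <- character()
  if (!is_count(cfg$n_patients) || cfg$n_patients < 1) {
    p <- c(p, "`n_patients` must be a positive count")
  }
  if (!is_count(cfg$n_controls) || cfg$n_controls < 1) {
    p <- c(p, "`n_controls` must be a positive count")
  }
  if (!is_count(cfg$n_matched_pairs)) {
    p <- c(p, "`n_matched_pairs` must be a count")
  } else if (cfg$n_matched_pairs > min(cfg$n_patients, cfg$n_controls)) {
    p <- c(p, paste0(
      "infeasible matching: `n_matched_pairs` (", cfg$n_matched_pairs,
      ") exceeds min(`n_patients`, `n_controls`) (",
      min(cfg$n_patients, cfg$n_controls), ")"
    ))
  }
  for (f in c(
    "female_fraction_patients", "fraction_biochem_controlled",
    "fraction_newly_diagnosed"
  )) {
    if (!is_proportion(cfg[[f]])) p <- c(p, paste0("`", f, "` must lie in [0, 1]"))
  }
  if (!is_count(cfg$n_sites) || cfg$n_sites < 1) {
    p <- c(p, "`n_sites` must be a positive count")
  }
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0) {
    p <- c(p, "`age_range` must be an increasing length-2 numeric")
  } else if (cfg$age_peak < cfg$age_range[1] || cfg$age_peak > cfg$age_range[2]) {
    p <- c(p, "`age_peak` must lie inside `age_range`")
  }
  if (!is.numeric(cfg$match_age_tolerance) || cfg$match_age_tolerance < 0) {
    p <- c(p, "`match_age_tolerance` must be >= 0")
  }
  p
}

#' Generate a synthetic matched case-control cohort
#'
#' Draws participant profiles for a case-control study with individually
#' matched pairs. Matched controls are generated from their patient's
#' attributes (same sex and site, age jittered within the matching
#' tolerance), which guarantees a feasible matching for any configuration.
#' Unmatched patients and unmatched controls are drawn from the same
#' marginal sex/age/site distributions, so the two groups are
#' indistinguishable in expectation.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#'
#' @return A tibble with one row per participant and columns
#'   `participant_id`, `group` (`"acromegaly"` or `"control"`), `sex`
#'   (`"F"`/`"M"`), `age` (years), `site`, `biochem_controlled` and
#'   `newly_diagnosed` (`NA` for controls), and `match_id` (the paired
#'   participant's id, or `NA` for unmatched participants).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' dplyr::count(cohort, group)
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  problems <- validate_cohort_config(config)
  if (length(problems)) stop_config(problems)

  withr::with_seed(derive_seed(seed, "cohort"), {
    np <- config$n_patients
    nc <- config$n_controls
    npair <- config$n_matched_pairs
    lo <- config$age_range[1]
    hi <- config$age_range[2]

    patients <- tibble(
      participant_id = sprintf("P%03d", seq_len(np)),
      group = "acromegaly",
      sex = ifelse(runif(np) < config$female_fraction_patients, "F", "M"),
      age = round(rtriangular(np, lo, hi, config$age_peak), 1),
      site = sample.int(config$n_sites, np, replace = TRUE),
      biochem_controlled = runif(np) < config$fraction_biochem_controlled
    )
    p_new <- if (config$fraction_biochem_controlled < 1) {
      min(1, config$fraction_newly_diagnosed /
        (1 - config$fraction_biochem_controlled))
    } else {
      0
    }
    patients$newly_diagnosed <- !patients$biochem_controlled &
      runif(np) < p_new

    matched_idx <- sort(sample.int(np, npair))
    patients$match_id <- NA_character_
    control_id <- sprintf("C%03d", seq_len(nc))

    matched_controls <- if (npair > 0) {
      src <- patients[matched_idx, ]
      tibble(
        participant_id = control_id[seq_len(npair)],
        group = "control",
        sex = src$sex,
        age = round(clamp(
          src$age + runif(npair, -config$match_age_tolerance,
            config$match_age_tolerance
          ),
          lo, hi
        ), 1),
        site = src$site,
        biochem_controlled = NA,
        newly_diagnosed = NA,
        match_id = src$participant_id
      )
    } else {
      NULL
    }
    patients$match_id[matched_idx] <- control_id[seq_len(npair)]

    n_free <- nc - npair
    free_controls <- if (n_free > 0) {
      tibble(
        participant_id = control_id[npair + seq_len(n_free)],
        group = "control",
        sex = ifelse(runif(n_free) < config$female_fraction_patients, "F", "M"),
        age = round(rtriangular(n_free, lo, hi, config$age_peak), 1),
        site = sample.int(config$n_sites, n_free, replace = TRUE),
        biochem_controlled = NA,
        newly_diagnosed = NA,
        match_id = NA_character_
      )
    } else {
      NULL
    }

    bind_rows(patients, matched_controls, free_controls)
  })
}

#' Truth labels of a cohort
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return A tibble with `participant_id` and `label` (1 for cases,
#'   0 for controls).
#' @export
cohort_truth <- function(cohort) {
  tibble(
    participant_id = cohort$participant_id,
    label = as.integer(cohort$group == "acromegaly")
  )
}

#' Write or read a cohort table as CSV
#'
#' @param cohort A cohort tibble.
#' @param path File path of the CSV.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  df$biochem_controlled <- as.logical(df$biochem_controlled)
  df$newly_diagnosed <- as.logical(df$newly_diagnosed)
  df$match_id <- as.character(df$match_id)
  df$match_id[df$match_id %in% c("", "NA")] <- NA_character_
  df
}
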
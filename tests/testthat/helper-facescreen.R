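# Shared fixtures, all built in code.

small_cohort_config <- function(n_pairs = 20, n_extra_cases = 2,
                                n_extra_controls = 2) {
  cohort_config(
    n_patients = n_pairs + n_extra_cases,
    n_controls = n_pairs + n_extra_controls,
    n_matched_pairs = n_pairs
  )
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(small_cohort_config(...), seed = seed)
}

# Sample tibble with a given feature matrix and labels, as consumed by
# train_model().
feature_samples <- function(x, labels, ids = NULL) {
  s <- tibble::tibble(
    participant_id = ids %||% sprintf("S%04d", seq_along(labels)),
    role = "train",
    label = as.integer(labels)
  )
  s$features <- x
  s
}

`%||%` <- rlang::`%||%`

# Independent brute-force Youden scan: evaluates J at every observed score
# and the -Inf sentinel directly from the confusion matrix.
brute_force_youden <- function(scores, labels) {
  cand <- c(-Inf, sort(unique(scores)))
  best <- -Inf
  for (tau in cand) {
    pred <- as.integer(scores >= tau)
    se <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    sp <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    best <- max(best, se + sp - 1)
  }
  best
}

# Independent AUC oracle: exhaustive pairwise comparison with half-credit
# for ties.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# One-shot cache for expensive acceptance fixtures shared across tests.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}
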
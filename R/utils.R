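# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed plus any mix of
# strings/integers (stage names, participant ids, fold indices).  Uses exact
# double arithmetic below 2^53, result always in [0, 2^31 - 2] so it is a
# valid R integer seed.
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(seed) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) {
      utf8ToInt(paste(part, collapse = "/"))
    } else {
      as.numeric(part)
    }
    for (k in codes) {
      x <- (x * 69069 + k + 1) %% m
    }
  }
  as.integer(x)
}

# Triangular distribution sampler on [a, b] with mode c (inverse CDF).
rtriangular <- function(n, a, b, c) {
  stopifnot(a <= c, c <= b, b > a)
  u <- runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
    a + sqrt(u * (b - a) * (c - a)),
    b - sqrt((1 - u) * (b - a) * (b - c))
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == round(x)
}

is_proportion <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}

stop_config <- function(msg) abort(msg, class = "facescreen_config_error")
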
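#' Parametric facial-morphology model
#'
#' The generator encodes the four facial features classically altered by
#' chronic growth-hormone excess: overall face width, mandible (jaw) size,
#' nose size and lip thickness. Each participant carries a latent
#' 4-dimensional morphology vector
#' \deqn{m = base + \delta \cdot mult^{[male]} \cdot [case] + \epsilon_b,}
#' with \eqn{\epsilon_b \sim N(0, \sigma_b^2 I)} between-subject variation,
#' and every rendered frame adds independent within-subject jitter
#' \eqn{\epsilon_w \sim N(0, \sigma_w^2 I)}. Because both noise components
#' are Gaussian and the disease effect is an additive mean shift, the
#' Bayes-optimal separability of the latent vectors has the closed form
#' AUC \eqn{= \Phi(d/\sqrt{2})} with
#' \eqn{d = \lVert\delta\rVert \cdot mult^{[male]} / \sigma_b}
#' (see [latent_separability()]), which downstream tests use as an oracle.
#'
#' @param base Named numeric of length 4 (`width`, `jaw`, `nose`, `lip`):
#'   control-group mean morphology.
#' @param effect Non-negative length-4 additive disease shift \eqn{\delta}.
#' @param male_effect_multiplier Scalar >= 1; the disease shift is
#'   multiplied by this factor in male cases (facial changes are typically
#'   more pronounced in men).
#' @param sigma_between Between-subject SD of each latent feature.
#' @param sigma_within Per-frame within-subject SD (captures pose/expression
#'   jitter between video frames).
#' @param image_size Side length in pixels of the square grayscale rendering.
#' @param edge_softness Width of the soft shape edges in normalized image
#'   coordinates; smooth edges make pixel intensities differentiable in the
#'   latent features.
#'
#' @return A `face_params` object.
#' @export
face_params <- function(base = c(width = 1, jaw = 1, nose = 1, lip = 1),
                        effect = c(width = 0.11, jaw = 0.11,
                                   nose = 0.11, lip = 0.11),
                        male_effect_multiplier = 1.3,
                        sigma_between = 0.15,
                        sigma_within = 0.05,
                        image_size = 64,
                        edge_softness = 0.07) {
  feat <- c("width", "jaw", "nose", "lip")
  base <- base[feat]
  effect <- effect[feat]
  if (anyNA(base) || anyNA(effect)) {
    stop_config("`base` and `effect` must be named vectors with entries width, jaw, nose, lip")
  }
  if (any(effect < 0)) stop_config("`effect` must be non-negative componentwise")
  if (male_effect_multiplier < 1) {
    stop_config("`male_effect_multiplier` must be >= 1")
  }
  if (sigma_between < 0 || sigma_within < 0) {
    stop_config("noise SDs must be >= 0")
  }
  if (!is_count(image_size) || image_size < 8) {
    stop_config("`image_size` must be a count >= 8")
  }
  structure(
    list(
      base = base, effect = effect,
      male_effect_multiplier = male_effect_multiplier,
      sigma_between = sigma_between, sigma_within = sigma_within,
      image_size = as.integer(image_size), edge_softness = edge_softness
    ),
    class = "face_params"
  )
}

#' Closed-form latent separability
#'
#' Bayes-optimal AUC for distinguishing case from control latent morphology
#' vectors, by sex: AUC \eqn{= \Phi(d/\sqrt{2})} where \eqn{d} is the
#' Mahalanobis distance \eqn{\lVert\delta\rVert mult^{[male]}/\sigma_b}
#' between the group means under isotropic Gaussian noise.
#'
#' @param params A [face_params()].
#' @return A tibble with columns `sex`, `d` and `auc`.
#' @export
#' @examples
#' latent_separability(face_params())
latent_separability <- function(params) {
  d_f <- sqrt(sum(params$effect^2)) / params$sigma_between
  d_m <- d_f * params$male_effect_multiplier
  tibble(
    sex = c("F", "M"),
    d = c(d_f, d_m),
    auc = pnorm(c(d_f, d_m) / sqrt(2))
  )
}

#' Calibrate the disease effect to a target latent AUC
#'
#' Rescales `effect` so that the closed-form separability of the baseline
#' (female, i.e. multiplier-free) latent shift equals `target_auc`.
#'
#' @param target_auc Target Bayes AUC in (0.5, 1).
#' @param params Template [face_params()] whose effect direction and noise
#'   are kept.
#' @return A `face_params` object with rescaled `effect`.
#' @export
#' @examples
#' latent_separability(face_params_for_auc(0.85))
face_params_for_auc <- function(target_auc, params = face_params()) {
  stopifnot(target_auc > 0.5, target_auc < 1)
  d_target <- sqrt(2) * qnorm(target_auc)
  d_now <- sqrt(sum(params$effect^2)) / params$sigma_between
  if (d_now <= 0) stop_config("template `effect` must be non-zero")
  params$effect <- params$effect * (d_target / d_now)
  params
}

# Subject-level latent morphology for one participant, deterministic in
# (seed, participant_id).
participant_latent <- function(profile, params, seed) {
  shift <- if (profile$group == "acromegaly") {
    params$effect *
      params$male_effect_multiplier^(profile$sex == "M")
  } else {
    0
  }
  withr::with_seed(
    derive_seed(seed, "latent", profile$participant_id),
    params$base + shift + rnorm(4, 0, params$sigma_between)
  )
}

#' Latent morphology of every cohort member
#'
#' Exposes the subject-level latent feature vectors that
#' [render_participant_video()] renders, for oracle-style analyses that
#' bypass pixels (e.g. closed-form separability checks).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param params A [face_params()].
#' @param seed Integer seed; must match the one used for rendering to get
#'   the identical latents.
#' @return A tibble with `participant_id`, `width`, `jaw`, `nose`, `lip`.
#' @export
draw_latents <- function(cohort, params = face_params(), seed = 1L) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    lat <- participant_latent(cohort[i, ], params, seed)
    tibble(
      participant_id = cohort$participant_id[i],
      width = lat[[1]], jaw = lat[[2]], nose = lat[[3]], lip = lat[[4]]
    )
  })
  bind_rows(rows)
}

# Cached normalized coordinate grids for a given image size.
coord_cache <- new.env(parent = emptyenv())
coord_grids <- function(s) {
  key <- as.character(s)
  if (is.null(coord_cache[[key]])) {
    ax <- seq(-1, 1, length.out = s)
    coord_cache[[key]] <- list(
      X = matrix(ax, nrow = s, ncol = s, byrow = TRUE), # column coordinate
      Y = matrix(ax, nrow = s, ncol = s, byrow = FALSE) # row coordinate, top = -1
    )
  }
  coord_cache[[key]]
}

# Soft inside-indicator of the ellipse g <= 1.
soft_inside <- function(g, softness) plogis((1 - g) / softness)

#' Render one face frame
#'
#' Deterministic grayscale rendering of a latent morphology vector at a
#' given head yaw: a head ellipse whose width scales with the `width`
#' feature (foreshortened as the head turns), a jaw region scaling with
#' `jaw`, a nose blob scaling with `nose` that translates with yaw, a lip
#' band whose thickness scales with `lip`, and a flat clothing band at the
#' image base. Shape edges are smooth so pixel intensities respond
#' continuously (and monotonically) to the latent features.
#'
#' @param latent Numeric length-4 vector (width, jaw, nose, lip).
#' @param yaw Head rotation in degrees, 0 = frontal, +/-90 = full profile.
#' @param image_size Side length in pixels.
#' @param edge_softness Soft-edge width in normalized coordinates.
#' @return A numeric `image_size` x `image_size` matrix in `[0, 1]`.
#' @export
render_face <- function(latent, yaw, image_size = 64, edge_softness = 0.07) {
  if (!is_count(image_size) || image_size < 8) {
    stop_config("`image_size` must be a count >= 8")
  }
  lat <- pmax(as.numeric(latent), 0.1)
  w <- lat[1]; j <- lat[2]; n <- lat[3]; l <- lat[4]
  g <- coord_grids(image_size)
  X <- g$X; Y <- g$Y
  yr <- yaw * pi / 180
  fore <- 0.6 + 0.4 * abs(cos(yr)) # foreshortening of horizontal extents
  sh <- sin(yr)
  cx <- 0.10 * sh

  ell <- function(cx, cy, rx, ry) ((X - cx) / rx)^2 + ((Y - cy) / ry)^2

  head_v <- 0.50 * soft_inside(ell(cx, -0.05, 0.50 * w * fore, 0.62), edge_softness)
  jaw_v <- 0.70 * soft_inside(ell(cx, 0.40, 0.27 * j * fore, 0.16 * j), edge_softness)
  nose_v <- 1.00 * soft_inside(
    ell(cx + 0.25 * sh, 0.00, 0.17 * n, 0.27 * n),
    edge_softness
  )
  lip_v <- 1.00 * soft_inside(
    ell(cx + 0.10 * sh, 0.44, 0.23 * fore * l, 0.11 * l),
    edge_softness
  )

  # Dark face on a white background (the emulated recordings are lit
  # against a white backdrop); clothing is a mid-gray band.
  img <- 1 - pmax(head_v, jaw_v, nose_v, lip_v)
  img[clothing_region(image_size)] <- 0.35
  clamp(img, 0, 1)
}

#' Clothing region of a rendered frame
#'
#' Logical mask of the fixed clothing band at the image base (normalized
#' row coordinate > 0.8).
#'
#' @param image_size Side length in pixels.
#' @return A logical `image_size` x `image_size` matrix.
#' @export
clothing_region <- function(image_size = 64) {
  coord_grids(image_size)$Y > 0.8
}

#' Render a participant's video-like yaw sweep
#'
#' Renders `n_frames` frames sweeping head yaw uniformly from -90 to +90
#' degrees (endpoints included). The participant's subject-level latent
#' morphology is drawn once (deterministically from `seed` and the
#' participant id) and every frame adds independent within-subject jitter.
#' Identical `(profile, params, seed)` reproduce the frames bit-exactly.
#'
#' @param profile One-row cohort tibble (a single participant).
#' @param params A [face_params()].
#' @param n_frames Number of frames, >= 3.
#' @param seed Integer seed.
#' @return A frame-set tibble with columns `participant_id`, `frame_index`,
#'   `yaw` (degrees) and list-columns `image` (numeric matrices) and `mask`
#'   (logical clothing masks).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 2, n_controls = 2,
#'   n_matched_pairs = 2), seed = 1)
#' fs <- render_participant_video(cohort[1, ], n_frames = 3, seed = 1)
#' fs$yaw
render_participant_video <- function(profile, params = face_params(),
                                     n_frames = 21, seed = 1L) {
  if (nrow(profile) != 1) stop_config("`profile` must be a single participant row")
  if (!is_count(n_frames) || n_frames < 3) stop_config("`n_frames` must be >= 3")
  lat <- participant_latent(profile, params, seed)
  yaws <- seq(-90, 90, length.out = n_frames)
  jitter <- withr::with_seed(
    derive_seed(seed, "frames", profile$participant_id),
    matrix(rnorm(4 * n_frames, 0, params$sigma_within), nrow = n_frames)
  )
  mask <- clothing_region(params$image_size)
  tibble(
    participant_id = profile$participant_id,
    frame_index = seq_len(n_frames),
    yaw = yaws,
    image = lapply(seq_len(n_frames), function(k) {
      render_face(lat + jitter[k, ], yaws[k],
        image_size = params$image_size,
        edge_softness = params$edge_softness
      )
    }),
    mask = replicate(n_frames, mask, simplify = FALSE)
  )
}
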
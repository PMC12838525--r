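#' Angle specification for the two image sets
#'
#' Defines which yaw angles feed the two per-participant image sets: a
#' training set spanning the full sweep (default 20 uniformly spaced angles
#' over \[-90, +90\] degrees) and a test set of 3 canonical views (frontal
#' 0, half-profile 45, full profile 90).
#'
#' @param train_angles Numeric vector of training yaw targets in degrees.
#' @param test_angles Numeric vector of test yaw targets in degrees.
#' @return An `angle_spec` object.
#' @export
angle_spec <- function(train_angles = seq(-90, 90, length.out = 20),
                       test_angles = c(0, 45, 90)) {
  if (any(abs(c(train_angles, test_angles)) > 90)) {
    stop_config("all angles must lie within [-90, 90] degrees")
  }
  structure(
    list(train_angles = train_angles, test_angles = test_angles),
    class = "angle_spec"
  )
}

#' Select the frames nearest to requested yaw angles
#'
#' For each requested angle, picks the frame whose actual yaw is nearest to
#' the target, breaking ties in favour of the earlier frame index.
#'
#' @param frameset A frame-set tibble from [render_participant_video()] (or
#'   [read_frames()]).
#' @param spec An [angle_spec()].
#' @return A tibble of image samples with columns `participant_id`, `role`
#'   (`"train"`/`"test"`), `target_yaw`, `actual_yaw`, `frame_index`, and
#'   list-columns `image` and `mask`.
#' @export
select_frames <- function(frameset, spec = angle_spec()) {
  if (nrow(frameset) == 0) stop_config("`frameset` is empty")
  pick <- function(targets, role) {
    idx <- vapply(targets, function(a) which.min(abs(frameset$yaw - a)), 1L)
    tibble(
      participant_id = frameset$participant_id[idx],
      role = role,
      target_yaw = targets,
      actual_yaw = frameset$yaw[idx],
      frame_index = frameset$frame_index[idx],
      image = frameset$image[idx],
      mask = frameset$mask[idx]
    )
  }
  bind_rows(
    pick(spec$train_angles, "train"),
    pick(spec$test_angles, "test")
  )
}

# Binary dilation of a logical matrix by a box structuring element of the
# given radius (Chebyshev ball), via shift-OR.
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -radius:radius) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    ro <- rs - dr
    for (dc in -radius:radius) {
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      co <- cs - dc
      out[rs, cs] <- out[rs, cs] | mask[ro, co]
    }
  }
  out
}

#' Mask clothing pixels to white
#'
#' Sets all pixels under the clothing mask to pure white (1). With
#' `manual_adjust = TRUE` the mask is first morphologically dilated by
#' `dilate_radius` pixels (box structuring element), emulating the manual
#' tightening applied to test images so that no clothing survives at the
#' mask boundary.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Logical matrix of the same dimensions.
#' @param manual_adjust Dilate the mask before applying it?
#' @param dilate_radius Dilation radius in pixels.
#' @return The masked image matrix.
#' @export
apply_clothing_mask <- function(image, mask, manual_adjust = FALSE,
                                dilate_radius = 2) {
  if (!identical(dim(image), dim(mask))) {
    stop_config("`image` and `mask` dimensions differ")
  }
  if (manual_adjust) mask <- dilate_mask(mask, dilate_radius)
  image[mask] <- 1
  image
}

#' Build the per-participant training and test image sets
#'
#' Extracts the training sweep (image set 1) and the 3-view test set
#' (image set 2) from a frame sequence and applies the clothing mask:
#' automatically for training images, with the manual-adjust dilation for
#' test images.
#'
#' @inheritParams select_frames
#' @param dilate_radius Dilation radius used for test-image masks.
#' @return A tibble like [select_frames()] but with masked images and no
#'   `mask` column.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 1, n_controls = 1,
#'   n_matched_pairs = 1), seed = 1)
#' fs <- render_participant_video(cohort[1, ], n_frames = 21, seed = 1)
#' sets <- build_image_sets(fs)
#' dplyr::count(sets, role)
build_image_sets <- function(frameset, spec = angle_spec(), dilate_radius = 2) {
  samples <- select_frames(frameset, spec)
  samples$image <- purrr::pmap(
    list(samples$image, samples$mask, samples$role == "test"),
    function(img, msk, adj) {
      apply_clothing_mask(img, msk, manual_adjust = adj,
        dilate_radius = dilate_radius)
    }
  )
  samples$mask <- NULL
  samples
}

#' Write or read a frame set as PNG files plus a frames.csv manifest
#'
#' Frames are written as `<participant_id>_<frameindex>.png`, clothing
#' masks as `<participant_id>_<frameindex>_mask.png`, and yaw annotations
#' to `frames.csv` (`participant_id`, `frame_index`, `yaw_deg`).
#'
#' @param frameset A frame-set tibble.
#' @param dir Directory to write to (created if missing).
#' @return `write_frames()` returns `dir` invisibly; `read_frames()`
#'   returns the frame-set tibble.
#' @export
write_frames <- function(frameset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(frameset))) {
    stem <- sprintf(
      "%s_%03d", frameset$participant_id[i], frameset$frame_index[i]
    )
    png::writePNG(frameset$image[[i]], file.path(dir, paste0(stem, ".png")))
    png::writePNG(
      matrix(as.numeric(frameset$mask[[i]]), nrow(frameset$mask[[i]])),
      file.path(dir, paste0(stem, "_mask.png"))
    )
  }
  write.csv(
    data.frame(
      participant_id = frameset$participant_id,
      frame_index = frameset$frame_index,
      yaw_deg = frameset$yaw
    ),
    file.path(dir, "frames.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  manifest <- read.csv(file.path(dir, "frames.csv"), stringsAsFactors = FALSE)
  stems <- sprintf("%s_%03d", manifest$participant_id, manifest$frame_index)
  tibble(
    participant_id = manifest$participant_id,
    frame_index = manifest$frame_index,
    yaw = manifest$yaw_deg,
    image = lapply(stems, function(s) png::readPNG(file.path(dir, paste0(s, ".png")))),
    mask = lapply(stems, function(s) {
      png::readPNG(file.path(dir, paste0(s, "_mask.png"))) > 0.5
    })
  )
}
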
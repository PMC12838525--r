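#' Pluggable feature-extraction backbone
#'
#' Lightweight stand-in backbones let the full training protocol run at
#' desk scale. Each named backbone is a deterministic feature extractor
#' with fixed "pretrained" weights derived from its name: the three
#' `imagenet_style_*` variants and the `face_pretrained_style` variant are
#' random linear projections of the pixel vector (distinct seeds, and a
#' larger feature dimension for the face-pretrained variant), and
#' `linear_probe` is 8x8 average pooling. Real pretrained networks can be
#' plugged in by supplying `extractor`, a `function(pixel_matrix)` returning
#' a feature matrix.
#'
#' @param name One of `"imagenet_style_a"`, `"imagenet_style_b"`,
#'   `"imagenet_style_c"`, `"face_pretrained_style"`, `"linear_probe"`.
#' @param feature_dim Feature dimension (ignored by `linear_probe`;
#'   defaults to 48 for `face_pretrained_style`, 32 otherwise).
#' @param frozen Phase-1 state of the backbone. When `TRUE` (the default)
#'   the backbone stays frozen in both phases and only the prediction head
#'   is trained (a linear probe); when `FALSE`, phase 2 of
#'   [train_model()] fine-tunes the projection weights as well.
#' @param extractor Optional custom extractor function (rows = images).
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(name = c(
                            "imagenet_style_a", "imagenet_style_b",
                            "imagenet_style_c", "face_pretrained_style",
                            "linear_probe"
                          ),
                          feature_dim = NULL,
                          frozen = TRUE,
                          extractor = NULL) {
  name <- match.arg(name)
  if (is.null(feature_dim)) {
    feature_dim <- if (name == "face_pretrained_style") 48L else 32L
  }
  if (name == "linear_probe") {
    feature_dim <- 64L
    frozen <- TRUE
  }
  structure(
    list(
      name = name, feature_dim = as.integer(feature_dim),
      frozen = isTRUE(frozen), extractor = extractor
    ),
    class = "backbone_spec"
  )
}

weight_cache <- new.env(parent = emptyenv())

# Fixed random projection weights for a named backbone, d x p, entries
# N(0, 1/p) so projected features have unit-order scale.
backbone_weights <- function(backbone, n_pixels) {
  key <- paste(backbone$name, backbone$feature_dim, n_pixels, sep = "|")
  if (is.null(weight_cache[[key]])) {
    weight_cache[[key]] <- withr::with_seed(
      derive_seed(20240101, "backbone", backbone$name, backbone$feature_dim, n_pixels),
      matrix(
        rnorm(backbone$feature_dim * n_pixels, 0, 1 / sqrt(n_pixels)),
        nrow = backbone$feature_dim
      )
    )
  }
  weight_cache[[key]]
}

# Flatten a list of equally sized image matrices into an n x p matrix.
flatten_images <- function(images) {
  do.call(rbind, lapply(images, as.vector))
}

# Average pooling to a grid x grid summary, as a cached p x grid^2
# aggregation matrix applied to the flattened (column-major) images.
pool_cache <- new.env(parent = emptyenv())
pool_features <- function(x, side, grid = 8) {
  key <- paste(side, grid, sep = "|")
  if (is.null(pool_cache[[key]])) {
    r <- rep(seq_len(side), times = side)
    cc <- rep(seq_len(side), each = side)
    cell <- (ceiling(cc * grid / side) - 1L) * grid + ceiling(r * grid / side)
    a <- matrix(0, side * side, grid * grid)
    a[cbind(seq_len(side * side), cell)] <- 1
    pool_cache[[key]] <- sweep(a, 2, colSums(a), "/")
  }
  x %*% pool_cache[[key]]
}

#' Extract backbone features from images
#'
#' Deterministic given the backbone and the input: the same images always
#' yield the same features.
#'
#' @param images A list of equally sized image matrices, or an
#'   already-flattened numeric matrix (one row per image).
#' @param backbone A [backbone_spec()].
#' @return A numeric matrix, one row per image, `feature_dim` columns.
#' @export
extract_features <- function(images, backbone) {
  x <- if (is.matrix(images)) images else flatten_images(images)
  if (!is.null(backbone$extractor)) {
    return(backbone$extractor(x))
  }
  if (backbone$name == "linear_probe") {
    side <- as.integer(sqrt(ncol(x)))
    return(pool_features(x, side))
  }
  w <- backbone_weights(backbone, ncol(x))
  x %*% t(w)
}

# Feature matrix for a sample tibble: uses a `features` matrix column when
# present, otherwise extracts from the `image` list-column.
sample_features <- function(samples, backbone) {
  if (!is.null(samples$features)) {
    as.matrix(samples$features)
  } else if (!is.null(samples$image)) {
    extract_features(samples$image, backbone)
  } else {
    stop_config("samples need a `features` or `image` column")
  }
}
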
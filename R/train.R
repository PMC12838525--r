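#' Training schedule configuration
#'
#' The trainer follows a two-phase schedule: phase 1 trains only the newly
#' added prediction head with the backbone frozen; phase 2 continues
#' training the whole network (for frozen backbones, e.g. the linear
#' probe, phase 2 also updates only the head). The development-set ROC AUC
#' is evaluated after every epoch (one complete pass through the training
#' set), the checkpoint with the best development AUC is the selected
#' model, and with early stopping enabled training halts once `patience`
#' epochs pass without improvement.
#'
#' @param phase1_epochs,phase2_epochs Epoch counts per phase (>= 0, at
#'   least one epoch overall).
#' @param lr_phase1,lr_phase2 Learning rates per phase.
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled L2 weight decay applied to the head
#'   weights each step; regularizes the learned discriminant direction.
#' @param early_stopping Enable patience-based early stopping?
#' @param patience Epochs without development-AUC improvement before
#'   stopping.
#' @param seed Integer seed controlling shuffling and initialization.
#' @return A `training_config` object.
#' @export
training_config <- function(phase1_epochs = 2, phase2_epochs = 12,
                            lr_phase1 = 3e-3, lr_phase2 = 3e-3,
                            batch_size = 64,
                            weight_decay = 1e-3,
                            early_stopping = FALSE, patience = 5,
                            seed = 1L) {
  if (!is_count(phase1_epochs) || !is_count(phase2_epochs) ||
    phase1_epochs + phase2_epochs < 1) {
    stop_config("need at least one training epoch")
  }
  if (early_stopping && (!is_count(patience) || patience < 1)) {
    stop_config("`patience` must be >= 1 when early stopping is enabled")
  }
  if (!is_count(batch_size) || batch_size < 1) {
    stop_config("`batch_size` must be a positive count")
  }
  structure(
    list(
      phase1_epochs = phase1_epochs, phase2_epochs = phase2_epochs,
      lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
      batch_size = batch_size, weight_decay = weight_decay,
      early_stopping = isTRUE(early_stopping), patience = patience,
      seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Train a binary image classifier under the two-phase schedule
#'
#' Fits a logistic prediction head on backbone features by minibatch
#' gradient descent. Features are standardized with training-set
#' statistics. For a non-frozen projection backbone, phase 2 also updates
#' the projection weights (fine-tuning); frozen backbones train the head
#' in both phases. The development AUC is tracked per epoch and the
#' best-epoch parameters are the ones kept. Bit-reproducible under a fixed
#' `config$seed`.
#'
#' @param train,dev Sample tibbles with a binary `label` column (1 = case)
#'   and either an `image` list-column or a `features` matrix column. The
#'   development set must contain both classes.
#' @param backbone A [backbone_spec()].
#' @param config A [training_config()].
#' @return A `face_model` object; see [tidy.face_model()] and
#'   [glance.face_model()].
#' @export
train_model <- function(train, dev,
                        backbone = backbone_spec("linear_probe"),
                        config = training_config()) {
  if (nrow(train) == 0 || nrow(dev) == 0) {
    stop_config("`train` and `dev` must be non-empty")
  }
  y <- train$label
  yd <- dev$label
  if (!all(c(y, yd) %in% c(0, 1))) stop_config("labels must be 0/1")
  if (length(unique(yd)) < 2) {
    stop_config("development set has a single class; AUC is undefined")
  }

  finetune <- !backbone$frozen && is.null(backbone$extractor) &&
    backbone$name != "linear_probe"
  if (finetune) {
    xr_train <- if (is.matrix(train$image)) train$image else flatten_images(train$image)
    xr_dev <- if (is.matrix(dev$image)) dev$image else flatten_images(dev$image)
    w_proj <- backbone_weights(backbone, ncol(xr_train))
    z_train <- xr_train %*% t(w_proj)
    z_dev <- xr_dev %*% t(w_proj)
  } else {
    w_proj <- NULL
    z_train <- sample_features(train, backbone)
    z_dev <- sample_features(dev, backbone)
  }
  # Centre per feature but scale by one global SD: per-feature scaling
  # would blow up near-constant features (e.g. the fixed clothing band),
  # amplifying any train/test shift in them by orders of magnitude.
  mu <- colMeans(z_train)
  sd_ <- rep(
    max(sqrt(mean(apply(z_train, 2, stats::var))), 1e-3),
    ncol(z_train)
  )
  scale_z <- function(z) sweep(sweep(z, 2, mu), 2, sd_, "/")

  d <- ncol(z_train)
  n <- nrow(z_train)
  head_w <- numeric(d)
  head_b <- 0
  total_epochs <- config$phase1_epochs + config$phase2_epochs

  # Adam state for the head (and projection when fine-tuning): adaptive
  # steps keep the whole searched learning-rate range trainable.
  adam <- list(
    mw = numeric(d), vw = numeric(d), mb = 0, vb = 0,
    mp = if (finetune) 0 * w_proj, vp = if (finetune) 0 * w_proj,
    t = 0
  )
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  adam_step <- function(m, v, g, t) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    list(m = m, v = v, step = (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps))
  }

  best <- list(auc = -Inf, epoch = 0L, w = head_w, b = head_b, proj = w_proj)
  traj <- vector("list", total_epochs)
  stopped <- NA_integer_

  withr::with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(total_epochs)) {
      phase <- if (epoch <= config$phase1_epochs) 1L else 2L
      lr <- if (phase == 1L) config$lr_phase1 else config$lr_phase2
      idx <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        b_idx <- idx[s:min(s + config$batch_size - 1, n)]
        zs <- scale_z(z_train[b_idx, , drop = FALSE])
        p <- plogis(drop(zs %*% head_w) + head_b)
        g <- (p - y[b_idx]) / length(b_idx)
        adam$t <- adam$t + 1
        if (phase == 2L && finetune) {
          gz <- sweep(outer(g, head_w), 2, sd_, "/")
          gp <- t(gz) %*% xr_train[b_idx, , drop = FALSE]
          up <- adam_step(adam$mp, adam$vp, gp, adam$t)
          adam$mp <- up$m; adam$vp <- up$v
          w_proj <- w_proj - lr * up$step
        }
        uw <- adam_step(adam$mw, adam$vw, drop(crossprod(zs, g)), adam$t)
        adam$mw <- uw$m; adam$vw <- uw$v
        head_w <- head_w - lr * uw$step -
          lr * (config$weight_decay %||% 0) * head_w
        ub <- adam_step(adam$mb, adam$vb, sum(g), adam$t)
        adam$mb <- ub$m; adam$vb <- ub$v
        head_b <- head_b - lr * ub$step
        if (phase == 2L && finetune) {
          z_train[b_idx, ] <- xr_train[b_idx, , drop = FALSE] %*% t(w_proj)
        }
      }
      if (finetune) z_dev <- xr_dev %*% t(w_proj)
      dev_scores <- plogis(drop(scale_z(z_dev) %*% head_w) + head_b)
      auc <- roc_auc(dev_scores, yd)
      traj[[epoch]] <- tibble(epoch = epoch, phase = phase, dev_auc = auc)
      if (auc > best$auc + 1e-12) {
        best <- list(
          auc = auc, epoch = epoch, w = head_w, b = head_b, proj = w_proj
        )
      }
      if (config$early_stopping && epoch - best$epoch >= config$patience) {
        stopped <- epoch
        break
      }
    }
  })

  structure(
    list(
      backbone = backbone, config = config,
      mu = mu, sd = sd_,
      head_w = best$w, head_b = best$b, proj = best$proj,
      finetuned = finetune,
      trajectory = bind_rows(traj),
      selected_epoch = best$epoch,
      best_dev_auc = best$auc,
      stopped_epoch = stopped,
      n_train = n
    ),
    class = "face_model"
  )
}

#' Predict scores from a trained model
#'
#' @param object A `face_model`.
#' @param newdata Sample tibble with an `image` or `features` column.
#' @param ... Unused.
#' @return Numeric vector of probability scores in `[0, 1]`.
#' @export
predict.face_model <- function(object, newdata, ...) {
  z <- if (object$finetuned) {
    x <- if (is.matrix(newdata$image)) newdata$image else flatten_images(newdata$image)
    x %*% t(object$proj)
  } else {
    sample_features(newdata, object$backbone)
  }
  zs <- sweep(sweep(z, 2, object$mu), 2, object$sd, "/")
  plogis(drop(zs %*% object$head_w) + object$head_b)
}

#' @export
print.face_model <- function(x, ...) {
  cat(
    "<face_model> backbone:", x$backbone$name,
    "| selected epoch:", x$selected_epoch,
    "| dev AUC:", round(x$best_dev_auc, 3),
    if (!is.na(x$stopped_epoch)) paste("| early-stopped at", x$stopped_epoch) else "",
    "\n"
  )
  invisible(x)
}

#' Tidy the per-epoch development trajectory of a model
#'
#' @param x A `face_model`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `phase`, `dev_auc`.
#' @export
tidy.face_model <- function(x, ...) x$trajectory

#' One-row summary of a trained model
#'
#' @param x A `face_model`.
#' @param ... Unused.
#' @return A tibble with `backbone`, `selected_epoch`, `best_dev_auc`,
#'   `stopped_epoch`, `n_epochs`, `n_train`.
#' @export
glance.face_model <- function(x, ...) {
  tibble(
    backbone = x$backbone$name,
    selected_epoch = x$selected_epoch,
    best_dev_auc = x$best_dev_auc,
    stopped_epoch = x$stopped_epoch,
    n_epochs = nrow(x$trajectory),
    n_train = x$n_train
  )
}
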
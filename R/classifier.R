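#' Training configuration for the frame-level attack classifier
#'
#' @param epochs training epochs per fold.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param lags temporal-difference lags (frames) for the input channels.
#' @param filters per-block convolution filter counts.
#' @param input_pool initial average-pool factor applied to the input
#'   (1 = none, 2 = halve each spatial dimension) before the conv blocks.
#' @param neg_ratio negatives sampled per positive frame for training
#'   (class-imbalance handling by resampling); remaining imbalance within the
#'   sample is compensated with a positive-class loss weight.
#' @param seed seed governing fold order, subsampling, initialization and
#'   batch shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 10L, batch_size = 32L,
                            learning_rate = 1e-3, lags = c(1L, 2L),
                            filters = c(8L, 16L, 32L), input_pool = 2L,
                            neg_ratio = 3, seed = 1L) {
  if (epochs < 1L) stop_invalid("epochs must be >= 1")
  lags <- as.integer(lags)
  if (!length(lags) || any(lags < 1L) || any(diff(lags) <= 0))
    stop_invalid("lags must be strictly increasing integers >= 1")
  check_number(neg_ratio, "neg_ratio", min = 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lags = lags,
                 filters = as.integer(filters),
                 input_pool = as.integer(input_pool),
                 neg_ratio = neg_ratio, seed = as.integer(seed)),
            class = "training_config")
}

# Difference stack of a session at network input resolution, laid out as
# H x W x T x C (the engine's batch-before-channels layout).
session_stack <- function(video, lags, input_pool = 1L) {
  pool_stack(aperm(build_difference_stack(session_gray(video), lags),
                   c(1L, 2L, 4L, 3L)),
             input_pool)
}

# per-channel symmetric normalization to [-1, 1] from training data
norm_stats <- function(X) {
  C <- dim(X)[4]
  center <- numeric(C); halfrange <- numeric(C)
  for (c in seq_len(C)) {
    v <- range(X[, , , c])
    center[c] <- (v[1] + v[2]) / 2
    halfrange[c] <- max((v[2] - v[1]) / 2, 1e-6)
  }
  list(center = center, halfrange = halfrange)
}

apply_norm <- function(X, ns) {
  for (c in seq_len(dim(X)[4]))
    X[, , , c] <- (X[, , , c] - ns$center[c]) / ns$halfrange[c]
  X
}

# Train one network on a list of (stack, labels); subsamples negatives.
fit_one_model <- function(stacks, labels, config, seed) {
  y <- unlist(labels)
  npos_total <- sum(y == 1L); nneg_total <- sum(y == 0L)
  pos_idx <- which(y == 1L)
  neg_idx <- which(y == 0L)
  n_neg_keep <- min(length(neg_idx),
                    max(50L, ceiling(config$neg_ratio * length(pos_idx))))
  sel <- with_seed(derive_seed(seed, 1L),
                   c(pos_idx, sample(neg_idx, n_neg_keep)))
  # map flat indices back to (video, frame)
  lens <- vapply(labels, length, 1L)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  d1 <- dim(stacks[[1L]])
  X <- array(0, c(d1[1], d1[2], length(sel), d1[4]))
  for (k in seq_along(sel)) {
    v <- findInterval(sel[k] - 1L, offs)
    X[, , k, ] <- stacks[[v]][, , sel[k] - offs[v], ]
  }
  ysel <- y[sel]
  ns <- norm_stats(X)
  X <- apply_norm(X, ns)
  # residual imbalance in the training sample handled by loss weighting
  pos_weight <- max(1, sum(ysel == 0) / max(1, sum(ysel == 1)))
  net <- cnn_init(d1[4], config$filters, seed = derive_seed(seed, 2L))
  net <- cnn_train(net, X, ysel,
                   epochs = config$epochs, batch_size = config$batch_size,
                   lr = config$learning_rate, pos_weight = pos_weight,
                   seed = derive_seed(seed, 3L))
  structure(list(net = net, norm = ns, lags = config$lags,
                 input_pool = config$input_pool,
                 input_hw = d1[1:2] * config$input_pool,
                 filters = config$filters,
                 n_pos_train = npos_total, n_neg_train = nneg_total,
                 config = config),
            class = "frame_classifier")
}

#' @export
print.frame_classifier <- function(x, ...) {
  cat(sprintf(
    "frame_classifier: %dx%d input, lags (%s), conv filters (%s), input pool %d\n",
    x$input_hw[1], x$input_hw[2], paste(x$lags, collapse = ","),
    paste(x$filters, collapse = ","), x$input_pool))
  invisible(x)
}

#' Train the frame classifier with leave-one-video-out cross-validation
#'
#' Runs one training per held-out video: the network is fit on the remaining
#' videos and its frame-level ROC AUC is measured on the held-out one. A fold
#' whose held-out video contains only one class has no defined AUC and is
#' reported as `NA`. The final model is retrained on all videos.
#'
#' @param videos list of labeled [video_session()] objects (>= 2).
#' @param config a [training_config()].
#' @return A list with elements `model` (a `frame_classifier`),
#'   `fold_metrics` (data frame: fold, held_out, n_pos_holdout, auc) and
#'   `mean_auc` (mean over folds with defined AUC).
#' @export
train_frame_classifier <- function(videos, config = training_config()) {
  if (!is.list(videos) || length(videos) < 2L)
    stop_invalid("need at least 2 labeled videos")
  for (v in videos)
    if (is.null(v$labels))
      stop_invalid("all videos must carry per-frame labels")
  stacks <- lapply(videos, session_stack, lags = config$lags,
                   input_pool = config$input_pool)
  labels <- lapply(videos, function(v) v$labels)

  nv <- length(videos)
  folds <- data.frame(fold = seq_len(nv),
                      held_out = vapply(videos, function(v)
                        v$id %||% "?", ""),
                      n_pos_holdout = vapply(labels, function(l)
                        sum(l == 1L), 1L),
                      auc = NA_real_)
  for (i in seq_len(nv)) {
    ytr <- unlist(labels[-i])
    if (length(unique(ytr)) < 2L)
      stop_invalid(sprintf(
        "training fold %d (held-out video '%s') contains a single class",
        i, folds$held_out[i]))
    fit <- fit_one_model(stacks[-i], labels[-i], config,
                         seed = derive_seed(config$seed, 100L + i))
    yte <- labels[[i]]
    if (length(unique(yte)) >= 2L) {
      p <- cnn_predict(fit$net, apply_norm(stacks[[i]], fit$norm))
      folds$auc[i] <- roc_auc(p, yte)
    }
  }
  final <- fit_one_model(stacks, labels, config,
                         seed = derive_seed(config$seed, 99L))
  list(model = final, fold_metrics = folds,
       mean_auc = mean(folds$auc, na.rm = TRUE))
}

#' Per-frame attack probabilities for a video
#'
#' @param model a `frame_classifier` from [train_frame_classifier()].
#' @param video a [video_session()].
#' @return A [probability_trace()] with one probability per frame.
#' @export
predict_probabilities <- function(model, video) {
  if (!inherits(model, "frame_classifier")) stop_invalid("not a frame_classifier")
  d <- dim(video$frames)
  if (!all(d[1:2] == model$input_hw))
    stop_invalid(sprintf("video geometry %dx%d does not match model input %dx%d",
                         d[1], d[2], model$input_hw[1], model$input_hw[2]))
  X <- apply_norm(session_stack(video, model$lags, model$input_pool),
                  model$norm)
  probability_trace(cnn_predict(model$net, X),
                    fps = video$fps, video_id = video$id)
}

#' Save / load a trained frame classifier
#'
#' The model directory holds `metadata.json` (architecture, lags, input size,
#' normalization constants) and `weights.txt` (flattened parameter vector at
#' full precision). Loading validates the metadata before inference;
#' reloaded models produce bit-identical probabilities.
#'
#' @param model a `frame_classifier`.
#' @param dir directory to create/read.
#' @return `save_model` returns `dir` invisibly; `load_model` returns the
#'   `frame_classifier`.
#' @export
save_model <- function(model, dir) {
  if (!inherits(model, "frame_classifier")) stop_invalid("not a frame_classifier")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(lags = model$lags, input_hw = model$input_hw,
               filters = model$filters, input_pool = model$input_pool,
               norm_center = model$norm$center,
               norm_halfrange = model$norm$halfrange,
               n_pos_train = model$n_pos_train,
               n_neg_train = model$n_neg_train)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"), digits = NA)
  theta <- flatten_params(model$net)
  writeLines(sprintf("%.17g", theta), file.path(dir, "weights.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mf <- file.path(dir, "metadata.json")
  wf <- file.path(dir, "weights.txt")
  if (!file.exists(mf) || !file.exists(wf))
    stop_invalid(sprintf("'%s' is not a model directory", dir))
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  in_channels <- length(meta$lags) + 1L
  net <- cnn_init(in_channels, as.integer(meta$filters), seed = 0L)
  theta <- as.numeric(readLines(wf))
  if (length(theta) != length(flatten_params(net)))
    stop_invalid("weights file does not match the declared architecture")
  net <- unflatten_params(net, theta)
  structure(list(net = net,
                 norm = list(center = meta$norm_center,
                             halfrange = meta$norm_halfrange),
                 lags = as.integer(meta$lags),
                 input_pool = as.integer(meta$input_pool),
                 input_hw = as.integer(meta$input_hw),
                 filters = as.integer(meta$filters),
                 n_pos_train = meta$n_pos_train,
                 n_neg_train = meta$n_neg_train,
                 config = NULL),
            class = "frame_classifier")
}
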
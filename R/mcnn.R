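#' Architecture of the dual-branch convolutional network
#'
#' The image branch applies three parallel same-padded convolutions (1x1, 3x3
#' and 5x5, Inception-style — small filter sizes because the input is only
#' 16x16 pixels) to the raw 6-band patch, concatenates them, then batch
#' normalization, 2x2 max pooling and two further 3x3 convolutions with a
#' second pooling. The temperature branch runs two 1-D convolutions (kernel
#' 3) over the 15-value window followed by a global max over positions. Both
#' branches flatten into one fully connected feature layer of `fc_width`
#' units (ReLU) and a softmax output. The post-activation feature layer is
#' what [extract_features()] returns and what the downstream SVM consumes.
#'
#' @param fc_width Width of the fused fully connected feature layer
#'   (default 512).
#' @param n_classes Number of output classes (2: habitat / non-habitat).
#' @param input_image Image input shape `c(rows, cols, bands)`.
#' @param input_temp Temperature window length (default 15).
#' @param inception_filters Filters per parallel first-stage convolution.
#' @param inception_kernels Kernel sizes of the parallel convolutions.
#' @param conv_filters Filters in each of the two later 3x3 convolutions.
#' @param temp_filters Filters per 1-D convolution in the temperature branch.
#' @param temp_kernel 1-D kernel size.
#' @param include_temp Keep the temperature branch? `FALSE` gives the
#'   image-only network used as an ablation baseline.
#' @return An `mcnn_config` object.
#' @export
mcnn_config <- function(fc_width = 512L, n_classes = 2L,
                        input_image = c(16L, 16L, 6L), input_temp = 15L,
                        inception_filters = c(32L, 32L, 32L),
                        inception_kernels = c(1L, 3L, 5L),
                        conv_filters = 64L,
                        temp_filters = 16L, temp_kernel = 3L,
                        include_temp = TRUE) {
  fc_width <- assert_count(fc_width, "fc_width", min = 1L)
  n_classes <- assert_count(n_classes, "n_classes", min = 2L)
  if (length(input_image) != 3L || any(input_image < 1)) {
    abort("`input_image` must be c(rows, cols, bands).",
          class = "habsuit_config_error")
  }
  if (length(inception_filters) != length(inception_kernels)) {
    abort("`inception_filters` and `inception_kernels` must have equal length.",
          class = "habsuit_config_error")
  }
  structure(list(fc_width = fc_width, n_classes = n_classes,
                 input_image = as.integer(input_image),
                 input_temp = as.integer(input_temp),
                 inception_filters = as.integer(inception_filters),
                 inception_kernels = as.integer(inception_kernels),
                 conv_filters = as.integer(conv_filters),
                 temp_filters = as.integer(temp_filters),
                 temp_kernel = as.integer(temp_kernel),
                 include_temp = isTRUE(include_temp)),
            class = "mcnn_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum number of epochs.
#' @param seed Seed controlling initialization order, shuffling and batching.
#' @param early_stop_patience Stop after this many epochs without validation
#'   accuracy improvement (ignored when no validation split is present).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         epochs = 20L, seed = 1L, early_stop_patience = 5L) {
  assert_positive(learning_rate, "learning_rate")
  batch_size <- assert_count(batch_size, "batch_size", min = 1L)
  epochs <- assert_count(epochs, "epochs", min = 0L)
  seed <- assert_count(seed, "seed")
  early_stop_patience <- assert_count(early_stop_patience,
                                      "early_stop_patience", min = 1L)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, seed = seed,
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

#' Assemble the network
#'
#' Builds the dual-branch network from its configuration. Weights are drawn
#' by normalized (Glorot) initialization — uniform with limits balanced by
#' fan-in and fan-out — under `seed`, so the same seed gives identical
#' initial weights.
#'
#' @param cfg An [mcnn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `mcnn_model` object; `glance()` reports the parameter count.
#' @export
build_mcnn <- function(cfg = mcnn_config(), seed = 1L) {
  stopifnot(inherits(cfg, "mcnn_config"))
  ii <- cfg$input_image
  with_seed(seed, {
    branches <- list()
    shapes <- list()
    for (i in seq_along(cfg$inception_filters)) {
      k <- cfg$inception_kernels[i]
      f <- cfg$inception_filters[i]
      branches[[i]] <- list(layer_conv2d(ii, f, c(k, k), "same"),
                            layer_relu(c(ii[1], ii[2], f)))
      shapes[[i]] <- c(ii[1], ii[2], f)
    }
    par <- layer_parallel(branches, shapes)
    cat_ch <- sum(cfg$inception_filters)
    s1 <- c(ii[1], ii[2], cat_ch)
    s2 <- c(ii[1] %/% 2L, ii[2] %/% 2L, cat_ch)
    s3 <- c(s2[1], s2[2], cfg$conv_filters)
    s4 <- c(s2[1] %/% 2L, s2[2] %/% 2L, cfg$conv_filters)
    image_chain <- list(
      par,
      layer_batchnorm(s1),
      layer_maxpool2(s1),
      layer_conv2d(s2, cfg$conv_filters, c(3L, 3L), "same"),
      layer_relu(s3),
      layer_batchnorm(s3),
      layer_conv2d(s3, cfg$conv_filters, c(3L, 3L), "same"),
      layer_relu(s3),
      layer_maxpool2(s3)
    )
    img_flat <- prod(s4)

    temp_chain <- NULL
    temp_flat <- 0L
    if (cfg$include_temp) {
      l1 <- cfg$input_temp - cfg$temp_kernel + 1L
      l2 <- l1 - cfg$temp_kernel + 1L
      temp_chain <- list(
        layer_conv1d(cfg$input_temp, 1L, cfg$temp_filters, cfg$temp_kernel),
        layer_relu(c(l1, 1L, cfg$temp_filters)),
        layer_conv1d(l1, cfg$temp_filters, cfg$temp_filters, cfg$temp_kernel),
        layer_relu(c(l2, 1L, cfg$temp_filters)),
        layer_global_maxpool1d(l2, cfg$temp_filters)
      )
      temp_flat <- cfg$temp_filters
    }
    head_chain <- list(layer_fc(img_flat + temp_flat, cfg$fc_width),
                       layer_relu(cfg$fc_width))
    out_layer <- layer_fc(cfg$fc_width, cfg$n_classes)

    model <- structure(
      list(cfg = cfg, image_chain = image_chain, temp_chain = temp_chain,
           head_chain = head_chain, out_layer = out_layer,
           img_flat = img_flat, temp_flat = temp_flat,
           classes = c("negative", "positive"), norm = NULL,
           history = tibble(epoch = integer(), loss = double(),
                            val_accuracy = double()),
           init_seed = seed),
      class = "mcnn_model")
    model$n_parameters <- n_params(model_param_layers(model))
    model
  })
}

model_param_layers <- function(model) {
  chains <- if (!is.null(model$chain)) {
    list(model$chain, list(model$out_layer))
  } else {
    c(list(model$image_chain, model$head_chain, list(model$out_layer)),
      if (!is.null(model$temp_chain)) list(model$temp_chain))
  }
  unlist(lapply(chains, collect_param_layers), recursive = FALSE)
}

#' @export
print.mcnn_model <- function(x, ...) {
  cat("<mcnn_model>", if (is.null(x$temp_chain)) "image-only" else "dual-branch",
      "| fc width", x$cfg$fc_width, "|", x$n_parameters, "parameters |",
      nrow(x$history), "epochs trained\n")
  invisible(x)
}

# stack a patch tibble into input matrices (image: (H*W*C) x N, temp: 15 x N)
samples_to_matrices <- function(samples, cfg, need_temp = TRUE) {
  n <- nrow(samples)
  Ximg <- vapply(samples$pixels, function(p) as.double(p),
                 double(prod(cfg$input_image)))
  dim(Ximg) <- c(prod(cfg$input_image), n)
  Xtemp <- NULL
  if (need_temp) {
    if (is.null(samples[["temp_window"]])) {
      abort("samples carry no `temp_window`; attach temperatures or use an image-only model.",
            class = "habsuit_parameter_error")
    }
    Xtemp <- vapply(samples$temp_window, function(tw) as.double(tw),
                    double(cfg$input_temp))
    dim(Xtemp) <- c(cfg$input_temp, n)
  }
  list(img = Ximg, temp = Xtemp)
}

# per-band standardization statistics from the training split
compute_norm <- function(Ximg, Xtemp, image_shape) {
  hw <- image_shape[1] * image_shape[2]
  nb <- image_shape[3]
  n <- ncol(Ximg)
  Xm <- matrix(Ximg, hw, nb * n)
  cs <- .colSums(Xm, hw, nb * n)
  csq <- .colSums(Xm^2, hw, nb * n)
  m <- hw * n
  mu <- .rowSums(matrix(cs, nb, n), nb, n) / m
  v <- .rowSums(matrix(csq, nb, n), nb, n) / m - mu^2
  band_sd <- sqrt(pmax(v, 1e-12))
  norm <- list(band_mean = mu, band_sd = band_sd, hw = hw)
  if (!is.null(Xtemp)) {
    norm$temp_mean <- mean(Xtemp)
    norm$temp_sd <- max(sd(as.vector(Xtemp)), 1e-12)
  }
  norm
}

apply_norm <- function(X, norm, what = c("img", "temp")) {
  what <- match.arg(what)
  if (is.null(norm)) return(X)
  if (what == "img") {
    (X - rep(norm$band_mean, each = norm$hw)) / rep(norm$band_sd, each = norm$hw)
  } else {
    (X - norm$temp_mean) / norm$temp_sd
  }
}

forward_model <- function(model, Ximg, Xtemp, training = FALSE) {
  if (!is.null(model$chain)) {
    feat <- chain_fwd(model$chain, Ximg, training)
    return(list(features = feat, logits = model$out_layer$fwd(feat, training)))
  }
  zi <- chain_fwd(model$image_chain, Ximg, training)
  z <- if (!is.null(model$temp_chain)) {
    rbind(zi, chain_fwd(model$temp_chain, Xtemp, training))
  } else {
    zi
  }
  feat <- chain_fwd(model$head_chain, z, training)
  logits <- model$out_layer$fwd(feat, training)
  list(features = feat, logits = logits)
}

backward_model <- function(model, dlogits) {
  dfeat <- model$out_layer$bwd(dlogits)
  if (!is.null(model$chain)) {
    chain_bwd(model$chain, dfeat)
    return(invisible(NULL))
  }
  dz <- chain_bwd(model$head_chain, dfeat)
  if (!is.null(model$temp_chain)) {
    chain_bwd(model$temp_chain,
              dz[(model$img_flat + 1L):nrow(dz), , drop = FALSE])
    dz <- dz[seq_len(model$img_flat), , drop = FALSE]
  }
  chain_bwd(model$image_chain, dz)
  invisible(NULL)
}

#' Train the network
#'
#' Minimizes softmax cross-entropy with Adam on the `"train"` split of
#' `samples`, recording per-epoch loss and validation accuracy (on the
#' `"val"` split, when present) and early-stopping on validation accuracy.
#' Input pixels are standardized per band, and the temperature window
#' globally, using training-split statistics stored on the model. Training is
#' deterministic given the seed (single-threaded numerics assumed).
#'
#' @param model An [build_mcnn()] model.
#' @param samples A labelled patch tibble with a `split` column (see
#'   [split_samples()]); rows with `split == "train"` are used for gradient
#'   steps, `"val"` for validation.
#' @param cfg A [train_config()].
#' @return The trained model; `tidy()` returns the epoch history.
#' @export
train_mcnn <- function(model, samples, cfg = train_config()) {
  stopifnot(inherits(model, "mcnn_model"), inherits(cfg, "train_config"))
  train <- samples[samples$split == "train", , drop = FALSE]
  if (nrow(train) == 0L) {
    abort("no training samples (split == 'train').",
          class = "habsuit_parameter_error")
  }
  if (length(unique(train$label)) < 2L) {
    abort("training split contains a single class; both classes are required.",
          class = "habsuit_parameter_error")
  }
  val <- samples[samples$split == "val", , drop = FALSE]
  need_temp <- !is.null(model$temp_chain)
  tr <- samples_to_matrices(train, model$cfg, need_temp)
  model$norm <- compute_norm(tr$img, tr$temp, model$cfg$input_image)
  Ximg <- apply_norm(tr$img, model$norm, "img")
  Xtemp <- if (need_temp) apply_norm(tr$temp, model$norm, "temp") else NULL
  y <- match(train$label, model$classes)

  Vimg <- NULL; Vtemp <- NULL; yv <- NULL
  if (nrow(val) > 0L) {
    va <- samples_to_matrices(val, model$cfg, need_temp)
    Vimg <- apply_norm(va$img, model$norm, "img")
    Vtemp <- if (need_temp) apply_norm(va$temp, model$norm, "temp") else NULL
    yv <- match(val$label, model$classes)
  }

  if (cfg$epochs == 0L) return(model)

  layers <- model_param_layers(model)
  n <- ncol(Ximg)
  history <- vector("list", cfg$epochs)
  best_acc <- -Inf
  best_snap <- NULL
  stall <- 0L
  step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- double()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        out <- forward_model(model, Ximg[, idx, drop = FALSE],
                             if (need_temp) Xtemp[, idx, drop = FALSE],
                             training = TRUE)
        ce <- softmax_ce(out$logits, y[idx])
        losses <- c(losses, ce$loss)
        backward_model(model, ce$dlogits)
        step <- step + 1L
        adam_step(layers, cfg$learning_rate, step)
      }
      val_acc <- NA_real_
      if (!is.null(yv)) {
        pv <- predict_matrices(model, Vimg, Vtemp)
        val_acc <- mean(max.col(t(pv), ties.method = "first") == yv)
      }
      history[[ep]] <- tibble(epoch = ep, loss = mean(losses),
                              val_accuracy = val_acc)
      if (!is.null(yv)) {
        if (val_acc > best_acc + 1e-12) {
          best_acc <- val_acc
          best_snap <- snapshot_params(layers)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$early_stop_patience) break
        }
      }
    }
  })
  if (!is.null(best_snap)) restore_params(layers, best_snap)
  model$history <- bind_rows(history)
  model$train_cfg <- cfg
  model
}

# class probabilities (n_classes x N) in inference mode, batched
predict_matrices <- function(model, Ximg, Xtemp, batch = 256L) {
  n <- ncol(Ximg)
  out <- matrix(0, model$cfg$n_classes, n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- forward_model(model, Ximg[, idx, drop = FALSE],
                        if (!is.null(Xtemp)) Xtemp[, idx, drop = FALSE])
    out[, idx] <- softmax_probs(fw$logits)
  }
  out
}

#' Predict from a trained network
#'
#' @param object A trained `mcnn_model`.
#' @param samples A patch tibble.
#' @param type `"prob"` (tibble of per-class probabilities plus
#'   `prob_positive`), `"class"` (labels), or `"feature"` (the penultimate
#'   feature matrix, see [extract_features()]).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.mcnn_model <- function(object, samples, type = c("prob", "class", "feature"),
                               ...) {
  type <- match.arg(type)
  if (type == "feature") return(extract_features(object, samples))
  need_temp <- !is.null(object$temp_chain)
  mats <- samples_to_matrices(samples, object$cfg, need_temp)
  Ximg <- apply_norm(mats$img, object$norm, "img")
  Xtemp <- if (need_temp) apply_norm(mats$temp, object$norm, "temp") else NULL
  p <- predict_matrices(object, Ximg, Xtemp)
  if (type == "class") {
    return(object$classes[max.col(t(p), ties.method = "first")])
  }
  out <- as_tibble(setNames(as.data.frame(t(p)),
                            paste0("prob_", object$classes)))
  out$patch_id <- samples$patch_id
  out$prob_positive <- p[match("positive", object$classes), ]
  select(out, "patch_id", dplyr::everything())
}

#' Extract penultimate-layer features
#'
#' Returns the post-activation outputs of the fused fully connected feature
#' layer, one `fc_width`-dimensional vector per sample, in input order. A
#' pure function of the model weights and the input: identical samples give
#' identical vectors.
#'
#' @param model A trained `mcnn_model`.
#' @param samples A patch tibble.
#' @param batch Forward-pass batch size.
#' @return A tibble: `patch_id` plus `f001 ... f<fc_width>`.
#' @export
extract_features <- function(model, samples, batch = 256L) {
  stopifnot(inherits(model, "mcnn_model"))
  need_temp <- !is.null(model$temp_chain)
  mats <- samples_to_matrices(samples, model$cfg, need_temp)
  Ximg <- apply_norm(mats$img, model$norm, "img")
  Xtemp <- if (need_temp) apply_norm(mats$temp, model$norm, "temp") else NULL
  n <- ncol(Ximg)
  feat <- matrix(0, model$cfg$fc_width, n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- forward_model(model, Ximg[, idx, drop = FALSE],
                        if (need_temp) Xtemp[, idx, drop = FALSE])
    feat[, idx] <- fw$features
  }
  out <- as_tibble(setNames(as.data.frame(t(feat)),
                            sprintf("f%03d", seq_len(model$cfg$fc_width))))
  out$patch_id <- samples$patch_id
  select(out, "patch_id", dplyr::everything())
}

#' @describeIn train_mcnn Epoch history (`epoch`, `loss`, `val_accuracy`).
#' @param x A trained `mcnn_model`.
#' @param ... Unused.
#' @method tidy mcnn_model
#' @export
tidy.mcnn_model <- function(x, ...) x$history

#' @describeIn train_mcnn One-row model summary.
#' @method glance mcnn_model
#' @export
glance.mcnn_model <- function(x, ...) {
  tibble(n_parameters = x$n_parameters,
         fc_width = x$cfg$fc_width,
         dual_branch = !is.null(x$temp_chain),
         epochs_trained = nrow(x$history),
         best_val_accuracy = if (nrow(x$history) > 0L)
           suppressWarnings(max(x$history$val_accuracy, na.rm = TRUE))
         else NA_real_)
}

#' Save / load a model
#'
#' A single-file container (RDS) embedding the architecture configuration,
#' all weights and batch-normalization running statistics, the input
#' standardization parameters and the training history.
#'
#' @param model A `mcnn_model` (or `densenet_model`).
#' @param path File path.
#' @return `save_mcnn()`: `path`, invisibly; `load_mcnn()`: the model.
#' @export
save_mcnn <- function(model, path) {
  layers <- if (inherits(model, "densenet_model")) {
    collect_param_layers(model$chain)
  } else {
    model_param_layers(model)
  }
  saveRDS(list(kind = class(model)[1], cfg = model$cfg,
               init_seed = model$init_seed,
               weights = snapshot_params(layers), norm = model$norm,
               history = model$history), path)
  invisible(path)
}

#' @rdname save_mcnn
#' @export
load_mcnn <- function(path) {
  blob <- readRDS(path)
  model <- if (blob$kind == "densenet_model") {
    build_densenet(blob$cfg, seed = blob$init_seed)
  } else {
    build_mcnn(blob$cfg, seed = blob$init_seed)
  }
  layers <- if (blob$kind == "densenet_model") {
    collect_param_layers(model$chain)
  } else {
    model_param_layers(model)
  }
  restore_params(layers, blob$weights)
  model$norm <- blob$norm
  model$history <- blob$history
  model
}

#' 1-D convolution primitive (valid, ReLU)
#'
#' Cross-correlates the input sequence with the kernel over all input
#' channels and rectifies: `y[i,j] = max(sum_m sum_k w[k,m,j] x[i+k-1,m], 0)`.
#' No padding: output length is `len - k + 1`.
#'
#' @param x Numeric vector (single channel) or matrix `len x channels`.
#' @param weights Numeric vector of length `k` (single in/out channel) or
#'   array `k x in_channels x out_filters`.
#' @param bias Per-filter bias (default 0).
#' @return Matrix `(len - k + 1) x out_filters` (a vector when one filter).
#' @export
conv1d_forward <- function(x, weights, bias = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (is.null(dim(weights))) weights <- array(weights, c(length(weights), 1L, 1L))
  if (length(dim(weights)) == 2L) {
    weights <- array(weights, c(dim(weights), 1L))
  }
  k <- dim(weights)[1]; cin <- dim(weights)[2]; fout <- dim(weights)[3]
  if (ncol(x) != cin) {
    abort("channel mismatch between `x` and `weights`.",
          class = "habsuit_shape_error")
  }
  ly <- layer_conv1d(nrow(x), cin, fout, k)
  for (f in seq_len(fout)) ly$W[f, ] <- as.vector(weights[, , f])
  ly$b <- if (is.null(bias)) numeric(fout) else rep_len(bias, fout)
  out <- pmax(ly$fwd(matrix(as.double(x), ncol = 1L)), 0)
  out <- matrix(out, ncol = fout)
  if (fout == 1L) drop(out) else out
}

#' 2-D convolution primitive (ReLU)
#'
#' Channel-summed 2-D cross-correlation followed by rectification:
#' `y[i,j,f] = max(sum_m sum_{w,h} W[w,h,m,f] x[i+w-1, j+h-1, m], 0)`.
#'
#' @param x Numeric matrix `H x W` (single channel) or array `H x W x C`.
#' @param weights Matrix `kh x kw` (single in/out channel) or array
#'   `kh x kw x C x F`.
#' @param bias Per-filter bias (default 0).
#' @param padding `"valid"` (default) or `"same"`.
#' @return Array `Ho x Wo x F` (a matrix when one filter).
#' @export
conv2d_forward <- function(x, weights, bias = NULL,
                           padding = c("valid", "same")) {
  padding <- match.arg(padding)
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (length(dim(weights)) == 2L) weights <- array(weights, c(dim(weights), 1L, 1L))
  if (length(dim(weights)) == 3L) weights <- array(weights, c(dim(weights), 1L))
  dw <- dim(weights)
  if (dim(x)[3] != dw[3]) {
    abort("channel mismatch between `x` and `weights`.",
          class = "habsuit_shape_error")
  }
  ly <- layer_conv2d(dim(x), dw[4], dw[1:2], padding)
  for (f in seq_len(dw[4])) ly$W[f, ] <- as.vector(weights[, , , f])
  ly$b <- if (is.null(bias)) numeric(dw[4]) else rep_len(bias, dw[4])
  out <- pmax(ly$fwd(matrix(as.double(x), ncol = 1L)), 0)
  out <- array(out, ly$out_shape)
  if (dw[4] == 1L) out[, , 1L] else out
}
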
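#' Grey-level co-occurrence texture configuration
#'
#' Patches are min-max quantized to `gray_levels` intensity levels and, for
#' each of eight (distance, direction) offsets — distances 1 and 2 pixels at
#' 0, 45, 90 and 135 degrees — a normalized symmetric co-occurrence matrix is
#' built and summarized by per-matrix statistics. The default statistic set
#' has eight members (mean, correlation, contrast, energy, homogeneity,
#' maximal probability, entropy, dissimilarity), giving a 64-value
#' descriptor; `stats = "named6"` keeps only the first six (48 values).
#'
#' @param gray_levels Number of quantization levels (default 64).
#' @param stats `"full8"` (default) or `"named6"`.
#' @param band Which band of the patch to use (default 1).
#' @return A `glcm_config` object.
#' @export
glcm_config <- function(gray_levels = 64L, stats = c("full8", "named6"),
                        band = 1L) {
  gray_levels <- assert_count(gray_levels, "gray_levels", min = 2L)
  stats <- match.arg(stats)
  band <- assert_count(band, "band", min = 1L)
  structure(list(gray_levels = gray_levels, stats = stats, band = band,
                 offsets = glcm_offsets()),
            class = "glcm_config")
}

# (drow, dcol) offsets: distances {1, 2} x directions {0, 45, 90, 135} deg
glcm_offsets <- function() {
  dirs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))
  out <- list()
  for (d in c(1L, 2L)) {
    for (a in names(dirs)) {
      out[[sprintf("d%d_a%s", d, a)]] <- d * dirs[[a]]
    }
  }
  out
}

glcm_stat_names <- function(stats) {
  base <- c("mean", "correlation", "contrast", "energy", "homogeneity",
            "max_prob")
  if (stats == "full8") c(base, "entropy", "dissimilarity") else base
}

# min-max quantization to levels 0 .. G-1; a constant patch maps to level 0
quantize_gray <- function(x, gray_levels) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(matrix(0L, nrow(x), ncol(x)))
  }
  q <- floor((x - rng[1]) / (rng[2] - rng[1]) * gray_levels)
  matrix(pmin(as.integer(q), gray_levels - 1L), nrow(x), ncol(x))
}

#' Co-occurrence matrix of a quantized image at one offset
#'
#' Counts pairs `(q[i, j], q[i + dr, j + dc])`, symmetrizes (each pair also
#' counted in reverse) and normalizes to sum to 1.
#'
#' @param x Numeric matrix (raw values; quantized internally).
#' @param gray_levels Number of levels.
#' @param offset `c(drow, dcol)`.
#' @return A `gray_levels x gray_levels` matrix summing to 1.
#' @export
glcm_matrix <- function(x, gray_levels, offset) {
  q <- quantize_gray(x, gray_levels)
  H <- nrow(q); W <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  ri <- max(1L, 1L - dr):min(H, H - dr)
  ci <- max(1L, 1L - dc):min(W, W - dc)
  if (length(ri) == 0L || length(ci) == 0L) {
    abort("offset larger than the patch.", class = "habsuit_parameter_error")
  }
  a <- q[ri, ci, drop = FALSE]
  b <- q[ri + dr, ci + dc, drop = FALSE]
  counts <- tabulate(as.vector(a) * gray_levels + as.vector(b) + 1L,
                     nbins = gray_levels^2)
  M <- matrix(counts, gray_levels, gray_levels, byrow = TRUE)
  M <- M + t(M)
  M / sum(M)
}

glcm_matrix_stats <- function(P, which_stats) {
  G <- nrow(P)
  v <- 0:(G - 1)
  px <- rowSums(P)
  mu <- sum(v * px)
  sigma2 <- sum((v - mu)^2 * px)
  dif <- outer(v, v, "-")
  vals <- c(
    mean = mu,
    correlation = if (sigma2 > 0) (sum(outer(v, v) * P) - mu^2) / sigma2 else 0,
    contrast = sum(dif^2 * P),
    energy = sum(P^2),
    homogeneity = sum(P / (1 + dif^2)),
    max_prob = max(P),
    entropy = -sum(P[P > 0] * log(P[P > 0])),
    dissimilarity = sum(abs(dif) * P)
  )
  vals[which_stats]
}

#' Texture descriptor of a single patch band
#'
#' @param x Numeric matrix, one band of a patch.
#' @param cfg A [glcm_config()].
#' @return Named numeric vector, `length(offsets) * length(stats)` values in
#'   fixed order: offsets `d1_a0, d1_a45, d1_a90, d1_a135, d2_a0, ...`, each
#'   contributing its statistics in the order of [glcm_config()].
#' @export
glcm_features <- function(x, cfg = glcm_config()) {
  stopifnot(is.matrix(x))
  sn <- glcm_stat_names(cfg$stats)
  out <- lapply(names(cfg$offsets), function(on) {
    s <- glcm_matrix_stats(glcm_matrix(x, cfg$gray_levels, cfg$offsets[[on]]),
                           sn)
    names(s) <- paste(on, sn, sep = "_")
    s
  })
  unlist(out)
}

#' Texture descriptors for a patch table
#'
#' @param samples A patch tibble (list-column `pixels`).
#' @param cfg A [glcm_config()]; `cfg$band` selects the band.
#' @return A tibble: `patch_id` plus one column per descriptor value.
#' @export
glcm_feature_table <- function(samples, cfg = glcm_config()) {
  feats <- vapply(samples$pixels,
                  function(px) glcm_features(px[, , cfg$band], cfg),
                  glcm_features(samples$pixels[[1]][, , cfg$band], cfg))
  out <- as_tibble(t(feats))
  out$patch_id <- samples$patch_id
  select(out, "patch_id", dplyr::everything())
}

#' Simplified DenseNet configuration
#'
#' A three-dense-block DenseNet for 16x16 input: a 7x7/48 stem convolution
#' (stride 1, same padding), 2x2 max pool, dense blocks of 6, 12 and 16
#' bottleneck units (1x1 then 3x3) joined by transition layers (1x1
#' convolution with compression 0.5 + 2x2 average pool), and a global
#' average pool classification head. Spatial sizes run
#' 16 -> 8 -> 8 -> 4 -> 4 -> 2 -> 1.
#'
#' @param growth_rate Channels added by each dense unit (default 12).
#' @param block_sizes Units per dense block.
#' @param stem_filters Stem convolution filters (48).
#' @param compression Transition-layer channel compression factor.
#' @param input_image Input shape; must tile to the stated spatial sizes.
#' @param n_classes Output classes.
#' @return A `densenet_config`.
#' @export
densenet_config <- function(growth_rate = 12L, block_sizes = c(6L, 12L, 16L),
                            stem_filters = 48L, compression = 0.5,
                            input_image = c(16L, 16L, 6L), n_classes = 2L) {
  growth_rate <- assert_count(growth_rate, "growth_rate", min = 1L)
  stem_filters <- assert_count(stem_filters, "stem_filters", min = 1L)
  assert_fraction(compression, "compression")
  if (length(block_sizes) != 3L) {
    abort("`block_sizes` must list three dense blocks.",
          class = "habsuit_config_error")
  }
  if (input_image[1] != input_image[2] || input_image[1] %% 8L != 0L) {
    abort("`input_image` must be square with side divisible by 8.",
          class = "habsuit_config_error")
  }
  structure(list(growth_rate = growth_rate,
                 block_sizes = as.integer(block_sizes),
                 stem_filters = stem_filters, compression = compression,
                 input_image = as.integer(input_image),
                 n_classes = assert_count(n_classes, "n_classes", min = 2L)),
            class = "densenet_config")
}

#' Assemble the DenseNet baseline
#'
#' @param cfg A [densenet_config()].
#' @param seed Weight-initialization seed.
#' @return A `densenet_model` (shares the training/prediction interface of
#'   [build_mcnn()] models); [densenet_shapes()] lists its per-stage spatial
#'   sizes.
#' @export
build_densenet <- function(cfg = densenet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "densenet_config"))
  ii <- cfg$input_image
  g <- cfg$growth_rate
  bott <- 4L * g
  with_seed(seed, {
    chain <- list()
    stages <- list()
    add <- function(layer, stage) {
      chain[[length(chain) + 1L]] <<- layer
      stages[[length(stages) + 1L]] <<- c(stage,
                                          layer$out_shape[1],
                                          layer$out_shape[2] %||% 1L)
    }
    s <- c(ii[1], ii[2], cfg$stem_filters)
    add(layer_conv2d(ii, cfg$stem_filters, c(7L, 7L), "same"), "stem_conv")
    add(layer_relu(s), "stem_relu")
    add(layer_maxpool2(s), "stem_pool")
    s <- c(s[1] %/% 2L, s[2] %/% 2L, cfg$stem_filters)
    for (bl in seq_along(cfg$block_sizes)) {
      nb <- cfg$block_sizes[bl]
      add(layer_dense_block(s, nb, g, bott), sprintf("dense_block_%d", bl))
      s[3] <- s[3] + nb * g
      if (bl < length(cfg$block_sizes)) {
        out_ch <- max(1L, floor(s[3] * cfg$compression))
        add(layer_batchnorm(s), sprintf("transition_%d_bn", bl))
        add(layer_relu(s), sprintf("transition_%d_relu", bl))
        add(layer_conv2d(s, out_ch, c(1L, 1L), "same"),
            sprintf("transition_%d_conv", bl))
        s[3] <- out_ch
        add(layer_avgpool2(s), sprintf("transition_%d_pool", bl))
        s[1] <- s[1] %/% 2L; s[2] <- s[2] %/% 2L
      }
    }
    add(layer_batchnorm(s), "head_bn")
    add(layer_relu(s), "head_relu")
    add(layer_global_avgpool(s), "global_avg_pool")
    out_layer <- layer_fc(s[3], cfg$n_classes)

    cfg$fc_width <- s[3]
    cfg$input_temp <- 0L
    shape_tbl <- bind_rows(lapply(stages, function(x) {
      tibble(stage = x[1], height = as.integer(x[2]), width = as.integer(x[3]))
    }))
    model <- structure(
      list(cfg = cfg, chain = chain, temp_chain = NULL, out_layer = out_layer,
           classes = c("negative", "positive"), norm = NULL,
           shapes = shape_tbl,
           history = tibble(epoch = integer(), loss = double(),
                            val_accuracy = double()),
           init_seed = seed),
      class = c("densenet_model", "mcnn_model"))
    model$n_parameters <- n_params(model_param_layers(model))
    model
  })
}

#' @export
print.densenet_model <- function(x, ...) {
  cat("<densenet_model> 3 dense blocks (", paste(x$cfg$block_sizes,
                                                 collapse = ", "),
      "units ), growth", x$cfg$growth_rate, "|", x$n_parameters,
      "parameters\n")
  invisible(x)
}

#' Per-stage spatial sizes of a DenseNet
#'
#' @param model A `densenet_model`.
#' @return A tibble `stage`, `height`, `width` — the forward-pass spatial
#'   size after every stage, for conformance checks against the designed
#'   16 -> 8 -> 8 -> 4 -> 4 -> 2 -> 1 progression.
#' @export
densenet_shapes <- function(model) {
  stopifnot(inherits(model, "densenet_model"))
  model$shapes
}

#' Run a baseline (or the full model) on a prepared sample set
#'
#' All methods consume the identical labelled, split patch tibble, so
#' comparisons are like-for-like:
#' \describe{
#'   \item{`glcm_svm`}{RBF-SVM on 64-value co-occurrence texture descriptors.}
#'   \item{`densenet`}{The simplified three-block DenseNet (image only).}
#'   \item{`cnn`}{The image branch + FC head with the temperature branch
#'     removed.}
#'   \item{`cnn_svm`}{As `cnn`, plus an SVM on its features.}
#'   \item{`mcnn`}{The dual-branch network, softmax output.}
#'   \item{`mcnn_svm`}{Dual-branch features + RBF-SVM.}
#' }
#' Networks train on the `"train"` split with validation-based early
#' stopping; SVM stages train on the `"val"` split features (the training
#' split standing in when no validation split exists); all methods are
#' evaluated on the `"test"` split.
#'
#' @param samples Labelled patch tibble with `split` assigned.
#' @param method One of the method names above.
#' @param train_cfg A [train_config()] shared by all network methods.
#' @param svm_cfg An [svm_config()] for SVM stages.
#' @param glcm_cfg A [glcm_config()] for the texture baseline.
#' @param seed Weight-initialization seed for the networks.
#' @return An `eval_report` on the test split, with the fitted model(s) in
#'   attribute `"models"` and the scored test tibble in `"scores"`.
#' @export
run_baseline <- function(samples,
                         method = c("mcnn_svm", "mcnn", "cnn", "cnn_svm",
                                    "glcm_svm", "densenet"),
                         train_cfg = train_config(),
                         svm_cfg = svm_config(),
                         glcm_cfg = glcm_config(),
                         seed = 1L) {
  method <- match.arg(method)
  test <- samples[samples$split == "test", , drop = FALSE]
  if (nrow(test) == 0L) {
    abort("no test samples (split == 'test').",
          class = "habsuit_parameter_error")
  }
  val <- samples[samples$split == "val", , drop = FALSE]
  train <- samples[samples$split == "train", , drop = FALSE]
  svm_train <- if (nrow(val) > 0L) val else train

  models <- list()
  if (method == "glcm_svm") {
    ft_train <- glcm_feature_table(bind_rows(train, val), glcm_cfg)
    fit <- train_svm(ft_train, bind_rows(train, val)$label, svm_cfg)
    scores <- predict(fit, glcm_feature_table(test, glcm_cfg), type = "prob")
    models$svm <- fit
  } else {
    net <- switch(method,
      densenet = build_densenet(seed = seed),
      cnn = ,
      cnn_svm = build_mcnn(mcnn_config(include_temp = FALSE), seed = seed),
      mcnn = ,
      mcnn_svm = build_mcnn(mcnn_config(), seed = seed)
    )
    net <- train_mcnn(net, samples, train_cfg)
    models$network <- net
    if (method %in% c("cnn_svm", "mcnn_svm")) {
      fit <- train_svm(extract_features(net, svm_train), svm_train$label,
                       svm_cfg)
      scores <- predict(fit, extract_features(net, test), type = "prob")
      models$svm <- fit
    } else {
      scores <- predict(net, test, type = "prob")$prob_positive
    }
  }
  report <- evaluate(scores, test$label)
  attr(report, "models") <- models
  attr(report, "scores") <- tibble(patch_id = test$patch_id,
                                   label = test$label, score = scores)
  attr(report, "method") <- method
  report
}
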
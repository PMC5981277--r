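#' RBF-SVM configuration
#'
#' @param C Soft-margin cost, > 0.
#' @param gamma Kernel width: a positive number, or `"scale"` (default) for
#'   `1 / (n_features * var(x))`.
#' @param probability Fit a probability model (Platt scaling via internal
#'   cross-validation) so calibrated probabilities are available.
#' @param seed Seed for the probability-calibration resampling.
#' @return An `svm_config` object.
#' @export
svm_config <- function(C = 1, gamma = "scale", probability = TRUE, seed = 1L) {
  assert_positive(C, "C")
  if (is.numeric(gamma)) {
    assert_positive(gamma, "gamma")
  } else if (!identical(gamma, "scale")) {
    abort('`gamma` must be a positive number or "scale".',
          class = "habsuit_parameter_error")
  }
  seed <- assert_count(seed, "seed")
  structure(list(C = C, gamma = gamma, probability = isTRUE(probability),
                 seed = seed),
            class = "svm_config")
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    as.matrix(features[, setdiff(names(features), "patch_id"), drop = FALSE])
  } else {
    as.matrix(features)
  }
}

#' Train an RBF-SVM on extracted features
#'
#' Fits a radial-basis-function support vector machine on network features
#' (or any numeric feature table). With `tune = TRUE` and a validation set, a
#' small grid over `C` in {0.1, 1, 10} and `gamma` in {scale, 0.01, 0.001} is
#' searched and the model with the best validation accuracy kept.
#'
#' @param features Feature tibble from [extract_features()] (a `patch_id`
#'   column is ignored) or a numeric matrix, one row per sample.
#' @param labels Character/factor labels (`"positive"` / `"negative"`).
#' @param cfg An [svm_config()].
#' @param tune Grid-search hyperparameters on the validation set?
#' @param val_features,val_labels Validation set for tuning.
#' @return An `svm_fit` object (the e1071 fit plus metadata).
#' @export
train_svm <- function(features, labels, cfg = svm_config(), tune = FALSE,
                      val_features = NULL, val_labels = NULL) {
  x <- feature_matrix(features)
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  if (length(unique(y[!is.na(y)])) < 2L) {
    abort("both classes must be present to train the SVM.",
          class = "habsuit_parameter_error")
  }
  grid <- if (tune && !is.null(val_features)) {
    tidyr::expand_grid(C = c(0.1, 1, 10),
                       gamma = list("scale", 0.01, 0.001))
  } else {
    tibble(C = cfg$C, gamma = list(cfg$gamma))
  }
  best <- NULL
  best_acc <- -Inf
  for (i in seq_len(nrow(grid))) {
    g <- grid$gamma[[i]]
    g_num <- if (identical(g, "scale")) 1 / (ncol(x) * max(var(as.vector(x)), 1e-12)) else g
    set.seed(cfg$seed)
    fit <- e1071::svm(x = x, y = y, kernel = "radial", cost = grid$C[i],
                      gamma = g_num, probability = cfg$probability,
                      scale = FALSE)
    acc <- if (tune && !is.null(val_features)) {
      vx <- feature_matrix(val_features)
      vy <- factor(as.character(val_labels), levels = c("negative", "positive"))
      mean(predict(fit, vx) == vy)
    } else 0
    if (is.null(best) || acc > best_acc) {
      best_acc <- acc
      best <- list(fit = fit, C = grid$C[i], gamma = g, gamma_num = g_num)
    }
  }
  structure(list(fit = best$fit, C = best$C, gamma = best$gamma,
                 gamma_num = best$gamma_num, cfg = cfg,
                 classes = c("negative", "positive"),
                 val_accuracy = if (tune && !is.null(val_features)) best_acc else NA_real_),
            class = "svm_fit")
}

#' @export
print.svm_fit <- function(x, ...) {
  cat("<svm_fit> RBF-SVM, C =", x$C, ", gamma =",
      if (identical(x$gamma, "scale")) sprintf("scale (%.3g)", x$gamma_num)
      else x$gamma, ",", x$fit$tot.nSV, "support vectors\n")
  invisible(x)
}

#' Predict with a fitted SVM
#'
#' @param object An `svm_fit`.
#' @param features Feature tibble or matrix.
#' @param type `"prob"` (probability of the positive class) or `"class"`.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or character labels.
#' @export
predict.svm_fit <- function(object, features, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- feature_matrix(features)
  if (type == "class") {
    return(as.character(predict(object$fit, x)))
  }
  if (!object$cfg$probability) {
    abort("SVM was fitted without probability outputs.",
          class = "habsuit_parameter_error")
  }
  pr <- predict(object$fit, x, probability = TRUE)
  attr(pr, "probabilities")[, "positive"]
}

#' Classification metrics from scores and labels
#'
#' Thresholds `scores` at `threshold` for the confusion matrix and computes
#' accuracy, precision, recall and F1 by their closed forms; AUC is the
#' rank statistic over the scores (Mann-Whitney, average ranks for ties), so
#' it is invariant under strictly monotone transforms. With one-class labels
#' the AUC is reported as `NA` and the threshold metrics still computed.
#'
#' @param scores Numeric scores (probability of the positive class).
#' @param labels `"positive"` / `"negative"` (character or factor).
#' @param threshold Decision threshold (default 0.5; `score >= threshold` is
#'   called positive).
#' @return An `eval_report`: confusion counts and metrics; `tidy()` gives a
#'   metric/value tibble, `glance()` a one-row summary.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.",
          class = "habsuit_parameter_error")
  }
  truth <- labels == "positive"
  pred <- scores >= threshold
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  n <- length(scores)
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  npos <- sum(truth); nneg <- n - npos
  auc <- if (npos > 0 && nneg > 0) {
    r <- rank(scores)
    (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
  } else NA_real_
  confusion <- matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(truth = c("positive", "negative"),
                                      predicted = c("positive", "negative")))
  structure(list(confusion = confusion, accuracy = accuracy,
                 precision = precision, recall = recall, f1 = f1, auc = auc,
                 n = n, threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  print(x$confusion)
  cat(sprintf("accuracy %.4f | precision %s | recall %s | F1 %s | AUC %s\n",
              x$accuracy, fmt_or_na(x$precision), fmt_or_na(x$recall),
              fmt_or_na(x$f1), fmt_or_na(x$auc)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' @describeIn evaluate Long metric/value tibble.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(metric = c("accuracy", "f1", "auc", "precision", "recall"),
         value = c(x$accuracy, x$f1, x$auc, x$precision, x$recall))
}

#' @describeIn evaluate One-row summary including counts.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, f1 = x$f1, auc = x$auc,
         precision = x$precision, recall = x$recall, n = x$n,
         tp = x$confusion[1, 1], fn = x$confusion[1, 2],
         fp = x$confusion[2, 1], tn = x$confusion[2, 2])
}

suitability_levels <- c("very low", "low", "moderate", "high", "very high")

# five equal-width probability bins [0,0.2), ..., [0.8,1]
quantize_suitability <- function(p) {
  pmin(pmax(floor(p * 5) + 1L, 1L), 5L)
}

#' Score a scene into a habitat-suitability map
#'
#' Tiles the scene into patches, scores each patch with the trained network
#' (and, when supplied, the SVM on its features), and quantizes the per-patch
#' probability of presence into five equal-width ordinal classes from
#' "very low" (`[0, 0.2)`) to "very high" (`[0.8, 1]`).
#'
#' @param scene A [raster_scene()].
#' @param model A trained `mcnn_model`.
#' @param svm An optional `svm_fit` applied to the model's features; when
#'   `NULL` the network's softmax probability is used directly.
#' @param temps Temperature table (required for a dual-branch model unless
#'   `image_only_fallback`).
#' @param image_only_fallback If temperatures are unavailable, score with an
#'   image-only model passed here instead of failing.
#' @return A `suitability_map`: probability and ordinal class grids over the
#'   patch tiling, georeferenced by the patch-level geotransform.
#' @export
predict_map <- function(scene, model, svm = NULL, temps = NULL,
                        image_only_fallback = NULL) {
  stopifnot(inherits(scene, "raster_scene"))
  patches <- extract_patches(scene)
  need_temp <- !is.null(model$temp_chain)
  if (need_temp) {
    if (is.null(temps)) {
      if (is.null(image_only_fallback)) {
        abort(paste("the model requires a temperature window but `temps` is",
                    "missing; supply temperatures or an `image_only_fallback`",
                    "model."), class = "habsuit_parameter_error")
      }
      model <- image_only_fallback
      need_temp <- FALSE
    } else {
      patches <- attach_temperature(patches, temps, scene)
      if (nrow(patches) == 0L) {
        abort("no temperature data in the scene window; cannot score patches.",
              class = "habsuit_parameter_error")
      }
    }
  }
  prob <- if (!is.null(svm)) {
    predict(svm, extract_features(model, patches), type = "prob")
  } else {
    predict(model, patches, type = "prob")$prob_positive
  }
  d <- dim(scene$bands)
  n_r <- d[1] %/% 16L; n_c <- d[2] %/% 16L
  pg <- matrix(NA_real_, n_r, n_c)
  pg[cbind(patches$row + 1L, patches$col + 1L)] <- prob
  cg <- matrix(NA_integer_, n_r, n_c)
  cg[] <- ifelse(is.na(pg), NA_integer_, quantize_suitability(pg))
  gt <- scene$geotransform
  patch_gt <- c(gt[1], gt[2] * 16, 0, gt[4], 0, gt[6] * 16)
  structure(list(scene_id = scene$scene_id, prob = pg, class_idx = cg,
                 class_levels = suitability_levels,
                 geotransform = patch_gt, acquired = scene$acquired),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat("<suitability_map>", x$scene_id, ":", nrow(x$prob), "x", ncol(x$prob),
      "patches\n")
  tab <- table(factor(x$class_levels[x$class_idx],
                      levels = x$class_levels))
  print(tab)
  invisible(x)
}

#' @describeIn predict_map One row per patch cell (`row`, `col`, `prob`,
#'   `class`).
#' @param x A `suitability_map`.
#' @param ... Unused.
#' @method tidy suitability_map
#' @export
tidy.suitability_map <- function(x, ...) {
  grid <- tidyr::expand_grid(row = seq_len(nrow(x$prob)) - 1L,
                             col = seq_len(ncol(x$prob)) - 1L)
  grid$prob <- x$prob[cbind(grid$row + 1L, grid$col + 1L)]
  grid$class <- factor(x$class_levels[x$class_idx[cbind(grid$row + 1L,
                                                        grid$col + 1L)]],
                       levels = x$class_levels)
  grid
}

#' Plot a suitability map
#'
#' @param object A `suitability_map`.
#' @param what `"class"` (ordinal legend) or `"prob"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot suitability_map
#' @export
autoplot.suitability_map <- function(object, what = c("class", "prob"), ...) {
  what <- match.arg(what)
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = object$scene_id) +
    ggplot2::theme_minimal()
  if (what == "class") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
      ggplot2::scale_fill_viridis_d(name = "Suitability", drop = FALSE)
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$prob)) +
      ggplot2::scale_fill_viridis_c(name = "P(presence)", limits = c(0, 1))
  }
}

#' Write a suitability map
#'
#' Writes the ordinal class grid (codes 1-5) and the probability grid as a
#' two-image TIFF with a JSON sidecar carrying the patch-level geotransform
#' and legend; or, with a `.json` path, the whole map as JSON.
#'
#' @param map A `suitability_map`.
#' @param path Output path (`.tif` or `.json`).
#' @return `path`, invisibly.
#' @export
write_suitability_map <- function(map, path) {
  stopifnot(inherits(map, "suitability_map"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(scene_id = map$scene_id,
                              geotransform = map$geotransform,
                              class_levels = map$class_levels,
                              prob = map$prob, class_idx = map$class_idx),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    # TIFF samples live in [0, 1]: class codes 1-5 stored as (code - 1) / 4
    cls <- matrix((as.double(map$class_idx) - 1) / 4, nrow(map$class_idx))
    imgs <- lapply(list(map$prob, cls), function(m) { m[is.na(m)] <- 0; m })
    tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
    jsonlite::write_json(list(scene_id = map$scene_id,
                              geotransform = map$geotransform,
                              class_levels = map$class_levels,
                              images = c("probability", "ordinal_class"),
                              class_encoding = "code = 1 + 4 * value"),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
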
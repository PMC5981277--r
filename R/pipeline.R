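#' End-to-end run configuration
#'
#' Bundles the per-stage configurations of the whole pipeline. The global
#' `seed` seeds every stage that was not given an explicit configuration, so
#' a run is reproducible from this one object.
#'
#' @param sim A [sim_config()] (default built from `seed`).
#' @param cleaning List: `max_speed_kmh`, `max_gap_h`, `interpolate`.
#' @param density A [density_params()].
#' @param split List: `train_pct`, `val_pct`, `test_pct`, `stratified`.
#' @param train A [train_config()].
#' @param svm An [svm_config()].
#' @param glcm A [glcm_config()].
#' @param methods Methods for the train/evaluate stages (see
#'   [run_baseline()]).
#' @param seed Global seed.
#' @param out_dir Output directory for all stage artifacts.
#' @return A `run_config` object.
#' @export
run_config <- function(sim = NULL, cleaning = NULL, density = NULL,
                       split = NULL, train = NULL, svm = NULL, glcm = NULL,
                       methods = c("mcnn", "mcnn_svm"), seed = 1L,
                       out_dir = "habsuit-run") {
  seed <- assert_count(seed, "seed")
  structure(list(
    sim = sim %||% sim_config(seed = seed),
    cleaning = utils::modifyList(list(max_speed_kmh = 120, max_gap_h = 24,
                                      interpolate = TRUE), cleaning %||% list()),
    density = density %||% density_params(),
    split = utils::modifyList(list(train_pct = 70, val_pct = 5,
                                   test_pct = 25, stratified = TRUE),
                              split %||% list()),
    train = train %||% train_config(seed = seed),
    svm = svm %||% svm_config(seed = seed),
    glcm = glcm %||% glcm_config(),
    methods = methods, seed = seed, out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Every top-level key mirrors an argument of [run_config()]; nested keys are
#' passed to the matching constructor.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  cfg <- run_config(
    sim = if (!is.null(y$sim)) do.call(sim_config, utils::modifyList(list(seed = seed), y$sim)),
    cleaning = y$cleaning,
    density = if (!is.null(y$density)) do.call(density_params, y$density),
    split = y$split,
    train = if (!is.null(y$train)) do.call(train_config, utils::modifyList(list(seed = seed), y$train)),
    svm = if (!is.null(y$svm)) do.call(svm_config, utils::modifyList(list(seed = seed), y$svm)),
    glcm = if (!is.null(y$glcm)) do.call(glcm_config, y$glcm),
    methods = y$methods %||% c("mcnn", "mcnn_svm"),
    seed = seed,
    out_dir = y$out_dir %||% "habsuit-run"
  )
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg
}

pipeline_stages <- c("simulate", "clean", "cluster", "build-samples",
                     "train", "evaluate", "predict-map")

stage_upstream <- list(
  "simulate" = character(),
  "clean" = "simulate",
  "cluster" = "clean",
  "build-samples" = c("cluster", "simulate"),
  "train" = "build-samples",
  "evaluate" = "train",
  "predict-map" = "train"
)

stage_dir <- function(cfg, stage) file.path(cfg$out_dir, stage)

stage_hash <- function(cfg, stage) {
  keep <- switch(stage,
    "simulate" = cfg[c("sim", "seed")],
    "clean" = cfg[c("sim", "cleaning", "seed")],
    "cluster" = cfg[c("sim", "cleaning", "density", "seed")],
    "build-samples" = cfg[c("sim", "cleaning", "density", "split", "seed")],
    "train" = cfg[c("sim", "cleaning", "density", "split", "train", "svm",
                    "glcm", "methods", "seed")],
    "evaluate" = cfg[c("sim", "cleaning", "density", "split", "train", "svm",
                       "glcm", "methods", "seed")],
    "predict-map" = cfg[c("sim", "cleaning", "density", "split", "train",
                          "svm", "methods", "seed")]
  )
  rlang::hash(keep)
}

write_stage_manifest <- function(cfg, stage, extra = list()) {
  m <- c(list(stage = stage, config_hash = stage_hash(cfg, stage),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("habsuit")),
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
         extra)
  jsonlite::write_json(m, file.path(stage_dir(cfg, stage), "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_up_to_date <- function(cfg, stage) {
  mf <- file.path(stage_dir(cfg, stage), "manifest.json")
  if (!file.exists(mf)) return(FALSE)
  m <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  identical(m$config_hash %||% "", stage_hash(cfg, stage))
}

require_upstream <- function(cfg, stage) {
  for (up in stage_upstream[[stage]]) {
    if (!file.exists(file.path(stage_dir(cfg, up), "manifest.json"))) {
      abort(sprintf("stage '%s' needs artifacts from stage '%s'; run that stage first.",
                    stage, up),
            class = "habsuit_stage_error")
    }
  }
}

#' Run one pipeline stage
#'
#' Executes a stage of the simulate -> clean -> cluster -> build-samples ->
#' train -> evaluate / predict-map pipeline, writing its artifacts under
#' `cfg$out_dir/<stage>/` together with a manifest recording the
#' configuration hash, seed and package version. Re-running a stage whose
#' manifest matches the current configuration is skipped unless
#' `force = TRUE`; a stage whose upstream artifacts are missing fails with an
#' error naming the stage to run first.
#'
#' @param stage One of `"simulate"`, `"clean"`, `"cluster"`,
#'   `"build-samples"`, `"train"`, `"evaluate"`, `"predict-map"`.
#' @param cfg A [run_config()].
#' @param force Re-run even when up to date.
#' @param verbose Emit progress messages.
#' @return The stage directory, invisibly.
#' @export
run_stage <- function(stage, cfg = run_config(), force = FALSE,
                      verbose = TRUE) {
  stage <- match.arg(stage, pipeline_stages)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) inform(paste0("[", stage, "] ", ...))
  if (!force && stage_up_to_date(cfg, stage)) {
    say("up-to-date; skipping (use force = TRUE to re-run).")
    return(invisible(stage_dir(cfg, stage)))
  }
  require_upstream(cfg, stage)
  dir.create(stage_dir(cfg, stage), recursive = TRUE, showWarnings = FALSE)
  sd <- function(s) stage_dir(cfg, s)

  if (stage == "simulate") {
    say("generating trajectories, scene and temperatures")
    tracks <- gen_trajectories(cfg$sim)
    write_tracks(tracks, file.path(sd(stage), "tracks.csv"))
    scene <- gen_raster(cfg$sim)
    write_scene(scene, file.path(sd(stage), "scene.tif"))
    stations <- sim_stations(cfg$sim)
    temps <- gen_temperature(cfg$sim, stations)
    readr::write_csv(temps, file.path(sd(stage), "temperature.csv"))
    write_stage_manifest(cfg, stage, list(n_fixes = nrow(tracks)))
  } else if (stage == "clean") {
    tracks <- read_tracks(file.path(sd("simulate"), "tracks.csv"))
    cleaned <- clean_tracks(tracks, max_speed_kmh = cfg$cleaning$max_speed_kmh,
                            max_gap_h = cfg$cleaning$max_gap_h,
                            interpolate = cfg$cleaning$interpolate)
    rep <- cleaning_report(cleaned)
    say(sprintf("removed %d, interpolated %d fixes", rep$removed, rep$added))
    readr::write_csv(select(cleaned, "animal", "lat", "lon", "time"),
                     file.path(sd(stage), "tracks_clean.csv"))
    jsonlite::write_json(rep, file.path(sd(stage), "report.json"),
                         auto_unbox = TRUE)
    write_stage_manifest(cfg, stage, rep)
  } else if (stage == "cluster") {
    tracks <- read_tracks(file.path(sd("clean"), "tracks_clean.csv"))
    stops <- cluster_stopovers(tracks, cfg$density)
    say(sprintf("%d stopovers", nrow(stops$stopovers)))
    write_stopovers(stops, file.path(sd(stage), "stopovers.csv"))
    write_stopovers(stops, file.path(sd(stage), "stopovers.geojson"))
    readr::write_csv(stops$assignments, file.path(sd(stage), "assignments.csv"))
    write_stage_manifest(cfg, stage,
                         list(n_stopovers = nrow(stops$stopovers)))
  } else if (stage == "build-samples") {
    scene <- read_scene(file.path(sd("simulate"), "scene.tif"))
    temps <- readr::read_csv(file.path(sd("simulate"), "temperature.csv"),
                             show_col_types = FALSE)
    members <- readr::read_csv(file.path(sd("cluster"), "assignments.csv"),
                               show_col_types = FALSE) %>%
      filter(!is.na(.data$stop_id))
    samples <- filter_scenes(list(scene)) %>%
      purrr::map(extract_patches) %>%
      bind_rows() %>%
      label_patches(members) %>%
      attach_temperature(temps, scene) %>%
      augment_samples() %>%
      split_samples(train_pct = cfg$split$train_pct,
                    val_pct = cfg$split$val_pct,
                    test_pct = cfg$split$test_pct,
                    seed = cfg$seed, stratified = cfg$split$stratified)
    say(sprintf("%d samples (%d positive)", nrow(samples),
                sum(samples$label == "positive")))
    write_samples(samples, sd(stage))
    write_stage_manifest(cfg, stage, list(n_samples = nrow(samples)))
  } else if (stage == "train") {
    samples <- read_samples(sd("build-samples"))
    for (method in cfg$methods) {
      say("training ", method)
      if (method == "glcm_svm") {
        tv <- samples[samples$split %in% c("train", "val"), , drop = FALSE]
        fit <- train_svm(glcm_feature_table(tv, cfg$glcm), tv$label, cfg$svm)
        saveRDS(fit, file.path(sd(stage), "glcm_svm.rds"))
        next
      }
      net <- switch(method,
        densenet = build_densenet(seed = cfg$seed),
        cnn = ,
        cnn_svm = build_mcnn(mcnn_config(include_temp = FALSE), seed = cfg$seed),
        build_mcnn(seed = cfg$seed))
      net <- train_mcnn(net, samples, cfg$train)
      save_mcnn(net, file.path(sd(stage), paste0(net_file(method), ".rds")))
      if (method %in% c("cnn_svm", "mcnn_svm")) {
        val <- samples[samples$split == "val", , drop = FALSE]
        if (nrow(val) == 0L) val <- samples[samples$split == "train", , drop = FALSE]
        fit <- train_svm(extract_features(net, val), val$label, cfg$svm)
        saveRDS(fit, file.path(sd(stage), paste0(method, ".rds")))
      }
    }
    write_stage_manifest(cfg, stage, list(methods = cfg$methods))
  } else if (stage == "evaluate") {
    samples <- read_samples(sd("build-samples"))
    test <- samples[samples$split == "test", , drop = FALSE]
    reports <- list()
    for (method in cfg$methods) {
      scores <- stage_scores(cfg, method, test, sd("train"))
      rep <- evaluate(scores, test$label)
      reports[[method]] <- glance(rep)
      say(sprintf("%s: accuracy %.3f, AUC %s", method, rep$accuracy,
                  fmt_or_na(rep$auc)))
    }
    out <- bind_rows(reports, .id = "method")
    readr::write_csv(out, file.path(sd(stage), "eval_report.csv"))
    jsonlite::write_json(out, file.path(sd(stage), "eval_report.json"),
                         dataframe = "rows", digits = NA)
    write_stage_manifest(cfg, stage)
  } else if (stage == "predict-map") {
    scene <- read_scene(file.path(sd("simulate"), "scene.tif"))
    temps <- readr::read_csv(file.path(sd("simulate"), "temperature.csv"),
                             show_col_types = FALSE)
    net <- load_mcnn(file.path(sd("train"), "mcnn.rds"))
    svm <- if (file.exists(file.path(sd("train"), "mcnn_svm.rds"))) {
      readRDS(file.path(sd("train"), "mcnn_svm.rds"))
    }
    m <- predict_map(scene, net, svm = svm, temps = temps)
    write_suitability_map(m, file.path(sd(stage), "suitability.tif"))
    write_suitability_map(m, file.path(sd(stage), "suitability.json"))
    say("map written")
    write_stage_manifest(cfg, stage)
  }
  invisible(stage_dir(cfg, stage))
}

net_file <- function(method) {
  switch(method, cnn = , cnn_svm = "cnn", densenet = "densenet", "mcnn")
}

stage_scores <- function(cfg, method, test, train_dir) {
  if (method == "glcm_svm") {
    fit <- readRDS(file.path(train_dir, "glcm_svm.rds"))
    return(predict(fit, glcm_feature_table(test, cfg$glcm), type = "prob"))
  }
  net_path <- file.path(train_dir, paste0(net_file(method), ".rds"))
  if (!file.exists(net_path)) {
    abort(sprintf("no trained model for '%s'; run stage 'train' first.", method),
          class = "habsuit_stage_error")
  }
  net <- load_mcnn(net_path)
  if (method %in% c("cnn_svm", "mcnn_svm")) {
    fit <- readRDS(file.path(train_dir, paste0(method, ".rds")))
    predict(fit, extract_features(net, test), type = "prob")
  } else {
    predict(net, test, type = "prob")$prob_positive
  }
}

#' Run the whole pipeline
#'
#' @param cfg A [run_config()].
#' @param stages Stages to run, in order.
#' @param force Re-run up-to-date stages.
#' @param verbose Progress messages.
#' @return `cfg$out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg = run_config(), stages = pipeline_stages,
                         force = FALSE, verbose = TRUE) {
  for (s in stages) run_stage(s, cfg, force = force, verbose = verbose)
  invisible(cfg$out_dir)
}
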
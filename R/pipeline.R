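#' Pipeline configuration
#'
#' Collects every tunable of the two-stage pipeline in one object that
#' round-trips losslessly through JSON.  Defaults follow the published
#' task parameterizations: for whole-image classification `sigma = 4`,
#' `kappa = 0.85`, `lambda = 0`; for detection `sigma = 3.5`,
#' `kappa = 0.4`, `lambda = 12`, 15-px patches and 2-px stage-2
#' smoothing; both use 50 iterations and a 0.001 response floor.
#'
#' @param task `"classify"` or `"detect"`.
#' @param sigma preprocessing Gaussian std (pixels).
#' @param kappa clustering similarity threshold.
#' @param lambda minimum cluster size.
#' @param patch_size keypoint patch side (detection).
#' @param scales resize-factor ladder (detection; length 1 = single
#'   scale).
#' @param smoothing_sigma stage-2 voting-kernel smoothing (pixels).
#' @param scale_sigma stage-2 scale-axis smoothing (scale steps).
#' @param n_iter steady-state iteration count.
#' @param response_floor steady-state response floor.
#' @param score_threshold detection score threshold.
#' @param seed integer seed for the synthetic data.
#' @param n_train,n_test glyph counts (classification data).
#' @param n_crops,n_scenes object-crop and scene counts (detection data).
#' @param n_classes glyph classes.
#' @param out output directory for artifacts.
#' @return object of class `pcbc_config` (a named list).
#' @export
pcbc_config <- function(task = c("classify", "detect"),
                        sigma = NULL, kappa = NULL, lambda = NULL,
                        patch_size = 15L, scales = 1,
                        smoothing_sigma = 2, scale_sigma = 0.5,
                        n_iter = 50L, response_floor = 0.001,
                        score_threshold = 0.01, seed = 1L,
                        n_train = 100L, n_test = 50L,
                        n_crops = 60L, n_scenes = 20L, n_classes = 10L,
                        out = "pcbc-out") {
  task <- match.arg(task)
  if (is.null(sigma)) sigma <- if (task == "classify") 4 else 3.5
  if (is.null(kappa)) kappa <- if (task == "classify") 0.85 else 0.4
  if (is.null(lambda)) lambda <- if (task == "classify") 0L else 12L
  structure(list(task = task, sigma = sigma, kappa = kappa,
                 lambda = as.integer(lambda),
                 patch_size = as.integer(patch_size), scales = scales,
                 smoothing_sigma = smoothing_sigma,
                 scale_sigma = scale_sigma, n_iter = as.integer(n_iter),
                 response_floor = response_floor,
                 score_threshold = score_threshold, seed = as.integer(seed),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_crops = as.integer(n_crops),
                 n_scenes = as.integer(n_scenes),
                 n_classes = as.integer(n_classes), out = out),
            class = "pcbc_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path file path.
#' @return a `pcbc_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pcbc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(pcbc_config, vals)
}

#' Write a pipeline configuration to a JSON file
#' @param config a `pcbc_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pcbc_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

log_event <- function(out, event, params) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  line <- jsonlite::toJSON(c(list(event = event,
                                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                             params),
                           auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = file.path(out, "run.log"), append = TRUE)
}

write_image_set <- function(images, labels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("img_%04d.pgm", seq_along(images))
  for (i in seq_along(images)) write_pgm(images[[i]], file.path(dir, files[i]))
  write.table(data.frame(file = files, label = labels), file.path(dir, "labels.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

read_image_set <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("missing labels file: ", lab_path)
  df <- read.table(lab_path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  images <- lapply(df$file, function(f) read_pgm(file.path(dir, f)))
  list(images = images, labels = as.character(df$label))
}

#' Run one pipeline step
#'
#' Subcommands: `make-data` (synthesize and write the datasets),
#' `build-dict` (cluster patches and save the dictionary), `train` (train
#' and save the full hierarchy), `classify` (predict test labels, write
#' predictions and metrics), `detect` (write detections for every scene),
#' `evaluate` (match detections against the ground truth and write
#' precision-recall/f/EER metrics; for the classification task, score
#' predictions).  Every step appends a structured record of the
#' parameters used to `<out>/run.log`.
#'
#' @param config a [pcbc_config()].
#' @param subcommand one of the above.
#' @return invisibly, a list of artifact paths written.
#' @export
run_pipeline <- function(config, subcommand = c("make-data", "build-dict",
                                                "train", "classify",
                                                "detect", "evaluate")) {
  stopifnot(inherits(config, "pcbc_config"))
  subcommand <- match.arg(subcommand)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_event(out, subcommand, unclass(config))
  fn <- switch(subcommand,
               "make-data" = pipeline_make_data,
               "build-dict" = pipeline_build_dict,
               "train" = pipeline_train,
               "classify" = pipeline_classify,
               "detect" = pipeline_detect,
               "evaluate" = pipeline_evaluate)
  invisible(fn(config))
}

pipeline_glyph_spec <- function(config) {
  if (config$task == "classify") {
    glyph_spec(n_classes = config$n_classes, seed = config$seed)
  } else {
    # the detection world mirrors a registered single-object task: modest
    # rotation/scale variation within the class, photometric variation on
    # top
    glyph_spec(n_classes = config$n_classes, jitter_deg = 4,
               scale_range = c(0.95, 1.05), seed = config$seed)
  }
}

pipeline_make_data <- function(config) {
  out <- config$out
  if (config$task == "classify") {
    ds <- make_glyph_dataset(pipeline_glyph_spec(config), config$n_train,
                             config$n_test)
    write_image_set(ds$train$images, ds$train$labels,
                    file.path(out, "data", "train"))
    write_image_set(ds$test$images, ds$test$labels,
                    file.path(out, "data", "test"))
    list(train = file.path(out, "data", "train"),
         test = file.path(out, "data", "test"))
  } else {
    gs <- pipeline_glyph_spec(config)
    crops <- make_object_crops(gs, config$n_crops, seed = gs$seed + 1L)
    sc <- make_scene_dataset(scene_spec(seed = gs$seed + 2L,
                                        scale_range = range(config$scales)),
                             gs, config$n_scenes)
    write_image_set(crops, rep("target", length(crops)),
                    file.path(out, "data", "crops"))
    write_image_set(sc$negatives, rep("non-target", length(sc$negatives)),
                    file.path(out, "data", "negatives"))
    write_image_set(sc$scenes, rep("scene", length(sc$scenes)),
                    file.path(out, "data", "scenes"))
    write_annotations(sc$annotations, file.path(out, "data", "annotations.txt"))
    list(crops = file.path(out, "data", "crops"),
         scenes = file.path(out, "data", "scenes"),
         annotations = file.path(out, "data", "annotations.txt"))
  }
}

pipeline_build_dict <- function(config) {
  out <- config$out
  patches <- if (config$task == "classify") {
    tr <- read_image_set(file.path(out, "data", "train"))
    extract_whole_image_patches(tr$images, tr$labels)
  } else {
    crops <- read_image_set(file.path(out, "data", "crops"))
    negs <- read_image_set(file.path(out, "data", "negatives"))
    c(extract_keypoint_patches(crops$images, crops$labels,
                               patch_size = config$patch_size,
                               scales = config$scales),
      extract_keypoint_patches(negs$images, negs$labels,
                               patch_size = config$patch_size,
                               scales = config$scales))
  }
  dict <- agglomerative_cluster(patches, config$kappa, config$lambda)
  dir.create(file.path(out, "model"), showWarnings = FALSE)
  path <- file.path(out, "model", "dictionary.rds")
  saveRDS(dict, path)
  list(dictionary = path)
}

pipeline_train <- function(config) {
  out <- config$out
  h <- if (config$task == "classify") {
    tr <- read_image_set(file.path(out, "data", "train"))
    pcbc_train_classifier(tr$images, tr$labels, sigma = config$sigma,
                          kappa = config$kappa, lambda_min = config$lambda,
                          n_iter = config$n_iter,
                          response_floor = config$response_floor)
  } else {
    crops <- read_image_set(file.path(out, "data", "crops"))
    negs <- read_image_set(file.path(out, "data", "negatives"))
    pcbc_train_detector(crops$images, negs$images, sigma = config$sigma,
                        kappa = config$kappa, lambda_min = config$lambda,
                        patch_size = config$patch_size,
                        scales = config$scales,
                        smoothing_sigma = config$smoothing_sigma,
                        scale_sigma = config$scale_sigma,
                        n_iter = config$n_iter,
                        response_floor = config$response_floor)
  }
  dir.create(file.path(out, "model"), showWarnings = FALSE)
  path <- file.path(out, "model", "hierarchy.rds")
  write_hierarchy(h, path)
  list(hierarchy = path)
}

pipeline_classify <- function(config) {
  out <- config$out
  h <- read_hierarchy(file.path(out, "model", "hierarchy.rds"))
  te <- read_image_set(file.path(out, "data", "test"))
  res <- classify(h, te$images)
  pred <- data.frame(file = sprintf("img_%04d.pgm", seq_along(te$images)),
                     label = te$labels, predicted = res$class)
  dir.create(file.path(out, "pred"), showWarnings = FALSE)
  ppath <- file.path(out, "pred", "predictions.csv")
  write.table(pred, ppath, sep = ",", row.names = FALSE, quote = FALSE)
  metrics <- list(task = "classify", n_test = length(te$labels),
                  classification_error = classification_error(res$class, te$labels))
  mpath <- file.path(out, "metrics.json")
  jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(predictions = ppath, metrics = mpath)
}

pipeline_detect <- function(config) {
  out <- config$out
  h <- read_hierarchy(file.path(out, "model", "hierarchy.rds"))
  sc <- read_image_set(file.path(out, "data", "scenes"))
  rows <- lapply(seq_along(sc$images), function(i) {
    d <- detect(h, sc$images[[i]], score_threshold = 0)
    if (nrow(d) == 0L) return(NULL)
    cbind(image = i, d)
  })
  dets <- do.call(rbind, c(list(data.frame(image = integer(0), row = numeric(0),
                                           col = numeric(0),
                                           scale_index = numeric(0),
                                           score = numeric(0))),
                           rows))
  dir.create(file.path(out, "pred"), showWarnings = FALSE)
  dpath <- file.path(out, "pred", "detections.csv")
  write.table(dets, dpath, sep = ",", row.names = FALSE, quote = FALSE)
  list(detections = dpath)
}

pipeline_evaluate <- function(config) {
  out <- config$out
  mpath <- file.path(out, "metrics.json")
  if (config$task == "classify") {
    ppath <- file.path(out, "pred", "predictions.csv")
    if (!file.exists(ppath)) stop("no predictions file at ", ppath,
                                  "; run the classify step first")
    pred <- read.table(ppath, sep = ",", header = TRUE, stringsAsFactors = FALSE)
    metrics <- list(task = "classify", n_test = nrow(pred),
                    classification_error = classification_error(pred$predicted,
                                                                pred$label))
  } else {
    dpath <- file.path(out, "pred", "detections.csv")
    if (!file.exists(dpath)) stop("no detections file at ", dpath,
                                  "; run the detect step first")
    dets <- read.table(dpath, sep = ",", header = TRUE)
    truth <- read_annotations(file.path(out, "data", "annotations.txt"))
    n_img <- config$n_scenes
    det_l <- lapply(seq_len(n_img), function(i) dets[dets$image == i, , drop = FALSE])
    tru_l <- lapply(seq_len(n_img), function(i) truth[truth$image == i, , drop = FALSE])
    curve <- pr_curve(det_l, tru_l)
    cpath <- file.path(out, "pr_curve.csv")
    write.table(curve, cpath, sep = ",", row.names = FALSE, quote = FALSE)
    fmax <- max(mapply(function(tp, fp, fn) if (tp + fp + fn == 0) NA else f_score(tp, fp, fn),
                       curve$tp, curve$fp, curve$fn), na.rm = TRUE)
    metrics <- list(task = "detect", n_truth = nrow(truth),
                    f_score = fmax, eer_percent = equal_error_rate(curve))
  }
  jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(metrics = mpath)
}

#' Command-line entry point
#'
#' Usage: `pcbc <subcommand> --config FILE [--seed N] [--out DIR]`, where
#' `<subcommand>` is one of `make-data`, `build-dict`, `train`,
#' `classify`, `detect`, `evaluate`.  Without `--config`, task defaults
#' are used (`--task classify|detect`).
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
pcbc_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) < 1L) stop("usage: pcbc <subcommand> [--config FILE] [--seed N] [--out DIR] [--task classify|detect]")
    sub <- argv[1L]
    opts <- list()
    i <- 2L
    while (i <= length(argv)) {
      key <- sub("^--", "", argv[i])
      if (i + 1L > length(argv)) stop("missing value for --", key)
      opts[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
    config <- if (!is.null(opts$config)) read_config(opts$config) else {
      pcbc_config(task = if (is.null(opts$task)) "classify" else opts$task)
    }
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) config$out <- opts$out
    run_pipeline(config, sub)
    0L
  }, error = function(e) {
    message("pcbc: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
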
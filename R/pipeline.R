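#' Configuration of a two-arm original-vs-corrected experiment
#'
#' One experiment generates (or loads) a labeled ROI dataset, then trains
#' and evaluates the SDAE classifier twice on exactly the same split and
#' with exactly the same seeded initial weights: once on the images as-is
#' (the "original" arm) and once after intensity-inhomogeneity correction
#' (the "corrected" arm). Any performance difference is then attributable
#' to the correction alone.
#'
#' @param n_benign,n_malignant Synthetic class sizes. Defaults 74 and 96
#'   (the private-style cohort).
#' @param test_fraction Held-out fraction. Default `27/170`.
#' @param bias_strength Injected bias peak amplitude. Default 0.15.
#' @param size ROI side length. Default 28.
#' @param speckle_sigma Speckle scale. Default 0.05.
#' @param data_seed Seed for dataset generation and the split.
#' @param correction List with `degree`, `cell_size`, `max_outer_iter`
#'   for [correct_image()], or the string `"off"` to skip the corrected
#'   arm's preprocessing (both arms then see identical data).
#' @param train An [sdae_config()]; its `seed` is shared by both arms.
#' @param out_dir Optional directory for metrics.json, per-arm prediction
#'   CSVs and a text summary.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_benign = 74, n_malignant = 96,
                              test_fraction = 27 / 170,
                              bias_strength = 0.15, size = 28,
                              speckle_sigma = 0.05, data_seed = 1L,
                              correction = list(degree = 2, cell_size = 4,
                                                max_outer_iter = 10),
                              train = sdae_config(), out_dir = NULL) {
  structure(list(n_benign = n_benign, n_malignant = n_malignant,
                 test_fraction = test_fraction,
                 bias_strength = bias_strength, size = size,
                 speckle_sigma = speckle_sigma,
                 data_seed = as.integer(data_seed),
                 correction = correction, train = train, out_dir = out_dir),
            class = "experiment_config")
}

# Correct every image in a list, silencing per-image fallback warnings into
# a count.
correct_image_set <- function(images, correction) {
  fallbacks <- 0L
  out <- lapply(images, function(img) {
    res <- withCallingHandlers(
      correct_image(img, degree = correction$degree,
                    cell_size = correction$cell_size,
                    max_outer_iter = correction$max_outer_iter),
      warning = function(w) {
        fallbacks <<- fallbacks + 1L
        invokeRestart("muffleWarning")
      })
    res$corrected
  })
  attr(out, "fallbacks") <- fallbacks
  out
}

#' Run the two-arm experiment
#'
#' Generates the seeded synthetic dataset, corrects the corrected arm's
#' train and test images, trains one SDAE per arm from identical initial
#' weights (same training seed), predicts on the held-out set, and reports
#' per-arm confusion counts, the five-metric suite, and loss traces.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_report`: `arms` (named list with
#'   `counts`, `metrics`, `predictions` data.frame, `train_accuracy`,
#'   `finetune_trace`, `init_checksum` per arm), `dataset_summary`, and
#'   the resolved `config`.
#' @export
run_experiment <- function(config) {
  ds <- make_dataset(config$n_benign, config$n_malignant,
                     config$test_fraction, seed = config$data_seed,
                     bias_strength = config$bias_strength,
                     size = config$size,
                     speckle_sigma = config$speckle_sigma)

  arms_data <- list(original = list(train = ds$train$images,
                                    test = ds$test$images))
  if (identical(config$correction, "off")) {
    arms_data$corrected <- arms_data$original
  } else {
    arms_data$corrected <- list(
      train = correct_image_set(ds$train$images, config$correction),
      test = correct_image_set(ds$test$images, config$correction))
  }

  arms <- lapply(names(arms_data), function(arm) {
    xs <- arms_data[[arm]]
    model <- train_sdae(images_to_matrix(xs$train), ds$train$labels,
                        config$train)
    pred_test <- predict(model, images_to_matrix(xs$test))
    pred_train <- predict(model, images_to_matrix(xs$train))
    counts <- confusion(ds$test$labels, pred_test$label)
    list(counts = counts,
         metrics = metric_suite(counts),
         predictions = data.frame(id = ds$test$ids,
                                  prob = pred_test$prob,
                                  pred_label = pred_test$label,
                                  true_label = ds$test$labels,
                                  arm = arm),
         train_accuracy = mean(pred_train$label == ds$train$labels),
         finetune_trace = model$finetune_trace,
         init_checksum = model$init_checksum,
         model = model)
  })
  names(arms) <- names(arms_data)

  report <- structure(
    list(arms = arms,
         dataset_summary = list(n_train = length(ds$train$labels),
                                n_test = length(ds$test$labels),
                                n_malignant_test = sum(ds$test$labels)),
         config = config),
    class = "experiment_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- lapply(report$arms, function(a)
    list(counts = unclass(a$counts),
         metrics = as.list(a$metrics),
         metrics_rounded = as.list(round_half_up(a$metrics)),
         train_accuracy = a$train_accuracy))
  jsonlite::write_json(
    list(schema = "sonodae-metrics/1", arms = metrics,
         dataset = report$dataset_summary),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  preds <- do.call(rbind, lapply(report$arms, `[[`, "predictions"))
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  cfg <- report$config
  cfg$train <- unclass(cfg$train)
  cfg$train$corruption <- unclass(cfg$train$corruption)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Two-arm original-vs-corrected experiment\n")
  cat(sprintf("  train n=%d, test n=%d (%d malignant)\n",
              x$dataset_summary$n_train, x$dataset_summary$n_test,
              x$dataset_summary$n_malignant_test))
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    m <- round_half_up(a$metrics)
    cat(sprintf(
      "  %-9s TP=%d TN=%d FP=%d FN=%d | acc %.2f prec %.2f rec %.2f spec %.2f F %.2f\n",
      arm, a$counts$TP, a$counts$TN, a$counts$FP, a$counts$FN,
      m["accuracy"], m["precision"], m["recall"], m["specificity"],
      m["f_measure"]))
  }
  invisible(x)
}
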
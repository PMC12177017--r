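# End-to-end orchestration: simulate/ingest -> label -> window -> features ->
# classify, per (position, window, frequency) grid cell, plus the
# accuracy-comparison regressions. These functions are the package's
# programmatic command surface.

#' Read a cohort configuration from YAML
#'
#' Field names mirror the arguments of [cohort_config()]; `behaviours` is a
#' list of mappings mirroring [behaviour_spec()].
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$behaviours)) {
    cfg$behaviours <- lapply(cfg$behaviours, function(b) do.call(behaviour_spec, b))
  }
  if (!is.null(cfg$transition_weights)) {
    cfg$transition_weights <- do.call(rbind, cfg$transition_weights)
  }
  do.call(cohort_config, cfg)
}

#' Simulate a cohort and write logger-style fixtures plus a manifest
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the file paths written (manifest last).
#' @export
simulate_cohort_to_dir <- function(config, out_dir) {
  cohort <- simulate_cohort(config)
  paths <- write_fixture(cohort$traces, cohort$annotations, out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ethoacc")),
    seed = config$seed, species = config$species,
    n_individuals = config$n_individuals,
    sample_rate_hz = config$sample_rate_hz,
    dynamic_range_g = config$dynamic_range_g,
    resolution_bits = config$resolution_bits,
    duration_s = config$duration_s,
    behaviours = behaviour_names(config),
    files = basename(paths))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest_path))
}

#' Read a fixture directory back into an in-memory cohort
#'
#' @param dir Directory written by [simulate_cohort_to_dir()] (or containing
#'   the same CSV dialects).
#' @param species Species label attached to the traces.
#' @return `list(traces = ..., annotations = ...)` as from [simulate_cohort()].
#' @export
read_cohort_dir <- function(dir, species = "unknown") {
  ann_files <- list.files(dir, pattern = "_annotations\\.csv$", full.names = TRUE)
  acc_files <- setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                       ann_files)
  traces <- list()
  for (f in acc_files) {
    tr <- read_accel_csv(f, species = species)
    traces[[paste(tr$individual_id, tr$position, sep = "_")]] <- tr
  }
  annotations <- list()
  for (f in ann_files) {
    ann <- read_annotation_csv(f)
    annotations[[ann$individual_id]] <- ann
  }
  list(traces = traces, annotations = annotations)
}

# Windows for one position at the native rate, ready for per-frequency reuse.
cohort_windows <- function(cohort, position, window_s, trim_s = 1) {
  out <- list()
  for (tr in cohort$traces) {
    if (tr$position != position) next
    ann <- cohort$annotations[[tr$individual_id]]
    if (is.null(ann)) next
    series <- align_labels(tr, ann, trim_s = trim_s)
    out <- c(out, segment(series, window_s))
  }
  out
}

#' Run the classification pipeline over a settings grid
#'
#' For every combination of position, window length and sampling frequency:
#' label the traces (trimming one second from each bout end), segment into
#' windows, downsample, compute the 18 summary metrics, drop behaviours seen
#' in three or fewer individuals, split 70/30 stratified by behaviour, tune
#' the forest by individual-blocked cross-validation, and evaluate on the
#' held-out test rows.
#'
#' @param cohort In-memory cohort (`list(traces, annotations)`), e.g. from
#'   [simulate_cohort()] or [read_cohort_dir()].
#' @param positions Positions to analyse.
#' @param window_s Window lengths (subset of 1, 2).
#' @param freqs Sampling frequencies (subset of 100, 50, 25, 12, 10, 8, 4, 2);
#'   must not be empty nor exceed the native rate.
#' @param train_fraction Training proportion of the stratified split.
#' @param mtry_grid Candidate `mtry` values for blocked-CV tuning.
#' @param n_trees Trees per forest.
#' @param seed Integer seed driving the split, up-sampling and forests.
#' @return A `pipeline_result`: `accuracy` (one row per grid cell with
#'   overall accuracy, minimum balanced accuracy, macro AUC, selected mtry,
#'   counts), `reports` (named `eval_report` list), `models` (named
#'   `trained_classifier` list), and a `manifest` of seeds and row counts.
#' @export
run_pipeline <- function(cohort, positions = c("scute1", "scute3"),
                         window_s = 2, freqs = c(100, 2),
                         train_fraction = 0.7, mtry_grid = c(2, 4, 6),
                         n_trees = 1000, seed = 1L) {
  if (length(freqs) == 0) stop("freqs must not be empty")
  if (!all(freqs %in% supported_freq_hz)) {
    stop("freqs must be a subset of ", paste(supported_freq_hz, collapse = ", "))
  }
  if (!all(window_s %in% supported_window_s)) stop("window_s must be 1 or 2")
  acc_rows <- list(); reports <- list(); models <- list(); log_rows <- list()
  for (pos in positions) {
    for (w in window_s) {
      native <- cohort_windows(cohort, pos, w)
      for (f in sort(freqs, decreasing = TRUE)) {
        cell <- sprintf("%s_w%g_f%g", pos, w, f)
        res <- tryCatch({
          wins <- lapply(native, resample, target_hz = f)
          tab <- build_feature_table(wins)
          tab <- filter_rare_behaviours(tab)
          if (nrow(tab) == 0) stop("no windows survive filtering")
          sp <- split_train_test(tab, train_fraction,
                                 seed = derive_seed(seed, 11L))
          model <- blocked_cv_tune(sp$train, mtry_grid = mtry_grid,
                                   n_trees = n_trees,
                                   seed = derive_seed(seed, 22L))
          report <- evaluate(model, sp$test)
          list(model = model, report = report,
               n_windows = length(wins), n_used = nrow(tab),
               n_classes = length(model$classes))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("grid cell %s failed: %s", cell, conditionMessage(res)))
          next
        }
        reports[[cell]] <- res$report
        models[[cell]] <- res$model
        acc_rows[[cell]] <- data.frame(
          species = cohort$traces[[1]]$species, position = pos,
          window_s = w, freq_hz = f,
          overall_accuracy = res$report$overall_accuracy,
          min_balanced_accuracy = min(res$report$balanced_accuracy),
          auc = res$report$auc, cv_auc = res$model$cv_auc,
          mtry = res$model$mtry, n_windows = res$n_windows,
          n_used = res$n_used, n_classes = res$n_classes,
          n_test = res$report$n_test, stringsAsFactors = FALSE)
        log_rows[[cell]] <- acc_rows[[cell]][c("position", "window_s", "freq_hz",
                                               "n_windows", "n_used", "n_classes")]
      }
    }
  }
  if (length(acc_rows) == 0) stop("no grid cell completed successfully")
  accuracy <- do.call(rbind, acc_rows)
  rownames(accuracy) <- NULL
  structure(
    list(accuracy = accuracy, reports = reports, models = models,
         manifest = list(seed = seed, positions = positions,
                         window_s = window_s, freqs = freqs,
                         train_fraction = train_fraction,
                         mtry_grid = mtry_grid, n_trees = n_trees,
                         cells = do.call(rbind, log_rows))),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d grid cells\n", nrow(x$accuracy)))
  print(x$accuracy[, c("position", "window_s", "freq_hz",
                       "overall_accuracy", "min_balanced_accuracy", "auc")],
        digits = 3)
  invisible(x)
}

#' Beta regression of pipeline accuracies on design factors
#'
#' Regresses overall accuracy (boundary-squeezed into the open unit interval)
#' on the requested design factors of an accuracy table — typically
#' `~ position` or `~ position * freq_hz` over several seeded pipeline runs —
#' and reports Wald tests plus Tukey-adjusted pairwise position contrasts.
#'
#' @param accuracy Accuracy table (rows from `pipeline_result$accuracy`,
#'   possibly stacked over seeds).
#' @param formula Mean-model formula; default `overall_accuracy ~ position`.
#' @param contrast_factor Factor for post-hoc contrasts (default "position").
#' @return `list(fit, wald, contrasts)`.
#' @export
accuracy_comparison <- function(accuracy,
                                formula = overall_accuracy ~ position,
                                contrast_factor = "position") {
  data <- accuracy
  for (v in c("position", "species")) {
    if (v %in% names(data)) data[[v]] <- factor(data[[v]])
  }
  fit <- fit_beta_regression(formula, data)
  list(fit = fit, wald = wald_tests(fit),
       contrasts = pairwise_contrasts(fit, contrast_factor))
}

#' Run the drag comparison from a CSV of solver outputs
#'
#' @param input_csv Path to a CSV accepted by [read_drag_csv()].
#' @param out_dir Optional directory; when given, the contrast table is
#'   written as `drag_contrasts.csv` and the full report as
#'   `drag_report.json`.
#' @return A `drag_report` (see [compare_drag()]).
#' @export
run_drag <- function(input_csv, out_dir = NULL) {
  obs <- read_drag_csv(input_csv)
  report <- compare_drag(obs)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(report$contrasts,
                     file.path(out_dir, "drag_contrasts.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(emmeans = as.list(report$emmeans),
           slopes = as.list(report$slopes),
           coefficients = wald_tests(report$fit),
           contrasts = report$contrasts),
      file.path(out_dir, "drag_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
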
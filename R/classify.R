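# Random-forest behaviour classification with individual-blocked
# cross-validation, up-sampling, and confusion-matrix evaluation.

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Drop behaviours observed in too few individuals
#'
#' A behaviour present in `max_individuals` (default 3) or fewer distinct
#' individuals is excluded, so every retained class appears in enough
#' individuals for a robust individual-blocked cross-validation design. The
#' exclusion is reported via `message()` and recorded in the `"excluded"`
#' attribute.
#'
#' @param table A feature table from [build_feature_table()].
#' @param max_individuals Exclusion threshold on the individual count.
#' @return The filtered table, with attribute `excluded` naming dropped
#'   behaviours.
#' @export
filter_rare_behaviours <- function(table, max_individuals = 3) {
  counts <- tapply(table$individual_id, table$behaviour,
                   function(ids) length(unique(ids)))
  rare <- names(counts)[counts <= max_individuals]
  if (length(rare)) {
    message("excluding behaviours observed in <= ", max_individuals,
            " individuals: ", paste(rare, collapse = ", "))
  }
  out <- table[!(table$behaviour %in% rare), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- rare
  out
}

#' Stratified train/test split
#'
#' Rows are partitioned class by class so that each behaviour contributes
#' `round(train_fraction * n_class)` rows to the training set, keeping the
#' class distribution balanced between the two sets. Data from the same
#' individual may appear in both sets (the comparative design pools
#' individuals); use the blocked cross-validation for individual-disjoint
#' validation.
#'
#' @param table Feature table.
#' @param train_fraction Proportion assigned to training (0 < f < 1).
#' @param seed Integer seed.
#' @return `list(train = ..., test = ...)`.
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  sizes <- table(table$behaviour)
  if (any(sizes < 2)) {
    stop("every behaviour class needs >= 2 rows to split; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  with_seed(seed, {
    train_idx <- integer(0)
    for (cls in names(sizes)) {
      idx <- which(table$behaviour == cls)
      n_tr <- max(1L, min(length(idx) - 1L,
                          as.integer(floor(train_fraction * length(idx) + 0.5))))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    train_idx <- sort(train_idx)
  })
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE])
}

#' Up-sample minority classes with replacement
#'
#' Every class is brought up to the majority-class count by random resampling
#' with replacement; all original rows are retained. Resampled copies keep
#' their `.row_id` and `individual_id` provenance tags, so the leakage guard
#' can still see where every training row came from.
#'
#' @param train Feature table (training rows).
#' @param seed Integer seed.
#' @return The up-sampled table.
#' @export
upsample <- function(train, seed = 1L) {
  if (nrow(train) == 0) return(train)
  sizes <- table(train$behaviour)
  target <- max(sizes)
  with_seed(seed, {
    extra_idx <- integer(0)
    for (cls in names(sizes)) {
      need <- target - sizes[[cls]]
      if (need > 0) {
        idx <- which(train$behaviour == cls)
        extra_idx <- c(extra_idx, sample(idx, need, replace = TRUE))
      }
    }
    extra_idx
  })
  out <- rbind(train, train[extra_idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Assert that no training row originates from a held-out individual
#'
#' The provenance guard of the blocked cross-validation: every training row
#' (including up-sampled copies, which keep their provenance tags) must come
#' from an individual other than the held-out one. Violations stop with an
#' error naming the individual and the offending row ids.
#'
#' @param train_rows Feature table used for fitting inside a fold.
#' @param holdout_individual Individual id of the fold's validation block.
#' @return Invisibly `TRUE` when clean.
#' @export
assert_no_leakage <- function(train_rows, holdout_individual) {
  bad <- train_rows$individual_id == holdout_individual
  if (any(bad)) {
    stop(sprintf(
      "leakage: %d training row(s) originate from held-out individual '%s' (row ids: %s)",
      sum(bad), holdout_individual,
      paste(utils::head(unique(train_rows$.row_id[bad]), 5), collapse = ", ")))
  }
  invisible(TRUE)
}

# Macro one-vs-rest AUC of a probability matrix against true labels.
# Classes lacking either positives or negatives in `truth` cannot be scored
# and are skipped; NA if nothing is scorable.
macro_ovr_auc <- function(truth, prob) {
  aucs <- c()
  for (cls in colnames(prob)) {
    pos <- truth == cls
    if (any(pos) && any(!pos)) {
      r <- pROC::roc(response = factor(pos, levels = c(FALSE, TRUE)),
                     predictor = prob[, cls], quiet = TRUE,
                     direction = "<", levels = c(FALSE, TRUE))
      aucs <- c(aucs, as.numeric(r$auc))
    }
  }
  if (length(aucs) == 0) NA_real_ else mean(aucs)
}

#' Tune and fit a random forest with individual-blocked cross-validation
#'
#' Folds are individuals: for each candidate `mtry`, each individual in turn
#' is held out, the forest is fitted on the remaining individuals' rows
#' (up-sampled inside the fold only — the held-out block is never resampled),
#' and macro one-vs-rest AUC is scored on the held-out individual. The `mtry`
#' with the highest mean AUC wins (ties to the smallest value), and the final
#' forest is refitted on the full up-sampled training set with impurity
#' variable importance.
#'
#' @param train Feature table (training rows, >= 2 individuals).
#' @param mtry_grid Candidate numbers of predictors per split.
#' @param n_trees Trees per forest (default 1000, the protocol maximum).
#' @param seed Integer seed.
#' @return A `trained_classifier`: the ranger model, class levels, selected
#'   `mtry`, `cv_auc` (mean blocked-CV AUC of the winner), the per-fold CV
#'   table, and the importance ranking over the 18 metrics.
#' @export
blocked_cv_tune <- function(train, mtry_grid = c(2, 4, 6), n_trees = 1000,
                            seed = 1L) {
  individuals <- unique(train$individual_id)
  if (length(individuals) < 2) stop("blocked CV needs >= 2 individuals")
  stopifnot(all(mtry_grid >= 1), all(mtry_grid <= length(feature_names)))
  classes <- sort(unique(train$behaviour))
  if (length(classes) < 2) {
    stop("training data holds fewer than 2 behaviour classes")
  }
  fit_data <- function(rows) {
    d <- rows[, c("behaviour", feature_names)]
    d$behaviour <- factor(d$behaviour, levels = classes)
    d
  }
  cv <- expand.grid(mtry = mtry_grid, fold = individuals,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cv$auc <- NA_real_
  for (i in seq_len(nrow(cv))) {
    ind <- cv$fold[i]
    tr <- train[train$individual_id != ind, , drop = FALSE]
    ho <- train[train$individual_id == ind, , drop = FALSE]
    tr_up <- upsample(tr, seed = derive_seed(seed, match(ind, individuals)))
    assert_no_leakage(tr_up, ind)
    fit <- ranger::ranger(
      dependent.variable.name = "behaviour", data = fit_data(tr_up),
      num.trees = n_trees, mtry = cv$mtry[i], probability = TRUE,
      seed = derive_seed(seed, 1000L + i), num.threads = 1)
    prob <- stats::predict(fit, data = fit_data(ho))$predictions
    cv$auc[i] <- macro_ovr_auc(ho$behaviour, prob)
  }
  grid <- sort(unique(mtry_grid))
  mean_auc <- vapply(grid, function(m) {
    mean(cv$auc[cv$mtry == m], na.rm = TRUE)
  }, numeric(1))
  names(mean_auc) <- grid
  best <- grid[which(mean_auc == max(mean_auc))[1]]  # ties -> smallest mtry
  train_up <- upsample(train, seed = derive_seed(seed, 555L))
  final <- ranger::ranger(
    dependent.variable.name = "behaviour", data = fit_data(train_up),
    num.trees = n_trees, mtry = best, probability = TRUE,
    importance = "impurity", seed = derive_seed(seed, 999L), num.threads = 1)
  structure(
    list(model = final, classes = classes, mtry = best, n_trees = n_trees,
         cv_auc = unname(mean_auc[as.character(best)]), cv_table = cv,
         importance = sort(final$variable.importance, decreasing = TRUE),
         seed = seed),
    class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> %d classes, mtry = %d, %d trees, blocked-CV AUC = %.3f\n",
              length(x$classes), x$mtry, x$n_trees, x$cv_auc))
  cat("top metrics:", paste(utils::head(names(x$importance), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a trained classifier on a test table
#'
#' Predictions are the maximum-probability class. Reports the truth-by-
#' prediction confusion matrix, overall accuracy, per-class balanced accuracy
#' (one-vs-rest mean of sensitivity and specificity), and macro one-vs-rest
#' AUC.
#'
#' @param model A `trained_classifier`.
#' @param test Feature table; its behaviours must be a subset of the model's
#'   classes.
#' @return An `eval_report`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "trained_classifier"))
  if (nrow(test) == 0) stop("empty test set")
  unknown <- setdiff(unique(test$behaviour), model$classes)
  if (length(unknown)) {
    stop("test contains classes unseen in training: ",
         paste(unknown, collapse = ", "))
  }
  d <- test[, feature_names]
  prob <- stats::predict(model$model, data = d)$predictions
  pred <- model$classes[max.col(prob, ties.method = "first")]
  truth <- factor(test$behaviour, levels = model$classes)
  pred <- factor(pred, levels = model$classes)
  confusion <- table(truth = truth, prediction = pred)
  eval_report(confusion, auc = macro_ovr_auc(test$behaviour, prob))
}

#' Build an evaluation report from a confusion matrix
#'
#' @param confusion Square count matrix, rows = truth, columns = prediction.
#' @param auc Optional macro one-vs-rest AUC to attach.
#' @return An `eval_report` with `overall_accuracy`, per-class
#'   `balanced_accuracy` ((sensitivity + specificity) / 2 in one-vs-rest
#'   form), and `n_test`.
#' @export
eval_report <- function(confusion, auc = NA_real_) {
  confusion <- as.matrix(as.table(confusion))
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  n <- sum(confusion)
  classes <- rownames(confusion)
  balanced <- vapply(seq_along(classes), function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    mean(c(sens, spec), na.rm = TRUE)
  }, numeric(1))
  names(balanced) <- classes
  structure(
    list(confusion = confusion,
         overall_accuracy = sum(diag(confusion)) / n,
         balanced_accuracy = balanced, auc = auc, n_test = n),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, overall accuracy = %.3f, macro AUC = %.3f\n",
              x$n_test, x$overall_accuracy, x$auc))
  cat("balanced accuracy per class:\n")
  print(round(x$balanced_accuracy, 3))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
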
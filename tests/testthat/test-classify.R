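# Rare-behaviour filtering, stratified splitting, up-sampling, blocked CV,
# and confusion-matrix evaluation.

test_that("behaviours in three or fewer individuals are excluded, four retained", {
  tab <- make_separable_table(k = 2, n_ind = 6, per = 4)
  rare3 <- tab[tab$behaviour == "beh1" | tab$individual_id %in%
                 sprintf("ind%02d", 1:3), ]
  out <- suppressMessages(filter_rare_behaviours(rare3))
  expect_identical(attr(out, "excluded"), "beh2")
  expect_false("beh2" %in% out$behaviour)

  rare4 <- tab[tab$behaviour == "beh1" | tab$individual_id %in%
                 sprintf("ind%02d", 1:4), ]
  out4 <- filter_rare_behaviours(rare4)
  expect_length(attr(out4, "excluded"), 0)
  expect_identical(sort(unique(out4$behaviour)), c("beh1", "beh2"))

  expect_length(attr(filter_rare_behaviours(tab), "excluded"), 0)
})

test_that("the stratified split respects class proportions and partitions rows", {
  tab <- make_separable_table(k = 3, n_ind = 5, per = 2)  # 10 rows per class
  sp <- split_train_test(tab, train_fraction = 0.7, seed = 4L)
  expect_identical(as.vector(table(sp$train$behaviour)), rep(7L, 3))
  expect_identical(as.vector(table(sp$test$behaviour)), rep(3L, 3))
  expect_identical(sort(c(sp$train$.row_id, sp$test$.row_id)), tab$.row_id)
  expect_length(intersect(sp$train$.row_id, sp$test$.row_id), 0)
  sp2 <- split_train_test(tab, train_fraction = 0.7, seed = 4L)
  expect_identical(sp$train$.row_id, sp2$train$.row_id)

  one_row <- tab[c(which(tab$behaviour == "beh1")[1],
                   which(tab$behaviour == "beh2")), ]
  expect_error(split_train_test(one_row), ">= 2 rows")
})

test_that("up-sampling equalises class counts and keeps all original rows", {
  tab <- make_separable_table(k = 2, n_ind = 5, per = 4)  # 20 rows per class
  train <- tab[c(which(tab$behaviour == "beh1"),
                 which(tab$behaviour == "beh2")[1:8]), ]
  up <- upsample(train, seed = 3L)
  expect_identical(as.vector(table(up$behaviour)), rep(20L, 2))
  expect_true(all(train$.row_id %in% up$.row_id))
  # copies keep provenance: every up-sampled row id existed in the input
  expect_true(all(up$.row_id %in% train$.row_id))
  # already balanced or single class: identity up to order
  expect_equal(nrow(upsample(tab, 1L)), nrow(tab))
  solo <- tab[tab$behaviour == "beh1", ]
  expect_identical(upsample(solo, 1L)$.row_id, solo$.row_id)
})

test_that("the leakage guard detects contaminated training folds", {
  tab <- make_separable_table(k = 2, n_ind = 4, per = 3)
  clean <- tab[tab$individual_id != "ind01", ]
  expect_no_error(assert_no_leakage(clean, "ind01"))
  dirty <- rbind(clean, tab[tab$individual_id == "ind01", ][1:2, ])
  expect_error(assert_no_leakage(dirty, "ind01"), "leakage.*ind01")
})

test_that("blocked CV uses one fold per individual and tunes mtry", {
  tab <- make_separable_table(k = 2, n_ind = 7, per = 6, seed = 2)
  model <- blocked_cv_tune(tab, mtry_grid = c(2, 4), n_trees = 100, seed = 1L)
  expect_identical(sort(unique(model$cv_table$fold)),
                   sprintf("ind%02d", 1:7))
  expect_equal(nrow(model$cv_table), 14)  # 7 folds x 2 mtry
  expect_true(model$mtry %in% c(2, 4))
  expect_length(model$importance, length(feature_names))
  single <- blocked_cv_tune(tab, mtry_grid = 3, n_trees = 50, seed = 1L)
  expect_equal(single$mtry, 3)
})

test_that("well-separated classes give near-perfect blocked-CV AUC", {
  tab <- make_separable_table(k = 3, n_ind = 6, per = 8, noise = 0.02)
  model <- blocked_cv_tune(tab, mtry_grid = 4, n_trees = 200, seed = 1L)
  expect_gte(model$cv_auc, 0.99)
  report <- evaluate(model, tab)
  expect_equal(report$overall_accuracy, 1)
})

test_that("individual-blocked scoring removes individual-driven optimism", {
  # Features carry individual signatures but no class signal: blocked CV must
  # hover near chance, while scoring a forest on rows from an individual it
  # trained on looks far better.
  set.seed(11)
  tab <- make_separable_table(k = 2, n_ind = 6, per = 10, noise = 1)
  tab[feature_names] <- lapply(tab[feature_names], function(x) {
    x + 3 * as.integer(factor(tab$individual_id)) %% 2
  })
  tab$behaviour <- paste0("beh", 1 + (seq_len(nrow(tab)) %% 2))
  blocked <- blocked_cv_tune(tab, mtry_grid = 4, n_trees = 200, seed = 2L)
  d <- tab[, c("behaviour", feature_names)]
  d$behaviour <- factor(d$behaviour)
  leaky_fit <- ranger::ranger(dependent.variable.name = "behaviour", data = d,
                              num.trees = 200, probability = TRUE, seed = 1,
                              num.threads = 1)
  ho <- tab$individual_id == "ind01"
  leaky_auc <- ethoacc:::macro_ovr_auc(
    tab$behaviour[ho], stats::predict(leaky_fit, data = d[ho, ])$predictions)
  expect_lt(blocked$cv_auc, 0.7)
  expect_gt(leaky_auc, 0.9)
})

test_that("evaluation reproduces hand-computed confusion-matrix statistics", {
  cm <- matrix(c(8, 2, 4, 6), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  rep <- eval_report(cm)
  expect_equal(rep$overall_accuracy, 0.7)
  expect_equal(unname(rep$balanced_accuracy["a"]), (0.8 + 0.6) / 2)
  expect_equal(unname(rep$balanced_accuracy["b"]), (0.6 + 0.8) / 2)
  expect_equal(rep$n_test, 20)

  perfect <- eval_report(diag(c(5, 7, 9)))
  expect_equal(perfect$overall_accuracy, 1)
  expect_true(all(perfect$balanced_accuracy == 1))
})

test_that("uniform random predictions score near chance accuracy", {
  set.seed(99)
  k <- 4
  accs <- replicate(200, {
    truth <- sample(letters[1:k], 60, replace = TRUE)
    pred <- sample(letters[1:k], 60, replace = TRUE)
    cm <- table(factor(truth, levels = letters[1:k]),
                factor(pred, levels = letters[1:k]))
    eval_report(cm)$overall_accuracy
  })
  expect_equal(mean(accs), 1 / k, tolerance = 0.02)
})

test_that("evaluation rejects unknown classes and empty tests", {
  tab <- make_separable_table(k = 2, n_ind = 4, per = 4)
  model <- blocked_cv_tune(tab, mtry_grid = 2, n_trees = 50, seed = 1L)
  expect_error(evaluate(model, tab[0, ]), "empty test set")
  bad <- tab[1:2, ]
  bad$behaviour <- "novel"
  expect_error(evaluate(model, bad), "unseen in training")
})
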
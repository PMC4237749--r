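test_that("make_meta_input width arithmetic and column bookkeeping", {
  ds <- generate(preset_paperlike(n_antigens = 4L,
                                  residues_per_antigen = c(40L, 50L),
                                  seed = 8L)) # 8 scores + 10 features
  both <- make_meta_input(ds, arch_spec("stack2"))
  expect_equal(ncol(both), 18)
  tools_only <- make_meta_input(ds, arch_spec("stack2",
                                              include_base_features = FALSE))
  expect_equal(ncol(tools_only), 8)
  feats_only <- make_meta_input(ds, arch_spec("stack2", use_score_block = FALSE))
  expect_equal(ncol(feats_only), 10)
  # the blocks are disjoint and their union is the full block
  expect_length(intersect(colnames(tools_only), colnames(feats_only)), 0)
  expect_setequal(c(colnames(tools_only), colnames(feats_only)),
                  colnames(both))
  expect_error(arch_spec("stack2", use_score_block = FALSE,
                         include_base_features = FALSE),
               "at least one")
})

test_that("fit_stack2 separates a separable fixture and is deterministic", {
  ds <- separable_dataset(n = 80, antigens = 8)
  for (lrn in c("tree", "knn", "svm")) {
    fit <- fit_stack2(ds, arch_spec("stack2", top_learner = lrn, seed = 3L))
    pred <- predict_meta(fit, ds)
    expect_equal(pred$label_hat, ds$labels,
                 label = paste("training accuracy 1.0 for", lrn))
  }

  hold <- toy_dataset(n = 60, antigens = 6, seed = 51)
  train <- toy_dataset(n = 120, antigens = 8, seed = 50)
  f1 <- fit_stack2(train, arch_spec("stack2", top_learner = "svm", seed = 9L))
  f2 <- fit_stack2(train, arch_spec("stack2", top_learner = "svm", seed = 9L))
  expect_equal(predict_meta(f1, hold)$score, predict_meta(f2, hold)$score)

  degenerate <- dataset_subset(train, rows = train$labels == 0)
  expect_error(fit_stack2(degenerate, arch_spec("stack2")), "single-class")
})

test_that("fit_stack3 builds a 3-column out-of-fold meta block", {
  ds <- toy_dataset(n = 150, antigens = 10, prevalence = 0.3, seed = 33)
  fit <- fit_stack3(ds, arch_spec("stack3", seed = 4L))
  expect_named(fit$models, c("tree", "knn", "ann"))
  expect_equal(fit$manifest$meta_columns,
               c("meta_tree", "meta_knn", "meta_ann"))
  # top learner input: 2 features + 2 scores + 3 meta columns
  expect_length(fit$manifest$top_columns, 7)

  # out-of-fold audit: no residue's meta feature came from a model that saw it
  for (aud in fit$manifest$oof) {
    for (fm in aud$fold_models) {
      expect_length(intersect(fm$train_idx, fm$predicted_idx), 0)
    }
    covered <- sort(unlist(lapply(aud$fold_models, `[[`, "predicted_idx")))
    expect_equal(covered, seq_len(nrow(ds$keys)))
  }

  expect_error(arch_spec("stack3", oof_folds = 1), "oof_folds")
  expect_error(arch_spec("stack3", level1_learners = c("tree", "knn")),
               "exactly 3")
})

test_that("oracle level-1 inputs propagate to a perfect top learner", {
  # the score block itself is an oracle; level-1 learners reproduce it and
  # the top learner inherits perfect training classification
  ds <- separable_dataset(n = 100, antigens = 10)
  fit <- fit_stack3(ds, arch_spec("stack3", include_base_features = FALSE,
                                  seed = 6L))
  pred <- predict_meta(fit, ds)
  m <- metrics(confusion(pred$label_hat, ds$labels))
  expect_equal(m$mcc, 1.0)
})

test_that("predict_meta is invariant to column permutation and handles empties", {
  train <- toy_dataset(n = 120, antigens = 8, n_scores = 3, seed = 60)
  test <- toy_dataset(n = 60, antigens = 6, n_scores = 3, seed = 61)
  fit <- fit_stack2(train, arch_spec("stack2", top_learner = "tree", seed = 2L))
  base <- predict_meta(fit, test)

  # permute score and feature columns in the input dataset
  perm <- test
  perm$scores <- perm$scores[, c(3, 1, 2)]
  perm$features <- perm$features[, c(2, 1)]
  expect_equal(predict_meta(fit, perm)$score, base$score)

  empty <- dataset_subset(test, rows = integer(0))
  expect_equal(nrow(predict_meta(fit, empty)), 0)

  # missing column errors by name
  broken <- test
  broken$scores <- broken$scores[, 1:2]
  expect_error(predict_meta(fit, broken), "s3")
})

test_that("label_hat always equals thresholding the score at 0.5", {
  train <- toy_dataset(n = 100, antigens = 8, seed = 70)
  test <- toy_dataset(n = 50, antigens = 5, seed = 71)
  for (kind in c("stack2", "stack3")) {
    fit <- fit_architecture(train, arch_spec(kind, seed = 3L))
    pred <- predict_meta(fit, test)
    expect_equal(pred$label_hat, as.integer(pred$score >= 0.5))
    expect_true(all(pred$threshold_used == 0.5))
  }
})

test_that("svm is the strongest stack2 meta learner on complementary data", {
  # comparative ordering on the generator's default complementarity:
  # mean CV MCC of svm >= each of tree/knn (ordering, not magnitudes)
  ds <- generate(small_train_config(71L))
  mccs <- sapply(c("svm", "tree", "knn"), function(lrn) {
    cross_validate(ds, arch_spec("stack2", top_learner = lrn, seed = 1L),
                   cv_spec(n_folds = 3, n_repeats = 1, seed = 5))$summary$mcc
  })
  expect_gte(mccs["svm"], max(mccs[c("tree", "knn")]) - 0.02)
})
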
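test_that("confusion counts match a brute-force loop oracle", {
  expect_equal(unclass(confusion(c(1, 0, 1), c(1, 0, 1)))[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 1L, FP = 0L, FN = 0L), ignore_attr = TRUE)
  cm <- confusion(c(0, 1, 0), c(1, 0, 1))
  expect_equal(cm$TP + cm$TN, 0)

  withr::with_seed(4, {
    pred <- as.integer(runif(100) < 0.4)
    truth <- as.integer(runif(100) < 0.3)
  })
  cm <- confusion(pred, truth)
  cells <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in seq_along(pred)) {
    cells[[if (pred[i] == 1 && truth[i] == 1) "TP"
           else if (pred[i] == 1) "FP"
           else if (truth[i] == 0) "TN" else "FN"]] <-
      cells[[if (pred[i] == 1 && truth[i] == 1) "TP"
             else if (pred[i] == 1) "FP"
             else if (truth[i] == 0) "TN" else "FN"]] + 1
  }
  expect_equal(c(TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN), cells)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("metrics reproduce the defining formulas and conventions", {
  cm <- epistack:::new_confusion(TP = 1, FP = 0, TN = 1, FN = 0)
  m <- metrics(cm)
  expect_equal(m$mcc, 1)
  expect_equal(m$fscore, 1)

  # identical mixed-class vectors: every measure is 1
  x <- c(1, 0, 1, 1, 0)
  m2 <- metrics(confusion(x, x))
  expect_equal(unlist(m2[c("tpr", "precision", "accuracy", "fscore", "mcc")]),
               c(tpr = 1, precision = 1, accuracy = 1, fscore = 1, mcc = 1))

  # random confusion matrices: agree with direct formulas; mcc in [-1, 1]
  withr::with_seed(12, reps <- replicate(20, sample(0:30, 4), simplify = FALSE))
  for (cells in reps) {
    cmr <- epistack:::new_confusion(cells[1], cells[2], cells[3], cells[4])
    mr <- metrics(cmr)
    expect_gte(mr$mcc, -1); expect_lte(mr$mcc, 1)
    expect_equal(mr$mcc, mcc_direct(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    if (mr$tpr + mr$precision > 0) {
      expect_equal(mr$fscore,
                   2 * mr$tpr * mr$precision / (mr$tpr + mr$precision),
                   tolerance = 1e-12)
      expect_lte(mr$fscore, max(mr$tpr, mr$precision) + 1e-12)
      expect_gte(mr$fscore, min(mr$tpr, mr$precision) - 1e-12)
    }
  }

  # label swap on balanced cells negates MCC
  cmb <- epistack:::new_confusion(TP = 10, FP = 3, TN = 10, FN = 3)
  swapped <- epistack:::new_confusion(TP = 3, FP = 10, TN = 3, FN = 10)
  expect_equal(metrics(swapped)$mcc, -metrics(cmb)$mcc, tolerance = 1e-12)

  # zero-division conventions
  none_pred <- metrics(confusion(c(0, 0, 0), c(1, 0, 1)))
  expect_equal(none_pred$precision, 0)
  expect_equal(none_pred$fscore, 0)
  expect_equal(none_pred$mcc, 0)
})

test_that("roc_auc equals the Mann-Whitney rank identity and handles edge cases", {
  # perfect separation
  truth <- c(rep(0L, 10), rep(1L, 10))
  expect_equal(roc_auc(c(rnorm(10), rnorm(10) + 100), truth)$auc, 1.0)
  # constant scores: chance
  expect_equal(roc_auc(rep(1, 20), truth)$auc, 0.5)
  expect_error(roc_auc(rnorm(5), rep(1L, 5)), "single class")

  withr::with_seed(31, {
    for (i in 1:20) {
      truth <- as.integer(runif(50) < 0.4)
      if (length(unique(truth)) < 2) next
      scores <- round(rnorm(50, mean = truth), 1) # ties likely
      expect_equal(roc_auc(scores, truth)$auc, auc_rank_oracle(scores, truth),
                   tolerance = 1e-10)
    }
  })
})

test_that("make_folds produces disjoint exhaustive grouped stratified folds", {
  ds <- generate(synthetic_config(n_antigens = 10L,
                                  residues_per_antigen = c(40L, 50L),
                                  epitope_fraction = 0.1, seed = 3L))
  spec <- cv_spec(n_folds = 5, n_repeats = 2, seed = 17)
  folds <- make_folds(ds, spec)
  expect_length(folds, 2)
  for (f in folds) {
    expect_length(f, nrow(ds$keys))
    expect_setequal(unique(f), 1:5)
    # grouped: all residues of an antigen share a fold
    per_antigen <- tapply(f, ds$keys$antigen_id, function(v) length(unique(v)))
    expect_true(all(per_antigen == 1))
    # 10 antigens over 5 folds -> 2 antigens each
    expect_equal(as.integer(tapply(ds$keys$antigen_id, f,
                                   function(a) length(unique(a)))),
                 rep(2L, 5))
  }
  expect_error(make_folds(ds, cv_spec(n_folds = 11)), "exceeds")
})

test_that("stratified folds keep epitope fractions near the global fraction", {
  ok <- 0L
  for (seed in 1:5) {
    ds <- generate(small_train_config(seed))
    f <- make_folds(ds, cv_spec(n_folds = 5, n_repeats = 1, seed = seed))[[1]]
    global <- mean(ds$labels)
    fracs <- tapply(ds$labels, f, mean)
    if (all(abs(fracs - global) <= 0.5 * global)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("cross_validate records one row per repeat x fold and averages them", {
  ds <- generate(synthetic_config(n_antigens = 10L,
                                  residues_per_antigen = c(40L, 50L),
                                  epitope_fraction = 0.15, seed = 6L))
  arch <- arch_spec("stack2", top_learner = "tree", seed = 2L)
  res <- cross_validate(ds, arch, cv_spec(n_folds = 5, n_repeats = 2, seed = 4))
  expect_equal(nrow(res$folds), 10)
  num_cols <- setdiff(names(res$folds), c("repeat_id", "fold"))
  expect_equal(unlist(res$summary[num_cols]),
               colMeans(res$folds[num_cols], na.rm = TRUE),
               tolerance = 1e-12)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res), res$summary)
})

test_that("an oracle score column drives CV MCC to 1", {
  tabs <- toy_tables(n = 150, antigens = 10, prevalence = 0.3, sep = Inf,
                     seed = 23)
  ds <- assemble_dataset(tabs$features, tabs$scores, tabs$labels)
  arch <- arch_spec("stack2", top_learner = "tree", include_base_features = FALSE,
                    seed = 1L)
  res <- cross_validate(ds, arch, cv_spec(n_folds = 3, n_repeats = 1, seed = 2))
  expect_equal(res$summary$mcc, 1.0)
})

test_that("paired_ttest matches the closed form and flags degeneracy", {
  a <- c(0.61, 0.58, 0.64, 0.60, 0.62)
  b <- c(0.55, 0.59, 0.60, 0.57, 0.58)
  out <- paired_ttest(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(abs(t_hand), df = length(d) - 1, lower.tail = FALSE)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, p_hand, tolerance = 1e-12)

  expect_warning(out2 <- paired_ttest(a, a), "zero variance")
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)

  # power sanity: a clear constant-plus-noise shift at n = 10 is significant
  withr::with_seed(2, {
    x <- rnorm(10)
    y <- x + 1 + rnorm(10, sd = 0.1)
  })
  expect_lt(paired_ttest(x, y)$p, 0.05)
})

test_that("reconstruct_confusion inverts rounded rates exactly", {
  # unique inversion
  cm <- reconstruct_confusion(0.194, 0.008, 0.520, P = 201, N = 4528)
  expect_equal(c(cm$TP, cm$FP, cm$TN, cm$FN), c(39, 36, 4492, 162))

  # trivial corner
  cm2 <- reconstruct_confusion(1.0, 0.0, 1.0, P = 10, N = 10)
  expect_equal(c(cm2$TP, cm2$FP), c(10, 0))

  # ambiguous case errors listing candidates unless a further rate is given
  expect_error(reconstruct_confusion(0.289, 0.050, 0.204, P = 201, N = 4528),
               "multiple consistent.*\\(58, 226\\), \\(58, 227\\)")
  cm3 <- reconstruct_confusion(0.289, 0.050, 0.204, P = 201, N = 4528,
                               mcc = 0.202)
  expect_equal(c(cm3$TP, cm3$FP), c(58, 227))

  # no solution
  expect_error(reconstruct_confusion(0.5, 0.5, 0.9999, P = 10, N = 10000),
               "no \\(TP, FP\\) pair|no integer counts")

  # round-trip property on random exact confusion matrices
  withr::with_seed(14, {
    for (i in 1:10) {
      P <- sample(50:300, 1); N <- sample(1000:5000, 1)
      TP <- sample(0:P, 1); FP <- sample(0:N, 1)
      m <- metrics(epistack:::new_confusion(TP, FP, N - FP, P - TP))
      got <- tryCatch(
        reconstruct_confusion(round(m$tpr, 3), round(m$fpr, 3),
                              round(m$precision, 3), P, N,
                              accuracy = round(m$accuracy, 3),
                              mcc = round(m$mcc, 3)),
        error = function(e) e
      )
      if (inherits(got, "confusion")) {
        expect_equal(c(got$TP, got$FP), c(TP, FP))
      } else {
        # reconstruction may legitimately stay ambiguous; it must say so
        expect_match(conditionMessage(got), "multiple consistent")
      }
    }
  })
})
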
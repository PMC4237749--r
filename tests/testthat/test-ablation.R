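# A cheap deterministic architecture for ablation mechanics.
ablation_arch <- function() {
  arch_spec("stack2", top_learner = "tree", seed = 5L)
}

test_that("backward elimination trace covers every component once", {
  train <- toy_dataset(n = 150, antigens = 10, n_scores = 3, prevalence = 0.3,
                       seed = 101)
  test <- toy_dataset(n = 90, antigens = 6, n_scores = 3, prevalence = 0.3,
                      seed = 102)
  trace <- backward_eliminate(train, c("s1", "s2", "s3"), ablation_arch(),
                              eval_holdout(test), "mcc")
  expect_equal(nrow(trace$steps), 3)
  expect_setequal(trace$steps$component, c("s1", "s2", "s3"))
  expect_false(anyDuplicated(trace$steps$component) > 0)
  expect_true(all(trace$steps$direction == "removed"))
  tab <- tidy(trace)
  expect_equal(tab$classifier[1], "(start)")
  expect_match(tab$classifier[2], "^\\\\")
})

test_that("greedy backward steps match brute-force single-removal enumeration", {
  train <- toy_dataset(n = 150, antigens = 10, n_scores = 3, prevalence = 0.3,
                       seed = 103)
  test <- toy_dataset(n = 90, antigens = 6, n_scores = 3, prevalence = 0.3,
                      seed = 104)
  arch <- ablation_arch()
  protocol <- eval_holdout(test)
  trace <- backward_eliminate(train, c("s1", "s2", "s3"), arch, protocol, "mcc")

  # independent brute force: at each state, evaluate every single removal
  remaining <- c("s1", "s2", "s3")
  for (i in seq_len(nrow(trace$steps))) {
    cand_mcc <- vapply(remaining, function(b) {
      keep <- setdiff(remaining, b)
      a <- arch
      tr <- train; pr <- protocol
      if (length(keep) > 0) {
        tr <- dataset_subset(train, score_cols = keep)
        pr$test <- dataset_subset(test, score_cols = keep)
      } else {
        a$use_score_block <- FALSE
      }
      fit <- fit_architecture(tr, a)
      pred <- predict_meta(fit, pr$test)
      metrics(confusion(pred$label_hat, pr$test$labels))$mcc
    }, numeric(1))
    worst <- names(cand_mcc)[which.min(cand_mcc)]
    expect_equal(trace$steps$component[i], worst)
    expect_equal(trace$steps$mcc[i], unname(min(cand_mcc)), tolerance = 1e-12)
    remaining <- setdiff(remaining, worst)
  }
})

test_that("forward selection picks the brute-force best addition each step", {
  train <- toy_dataset(n = 150, antigens = 10, n_scores = 4, prevalence = 0.3,
                       seed = 105)
  test <- toy_dataset(n = 90, antigens = 6, n_scores = 4, prevalence = 0.3,
                      seed = 106)
  arch <- ablation_arch()
  protocol <- eval_holdout(test)
  trace <- forward_select(train, start_set = "s1",
                          candidates = c("s2", "s3", "s4"),
                          arch, protocol, "mcc")
  expect_equal(nrow(trace$steps), 3)
  expect_true(all(trace$steps$direction == "added"))

  current <- "s1"
  remaining <- c("s2", "s3", "s4")
  for (i in seq_len(nrow(trace$steps))) {
    cand_mcc <- vapply(remaining, function(b) {
      keep <- sort(c(current, b))
      fit <- fit_architecture(dataset_subset(train, score_cols = keep), arch)
      pred <- predict_meta(fit, dataset_subset(test, score_cols = keep))
      metrics(confusion(pred$label_hat, test$labels))$mcc
    }, numeric(1))
    best <- names(cand_mcc)[which.max(cand_mcc)]
    expect_equal(trace$steps$component[i], best)
    current <- sort(c(current, best))
    remaining <- setdiff(remaining, best)
  }

  expect_error(forward_select(train, "s1", c("s1", "s2"), arch, protocol),
               "disjoint")
  one <- forward_select(train, character(0), "s2", arch, protocol)
  expect_equal(nrow(one$steps), 1)
  expect_equal(one$steps$component, "s2")
})

test_that("traces are deterministic given seed and measure", {
  train <- toy_dataset(n = 120, antigens = 8, n_scores = 3, seed = 107)
  test <- toy_dataset(n = 60, antigens = 6, n_scores = 3, seed = 108)
  t1 <- backward_eliminate(train, c("s1", "s2", "s3"), ablation_arch(),
                           eval_holdout(test), "mcc")
  t2 <- backward_eliminate(train, c("s1", "s2", "s3"), ablation_arch(),
                           eval_holdout(test), "mcc")
  expect_equal(t1$steps, t2$steps)
})

test_that("backward elimination removes a planted oracle first, noise last", {
  # one oracle column, one pure-noise column: removing the oracle must hurt
  # most (removed first); the noise column survives to the end
  hits <- 0L
  for (seed in 1:10) {
    withr::with_seed(seed, {
      keys <- key_block(240, antigens = 12)
      label <- as.integer(runif(240) < 0.25)
      if (sum(label) < 2) label[1:2] <- 1L
      scores <- tibble::tibble(
        oracle = as.numeric(label),
        noise = rnorm(240)
      )
      feats <- tibble::tibble(f1 = rnorm(240)) # uninformative features
      tabs <- list(
        features = dplyr::bind_cols(keys, feats),
        scores = dplyr::bind_cols(keys, scores),
        labels = dplyr::bind_cols(keys, tibble::tibble(label = label))
      )
    })
    ds <- assemble_dataset(tabs$features, tabs$scores, tabs$labels)
    idx <- ds$keys$antigen_id %in% sprintf("TST%02d_A", 1:8)
    train <- dataset_subset(ds, rows = idx)
    test <- dataset_subset(ds, rows = !idx)
    trace <- backward_eliminate(train, c("noise", "oracle"), ablation_arch(),
                                eval_holdout(test), "mcc")
    if (trace$steps$component[1] == "oracle") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("block ablation separates score-borne and feature-borne signal", {
  # only the score block carries signal here
  withr::with_seed(77, {
    keys <- key_block(300, antigens = 10)
    label <- as.integer(runif(300) < 0.25)
    tabs <- list(
      features = dplyr::bind_cols(keys, tibble::tibble(f1 = rnorm(300),
                                                       f2 = rnorm(300))),
      scores = dplyr::bind_cols(keys, tibble::tibble(
        s1 = rnorm(300) + 3 * label, s2 = rnorm(300) + 2 * label)),
      labels = dplyr::bind_cols(keys, tibble::tibble(label = label))
    )
  })
  ds <- assemble_dataset(tabs$features, tabs$scores, tabs$labels)
  idx <- ds$keys$antigen_id %in% sprintf("TST%02d_A", 1:6)
  train <- dataset_subset(ds, rows = idx)
  test <- dataset_subset(ds, rows = !idx)
  tab <- block_ablation(train, ablation_arch(), eval_holdout(test))
  expect_setequal(tab$model, c("full", "tool_based", "feature_based"))
  mcc <- setNames(tab$mcc, tab$model)
  expect_lt(mcc["feature_based"], 0.2)  # features carry no signal
  expect_gt(mcc["tool_based"], 0.5)
  expect_gt(mcc["full"], 0.5)
  expect_error(block_ablation(train,
                              arch_spec("stack2", include_base_features = FALSE),
                              eval_holdout(test)),
               "both blocks")
})
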
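# Internal wrappers giving the four meta learners (tree, knn, ann, svm) a
# uniform fit/predict-probability interface. Features are z-scored (training
# statistics only) for the distance/margin-based learners; the tree consumes
# raw values.

.learner_names <- c("tree", "knn", "ann", "svm")

.default_learner_control <- function() {
  list(
    knn_k = 3L,
    ann_size = 16L, ann_decay = 0.01, ann_maxit = 100L,
    svm_cost = 1, svm_gamma = NULL, # NULL = 1/ncol (libsvm default)
    svm_tune = FALSE, svm_tune_cost = c(0.5, 1, 4), svm_tune_gamma = NULL,
    class_weights = FALSE,
    tree_cp = 0.01, tree_minsplit = 20L
  )
}

.scale_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

.check_learner_input <- function(x, y) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2) {
    abort("degenerate training set: single-class labels")
  }
  if (is.null(colnames(x)) || any(colnames(x) == "")) {
    abort("learner input matrix must have column names")
  }
  invisible(NULL)
}

# y: integer 0/1. Returns an epi_learner object whose .predict_prob() gives
# P(label = 1).
.fit_learner <- function(name, x, y, control = list(), seed = 1L) {
  name <- match.arg(name, .learner_names)
  ctl <- modifyList(.default_learner_control(), control)
  .check_learner_input(x, y)
  yf <- factor(y, levels = c(0, 1))
  cw <- if (isTRUE(ctl$class_weights)) {
    w <- length(y) / (2 * table(yf)); setNames(as.numeric(w), names(w))
  } else NULL

  withr::with_seed(seed, {
    fit <- switch(
      name,
      tree = {
        df <- data.frame(.y = yf, x, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = ctl$tree_cp,
                                                    minsplit = ctl$tree_minsplit))
      },
      knn = {
        sc <- .scale_fit(x)
        list(train = .scale_apply(x, sc), y = yf, k = ctl$knn_k, scaling = sc)
      },
      ann = {
        sc <- .scale_fit(x)
        nnet::nnet(.scale_apply(x, sc), as.numeric(y),
                   size = ctl$ann_size, decay = ctl$ann_decay,
                   maxit = ctl$ann_maxit, entropy = TRUE, trace = FALSE,
                   MaxNWts = 20000)
      },
      svm = {
        sc <- .scale_fit(x)
        xs <- .scale_apply(x, sc)
        gamma <- ctl$svm_gamma %||% (1 / ncol(x))
        cost <- ctl$svm_cost
        if (isTRUE(ctl$svm_tune)) {
          gammas <- ctl$svm_tune_gamma %||% (gamma * c(0.25, 1, 4))
          tuned <- e1071::tune.svm(xs, yf, cost = ctl$svm_tune_cost,
                                   gamma = gammas, kernel = "radial",
                                   class.weights = cw)
          cost <- tuned$best.parameters$cost
          gamma <- tuned$best.parameters$gamma
        }
        e1071::svm(xs, yf, kernel = "radial", cost = cost, gamma = gamma,
                   probability = TRUE, class.weights = cw)
      }
    )
    if (name %in% c("ann", "svm")) attr(fit, "epistack_scaling") <- .scale_fit(x)
    structure(list(learner = name, fit = fit, columns = colnames(x), seed = seed),
              class = "epi_learner")
  })
}

# Realigns newx columns to the training manifest before predicting.
.predict_prob <- function(object, newx) {
  stopifnot(inherits(object, "epi_learner"), is.matrix(newx))
  missing <- setdiff(object$columns, colnames(newx))
  if (length(missing) > 0) {
    abort(paste0("prediction input missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  newx <- newx[, object$columns, drop = FALSE]
  if (nrow(newx) == 0) return(numeric(0))
  switch(
    object$learner,
    tree = {
      df <- data.frame(newx, check.names = FALSE)
      unname(predict(object$fit, newdata = df, type = "prob")[, "1"])
    },
    knn = {
      m <- object$fit
      xs <- .scale_apply(newx, m$scaling)
      pred <- class::knn(m$train, xs, m$y, k = m$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    ann = {
      sc <- attr(object$fit, "epistack_scaling")
      as.numeric(predict(object$fit, .scale_apply(newx, sc)))
    },
    svm = {
      sc <- attr(object$fit, "epistack_scaling")
      p <- predict(object$fit, .scale_apply(newx, sc), probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    }
  )
}

# Out-of-fold probability predictions: row i is predicted by the model whose
# training fold excluded i. Returns the oof vector plus bookkeeping for
# leakage audits.
.oof_predict <- function(name, x, y, control, n_folds, seed) {
  stopifnot(n_folds >= 2)
  ds <- new_epi_dataset(
    keys = tibble::tibble(antigen_id = as.character(seq_along(y)), chain = "A",
                          position = seq_along(y),
                          aa = rep("A", length(y))),
    features = x, scores = x[, 0, drop = FALSE], labels = y
  )
  fold_of <- make_folds(ds, cv_spec(n_folds = n_folds, n_repeats = 1L,
                                    stratified = TRUE, group_by_antigen = FALSE,
                                    seed = seed))[[1]]
  oof <- rep(NA_real_, length(y))
  fold_models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    if (length(unique(y[tr])) < 2) {
      abort(sprintf("out-of-fold split %d is single-class; use fewer folds", f))
    }
    m <- .fit_learner(name, x[tr, , drop = FALSE], y[tr], control,
                      seed = seed + f)
    oof[te] <- .predict_prob(m, x[te, , drop = FALSE])
    fold_models[[f]] <- list(train_idx = tr, predicted_idx = te)
  }
  list(oof = oof, fold_of = fold_of, fold_models = fold_models)
}

.meta_feature_values <- function(prob, form) {
  switch(form,
         probability = prob,
         score = prob,
         label = as.numeric(prob >= 0.5),
         abort(paste0("unknown meta_feature_form: ", form)))
}
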